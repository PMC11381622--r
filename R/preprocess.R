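#' Preprocessing configuration
#'
#' Defaults follow the pipeline's reference settings: a variable is dropped
#' when more than 25% of its cells are missing, a subject when more than 30%
#' of the surviving variables are missing; continuous modelling variables
#' with sample skewness above 1 are log(1+x)-transformed; iterative
#' imputation runs 10 round-robin passes.
#'
#' @param var_missing_threshold fraction in `[0, 1]`; variables with a missing
#'   fraction strictly greater than this are dropped.
#' @param subject_missing_threshold fraction in `[0, 1]`; subjects with a
#'   missing fraction (over surviving variables) strictly greater than this
#'   are dropped.
#' @param skew_threshold sample-skewness cutoff for the log transform.
#' @param imputation_rounds number of round-robin imputation passes.
#' @param seed integer seed recorded with the run.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(var_missing_threshold = 0.25,
                              subject_missing_threshold = 0.30,
                              skew_threshold = 1.0,
                              imputation_rounds = 10L,
                              seed = 0L) {
  stopifnot(var_missing_threshold >= 0, var_missing_threshold <= 1,
            subject_missing_threshold >= 0, subject_missing_threshold <= 1,
            imputation_rounds >= 1)
  structure(list(var_missing_threshold = var_missing_threshold,
                 subject_missing_threshold = subject_missing_threshold,
                 skew_threshold = skew_threshold,
                 imputation_rounds = as.integer(imputation_rounds),
                 seed = as.integer(seed)),
            class = "preprocess_config")
}

#' Mask invalid values and harmonise units
#'
#' Cells outside a variable's valid range are marked missing (e.g. a negative
#' heart rate); columns recorded in a non-canonical unit are rescaled by a
#' conversion factor (e.g. inches to centimetres with factor 2.54).
#'
#' @param table a [cohort_table()].
#' @param rules list of rules; each rule is a list with `variable` and either
#'   `valid_range = c(low, high)` or `factor` (multiplier) plus an optional
#'   `unit` naming the canonical unit after conversion.
#' @return A [cohort_table()] with invalid cells set to `NA` and converted
#'   columns rescaled; all other cells unchanged.
#' @export
apply_validity_and_units <- function(table, rules = list()) {
  stopifnot(inherits(table, "cohort_table"))
  for (rule in rules) {
    v <- rule$variable
    if (is.null(v) || !v %in% table$meta$name) {
      stop("rule refers to unknown variable: ", v %||% "<unnamed>")
    }
    col <- as.numeric(table$values[[v]])
    if (!is.null(rule$factor)) {
      col <- col * rule$factor
      if (!is.null(rule$unit)) {
        table$meta$unit[table$meta$name == v] <- rule$unit
      }
    }
    if (!is.null(rule$valid_range)) {
      lo <- rule$valid_range[[1]]
      hi <- rule$valid_range[[2]]
      col[!is.na(col) & (col < lo | col > hi)] <- NA_real_
      table$meta$valid_low[table$meta$name == v] <- lo
      table$meta$valid_high[table$meta$name == v] <- hi
    }
    table$values[[v]] <- col
  }
  table
}

#' Drop variables and subjects with excessive missingness
#'
#' Variables whose missing fraction strictly exceeds the variable threshold
#' are removed first; then subjects whose missing fraction over the surviving
#' variables strictly exceeds the subject threshold. Boundary cases (missing
#' fraction exactly at the threshold) are retained.
#'
#' @param table a [cohort_table()].
#' @param cfg a [preprocess_config()].
#' @return `list(table = filtered cohort_table, report = list(dropped_variables,
#'   dropped_subjects))`.
#' @export
filter_missingness <- function(table, cfg = preprocess_config()) {
  stopifnot(inherits(table, "cohort_table"))
  if (nrow(table$values) == 0L || ncol(table$values) == 0L) {
    stop("table is empty")
  }
  miss <- is.na(table$values)
  var_frac <- colMeans(miss)
  drop_vars <- colnames(table$values)[var_frac > cfg$var_missing_threshold]
  keep_vars <- setdiff(colnames(table$values), drop_vars)
  if (length(keep_vars) == 0L) {
    stop("empty after filtering: all variables removed")
  }
  sub_frac <- rowMeans(miss[, keep_vars, drop = FALSE])
  drop_rows <- which(sub_frac > cfg$subject_missing_threshold)
  drop_subjects <- table$subject_ids[drop_rows]
  keep_rows <- setdiff(seq_len(nrow(table$values)), drop_rows)
  if (length(keep_rows) == 0L) {
    stop("empty after filtering: all subjects removed")
  }
  out <- subset_cohort(table, subjects = keep_rows, variables = keep_vars)
  list(table = out,
       report = list(dropped_variables = drop_vars,
                     dropped_subjects = drop_subjects))
}

#' Log-transform positively skewed variables
#'
#' Each continuous modelling variable whose moment-based sample skewness
#' exceeds `skew_threshold` and whose non-missing values are all nonnegative
#' is replaced by `log(1 + x)`; the transform is monotone, so within-column
#' ranks are preserved. Variables with negative values are skipped and
#' reported.
#'
#' @param table a [cohort_table()].
#' @param skew_threshold skewness cutoff (default 1).
#' @return `list(table = , transformed = character vector, skipped = character
#'   vector of skewed-but-negative variables)`.
#' @export
transform_skewed <- function(table, skew_threshold = 1.0) {
  stopifnot(inherits(table, "cohort_table"))
  cand <- table$meta$name[table$meta$role == "modelling" &
                            table$meta$vtype == "continuous"]
  transformed <- character()
  skipped <- character()
  for (v in cand) {
    col <- as.numeric(table$values[[v]])
    sk <- sample_skewness(col)
    if (is.na(sk) || sk <= skew_threshold) next
    if (any(col < 0, na.rm = TRUE)) {
      skipped <- c(skipped, v)
      next
    }
    table$values[[v]] <- log1p(col)
    transformed <- c(transformed, v)
  }
  list(table = table, transformed = transformed, skipped = skipped)
}

#' Multivariate iterative imputation of the modelling variables
#'
#' Chained-equations style imputation: missing cells are initialised to the
#' column mean, then each incomplete modelling variable is regressed in turn
#' on all other modelling variables (ridge-stabilised least squares on the
#' observed rows) and its missing cells replaced by predictions, for
#' `cfg$imputation_rounds` full passes. Observed cells are never altered and
#' the procedure is deterministic.
#'
#' @param table a [cohort_table()] whose modelling variables each have at
#'   least one observed value.
#' @param cfg a [preprocess_config()].
#' @return `list(table = completed cohort_table, imputed_cell_count = integer)`.
#' @export
impute_cohort <- function(table, cfg = preprocess_config()) {
  stopifnot(inherits(table, "cohort_table"))
  vars <- modelling_variables(table)
  m <- modelling_matrix(table)
  miss <- is.na(m)
  all_missing <- colSums(!miss) == 0L
  if (any(all_missing)) {
    stop("modelling variable(s) with no observed values: ",
         paste(vars[all_missing], collapse = ", "))
  }
  n_imputed <- sum(miss)
  if (n_imputed > 0L) {
    mu <- colMeans(m, na.rm = TRUE)
    for (j in seq_along(vars)) {
      m[miss[, j], j] <- mu[j]
    }
    incomplete <- which(colSums(miss) > 0L)
    if (ncol(m) > 1L) {
      for (round in seq_len(cfg$imputation_rounds)) {
        for (j in incomplete) {
          obs <- !miss[, j]
          z <- m[, -j, drop = FALSE]
          zc <- scale(z[obs, , drop = FALSE], scale = FALSE)
          yc <- m[obs, j] - mean(m[obs, j])
          ridge <- 1e-8 * sum(obs)
          beta <- solve(crossprod(zc) + ridge * diag(ncol(zc)),
                        crossprod(zc, yc))
          pred <- mean(m[obs, j]) +
            (m[!obs, , drop = FALSE][, -j, drop = FALSE] -
               rep(attr(zc, "scaled:center"), each = sum(!obs))) %*% beta
          m[!obs, j] <- as.numeric(pred)
        }
      }
    }
    for (j in seq_along(vars)) {
      table$values[[vars[j]]] <- m[, j]
    }
  }
  list(table = table, imputed_cell_count = n_imputed)
}

#' Standardise continuous modelling variables
#'
#' z-scores each continuous modelling variable (mean 0, unit standard
#' deviation) and records the location/scale parameters so values can be
#' mapped back to the original units. GTM's spherical-noise model assumes
#' comparable variable scales, which this step provides.
#'
#' @param table a complete [cohort_table()].
#' @return `list(table = , scaler = data.frame(variable, center, scale))`.
#' @export
standardize_cohort <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  vars <- table$meta$name[table$meta$role == "modelling" &
                            table$meta$vtype == "continuous"]
  center <- numeric(length(vars))
  scale_ <- numeric(length(vars))
  for (i in seq_along(vars)) {
    col <- as.numeric(table$values[[vars[i]]])
    if (anyNA(col)) stop("standardize requires a complete table (", vars[i], ")")
    s <- stats::sd(col)
    if (!is.finite(s) || s <= .Machine$double.eps) {
      stop("zero-variance variable: ", vars[i])
    }
    center[i] <- mean(col)
    scale_[i] <- s
    table$values[[vars[i]]] <- (col - center[i]) / s
  }
  list(table = table,
       scaler = data.frame(variable = vars, center = center, scale = scale_,
                           stringsAsFactors = FALSE))
}

#' Invert a standardisation
#'
#' @param table a [cohort_table()] on the standardized scale.
#' @param scaler the `scaler` data.frame returned by [standardize_cohort()].
#' @return The table on the original scale.
#' @export
inverse_standardize <- function(table, scaler) {
  for (i in seq_len(nrow(scaler))) {
    v <- scaler$variable[i]
    table$values[[v]] <- as.numeric(table$values[[v]]) * scaler$scale[i] +
      scaler$center[i]
  }
  table
}

#' One-hot encode ordinal variables
#'
#' Replaces each named ordinal variable by one 0/1 indicator column per
#' observed level (named `<variable>.<level>`); the indicators sum to 1 for
#' every subject whose source value is non-missing, and are `NA` where it is
#' missing. The encoded columns are typed categorical, matching how ordinals
#' are treated in downstream group comparisons.
#'
#' @param table a [cohort_table()].
#' @param variables names of ordinal variables to encode.
#' @return A [cohort_table()] with the named variables replaced by indicators.
#' @export
encode_ordinals <- function(table, variables) {
  stopifnot(inherits(table, "cohort_table"))
  for (v in variables) {
    idx <- match(v, table$meta$name)
    if (is.na(idx)) stop("unknown variable: ", v)
    if (table$meta$vtype[idx] != "ordinal") {
      stop("variable is not ordinal: ", v)
    }
    col <- table$values[[v]]
    levels_ <- sort(unique(col[!is.na(col)]))
    ind <- sapply(levels_, function(l) as.numeric(col == l))
    ind <- matrix(ind, nrow = nrow(table$values), ncol = length(levels_))
    colnames(ind) <- paste0(v, ".", levels_)
    pos <- idx
    vals <- table$values
    before <- vals[, seq_len(pos - 1L), drop = FALSE]
    after <- if (pos < ncol(vals)) {
      vals[, seq(pos + 1L, ncol(vals)), drop = FALSE]
    } else {
      vals[, 0, drop = FALSE]
    }
    new_vals <- cbind(before, as.data.frame(ind, check.names = FALSE), after)
    old_row <- table$meta[idx, ]
    new_meta_rows <- do.call(rbind, lapply(colnames(ind), function(nm) {
      r <- old_row
      r$name <- nm
      r$vtype <- "categorical"
      r$valid_low <- NA_real_
      r$valid_high <- NA_real_
      r
    }))
    new_meta <- rbind(table$meta[seq_len(idx - 1L), ],
                      new_meta_rows,
                      if (idx < nrow(table$meta)) {
                        table$meta[seq(idx + 1L, nrow(table$meta)), ]
                      })
    table <- cohort_table(new_vals, new_meta, table$subject_ids)
  }
  table
}

#' Run the full preprocessing chain
#'
#' Applies, in order: validity masking and unit harmonisation, missingness
#' filtering (variables first, then subjects), log transformation of
#' positively skewed continuous modelling variables, multivariate iterative
#' imputation of the modelling variables, and standardisation.
#'
#' @param table a raw [cohort_table()].
#' @param cfg a [preprocess_config()].
#' @param rules validity/unit rules for [apply_validity_and_units()].
#' @return `list(table, scaler, report)` where `report` records dropped
#'   variables/subjects, log-transformed variables, imputed cell count and
#'   unit conversions.
#' @export
preprocess <- function(table, cfg = preprocess_config(), rules = list()) {
  conversions <- vapply(Filter(function(r) !is.null(r$factor), rules),
                        function(r) r$variable, character(1))
  table <- apply_validity_and_units(table, rules)
  filt <- filter_missingness(table, cfg)
  trans <- transform_skewed(filt$table, cfg$skew_threshold)
  imp <- impute_cohort(trans$table, cfg)
  std <- standardize_cohort(imp$table)
  report <- list(dropped_variables = filt$report$dropped_variables,
                 dropped_subjects = filt$report$dropped_subjects,
                 log_transformed = trans$transformed,
                 skew_skipped = trans$skipped,
                 imputed_cell_count = imp$imputed_cell_count,
                 unit_conversions = conversions,
                 seed = cfg$seed)
  list(table = std$table, scaler = std$scaler, report = report)
}
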