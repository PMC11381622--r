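# Seeded synthetic cohorts with the structure the GTM model assumes: cluster
# structure in a 2-D latent space mapped smoothly (low-order polynomial) into
# D dimensions with spherical Gaussian noise. Schema presets mimic the shape
# of a general-population biobank table (40 genomic principal components + 27
# biological assay variables) and a critical-care vitals/labs table (21
# variables); the presets carry realistic names only - no distributional
# claims about any real cohort are made.

ukb_like_names <- function() {
  c(paste0("pc", 1:40),
    c("albumin", "alkaline_phosphatase", "alanine_aminotransferase",
      "apolipoprotein_a", "apolipoprotein_b", "aspartate_aminotransferase",
      "c_reactive_protein", "calcium", "cholesterol", "creatinine",
      "cystatin_c", "direct_bilirubin", "gamma_glutamyltransferase",
      "glucose", "hba1c", "hdl_cholesterol", "igf1", "ldl_cholesterol",
      "lipoprotein_a", "phosphate", "shbg", "testosterone",
      "total_bilirubin", "total_protein", "triglycerides", "urate", "urea"))
}

mimic_like_names <- function() {
  c("heart_rate", "respiratory_rate", "temperature", "spo2",
    "systolic_bp", "diastolic_bp", "mean_bp", "glucose", "hemoglobin",
    "hematocrit", "platelet_count", "wbc", "sodium", "potassium",
    "chloride", "bicarbonate", "bun", "creatinine", "magnesium",
    "phosphate", "lactate")
}

#' Specification of a synthetic cohort
#'
#' @param n_subjects number of subjects.
#' @param n_dims number of modelling variables (overridden by non-generic
#'   schemas: `"ukb_like"` has 67, `"mimic_like"` 21).
#' @param n_clusters number of planted clusters (>= 1).
#' @param cluster_separation distance between adjacent cluster centres in the
#'   2-D latent space, in units of the within-cluster standard deviation (1).
#' @param noise_sd spherical observation-noise standard deviation in data
#'   space.
#' @param skewed_fraction fraction of modelling columns transformed to be
#'   positively skewed (exponentiated), to exercise the log-transform step.
#' @param missing_rate_cell completely-at-random per-cell missingness rate
#'   applied by [inject_missingness()].
#' @param missing_rate_var elevated missingness rate for designated columns
#'   (to exercise the variable filter).
#' @param n_investigative number of held-out investigative columns.
#' @param investigative_effect planted between-cluster mean shift of each
#'   investigative column, in within-cluster standard deviations (0 makes
#'   them independent of the clusters).
#' @param schema `"generic"`, `"ukb_like"` or `"mimic_like"`.
#' @param seed integer seed; generation is deterministic given the spec.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 500L, n_dims = 10L, n_clusters = 3L,
                        cluster_separation = 5, noise_sd = 1,
                        skewed_fraction = 0, missing_rate_cell = 0,
                        missing_rate_var = 0.5, n_investigative = 2L,
                        investigative_effect = 1,
                        schema = c("generic", "ukb_like", "mimic_like"),
                        seed = 0L) {
  schema <- match.arg(schema)
  stopifnot(n_subjects >= 1, n_clusters >= 1, cluster_separation >= 0,
            noise_sd >= 0, skewed_fraction >= 0, skewed_fraction <= 1,
            missing_rate_cell >= 0, missing_rate_cell <= 1,
            missing_rate_var >= 0, missing_rate_var <= 1,
            n_investigative >= 0)
  if (schema == "ukb_like") n_dims <- 67L
  if (schema == "mimic_like") n_dims <- 21L
  structure(list(n_subjects = as.integer(n_subjects),
                 n_dims = as.integer(n_dims),
                 n_clusters = as.integer(n_clusters),
                 cluster_separation = cluster_separation,
                 noise_sd = noise_sd, skewed_fraction = skewed_fraction,
                 missing_rate_cell = missing_rate_cell,
                 missing_rate_var = missing_rate_var,
                 n_investigative = as.integer(n_investigative),
                 investigative_effect = investigative_effect,
                 schema = schema, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort with planted cluster structure
#'
#' Latent points are drawn from `n_clusters` unit-variance Gaussian blobs in
#' 2-D whose adjacent centres sit `cluster_separation` apart; a seeded smooth
#' quadratic map carries them into `n_dims` dimensions, and spherical
#' Gaussian noise of sd `noise_sd` is added. A leading fraction of columns is
#' exponentiated to induce positive skew; investigative columns carry a
#' planted between-cluster mean shift of `investigative_effect` within-group
#' standard deviations plus unit noise.
#'
#' @param spec a [cohort_spec()].
#' @return `list(table = cohort_table, labels = integer planted cluster
#'   labels)`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  d <- spec$n_dims
  g <- spec$n_clusters
  centres <- if (g == 1L) {
    matrix(0, 1L, 2L)
  } else {
    r <- spec$cluster_separation / (2 * sin(pi / g))
    theta <- 2 * pi * (seq_len(g) - 1L) / g
    cbind(r * cos(theta), r * sin(theta))
  }
  labels <- rep_len(seq_len(g), n)
  z <- centres[labels, , drop = FALSE] + matrix(stats::rnorm(2 * n), n, 2L)
  # smooth low-order polynomial map into data space
  a_lin <- matrix(stats::rnorm(d * 2L), d, 2L)
  b_quad <- matrix(stats::rnorm(d * 3L, sd = 0.05), d, 3L)
  zq <- cbind(z[, 1]^2, z[, 2]^2, z[, 1] * z[, 2])
  x <- z %*% t(a_lin) + zq %*% t(b_quad) +
    matrix(stats::rnorm(n * d, sd = spec$noise_sd), n, d)
  n_skew <- round(spec$skewed_fraction * d)
  if (n_skew > 0L) {
    for (j in seq_len(n_skew)) {
      x[, j] <- exp(x[, j] / stats::sd(x[, j]))
    }
  }
  names_mod <- switch(spec$schema,
                      ukb_like = ukb_like_names(),
                      mimic_like = mimic_like_names(),
                      sprintf("v%02d", seq_len(d)))
  colnames(x) <- names_mod
  values <- as.data.frame(x)
  meta <- data.frame(name = names_mod, role = "modelling",
                     vtype = "continuous", stringsAsFactors = FALSE)
  if (spec$n_investigative > 0L) {
    offsets <- labels - (g + 1) / 2
    for (j in seq_len(spec$n_investigative)) {
      nm <- sprintf("inv%02d", j)
      values[[nm]] <- spec$investigative_effect * offsets + stats::rnorm(n)
      meta <- rbind(meta, data.frame(name = nm, role = "investigative",
                                     vtype = "continuous",
                                     stringsAsFactors = FALSE))
    }
  }
  table <- cohort_table(values, meta)
  list(table = table, labels = labels)
}

#' Inject missing values completely at random
#'
#' Sets modelling-variable cells missing at rate `spec$missing_rate_cell`;
#' columns named in `elevate` get the higher `spec$missing_rate_var` rate, to
#' exercise the missingness filters. Deterministic per seed.
#'
#' @param table a [cohort_table()].
#' @param spec a [cohort_spec()] (its `missing_rate_cell`, `missing_rate_var`
#'   and `seed` fields are used).
#' @param elevate character vector of columns to push to the elevated rate.
#' @return The table with injected `NA` cells.
#' @export
inject_missingness <- function(table, spec, elevate = character()) {
  stopifnot(inherits(table, "cohort_table"), inherits(spec, "cohort_spec"))
  set.seed(spec$seed + 1L)
  n <- nrow(table$values)
  for (v in modelling_variables(table)) {
    rate <- if (v %in% elevate) spec$missing_rate_var else spec$missing_rate_cell
    if (rate <= 0) next
    hit <- stats::runif(n) < rate
    col <- table$values[[v]]
    col[hit] <- NA
    table$values[[v]] <- col
  }
  table
}

#' Write a synthetic cohort to disk
#'
#' Emits the same CSV + metadata sidecar pair that [read_cohort()] consumes,
#' plus the planted labels as a separate CSV.
#'
#' @param cohort result of [generate_cohort()].
#' @param path cohort CSV path.
#' @param meta_path metadata sidecar path (YAML or JSON).
#' @param labels_path planted-labels CSV path (optional).
#' @return `path`, invisibly.
#' @export
write_synthetic_cohort <- function(cohort, path, meta_path,
                                   labels_path = NULL) {
  write_cohort(cohort$table, path, meta_path)
  if (!is.null(labels_path)) {
    utils::write.csv(data.frame(subject_id = cohort$table$subject_ids,
                                label = cohort$labels),
                     labels_path, row.names = FALSE)
  }
  invisible(path)
}
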