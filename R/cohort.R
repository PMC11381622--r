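#' Cohort table: subjects by variables with roles and types
#'
#' The central data container: one row per subject, one column per variable,
#' plus a metadata table assigning every variable a `role` (`"modelling"`
#' variables enter the GTM model; `"investigative"` variables are reserved for
#' post-hoc interpretation) and a `vtype` (`"continuous"`, `"categorical"` or
#' `"ordinal"`). Missing values are `NA`.
#'
#' @param values data.frame of variable columns (no subject-id column).
#' @param meta data.frame with columns `name`, `role`, `vtype` and optionally
#'   `unit`, `valid_low`, `valid_high`. One row per variable, matching the
#'   columns of `values` by name.
#' @param subject_ids character vector of unique subject identifiers; defaults
#'   to `"S1"..."SN"`.
#' @return An object of class `cohort_table` with elements `values`, `meta`
#'   and `subject_ids`.
#' @export
#' @examples
#' ct <- cohort_table(
#'   data.frame(hr = c(72, 80), age = c(61, 67)),
#'   data.frame(name = c("hr", "age"),
#'              role = c("modelling", "investigative"),
#'              vtype = "continuous")
#' )
cohort_table <- function(values, meta, subject_ids = NULL) {
  stopifnot(is.data.frame(values), is.data.frame(meta))
  values <- as.data.frame(values, stringsAsFactors = FALSE)
  meta <- normalize_meta(meta)
  if (is.null(subject_ids)) {
    subject_ids <- paste0("S", seq_len(nrow(values)))
  }
  subject_ids <- as.character(subject_ids)
  if (anyDuplicated(subject_ids)) {
    stop("subject_ids must be unique")
  }
  if (length(subject_ids) != nrow(values)) {
    stop("subject_ids length does not match number of rows")
  }
  if (anyDuplicated(meta$name)) {
    stop("variable names must be unique")
  }
  if (!setequal(meta$name, colnames(values))) {
    missing_meta <- setdiff(colnames(values), meta$name)
    extra_meta <- setdiff(meta$name, colnames(values))
    stop("metadata and value columns disagree (missing: ",
         paste(missing_meta, collapse = ", "), "; extra: ",
         paste(extra_meta, collapse = ", "), ")")
  }
  meta <- meta[match(colnames(values), meta$name), , drop = FALSE]
  rownames(meta) <- NULL
  bad_range <- !is.na(meta$valid_low) & meta$vtype != "continuous"
  if (any(bad_range)) {
    stop("valid_range is only allowed on continuous variables: ",
         paste(meta$name[bad_range], collapse = ", "))
  }
  bad_order <- !is.na(meta$valid_low) & !is.na(meta$valid_high) &
    meta$valid_low >= meta$valid_high
  if (any(bad_order)) {
    stop("valid_range must have low < high: ",
         paste(meta$name[bad_order], collapse = ", "))
  }
  structure(list(values = values, meta = meta, subject_ids = subject_ids),
            class = "cohort_table")
}

normalize_meta <- function(meta) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!all(c("name", "role", "vtype") %in% colnames(meta))) {
    stop("meta needs columns name, role, vtype")
  }
  meta$name <- as.character(meta$name)
  meta$role <- as.character(meta$role)
  meta$vtype <- as.character(meta$vtype)
  bad_role <- !meta$role %in% c("modelling", "investigative")
  if (any(bad_role)) {
    stop("unknown role for: ", paste(meta$name[bad_role], collapse = ", "))
  }
  bad_vtype <- !meta$vtype %in% c("continuous", "categorical", "ordinal")
  if (any(bad_vtype)) {
    stop("unknown vtype for: ", paste(meta$name[bad_vtype], collapse = ", "))
  }
  if (is.null(meta$unit)) meta$unit <- NA_character_
  if (is.null(meta$valid_low)) meta$valid_low <- NA_real_
  if (is.null(meta$valid_high)) meta$valid_high <- NA_real_
  meta$unit <- as.character(meta$unit)
  meta$valid_low <- as.numeric(meta$valid_low)
  meta$valid_high <- as.numeric(meta$valid_high)
  meta[, c("name", "role", "vtype", "unit", "valid_low", "valid_high")]
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d subjects x %d variables (%d modelling, %d investigative)\n",
              nrow(x$values), ncol(x$values),
              sum(x$meta$role == "modelling"),
              sum(x$meta$role == "investigative")))
  invisible(x)
}

#' @export
dim.cohort_table <- function(x) dim(x$values)

#' Names of the modelling / investigative variables
#' @param table a [cohort_table()].
#' @return Character vector of variable names.
#' @export
modelling_variables <- function(table) {
  table$meta$name[table$meta$role == "modelling"]
}

#' @rdname modelling_variables
#' @export
investigative_variables <- function(table) {
  table$meta$name[table$meta$role == "investigative"]
}

#' Numeric matrix of the modelling variables
#'
#' @param table a [cohort_table()].
#' @return N x D numeric matrix (subjects x modelling variables), with subject
#'   ids as row names.
#' @export
modelling_matrix <- function(table) {
  vars <- modelling_variables(table)
  m <- as.matrix(as.data.frame(lapply(table$values[vars], as.numeric)))
  colnames(m) <- vars
  rownames(m) <- table$subject_ids
  m
}

#' Subset a cohort table
#'
#' Row/column subsetting that keeps values, metadata and subject ids
#' consistent.
#'
#' @param table a [cohort_table()].
#' @param subjects row indices (or logical mask) to keep; `NULL` keeps all.
#' @param variables variable names to keep; `NULL` keeps all.
#' @return The subsetted [cohort_table()].
#' @export
subset_cohort <- function(table, subjects = NULL, variables = NULL) {
  values <- table$values
  ids <- table$subject_ids
  meta <- table$meta
  if (!is.null(variables)) {
    values <- values[, variables, drop = FALSE]
    meta <- meta[meta$name %in% variables, , drop = FALSE]
  }
  if (!is.null(subjects)) {
    values <- values[subjects, , drop = FALSE]
    ids <- ids[subjects]
  }
  rownames(values) <- NULL
  cohort_table(values, meta, ids)
}

#' Read / write a cohort table as CSV plus a metadata sidecar
#'
#' The CSV holds one `subject_id` column followed by one column per variable;
#' missing cells are empty or `NA`. The sidecar (YAML or JSON, by file
#' extension) lists one entry per variable with `name`, `role`, `vtype` and
#' optional `unit` and `valid_range`.
#'
#' @param path CSV file path.
#' @param meta_path sidecar path (`.yaml`/`.yml` or `.json`).
#' @return `read_cohort()` returns a [cohort_table()]; `write_cohort()`
#'   returns `path` invisibly.
#' @export
read_cohort <- function(path, meta_path) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  if (!"subject_id" %in% colnames(raw)) {
    stop("cohort CSV needs a subject_id column")
  }
  ids <- as.character(raw$subject_id)
  values <- raw[, setdiff(colnames(raw), "subject_id"), drop = FALSE]
  meta <- read_variable_meta(meta_path)
  cohort_table(values, meta, ids)
}

read_variable_meta <- function(meta_path) {
  ext <- tolower(tools::file_ext(meta_path))
  spec <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(meta_path)
  } else if (ext == "json") {
    jsonlite::read_json(meta_path, simplifyVector = FALSE)
  } else {
    stop("unsupported metadata format: ", ext)
  }
  entries <- spec$variables %||% spec
  meta <- do.call(rbind, lapply(entries, function(e) {
    vr <- e$valid_range
    data.frame(name = e$name, role = e$role, vtype = e$vtype,
               unit = e$unit %||% NA_character_,
               valid_low = if (is.null(vr)) NA_real_ else as.numeric(vr[[1]]),
               valid_high = if (is.null(vr)) NA_real_ else as.numeric(vr[[2]]),
               stringsAsFactors = FALSE)
  }))
  meta
}

#' @rdname read_cohort
#' @param table a [cohort_table()].
#' @export
write_cohort <- function(table, path, meta_path = NULL) {
  out <- cbind(subject_id = table$subject_ids, table$values)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  if (!is.null(meta_path)) {
    write_variable_meta(table$meta, meta_path)
  }
  invisible(path)
}

write_variable_meta <- function(meta, meta_path) {
  entries <- lapply(seq_len(nrow(meta)), function(i) {
    e <- list(name = meta$name[i], role = meta$role[i], vtype = meta$vtype[i])
    if (!is.na(meta$unit[i])) e$unit <- meta$unit[i]
    if (!is.na(meta$valid_low[i])) {
      e$valid_range <- c(meta$valid_low[i], meta$valid_high[i])
    }
    e
  })
  ext <- tolower(tools::file_ext(meta_path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(list(variables = entries), meta_path)
  } else if (ext == "json") {
    jsonlite::write_json(list(variables = entries), meta_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    stop("unsupported metadata format: ", ext)
  }
  invisible(meta_path)
}
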