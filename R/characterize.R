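# Post-hoc phenotype characterisation: descriptive summaries and
# between-group tests. Continuous variables are summarised by median and
# interquartile range and compared across phenotypes with the
# Kruskal-Wallis rank-sum test; categorical (and one-hot encoded ordinal)
# variables by counts/proportions and Pearson's chi-squared test. Raw
# p-values are thresholded at 0.05 with no multiple-testing adjustment by
# default (a Benjamini-Hochberg option is available).

#' Per-phenotype descriptive summaries
#'
#' Continuous variables: per-group n, median and quartiles (linear
#' interpolation, quantile type 7). Categorical/ordinal variables: per-level
#' count and percentage within each group. Missing values are excluded per
#' variable, with the non-missing n reported.
#'
#' @param table a [cohort_table()].
#' @param labels per-subject group labels, length N.
#' @return A long data.frame with columns `variable`, `vtype`, `group`,
#'   `level` (NA for continuous), `n`, `median`, `q1`, `q3`, `count`, `pct`.
#' @export
summarize_phenotypes <- function(table, labels) {
  stopifnot(inherits(table, "cohort_table"))
  if (length(labels) != nrow(table$values)) {
    stop("labels must have one entry per subject")
  }
  groups <- sort(unique(labels))
  rows <- list()
  for (i in seq_len(nrow(table$meta))) {
    v <- table$meta$name[i]
    vt <- table$meta$vtype[i]
    col <- table$values[[v]]
    for (g in groups) {
      gv <- col[labels == g]
      gv_ok <- gv[!is.na(gv)]
      if (vt == "continuous") {
        q <- if (length(gv_ok)) {
          stats::quantile(as.numeric(gv_ok), c(0.25, 0.5, 0.75), type = 7,
                          names = FALSE)
        } else {
          rep(NA_real_, 3)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, vtype = vt, group = g, level = NA_character_,
          n = length(gv_ok), median = q[2], q1 = q[1], q3 = q[3],
          count = NA_integer_, pct = NA_real_, stringsAsFactors = FALSE)
      } else {
        levels_ <- sort(unique(col[!is.na(col)]))
        for (lev in levels_) {
          cnt <- sum(gv_ok == lev)
          rows[[length(rows) + 1L]] <- data.frame(
            variable = v, vtype = vt, group = g, level = as.character(lev),
            n = length(gv_ok), median = NA_real_, q1 = NA_real_,
            q3 = NA_real_, count = cnt,
            pct = if (length(gv_ok)) 100 * cnt / length(gv_ok) else NA_real_,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Between-phenotype tests
#'
#' Continuous variables: Kruskal-Wallis H (midrank ties correction,
#' chi-squared reference with g-1 degrees of freedom). Categorical/ordinal
#' variables: Pearson chi-squared on the level x group contingency table
#' without continuity correction. Variables constant across all subjects are
#' skipped and reported as NA.
#'
#' @param table a [cohort_table()].
#' @param labels per-subject group labels with at least two non-empty groups.
#' @param adjust `"none"` (default, mirroring a raw p < 0.05 rule) or
#'   `"BH"` for Benjamini-Hochberg adjusted p-values in `p_adjusted`.
#' @param alpha significance threshold (default 0.05).
#' @return data.frame of class `comparison_table`: `variable`, `vtype`,
#'   `test`, `statistic`, `df`, `p_value`, (`p_adjusted`,) `significant`.
#' @export
compare_phenotypes <- function(table, labels, adjust = c("none", "BH"),
                               alpha = 0.05) {
  stopifnot(inherits(table, "cohort_table"))
  adjust <- match.arg(adjust)
  if (length(labels) != nrow(table$values)) {
    stop("labels must have one entry per subject")
  }
  if (length(unique(labels)) < 2L) stop("need at least 2 groups")
  rows <- lapply(seq_len(nrow(table$meta)), function(i) {
    v <- table$meta$name[i]
    vt <- table$meta$vtype[i]
    col <- table$values[[v]]
    ok <- !is.na(col)
    out <- data.frame(variable = v, vtype = vt, test = NA_character_,
                      statistic = NA_real_, df = NA_real_,
                      p_value = NA_real_, stringsAsFactors = FALSE)
    if (length(unique(col[ok])) < 2L || length(unique(labels[ok])) < 2L) {
      return(out)  # constant or single-group: skipped
    }
    if (vt == "continuous") {
      kw <- stats::kruskal.test(as.numeric(col[ok]), factor(labels[ok]))
      out$test <- "kruskal_wallis"
      out$statistic <- unname(kw$statistic)
      out$df <- unname(kw$parameter)
      out$p_value <- kw$p.value
    } else {
      tab <- table(factor(col[ok]), factor(labels[ok]))
      cs <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      out$test <- "chi_squared"
      out$statistic <- unname(cs$statistic)
      out$df <- unname(cs$parameter)
      out$p_value <- cs$p.value
    }
    out
  })
  res <- do.call(rbind, rows)
  if (adjust == "BH") {
    res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
    res$significant <- !is.na(res$p_adjusted) & res$p_adjusted < alpha
  } else {
    res$significant <- !is.na(res$p_value) & res$p_value < alpha
  }
  class(res) <- c("comparison_table", class(res))
  res
}

#' Export a characteristics table
#'
#' Writes a wide per-phenotype characteristics CSV (variable rows, one
#' column per phenotype holding `median (Q1-Q3)` or `count (pct%)`, plus the
#' test p-value column), mirroring the usual cohort-description layout.
#'
#' @param summary result of [summarize_phenotypes()].
#' @param comparison result of [compare_phenotypes()].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_characteristics <- function(summary, comparison, path) {
  groups <- sort(unique(summary$group))
  keys <- unique(summary[, c("variable", "vtype", "level")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    v <- keys$variable[i]
    lev <- keys$level[i]
    sub <- summary[summary$variable == v &
                     (is.na(lev) | (!is.na(summary$level) & summary$level == lev)), ]
    cells <- vapply(groups, function(g) {
      r <- sub[sub$group == g, ]
      if (nrow(r) == 0L) return("")
      if (keys$vtype[i] == "continuous") {
        sprintf("%.3g (%.3g-%.3g)", r$median, r$q1, r$q3)
      } else {
        sprintf("%d (%.1f%%)", r$count, r$pct)
      }
    }, character(1))
    p <- comparison$p_value[comparison$variable == v]
    data.frame(variable = if (is.na(lev)) v else paste0(v, ": ", lev),
               t(cells),
               p_value = if (length(p)) p[1] else NA_real_,
               stringsAsFactors = FALSE, check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  colnames(out) <- c("variable", paste0("phenotype_", groups), "p_value")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
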