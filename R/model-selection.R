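# Hyperparameter selection by cross-validated held-out negative
# log-likelihood over a grid of (latent side, RBF side, lambda) candidates.

#' A candidate hyperparameter configuration
#'
#' @param side latent lattice side (>= 2).
#' @param rbf_side RBF lattice side (>= 1).
#' @param lambda nonnegative regularisation weight.
#' @return A list of class `candidate_config`.
#' @export
candidate_config <- function(side, rbf_side, lambda = 1.0) {
  stopifnot(side >= 2, rbf_side >= 1, lambda >= 0)
  structure(list(side = as.integer(side), rbf_side = as.integer(rbf_side),
                 lambda = as.numeric(lambda)),
            class = "candidate_config")
}

#' The default candidate grid
#'
#' An illustrative search grid around the reference configuration; it always
#' contains the (side 15, 14 x 14 RBFs, lambda 1) setting used for cohort
#' phenotyping.
#'
#' @return data.frame with columns `side`, `rbf_side`, `lambda`.
#' @export
default_grid <- function() {
  g <- expand.grid(side = c(10L, 15L), rbf_side = c(10L, 14L),
                   lambda = c(0.1, 1, 10))
  g[order(g$side, g$rbf_side, g$lambda), , drop = FALSE]
}

# Seeded contiguous-block fold assignment after a single shuffle; fold sizes
# differ by at most 1.
make_folds <- function(n, folds, seed, shuffle = TRUE) {
  folds <- as.integer(folds)
  if (folds < 2L) stop("folds must be >= 2")
  if (folds > n) stop("folds must not exceed the number of subjects")
  perm <- if (shuffle) {
    set.seed(seed)
    sample.int(n)
  } else {
    seq_len(n)
  }
  sizes <- rep(n %/% folds, folds)
  extra <- n %% folds
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  split(perm, rep(seq_len(folds), times = sizes))
}

cv_score_folds <- function(x, config, fold_ids, seed, max_iter, tol, init) {
  vapply(fold_ids, function(test_idx) {
    train <- x[-test_idx, , drop = FALSE]
    test <- x[test_idx, , drop = FALSE]
    model <- gtm_fit(train, side = config$side, rbf_side = config$rbf_side,
                     lambda = config$lambda, seed = seed,
                     max_iter = max_iter, tol = tol, init = init)
    -gtm_e_step(model, test)$log_likelihood / nrow(test)
  }, numeric(1))
}

#' Cross-validated held-out negative log-likelihood of one configuration
#'
#' Subjects are shuffled once with `seed` and split into `folds` near-equal
#' contiguous blocks; for each fold a GTM is fitted on the complement and the
#' mean per-subject negative log-likelihood of the held-out fold under the
#' fitted mixture is recorded.
#'
#' @param data complete, standardized numeric matrix or [cohort_table()].
#' @param config a [candidate_config()] (or list with `side`, `rbf_side`,
#'   `lambda`).
#' @param folds number of folds (default 10).
#' @param seed integer seed for the fold shuffle and the fits.
#' @param max_iter,tol,init passed to [gtm_fit()].
#' @param shuffle set `FALSE` to split in input order (diagnostics only).
#' @return Numeric vector of per-fold test NLL values, length `folds`.
#' @export
cv_score <- function(data, config, folds = 10L, seed = 0L, max_iter = 200L,
                     tol = 1e-6, init = "pca", shuffle = TRUE) {
  x <- as_data_matrix(data)
  fold_ids <- make_folds(nrow(x), folds, seed, shuffle)
  unname(cv_score_folds(x, config, fold_ids, seed, max_iter, tol, init))
}

#' Grid search over candidate configurations
#'
#' Scores every candidate with [cv_score()] on a single shared fold
#' partition (a paired comparison). The default selection rule is a
#' one-standard-error rule: among configurations whose mean test NLL lies
#' within one standard error of the best mean, pick the one with the
#' smallest fold-to-fold standard deviation - rewarding both good held-out
#' fit and stability; ties break to the smaller latent grid, then the
#' smaller basis, then the larger lambda. `rule = "mean"` selects the best
#' mean outright (same tie-breaks).
#'
#' @param data complete, standardized numeric matrix or [cohort_table()].
#' @param grid data.frame with columns `side`, `rbf_side`, `lambda` (default
#'   [default_grid()]).
#' @param folds number of folds (default 10).
#' @param seed integer seed.
#' @param rule `"one_se"` (default) or `"mean"`.
#' @param max_iter,tol,init passed to [gtm_fit()].
#' @return A list of class `selection_result`: `table` (one row per
#'   candidate with per-fold NLLs, mean, sd, failed flag), `selected`
#'   ([candidate_config()]), `folds`, `seed`, `rule`.
#' @export
grid_search <- function(data, grid = default_grid(), folds = 10L, seed = 0L,
                        rule = c("one_se", "mean"), max_iter = 200L,
                        tol = 1e-6, init = "pca") {
  rule <- match.arg(rule)
  if (nrow(grid) == 0L) stop("empty candidate grid")
  x <- as_data_matrix(data)
  fold_ids <- make_folds(nrow(x), folds, seed, shuffle = TRUE)
  nf <- length(fold_ids)
  scores <- matrix(NA_real_, nrow(grid), nf,
                   dimnames = list(NULL, paste0("fold_", seq_len(nf))))
  failed <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- candidate_config(grid$side[i], grid$rbf_side[i], grid$lambda[i])
    res <- tryCatch(cv_score_folds(x, cfg, fold_ids, seed, max_iter, tol, init),
                    error = function(e) {
                      warning("candidate (", cfg$side, ", ", cfg$rbf_side,
                              ", ", cfg$lambda, ") failed: ",
                              conditionMessage(e), call. = FALSE)
                      NULL
                    })
    if (is.null(res) || any(!is.finite(res))) {
      failed[i] <- TRUE
    } else {
      scores[i, ] <- res
    }
  }
  if (all(failed)) stop("all candidate configurations failed")
  tab <- cbind(grid,
               as.data.frame(scores),
               mean = rowMeans(scores),
               sd = apply(scores, 1L, stats::sd),
               failed = failed)
  ok <- which(!failed)
  best <- ok[which.min(tab$mean[ok])]
  eligible <- if (rule == "one_se") {
    se_best <- tab$sd[best] / sqrt(nf)
    ok[tab$mean[ok] <= tab$mean[best] + se_best]
  } else {
    best
  }
  key <- if (rule == "one_se") tab$sd[eligible] else tab$mean[eligible]
  ord <- order(key, tab$side[eligible]^2, tab$rbf_side[eligible]^2,
               -tab$lambda[eligible])
  sel <- eligible[ord[1L]]
  structure(list(table = tab,
                 selected = candidate_config(tab$side[sel], tab$rbf_side[sel],
                                             tab$lambda[sel]),
                 folds = nf, seed = as.integer(seed), rule = rule),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d candidates, %d folds (rule: %s)\n",
              nrow(x$table), x$folds, x$rule))
  cat(sprintf("selected: side=%d rbf_side=%d lambda=%g\n",
              x$selected$side, x$selected$rbf_side, x$selected$lambda))
  invisible(x)
}

#' Export a selection result
#'
#' Writes the candidate table (config columns, per-fold NLLs, mean, sd) as
#' CSV and the selected configuration as JSON.
#'
#' @param result a `selection_result`.
#' @param csv_path,json_path output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_selection <- function(result, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(result$table, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    write_json_file(list(side = result$selected$side,
                         rbf_side = result$selected$rbf_side,
                         lambda = result$selected$lambda,
                         folds = result$folds, seed = result$seed,
                         rule = result$rule),
                    json_path)
  }
  invisible(c(csv_path, json_path))
}
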