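#' Derive macro-cluster phenotypes from a fitted GTM
#'
#' Two-level clustering: Ward's minimum-variance linkage (Euclidean metric)
#' of the K reference vectors merges the micro-clusters; cutting the
#' dendrogram at `k` labels every latent node with a phenotype, and each
#' subject inherits the phenotype of its maximum-responsibility node.
#' Clustering operates on the reference vectors in the (standardized) data
#' space, unweighted by node occupancy.
#'
#' @param model a fitted `gtm` model.
#' @param data the complete, standardized data the model was fitted on
#'   (matrix or [cohort_table()]).
#' @param k number of phenotypes (>= 2); a user decision, typically made by
#'   inspecting the dendrogram (see [suggest_k()] for an advisory heuristic).
#' @return A list of class `phenotype_assignment`: `k`, `node_labels`
#'   (length K), `micro` (per-subject node index), `subject_labels` (length
#'   N), `dendrogram`, and `empty_phenotypes` (phenotype ids with no
#'   subjects, which can legitimately occur when a phenotype's nodes attract
#'   no argmax assignments).
#' @export
derive_phenotypes <- function(model, data, k) {
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop("k must be >= 2")
  y <- reference_vectors(model)
  dend <- ward_linkage(y)
  node_labels <- cut_dendrogram(dend, k)
  micro <- assign_micro(model, data)
  subject_labels <- node_labels[micro]
  empty <- setdiff(seq_len(k), unique(subject_labels))
  structure(list(k = k, node_labels = node_labels, micro = micro,
                 subject_labels = subject_labels, dendrogram = dend,
                 empty_phenotypes = empty),
            class = "phenotype_assignment")
}

#' @export
print.phenotype_assignment <- function(x, ...) {
  cat(sprintf("<phenotype_assignment> %d phenotypes over %d nodes, %d subjects\n",
              x$k, length(x$node_labels), length(x$subject_labels)))
  tab <- table(factor(x$subject_labels, levels = seq_len(x$k)))
  cat("subjects per phenotype:", paste(tab, collapse = ", "), "\n")
  if (length(x$empty_phenotypes)) {
    cat("empty at subject level:", paste(x$empty_phenotypes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Export a phenotype assignment as CSV
#'
#' One row per subject: `subject_id`, `micro_node`, `phenotype`.
#'
#' @param assignment a [derive_phenotypes()] result.
#' @param table the [cohort_table()] providing subject ids (or `NULL` to use
#'   row numbers).
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_phenotypes <- function(assignment, table = NULL, path) {
  ids <- if (!is.null(table)) {
    table$subject_ids
  } else {
    paste0("S", seq_along(assignment$subject_labels))
  }
  out <- data.frame(subject_id = ids,
                    micro_node = assignment$micro,
                    phenotype = assignment$subject_labels)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
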