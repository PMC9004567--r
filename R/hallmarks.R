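#' Summarize hallmark-of-aging annotations over a target list
#'
#' Counts, for the genes in `targets` that carry at least one hallmark
#' annotation, how many are linked to each of the 12 hallmarks, which are
#' linked to two or more, and which to all twelve. Unannotated targets are
#' reported separately, not dropped silently.
#'
#' @param annotations Annotation table from [read_hallmark_annotations()]
#'   (or with the same columns).
#' @param targets Character vector of target gene symbols.
#' @return An object of class `hallmark_summary`: list with
#'   `per_hallmark_counts` (named integer vector over all 12 hallmarks),
#'   `multi_hallmark_genes`, `all_hallmark_genes`, `annotated_total`,
#'   `unannotated` (targets without any hallmark).
#' @export
summarize_hallmarks <- function(annotations, targets) {
  targets <- unique(norm_symbol(targets))
  idx <- match(targets, norm_symbol(annotations$gene))
  hl <- annotations$hallmarks[idx[!is.na(idx)]]
  genes <- targets[!is.na(idx)]
  n_hl <- vapply(hl, length, 0L)
  annotated <- genes[n_hl >= 1L]
  counts <- setNames(integer(length(HALLMARKS)), HALLMARKS)
  tab <- table(unlist(hl))
  counts[names(tab)] <- as.integer(tab)
  structure(list(
    per_hallmark_counts = counts,
    multi_hallmark_genes = sort(genes[n_hl >= 2L]),
    all_hallmark_genes = sort(genes[n_hl == length(HALLMARKS)]),
    annotated_total = length(annotated),
    annotated_genes = sort(annotated),
    unannotated = sort(setdiff(targets, annotated))),
    class = "hallmark_summary")
}

#' @export
print.hallmark_summary <- function(x, ...) {
  cat(sprintf("Hallmark summary: %d annotated target(s), %d unannotated\n",
              x$annotated_total, length(x$unannotated)))
  ord <- order(-x$per_hallmark_counts, names(x$per_hallmark_counts))
  top <- x$per_hallmark_counts[ord]
  top <- top[top > 0]
  if (length(top)) {
    cat("  per-hallmark counts:\n")
    for (i in seq_along(top))
      cat(sprintf("    %-38s %d\n", names(top)[i], top[i]))
  }
  if (length(x$all_hallmark_genes))
    cat("  all 12 hallmarks:", paste(x$all_hallmark_genes, collapse = ", "),
        "\n")
  invisible(x)
}

#' Select dual-purpose candidate targets
#'
#' A deterministic conjunctive rule engine over the upstream evidence. A
#' gene is retained when every enabled criterion holds:
#' \itemize{
#'   \item `require_hallmark`: at least one hallmark-of-aging annotation;
#'   \item `require_dual_purpose`: a same-direction consistency call in
#'     two or more AAD disease classes ([dual_purpose_filter()]);
#'   \item `require_safety`: no safety flag in the annotation table;
#'   \item `exclude_cancer_driver_antagonism`: a flagged cancer driver
#'     (e.g. a tumor suppressor) is excluded when the therapeutic direction
#'     would be antagonism — that is, when the gene's aging role is
#'     pro-aging, so the proposed therapy inhibits it.
#' }
#' The therapeutic rationale follows the annotated role: a pro-aging gene is
#' to be antagonized, an anti-aging gene agonized. Genes whose dual-purpose
#' call is direction-ambiguous are kept with `ambiguous = TRUE`, never
#' silently dropped.
#'
#' @param annotations Annotation table ([read_hallmark_annotations()]).
#' @param dual_calls Output of [dual_purpose_filter()].
#' @param targets Character vector restricting the candidate universe
#'   (e.g. the AAD-specific or full target list).
#' @param require_hallmark,require_dual_purpose,require_safety,exclude_cancer_driver_antagonism
#'   Individual criteria toggles, all on by default. Disabling a criterion
#'   can only enlarge the output.
#' @return A data.frame, one row per retained (gene, direction):
#'   `gene`, `novelty`, `hallmarks`, `direction`, `n_classes_consistent`,
#'   `direction_rationale`, `cancer_driver`, `safety_flag`, `ambiguous`.
#' @export
select_candidates <- function(annotations, dual_calls, targets,
                              require_hallmark = TRUE,
                              require_dual_purpose = TRUE,
                              require_safety = TRUE,
                              exclude_cancer_driver_antagonism = TRUE) {
  targets <- unique(norm_symbol(targets))
  base <- data.frame(gene = targets, stringsAsFactors = FALSE)
  idx <- match(base$gene, norm_symbol(annotations$gene))
  base$novelty <- annotations$novelty[idx]
  base$n_hallmarks <- ifelse(is.na(idx), 0L,
                             vapply(annotations$hallmarks[idx], length, 0L))
  base$hallmarks <- ifelse(is.na(idx), "",
                           vapply(annotations$hallmarks[idx],
                                  paste, "", collapse = ";"))
  base$role <- annotations$role[idx]
  base$cancer_driver <- ifelse(is.na(idx), FALSE,
                               annotations$cancer_driver[idx])
  base$safety_flag <- ifelse(is.na(idx), FALSE, annotations$safety_flag[idx])

  dp <- dual_calls
  dp$gene <- norm_symbol(dp$gene)
  dp <- dp[dp$gene %in% base$gene, , drop = FALSE]
  out <- merge(base, dp, by = "gene", all.x = TRUE)

  keep <- rep(TRUE, nrow(out))
  if (require_hallmark) keep <- keep & out$n_hallmarks >= 1L
  if (require_dual_purpose) keep <- keep & !is.na(out$direction)
  if (require_safety) keep <- keep & !out$safety_flag
  out$direction_rationale <- ifelse(
    !is.na(out$role) & out$role == "anti_aging",
    "anti_aging_agonize", "pro_aging_antagonize")
  if (exclude_cancer_driver_antagonism)
    keep <- keep & !(out$cancer_driver &
                     out$direction_rationale == "pro_aging_antagonize")
  out <- out[keep, , drop = FALSE]
  out$ambiguous <- !is.na(out$ambiguous) & out$ambiguous
  out <- out[order(out$gene, out$direction), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("gene", "novelty", "hallmarks", "direction",
          "n_classes_consistent", "direction_rationale", "cancer_driver",
          "safety_flag", "ambiguous")]
}
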