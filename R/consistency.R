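#' Per-class expression-consistency profiles
#'
#' For each (gene, disease class) the fraction of the gene's age-associated
#' case-control comparisons with positive and with negative logFC, and the
#' resulting direction call: `up` when the up-fraction reaches `threshold`,
#' `down` when the down-fraction does, otherwise `inconsistent`. The
#' comparison is inclusive (a fraction of exactly 0.60 meets the default
#' threshold), and a comparison with logFC exactly zero counts toward
#' neither direction.
#'
#' Only AAD-category records enter the profiles; NAAD records are used by
#' [compare_logfc_groups()] only.
#'
#' @param records Comparison records (see [read_comparisons()] or
#'   [gen_comparisons()]).
#' @param genes Optional character vector restricting the profiled genes.
#' @param threshold Consistency threshold in (0.5, 1]; default 0.60.
#' @return A data.frame with one row per observed (gene, disease_class):
#'   `gene`, `disease_class`, `n_comparisons`, `frac_up`, `frac_down`,
#'   `call`.
#' @export
consistency_profiles <- function(records, genes = NULL, threshold = 0.60) {
  if (threshold <= 0.5 || threshold > 1)
    stop("threshold must be in (0.5, 1]")
  rec <- records[records$category == "AAD", , drop = FALSE]
  if (!is.null(genes)) rec <- rec[rec$gene %in% genes, , drop = FALSE]
  if (!nrow(rec)) stop("no AAD comparison records for the requested genes")
  key <- interaction(rec$gene, rec$disease_class, drop = TRUE, sep = "\r")
  n <- as.integer(tapply(rec$logfc, key, length))
  up <- as.integer(tapply(rec$logfc > 0, key, sum))
  down <- as.integer(tapply(rec$logfc < 0, key, sum))
  parts <- strsplit(levels(key), "\r", fixed = TRUE)
  out <- data.frame(
    gene = vapply(parts, `[`, "", 1L),
    disease_class = vapply(parts, `[`, "", 2L),
    n_comparisons = n,
    frac_up = up / n,
    frac_down = down / n,
    stringsAsFactors = FALSE)
  out$call <- ifelse(out$frac_up >= threshold, "up",
                     ifelse(out$frac_down >= threshold, "down",
                            "inconsistent"))
  out <- out[order(out$gene, out$disease_class), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  out
}

#' Consistency profile of one gene in one disease class
#'
#' Scalar convenience wrapper around [consistency_profiles()].
#'
#' @inheritParams consistency_profiles
#' @param gene Gene symbol.
#' @param disease_class One of the disease-class vocabulary terms.
#' @return A one-row data.frame as in [consistency_profiles()].
#' @export
consistency_profile <- function(records, gene, disease_class,
                                threshold = 0.60) {
  prof <- consistency_profiles(records, genes = gene, threshold = threshold)
  row <- prof[prof$disease_class == disease_class, , drop = FALSE]
  if (!nrow(row))
    stop("no AAD comparison records for gene ", gene, " in class ",
         disease_class)
  rownames(row) <- NULL
  row
}

#' Dual-purpose filter over consistency profiles
#'
#' A gene passes when it is consistently dysregulated in the same direction
#' in at least `min_classes` disease classes. A gene that (pathologically)
#' reaches `min_classes` in both directions is emitted once per direction
#' with `ambiguous = TRUE`, never silently dropped.
#'
#' @param profiles Output of [consistency_profiles()].
#' @param min_classes Minimum number of same-direction consistent classes
#'   (default 2).
#' @return A data.frame with columns `gene`, `direction`,
#'   `n_classes_consistent`, `classes` (semicolon-joined), `ambiguous`;
#'   zero rows if nothing passes.
#' @export
dual_purpose_filter <- function(profiles, min_classes = 2L) {
  if (min_classes < 1L) stop("min_classes must be >= 1")
  res <- list()
  for (dir in c("up", "down")) {
    hit <- profiles[profiles$call == dir, , drop = FALSE]
    if (!nrow(hit)) next
    cls <- tapply(hit$disease_class, hit$gene,
                  function(x) sort(unique(x)), simplify = FALSE)
    nc <- vapply(cls, length, 0L)
    keep <- nc >= min_classes
    if (!any(keep)) next
    res[[dir]] <- data.frame(
      gene = names(cls)[keep],
      direction = dir,
      n_classes_consistent = as.integer(nc[keep]),
      classes = vapply(cls[keep], paste, "", collapse = ";"),
      stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(gene = character(), direction = character(),
               n_classes_consistent = integer(), classes = character(),
               stringsAsFactors = FALSE)
  out$ambiguous <- out$gene %in% out$gene[duplicated(out$gene)]
  out <- out[order(out$gene, out$direction), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare a gene's logFC between disease categories
#'
#' Two-sample two-tailed t-test of the gene's logFC values in AAD versus
#' NAAD comparisons. The Welch (unequal-variance) variant is the default;
#' `var.equal = TRUE` gives the classical Student test.
#'
#' @param records Comparison records covering both categories.
#' @param gene Gene symbol.
#' @param var.equal Assume equal variances? Default `FALSE` (Welch).
#' @return A one-row data.frame: `gene`, `t_statistic`, `df`, `p_value`,
#'   `n_aad`, `n_naad`, `mean_logfc_aad`, `mean_logfc_naad`.
#' @export
compare_logfc_groups <- function(records, gene, var.equal = FALSE) {
  rec <- records[records$gene == gene, , drop = FALSE]
  x <- rec$logfc[rec$category == "AAD"]
  y <- rec$logfc[rec$category == "NAAD"]
  if (length(x) < 2L || length(y) < 2L)
    stop("gene ", gene, " needs >= 2 logFC values in each category (has ",
         length(x), " AAD, ", length(y), " NAAD)")
  tt <- stats::t.test(x, y, alternative = "two.sided", var.equal = var.equal)
  data.frame(gene = gene,
             t_statistic = unname(tt$statistic),
             df = unname(tt$parameter),
             p_value = tt$p.value,
             n_aad = length(x), n_naad = length(y),
             mean_logfc_aad = mean(x), mean_logfc_naad = mean(y),
             stringsAsFactors = FALSE)
}

#' Category comparison for many genes, with BH-adjusted p-values
#'
#' Runs [compare_logfc_groups()] per gene and appends a Benjamini-Hochberg
#' column. The adjusted values are reported for reference only; no filter in
#' this package uses them.
#'
#' @inheritParams compare_logfc_groups
#' @param genes Character vector of genes; defaults to all genes with enough
#'   observations in both categories.
#' @return A data.frame, one row per gene, ordered by p-value, with `p_bh`.
#' @export
compare_logfc_table <- function(records, genes = NULL, var.equal = FALSE) {
  if (is.null(genes)) {
    tab <- table(records$gene, records$category)
    ok <- rownames(tab)[tab[, "AAD"] >= 2L & tab[, "NAAD"] >= 2L]
    genes <- ok
  }
  if (!length(genes)) stop("no gene with >= 2 observations in each category")
  rows <- lapply(genes, function(g)
    compare_logfc_groups(records, g, var.equal = var.equal))
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}
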