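#' Combine per-disease ranked lists into one aggregated target table
#'
#' Each disease contributes its top `rank_cap` genes; the union is scored by
#' (1) occurrence — the number of diseases whose capped list contains the
#' gene — descending, then (2) mean rank over those diseases, ascending, then
#' (3) gene symbol, ascending, as a deterministic final tie-break. Ranks
#' beyond `rank_cap` are excluded from both occurrence and the mean, not
#' clamped: a gene absent from a disease's top slice simply does not count
#' there.
#'
#' @param ranked A data.frame of ranked-list rows (columns `disease`,
#'   `novelty`, `gene`, `rank`) for a single novelty setting, e.g. one
#'   category's share of [read_ranked_lists()] output.
#' @param rank_cap Per-disease list depth (default 100).
#' @return A data.frame of class `aggregated_targets` with columns `gene`,
#'   `occurrence`, `mean_rank`, ordered per the sort keys; attributes
#'   `novelty` and `n_diseases`.
#' @export
#' @examples
#' rl <- data.frame(disease = c("d1", "d1", "d2"), novelty = "high_confidence",
#'                  gene = c("A", "B", "A"), rank = c(1L, 2L, 1L))
#' combine_lists(rl)
combine_lists <- function(ranked, rank_cap = 100L) {
  if (is.null(ranked) || !nrow(ranked)) stop("no ranked lists supplied")
  nov <- unique(ranked$novelty)
  if (length(nov) > 1L)
    stop("mixed novelty settings in one aggregation: ",
         paste(nov, collapse = ", "))
  if (rank_cap < 1L) stop("rank_cap must be >= 1")
  ranked <- ranked[ranked$rank <= rank_cap, , drop = FALSE]
  if (!nrow(ranked)) stop("no entries at or below rank_cap = ", rank_cap)
  occ <- tapply(ranked$disease, ranked$gene,
                function(d) length(unique(d)))
  mr <- tapply(ranked$rank, ranked$gene, mean)
  genes <- names(occ)
  out <- data.frame(gene = genes,
                    occurrence = as.integer(occ),
                    mean_rank = as.numeric(mr[genes]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$occurrence, out$mean_rank, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            novelty = nov,
            n_diseases = length(unique(ranked$disease)),
            class = c("aggregated_targets", "data.frame"))
}

#' @export
print.aggregated_targets <- function(x, n = 10L, ...) {
  cat(sprintf("Aggregated targets (%s): %d genes over %d disease lists\n",
              attr(x, "novelty"), nrow(x), attr(x, "n_diseases")))
  print.data.frame(utils::head(x, n))
  if (nrow(x) > n) cat("... ", nrow(x) - n, " more rows\n", sep = "")
  invisible(x)
}

#' Take the top-k genes of an aggregated target table
#'
#' @param agg An `aggregated_targets` table (already ordered).
#' @param k Number of genes to keep (default 100).
#' @return Character vector of the first `min(k, nrow(agg))` genes, order
#'   preserved.
#' @export
select_top <- function(agg, k = 100L) {
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    stop("k must be a positive integer")
  utils::head(agg$gene, k)
}

#' Classify targets as category-specific or common
#'
#' Set algebra on the two top lists: genes in the AAD list only are the
#' age-associated targets, genes in both are common, genes in the NAAD list
#' only are NAAD-specific.
#'
#' @param aad_top,naad_top Character vectors of gene symbols (deduplicated).
#' @return An object of class `target_classification`: a list with character
#'   vectors `aad_specific`, `common`, `naad_specific` (each sorted).
#' @export
#' @examples
#' classify_targets(c("A", "B", "C"), c("B", "C", "D"))
classify_targets <- function(aad_top, naad_top) {
  aad_top <- unique(as.character(aad_top))
  naad_top <- unique(as.character(naad_top))
  structure(list(aad_specific = sort(setdiff(aad_top, naad_top)),
                 common = sort(intersect(aad_top, naad_top)),
                 naad_specific = sort(setdiff(naad_top, aad_top))),
            class = "target_classification")
}

#' @export
print.target_classification <- function(x, ...) {
  cat(sprintf(
    "Target classification: %d AAD-specific, %d common, %d NAAD-specific\n",
    length(x$aad_specific), length(x$common), length(x$naad_specific)))
  invisible(x)
}

#' @export
as.data.frame.target_classification <- function(x, ...) {
  data.frame(
    gene = c(x$aad_specific, x$common, x$naad_specific),
    set = rep(c("aad_specific", "common", "naad_specific"),
              c(length(x$aad_specific), length(x$common),
                length(x$naad_specific))),
    stringsAsFactors = FALSE)
}
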