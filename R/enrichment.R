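#' Hypergeometric enrichment of a target list in a gene pool
#'
#' Given a background universe of `N` genes containing a pool of `K` genes,
#' a list of `n` identified targets, and an observed overlap of `r` genes,
#' computes the expected overlap under random draws, the fold enrichment,
#' and the upper-tail probability
#' \deqn{p \;=\; 1 - \sum_{i=0}^{r-1} \frac{\binom{K}{i}\binom{N-K}{n-i}}
#'       {\binom{N}{n}} \;=\; P(X \ge r),}
#' i.e. the probability of observing an overlap at least as large as `r`.
#' Note the tail includes `r` itself (the sum runs to `r - 1`): an
#' off-by-one here is the classic enrichment bug, so the convention is
#' stated explicitly. `r = 0` gives `p = 1` exactly (empty sum).
#'
#' The tail is accumulated in log space via `lchoose` and a log-sum-exp, so
#' backgrounds of thousands of genes (the druggable universe here is 5,626)
#' do not overflow; the shorter of the two tails is summed and complemented.
#'
#' @param N Background universe size (druggable genes).
#' @param K Pool size within the background.
#' @param n Number of identified targets.
#' @param r Observed overlap, `0 <= r <= min(n, K)`.
#' @param overlap_genes Optional character vector of the overlapping symbols
#'   (carried through by [overlap_and_test()]).
#' @return An object of class `enrichment_result`: a list with `N`, `K`,
#'   `n`, `r`, `expected` (`n*K/N`), `fold` (`r/expected`), `p_value`, and
#'   `overlap_genes`.
#' @export
#' @examples
#' hypergeom_enrichment(N = 5626, K = 62, n = 100, r = 14)
hypergeom_enrichment <- function(N, K, n, r, overlap_genes = NULL) {
  N <- as.integer(N); K <- as.integer(K); n <- as.integer(n); r <- as.integer(r)
  if (any(!is.finite(c(N, K, n, r)))) stop("N, K, n, r must be finite integers")
  if (K > N) stop("K (", K, ") cannot exceed the background N (", N, ")")
  if (n > N) stop("n (", n, ") cannot exceed the background N (", N, ")")
  if (r < 0 || r > min(n, K))
    stop("r (", r, ") must lie in [0, min(n, K) = ", min(n, K), "]")
  expected <- n * K / N
  fold <- if (expected > 0) r / expected else NA_real_
  p <- hyper_upper_tail(N, K, n, r)
  structure(list(N = N, K = K, n = n, r = r,
                 expected = expected, fold = fold,
                 p_value = p, overlap_genes = overlap_genes),
            class = "enrichment_result")
}

# log point mass of the hypergeometric at i successes
lhyper_point <- function(N, K, n, i) {
  lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
}

# P(X >= r) for X ~ Hypergeom(N, K, n). The upper tail is summed directly
# in log space: complementing the lower sum (1 - sum_{i<r}) would cancel
# catastrophically exactly when p is small, which is the regime that matters
# for enrichment.
hyper_upper_tail <- function(N, K, n, r) {
  if (r <= 0) return(1)
  hi <- min(n, K)              # support upper bound
  if (r > hi) return(0)
  p <- exp(logsumexp(lhyper_point(N, K, n, r:hi)))
  min(max(p, 0), 1)  # clamp against round-off
}

logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "Hypergeometric enrichment: N = %d, K = %d, n = %d, r = %d\n",
    x$N, x$K, x$n, x$r))
  cat(sprintf("  expected = %.2f, fold = %.2f, p = %.3g\n",
              x$expected, x$fold, x$p_value))
  if (!is.null(x$overlap_genes) && length(x$overlap_genes))
    cat("  overlap:", paste(x$overlap_genes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.enrichment_result <- function(x, ...) {
  data.frame(N = x$N, K = x$K, n = x$n, r = x$r, expected = x$expected,
             fold = x$fold, p_value = x$p_value,
             overlap_genes = paste(x$overlap_genes, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Overlap a target list with a curated pool and test enrichment
#'
#' Intersects the (case-normalized, deduplicated) target list with the
#' pool's genes and delegates to [hypergeom_enrichment()] with
#' `N = pool$background_size`, `K = |pool|`, `n = |targets|`,
#' `r = |overlap|`.
#'
#' @param targets Character vector of target gene symbols.
#' @param pool A [gene_pool()] object.
#' @return An `enrichment_result` carrying the overlapping symbols.
#' @export
overlap_and_test <- function(targets, pool) {
  if (!inherits(pool, "gene_pool")) stop("pool must be a gene_pool object")
  targets <- unique(norm_symbol(targets))
  targets <- targets[nzchar(targets)]
  if (!length(targets)) stop("empty target list")
  if (pool$background_size < max(length(targets), length(pool$genes)))
    stop("background smaller than the target list or pool")
  ov <- sort(intersect(targets, pool$genes))
  hypergeom_enrichment(N = pool$background_size, K = length(pool$genes),
                       n = length(targets), r = length(ov),
                       overlap_genes = ov)
}
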