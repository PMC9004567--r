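# small in-code fixtures shared across test files

# a compact registry: two AAD diseases in distinct classes, two NAADs
tiny_registry <- function() {
  data.frame(
    disease = c("aad1", "aad2", "naad1", "naad2"),
    category = c("AAD", "AAD", "NAAD", "NAAD"),
    disease_class = c("neurological", "fibrotic", "inflammatory",
                      "infectious"),
    n_comparisons = c(3L, 2L, 2L, 2L),
    stringsAsFactors = FALSE)
}

# random ranked-list table: each disease gets a permutation of `depth` genes
random_ranked <- function(diseases, n_genes = 30L, depth = 10L,
                          novelty = "high_confidence") {
  genes <- sprintf("G%03d", seq_len(n_genes))
  do.call(rbind, lapply(diseases, function(d)
    data.frame(disease = d, novelty = novelty,
               gene = sample(genes, depth), rank = seq_len(depth),
               stringsAsFactors = FALSE)))
}

# comparison records from an explicit gene x comparison logfc matrix
records_from_matrix <- function(m, disease, category, disease_class) {
  data.frame(
    gene = rep(rownames(m), ncol(m)),
    comparison_id = rep(paste0(disease, "_c", seq_len(ncol(m))),
                        each = nrow(m)),
    disease = disease,
    logfc = as.vector(m),
    category = category,
    disease_class = disease_class,
    stringsAsFactors = FALSE)
}

# independent brute-force ordering oracle for aggregation: full pairwise
# comparison sort on (-occurrence, mean_rank, gene)
oracle_aggregate <- function(ranked, rank_cap) {
  ranked <- ranked[ranked$rank <= rank_cap, , drop = FALSE]
  genes <- unique(ranked$gene)
  occ <- sapply(genes, function(g)
    length(unique(ranked$disease[ranked$gene == g])))
  mr <- sapply(genes, function(g) mean(ranked$rank[ranked$gene == g]))
  lt <- function(i, j) {
    if (occ[i] != occ[j]) return(occ[i] > occ[j])
    if (mr[i] != mr[j]) return(mr[i] < mr[j])
    genes[i] < genes[j]
  }
  # selection sort via the pairwise comparator
  idx <- seq_along(genes)
  for (a in seq_along(idx)) {
    best <- a
    for (b in seq_along(idx)) if (b > a && lt(idx[b], idx[best])) best <- b
    tmp <- idx[a]; idx[a] <- idx[best]; idx[best] <- tmp
  }
  genes[idx]
}

# exhaustive hypergeometric upper tail by enumerating every size-n draw
oracle_tail_enumeration <- function(N, K, n, r) {
  draws <- utils::combn(N, n)
  in_pool <- draws <= K          # pool = elements 1..K
  overlaps <- colSums(in_pool)
  mean(overlaps >= r)
}

# exact upper tail from integer-exact choose() (valid for small N)
oracle_tail_choose <- function(N, K, n, r) {
  if (r <= 0) return(1)
  i <- r:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}
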