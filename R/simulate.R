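#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults mirror the study design this package emulates: a universe of
#' 5,626 druggable genes, 14 AADs with 87 comparisons and 19 NAADs with 126
#' comparisons in the default disease registry, planted effects with a 0.9
#' per-comparison sign-agreement probability, and a geometric rank advantage
#' for planted genes in their relevant diseases.
#'
#' @param seed Integer seed governing all randomness (substreams per disease
#'   are derived from it, so a fixed seed gives byte-identical output).
#' @param n_genes Gene-universe size (default 5626).
#' @param diseases Disease registry data.frame (default [disease_registry()]).
#' @param n_planted_aad Genes planted as prioritized and dysregulated in
#'   AAD diseases only (default 30).
#' @param n_planted_common Genes planted in all diseases (default 30).
#' @param planted_sign_prob Probability that one comparison's logFC for a
#'   planted gene carries the planted sign; in (0.5, 1], default 0.9.
#' @param planted_rank_geometric_p Success probability of the geometric
#'   rank advantage: a planted gene enters a relevant disease's ranking
#'   after `G ~ Geometric(p)` null genes, so larger values push planted
#'   genes toward rank 1 (default 0.05, i.e. a mean within-disease rank of
#'   about 20).
#' @param noise_logfc_sd Standard deviation of null logFC noise (default 1).
#' @param planted_logfc_mean Mean logFC magnitude of planted effects
#'   (default 1.5).
#' @param novelty Novelty label stamped on generated lists (default
#'   `"high_confidence"`).
#' @param list_depth Per-disease ranked-list length (default 100).
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 5626L,
                       diseases = disease_registry(),
                       n_planted_aad = 30L,
                       n_planted_common = 30L,
                       planted_sign_prob = 0.9,
                       planted_rank_geometric_p = 0.05,
                       noise_logfc_sd = 1.0,
                       planted_logfc_mean = 1.5,
                       novelty = "high_confidence",
                       list_depth = 100L) {
  validate_disease_registry(diseases)
  novelty <- match.arg(novelty, NOVELTY_LEVELS)
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              diseases = diseases,
              n_planted_aad = as.integer(n_planted_aad),
              n_planted_common = as.integer(n_planted_common),
              planted_sign_prob = planted_sign_prob,
              planted_rank_geometric_p = planted_rank_geometric_p,
              noise_logfc_sd = noise_logfc_sd,
              planted_logfc_mean = planted_logfc_mean,
              novelty = novelty, list_depth = as.integer(list_depth))
  if (cfg$n_planted_aad < 0L || cfg$n_planted_common < 0L)
    stop("planted counts must be non-negative")
  if (cfg$n_planted_aad + cfg$n_planted_common > cfg$n_genes)
    stop("planted genes exceed the gene universe")
  if (cfg$n_planted_aad + cfg$n_planted_common > cfg$list_depth)
    stop("planted genes (", cfg$n_planted_aad + cfg$n_planted_common,
         ") exceed the per-disease list capacity (", cfg$list_depth, ")")
  if (planted_sign_prob <= 0.5 || planted_sign_prob > 1)
    stop("planted_sign_prob must be in (0.5, 1]")
  if (planted_rank_geometric_p <= 0 || planted_rank_geometric_p > 1)
    stop("planted_rank_geometric_p must be in (0, 1]")
  if (noise_logfc_sd <= 0) stop("noise_logfc_sd must be positive")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Simulation config: seed %d, %d genes, %d diseases (%d comparisons)\n",
    x$seed, x$n_genes, nrow(x$diseases), sum(x$diseases$n_comparisons)))
  cat(sprintf(
    "  planted: %d AAD-only + %d common, sign prob %.2f, rank geometric p %.3f\n",
    x$n_planted_aad, x$n_planted_common, x$planted_sign_prob,
    x$planted_rank_geometric_p))
  invisible(x)
}

gene_universe <- function(n_genes) sprintf("G%05d", seq_len(n_genes))

#' Planted ground truth of a simulation
#'
#' Derived deterministically from the config seed, so [gen_ranked_lists()]
#' and [gen_comparisons()] agree on which genes are planted without passing
#' state between them.
#'
#' @param config A [sim_config()].
#' @return A list of class `ground_truth`: data.frames `planted_aad` and
#'   `planted_common` (columns `gene`, `direction` in -1/+1) and character
#'   vector `null_genes`.
#' @export
ground_truth <- function(config) {
  genes <- gene_universe(config$n_genes)
  n_pl <- config$n_planted_aad + config$n_planted_common
  with_substream(config$seed, "truth", {
    planted <- sample(genes, n_pl)
    dirs <- sample(c(-1L, 1L), n_pl, replace = TRUE)
  })
  aad_idx <- seq_len(config$n_planted_aad)
  structure(list(
    planted_aad = data.frame(gene = planted[aad_idx],
                             direction = dirs[aad_idx],
                             stringsAsFactors = FALSE),
    planted_common = data.frame(gene = planted[-aad_idx],
                                direction = dirs[-aad_idx],
                                stringsAsFactors = FALSE),
    null_genes = setdiff(genes, planted)),
    class = "ground_truth")
}

# run expr under a deterministic substream of `seed` tagged by `tag`,
# restoring the caller's RNG state afterwards
with_substream <- function(seed, tag, expr) {
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% 2147483629
  sub <- as.integer(((seed %% 2147483629) * 7919 + h) %% 2147483629)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(sub)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  eval(expr, envir = parent.frame())
}

#' Generate per-disease ranked target lists with planted ground truth
#'
#' For every disease in the config's registry a top-`list_depth` ranked list
#' is drawn. Null genes are ordered uniformly at random. Each planted gene
#' relevant to the disease (AAD-planted genes in AAD diseases, common-planted
#' genes everywhere) is inserted into that ordering after
#' `G ~ Geometric(planted_rank_geometric_p)` null genes, so its rank is
#' geometrically concentrated near the top; at `p = 1` planted genes occupy
#' the first ranks exactly.
#'
#' @param config A [sim_config()].
#' @return A list with `ranked` (data.frame `disease`, `novelty`, `gene`,
#'   `rank`) and `truth` (the [ground_truth()]).
#' @export
gen_ranked_lists <- function(config) {
  truth <- ground_truth(config)
  genes <- gene_universe(config$n_genes)
  reg <- config$diseases
  out <- vector("list", nrow(reg))
  for (i in seq_len(nrow(reg))) {
    dis <- reg$disease[i]
    planted <- truth$planted_common$gene
    if (reg$category[i] == "AAD")
      planted <- c(truth$planted_aad$gene, planted)
    nulls <- setdiff(genes, c(truth$planted_aad$gene,
                              truth$planted_common$gene))
    with_substream(config$seed, paste0("rank:", dis), {
      null_order <- sample(nulls)
      # insertion key: planted gene sits after G null genes; fractional part
      # breaks ties among planted genes sharing a depth
      depth <- stats::rgeom(length(planted), config$planted_rank_geometric_p)
      jitter <- stats::runif(length(planted))
    })
    key <- c(seq_along(null_order), depth + jitter)
    ord <- order(key)
    full <- c(null_order, planted)[ord]
    # AAD-only planted genes get no advantage in NAAD diseases: they were
    # excluded from `nulls` above, so append them at uniform positions there
    if (reg$category[i] != "AAD" && config$n_planted_aad > 0L) {
      with_substream(config$seed, paste0("rank-null:", dis), {
        pos <- sample(length(full) + config$n_planted_aad,
                      config$n_planted_aad)
      })
      merged <- character(length(full) + config$n_planted_aad)
      merged[pos] <- truth$planted_aad$gene
      merged[-pos] <- full
      full <- merged
    }
    top <- utils::head(full, config$list_depth)
    out[[i]] <- data.frame(disease = dis, novelty = config$novelty,
                           gene = top, rank = seq_along(top),
                           stringsAsFactors = FALSE)
  }
  ranked <- do.call(rbind, out)
  rownames(ranked) <- NULL
  list(ranked = ranked, truth = truth)
}

#' Generate logFC comparison records with planted effects
#'
#' One record per (gene, comparison), with the comparison counts per disease
#' taken from the config's registry. Null logFC is centred Gaussian noise
#' with sd `noise_logfc_sd`. A planted gene relevant to the comparison's
#' category draws its logFC as `s * |N(planted_logfc_mean, noise_logfc_sd)|`
#' where the sign `s` equals the planted direction with probability
#' `planted_sign_prob` and is flipped otherwise — so the per-comparison
#' probability of the correct sign is exactly `planted_sign_prob`.
#'
#' @param config A [sim_config()].
#' @param truth Matching [ground_truth()]; defaults to deriving it from the
#'   config.
#' @return A data.frame of comparison records (`gene`, `comparison_id`,
#'   `disease`, `logfc`, `category`, `disease_class`).
#' @export
gen_comparisons <- function(config, truth = ground_truth(config)) {
  genes <- gene_universe(config$n_genes)
  reg <- config$diseases
  planted_dir <- c(stats::setNames(truth$planted_aad$direction,
                                   truth$planted_aad$gene),
                   stats::setNames(truth$planted_common$direction,
                                   truth$planted_common$gene))
  common_set <- truth$planted_common$gene
  aad_set <- truth$planted_aad$gene
  out <- vector("list", nrow(reg))
  for (i in seq_len(nrow(reg))) {
    dis <- reg$disease[i]
    nc <- reg$n_comparisons[i]
    ng <- length(genes)
    planted_here <- if (reg$category[i] == "AAD") c(aad_set, common_set)
                    else common_set
    is_planted <- genes %in% planted_here
    with_substream(config$seed, paste0("logfc:", dis), {
      lf <- stats::rnorm(ng * nc, 0, config$noise_logfc_sd)
      idx <- which(rep(is_planted, nc))
      if (length(idx)) {
        dirs <- planted_dir[rep(genes, nc)[idx]]
        flip <- ifelse(stats::runif(length(idx)) < config$planted_sign_prob,
                       1L, -1L)
        mag <- abs(stats::rnorm(length(idx), config$planted_logfc_mean,
                                config$noise_logfc_sd))
        lf[idx] <- dirs * flip * mag
      }
    })
    out[[i]] <- data.frame(
      gene = rep(genes, nc),
      comparison_id = rep(sprintf("%s_c%02d", gsub("[^A-Za-z0-9]+", "_", dis),
                                  seq_len(nc)), each = ng),
      disease = dis,
      logfc = lf,
      category = reg$category[i],
      disease_class = reg$disease_class[i],
      stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, out)
  rownames(rec) <- NULL
  rec
}
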