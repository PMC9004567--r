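#' @importFrom data.table fread fwrite
#' @importFrom utils packageVersion head
#' @importFrom stats setNames
NULL

# provenance line written at the top of every output table
provenance_line <- function() {
  sprintf("# gerotarget %s | written %s",
          as.character(utils::packageVersion("gerotarget")),
          format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

# count leading '#' lines so fread can skip them
n_comment_lines <- function(path) {
  n <- 0L
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln) || !startsWith(ln, "#")) break
    n <- n + 1L
  }
  n
}

read_table_file <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- data.table::fread(path, sep = sep, header = TRUE,
                          skip = n_comment_lines(path), data.table = FALSE,
                          colClasses = NULL, showProgress = FALSE)
  if (!nrow(df) && !ncol(df)) stop("empty file: ", path)
  df
}

#' Write a table as TSV with a provenance header
#'
#' All pipeline outputs are tab-delimited text with one leading `#` line
#' recording the package version and timestamp; readers in this package skip
#' such lines transparently. Set `stamp = FALSE` for byte-reproducible output
#' (the determinism tests and the pipeline's hashed report use this).
#'
#' @param x A data.frame.
#' @param path Output path.
#' @param stamp Write the provenance line? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, stamp = TRUE) {
  if (stamp) {
    writeLines(provenance_line(), path)
    data.table::fwrite(x, path, sep = "\t", append = TRUE, col.names = TRUE)
  } else {
    data.table::fwrite(x, path, sep = "\t")
  }
  invisible(path)
}

resolve_schema <- function(df, schema, path) {
  miss <- setdiff(names(schema), names(schema)[unlist(schema) %in% names(df)])
  if (length(miss))
    stop("missing column(s) in ", path, ": ",
         paste(sprintf("%s (expected as '%s')", miss, unlist(schema)[miss]),
               collapse = ", "))
  out <- df[unlist(schema)]
  names(out) <- names(schema)
  out
}

#' Read per-disease ranked target lists
#'
#' Parses a delimited table of prioritized genes, one row per
#' (disease, novelty, gene) with an integer rank starting at 1. Gene symbols
#' are upper-cased and whitespace-stripped; duplicate genes within one
#' (disease, novelty) list are a validation error, as are duplicated ranks.
#'
#' @param path Path to a TSV/CSV file.
#' @param schema Named character vector mapping the canonical column names
#'   `disease`, `novelty`, `gene`, `rank` to the columns in the file.
#' @param sep Field separator (default tab).
#' @return A data.frame with canonical columns `disease`, `novelty`, `gene`,
#'   `rank`, row order preserved from the file.
#' @export
read_ranked_lists <- function(path,
                              schema = c(disease = "disease",
                                         novelty = "novelty",
                                         gene = "gene", rank = "rank"),
                              sep = "\t") {
  df <- read_table_file(path, sep = sep)
  out <- resolve_schema(df, as.list(schema), path)
  out$gene <- norm_symbol(out$gene)
  out$disease <- trimws(as.character(out$disease))
  out$novelty <- trimws(as.character(out$novelty))
  out$rank <- as.integer(out$rank)
  validate_ranked_lists(out)
}

#' Validate ranked target lists
#'
#' @param x A data.frame with columns `disease`, `novelty`, `gene`, `rank`.
#' @return `x` (invisibly valid, returned visibly for chaining).
#' @export
validate_ranked_lists <- function(x) {
  bad <- setdiff(unique(x$novelty), NOVELTY_LEVELS)
  if (length(bad))
    stop("unknown novelty setting(s): ", paste(bad, collapse = ", "))
  if (any(!is.finite(x$rank)) || any(x$rank < 1L))
    stop("ranks must be integers >= 1")
  key <- paste(x$disease, x$novelty, x$gene, sep = "\r")
  if (anyDuplicated(key)) {
    off <- x[duplicated(key), c("disease", "novelty", "gene"), drop = FALSE]
    stop("duplicate gene(s) within a ranked list: ",
         paste(utils::head(sprintf("%s/%s/%s", off$disease, off$novelty,
                                   off$gene), 5L), collapse = "; "))
  }
  rkey <- paste(x$disease, x$novelty, x$rank, sep = "\r")
  if (anyDuplicated(rkey))
    stop("duplicate rank value(s) within a ranked list; resolve ties upstream")
  x
}

#' Read case-control comparison records
#'
#' Parses the long-format logFC table: one row per (gene, comparison), with
#' the comparison's disease. `category` and `disease_class` are taken from
#' the file if present, otherwise joined from `registry`. Rows with
#' non-finite or unparseable logFC are dropped and their count reported in
#' the `n_rejected` attribute (and a message).
#'
#' @param path Path to a TSV/CSV file with columns `gene`, `comparison_id`,
#'   `disease`, `logfc`.
#' @param registry Disease registry data.frame (default [disease_registry()]).
#' @param sep Field separator.
#' @return A data.frame with columns `gene`, `comparison_id`, `disease`,
#'   `logfc`, `category`, `disease_class`, attribute `n_rejected`.
#' @export
read_comparisons <- function(path, registry = disease_registry(), sep = "\t") {
  df <- read_table_file(path, sep = sep)
  need <- c("gene", "comparison_id", "disease", "logfc")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  df$gene <- norm_symbol(df$gene)
  df$disease <- trimws(as.character(df$disease))
  lf <- suppressWarnings(as.numeric(df$logfc))
  keep <- is.finite(lf)
  n_rej <- sum(!keep)
  if (n_rej) {
    bad_lines <- which(!keep)
    message(n_rej, " row(s) with non-finite logFC rejected (data line(s) ",
            paste(utils::head(bad_lines, 5L), collapse = ", "),
            if (n_rej > 5L) ", ..." else "", ")")
  }
  df <- df[keep, , drop = FALSE]
  df$logfc <- lf[keep]
  validate_disease_registry(registry)
  unknown <- setdiff(unique(df$disease), registry$disease)
  if (length(unknown))
    stop("unknown disease(s) not in registry: ",
         paste(unknown, collapse = ", "))
  idx <- match(df$disease, registry$disease)
  df$category <- registry$category[idx]
  df$disease_class <- registry$disease_class[idx]
  key <- paste(df$gene, df$comparison_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (gene, comparison_id) pair(s), e.g. ",
         paste(utils::head(sub("\r", " in ", key[duplicated(key)]), 3L),
               collapse = "; "))
  out <- df[, c("gene", "comparison_id", "disease", "logfc", "category",
                "disease_class")]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- n_rej
  out
}

#' Construct a curated gene pool
#'
#' A pool is a named, deduplicated set of gene symbols together with the size
#' of the background universe it was drawn from (here, the druggable-gene
#' universe used as `N` in enrichment).
#'
#' @param name Pool name.
#' @param genes Character vector of gene symbols (case-normalized,
#'   deduplicated).
#' @param background_size Size of the background universe; must be at least
#'   the pool size.
#' @return An object of class `gene_pool`.
#' @export
gene_pool <- function(name, genes, background_size) {
  genes <- unique(norm_symbol(genes))
  genes <- genes[nzchar(genes)]
  if (!length(genes)) stop("gene pool '", name, "' is empty")
  background_size <- as.integer(background_size)
  if (!is.finite(background_size) || background_size < length(genes))
    stop("background_size (", background_size,
         ") must be >= pool size (", length(genes), ")")
  structure(list(name = name, genes = genes,
                 background_size = background_size),
            class = "gene_pool")
}

#' @export
print.gene_pool <- function(x, ...) {
  cat(sprintf("Gene pool '%s': %d genes over a background of %d\n",
              x$name, length(x$genes), x$background_size))
  invisible(x)
}

#' Read a gene pool from a one-symbol-per-line file
#'
#' Blank lines and `#` comment lines are ignored; symbols are upper-cased so
#' e.g. "mtor" and "MTOR" collapse to one entry.
#'
#' @inheritParams gene_pool
#' @param path Path to a plain-text file, one gene symbol per line.
#' @return A `gene_pool` object.
#' @export
read_gene_pool <- function(path, name = basename(path),
                           background_size = 5626L) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty gene pool file: ", path)
  gene_pool(name, lines, background_size)
}

#' Read a gene-to-hallmark annotation table
#'
#' Expected columns: `gene`; `hallmarks` (semicolon-separated terms from the
#' 12-term hallmark vocabulary, possibly empty); optional `role`
#' (`pro_aging`/`anti_aging`), `cancer_driver` (0/1), `safety_flag` (0/1),
#' `novelty`. A hallmark term outside the vocabulary is a validation error.
#'
#' @param path Path to a TSV/CSV file.
#' @param sep Field separator.
#' @return A data.frame with a list-column `hallmarks` of character vectors.
#' @export
read_hallmark_annotations <- function(path, sep = "\t") {
  df <- read_table_file(path, sep = sep)
  need <- c("gene", "hallmarks")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  df$gene <- norm_symbol(df$gene)
  hl <- strsplit(as.character(df$hallmarks), ";", fixed = TRUE)
  hl <- lapply(hl, function(h) {
    h <- tolower(trimws(h))
    h[nzchar(h)]
  })
  bad <- setdiff(unique(unlist(hl)), HALLMARKS)
  if (length(bad))
    stop("hallmark term(s) outside the 12-term vocabulary: ",
         paste(bad, collapse = "; "))
  out <- data.frame(gene = df$gene, stringsAsFactors = FALSE)
  out$hallmarks <- hl
  for (col in c("role", "novelty"))
    out[[col]] <- if (col %in% names(df)) trimws(as.character(df[[col]])) else NA_character_
  for (col in c("cancer_driver", "safety_flag"))
    out[[col]] <- if (col %in% names(df)) as.logical(as.integer(df[[col]])) else FALSE
  if (anyDuplicated(out$gene))
    stop("duplicate gene(s) in annotation table: ",
         paste(unique(out$gene[duplicated(out$gene)]), collapse = ", "))
  out
}

#' Write hallmark annotations back to TSV
#'
#' Inverse of [read_hallmark_annotations()]: the list-column is re-joined
#' with semicolons.
#'
#' @param x Annotation data.frame with list-column `hallmarks`.
#' @param path Output path.
#' @param stamp Write the provenance line?
#' @return `path`, invisibly.
#' @export
write_hallmark_annotations <- function(x, path, stamp = TRUE) {
  flat <- x
  flat$hallmarks <- vapply(x$hallmarks, paste, "", collapse = ";")
  flat$cancer_driver <- as.integer(flat$cancer_driver)
  flat$safety_flag <- as.integer(flat$safety_flag)
  write_tsv(flat, path, stamp = stamp)
}
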