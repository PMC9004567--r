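#' Closed vocabularies
#'
#' Category, disease-class, novelty-setting and hallmark vocabularies used
#' throughout the package. All gene symbols and vocabulary values are matched
#' after case normalization on ingest; the vocabularies themselves are fixed.
#'
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
CATEGORIES <- c("AAD", "NAAD")

#' @rdname vocabularies
#' @export
DISEASE_CLASSES <- c("neurological", "metabolic", "inflammatory",
                     "fibrotic", "infectious")

#' @rdname vocabularies
#' @export
NOVELTY_LEVELS <- c("high_confidence", "medium_novel", "highly_novel")

#' @rdname vocabularies
#' @export
HALLMARKS <- c(
  "altered intercellular communications",
  "cellular senescence",
  "deregulated nutrient signaling",
  "epigenetic shift",
  "genomic instability",
  "impaired proteostasis",
  "mitochondrial dysfunction",
  "stem cell exhaustion",
  "telomere attrition",
  "extracellular matrix stiffness",
  "inflammation",
  "retrotranspositions"
)

#' Default disease registry
#'
#' The study design this package emulates: 14 age-associated diseases (AADs,
#' 87 case-control comparisons) and 19 non-age-associated diseases (NAADs,
#' 126 comparisons), each assigned to one of five disease classes. The
#' infectious class occurs only among NAADs, so the AAD-only consistency
#' analysis never sees it.
#'
#' @param category Optional filter, `"AAD"` or `"NAAD"`.
#' @return A data.frame with columns `disease`, `category`, `disease_class`,
#'   `n_comparisons`.
#' @export
#' @examples
#' d <- disease_registry()
#' tapply(d$n_comparisons, d$category, sum)  # 87 AAD, 126 NAAD
disease_registry <- function(category = NULL) {
  aad <- data.frame(
    disease = c("Alzheimer's disease", "Amyotrophic lateral sclerosis",
                "Chronic kidney disease", "Chronic obstructive pulmonary disease",
                "Cirrhosis of liver", "Idiopathic pulmonary fibrosis",
                "Obesity", "Osteoarthritis", "Osteoporosis",
                "Parkinson's disease", "Primary myelofibrosis",
                "Pulmonary arterial hypertension", "Rheumatoid arthritis",
                "Type II diabetes mellitus"),
    disease_class = c("neurological", "neurological", "metabolic",
                      "inflammatory", "fibrotic", "fibrotic", "metabolic",
                      "inflammatory", "metabolic", "neurological", "fibrotic",
                      "metabolic", "inflammatory", "metabolic"),
    n_comparisons = c(12L, 10L, 7L, 6L, 5L, 11L, 10L, 5L, 2L, 4L, 2L, 5L, 4L, 4L),
    stringsAsFactors = FALSE
  )
  aad$category <- "AAD"
  naad <- data.frame(
    disease = c("Acromegaly", "Asthma", "Bipolar disorder", "Celiac disease",
                "Crohn's disease", "Cystic fibrosis", "Hepatitis, alcoholic",
                "Hepatitis C virus infection", "Huntington's disease",
                "Infectious meningitis", "Influenza", "Multiple sclerosis",
                "Psoriasis", "Pulmonary tuberculosis", "Schizophrenia",
                "Systemic lupus erythematosus", "Systemic scleroderma",
                "Type I diabetes mellitus", "Ulcerative colitis"),
    disease_class = c("metabolic", "inflammatory", "neurological",
                      "inflammatory", "inflammatory", "fibrotic", "metabolic",
                      "infectious", "neurological", "infectious", "infectious",
                      "inflammatory", "inflammatory", "infectious",
                      "neurological", "inflammatory", "fibrotic", "metabolic",
                      "inflammatory"),
    n_comparisons = c(2L, 13L, 4L, 3L, 8L, 5L, 3L, 2L, 5L, 3L, 5L, 11L, 11L,
                      7L, 4L, 9L, 6L, 12L, 13L),
    stringsAsFactors = FALSE
  )
  naad$category <- "NAAD"
  reg <- rbind(aad, naad)[, c("disease", "category", "disease_class",
                              "n_comparisons")]
  validate_disease_registry(reg)
  if (!is.null(category)) {
    category <- match.arg(category, CATEGORIES)
    reg <- reg[reg$category == category, , drop = FALSE]
    rownames(reg) <- NULL
  }
  reg
}

#' Validate a disease registry table
#'
#' Checks the closed vocabularies, positive comparison counts and uniqueness
#' of disease names. Any custom registry passed to the simulator or readers
#' goes through this check.
#'
#' @param reg A data.frame with columns `disease`, `category`,
#'   `disease_class`, `n_comparisons`.
#' @return `reg`, invisibly, if valid; otherwise an error.
#' @export
validate_disease_registry <- function(reg) {
  need <- c("disease", "category", "disease_class", "n_comparisons")
  miss <- setdiff(need, names(reg))
  if (length(miss))
    stop("disease registry is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(reg$disease))
    stop("duplicate disease name(s): ",
         paste(unique(reg$disease[duplicated(reg$disease)]), collapse = ", "))
  bad <- setdiff(unique(reg$category), CATEGORIES)
  if (length(bad))
    stop("unknown category value(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(reg$disease_class), DISEASE_CLASSES)
  if (length(bad))
    stop("unknown disease_class value(s): ", paste(bad, collapse = ", "))
  if (any(!is.finite(reg$n_comparisons)) || any(reg$n_comparisons < 1))
    stop("n_comparisons must be >= 1 for every disease")
  invisible(reg)
}

# canonical gene-symbol normalization: upper-case, strip surrounding whitespace
norm_symbol <- function(x) toupper(trimws(as.character(x)))
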