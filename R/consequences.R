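# Consequence vocabulary ------------------------------------------------
#
# Terms follow the Sequence Ontology names used by VEP; a trailing
# "_variant" suffix is tolerated and stripped on normalisation so that
# "missense" and "missense_variant" are interchangeable.

.CODING_TERMS <- c(
  "missense", "stop_gained", "stop_lost", "start_lost", "frameshift",
  "inframe_insertion", "inframe_deletion", "protein_altering",
  "coding_sequence", "incomplete_terminal_codon",
  "synonymous", "stop_retained", "start_retained"
)

.SYNONYMOUS_TERMS <- c("synonymous", "stop_retained", "start_retained")

# Canonical splice-site disruptions: treated as predicted loss of function.
.SPLICE_SITE_TERMS <- c("splice_donor", "splice_acceptor")

.SPLICE_REGION_TERMS <- c(
  "splice_region", "splice_donor_region", "splice_donor_5th_base",
  "splice_polypyrimidine_tract"
)

#' Default predicted loss-of-function consequence terms
#'
#' The consequence classes counted as predicted loss of function (pLoF):
#' stop gained, frameshift, canonical splice donor/acceptor, start lost and
#' stop lost. The set is configurable wherever it is consumed.
#'
#' @return Character vector of normalised consequence terms.
#' @export
lof_terms <- function() {
  c("stop_gained", "frameshift", "splice_donor", "splice_acceptor",
    "start_lost", "stop_lost")
}

normalise_term <- function(term) sub("_variant$", "", tolower(trimws(term)))

is_coding_term <- function(term) normalise_term(term) %in% .CODING_TERMS

is_synonymous_term <- function(term) normalise_term(term) %in% .SYNONYMOUS_TERMS

is_splice_site_term <- function(term) normalise_term(term) %in% .SPLICE_SITE_TERMS

is_lof_term <- function(term, terms = lof_terms()) normalise_term(term) %in% terms

# Packed per-transcript consequence strings -----------------------------
#
# A variant's transcript consequences travel as a single packed string
# "transcript|term|distance;transcript|term|distance" so that candidate
# tables round-trip losslessly through TSV. Distance is the genomic
# distance in bp to the nearest annotated exon boundary ("." when unknown
# or not applicable, e.g. for exonic consequences it is 0).

#' Pack per-transcript consequences into a single string
#'
#' @param df Data frame with columns `transcript`, `term` and `distance`
#'   (bp to the nearest exon boundary; `NA` allowed).
#' @return Length-one character string.
#' @seealso [csq_unpack()]
#' @export
csq_pack <- function(df) {
  if (is.null(df) || nrow(df) == 0) return(NA_character_)
  paste(sprintf("%s|%s|%s", df$transcript, df$term,
                ifelse(is.na(df$distance), ".", df$distance)),
        collapse = ";")
}

#' Unpack a packed consequence string
#'
#' @param x Packed string as produced by [csq_pack()], or `NA`.
#' @return Data frame with columns `transcript`, `term` (normalised) and
#'   `distance` (numeric, `NA` when unknown).
#' @export
csq_unpack <- function(x) {
  empty <- data.frame(transcript = character(), term = character(),
                      distance = numeric(), stringsAsFactors = FALSE)
  if (length(x) != 1) stop("csq_unpack() expects a single packed string")
  if (is.na(x) || !nzchar(x)) return(empty)
  parts <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], "|", fixed = TRUE)
  bad <- vapply(parts, function(p) length(p) < 2, logical(1))
  if (any(bad)) stop("malformed consequence entry: ", x)
  data.frame(
    transcript = vapply(parts, `[`, "", 1),
    term = normalise_term(vapply(parts, `[`, "", 2)),
    distance = suppressWarnings(as.numeric(vapply(parts, function(p) {
      if (length(p) >= 3) p[3] else NA_character_
    }, ""))),
    stringsAsFactors = FALSE
  )
}

#' Transcript consequences qualifying under a coding window rule
#'
#' A transcript consequence qualifies when it is a coding, non-synonymous
#' consequence, a canonical splice-site disruption, or any other consequence
#' lying within `window` bp of an annotated exon boundary. Synonymous
#' consequences never qualify.
#'
#' @param csq Packed consequence string or a data frame as returned by
#'   [csq_unpack()].
#' @param window Window in bp around exon boundaries (20 for the
#'   panel-agnostic strategy, 8 for the panel-based strategy).
#' @return Data frame of qualifying consequences with logical columns
#'   `splicing` (the hit qualifies through splice relevance rather than a
#'   plainly coding term) and `canonical` (canonical splice donor/acceptor).
#' @export
consequence_hits <- function(csq, window) {
  df <- if (is.data.frame(csq)) csq else csq_unpack(csq)
  if (nrow(df) == 0) {
    df$splicing <- logical(0)
    df$canonical <- logical(0)
    return(df)
  }
  df$term <- normalise_term(df$term)
  coding <- is_coding_term(df$term) & !is_synonymous_term(df$term)
  canonical <- is_splice_site_term(df$term)
  near <- !is.na(df$distance) & abs(df$distance) <= window &
    !is_coding_term(df$term)
  keep <- coding | canonical | near
  out <- df[keep, , drop = FALSE]
  out$splicing <- (canonical | near)[keep] |
    out$term %in% .SPLICE_REGION_TERMS
  out$canonical <- canonical[keep]
  rownames(out) <- NULL
  out
}
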