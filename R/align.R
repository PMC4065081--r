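# Alignment layer: thin wrappers around Biostrings pairwiseAlignment with the
# package's fixed scoring. Local protein search mimics a BLAST-like bit score
# and e-value via fixed Karlin-Altschul-style constants (not fitted).

.blosum62 <- local({
  env <- new.env()
  function() {
    if (is.null(env$m)) {
      e2 <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e2)
      env$m <- e2$BLOSUM62
    }
    env$m
  }
})

# Fixed, versioned score calibration constants (BLOSUM62, affine 11/1).
.KA_LAMBDA <- 0.267
.KA_K <- 0.041

#' Local protein alignment with BLAST-like significance
#'
#' Optimal Smith-Waterman local alignment under BLOSUM62 with affine gaps
#' (open 11, extend 1). The raw score is converted to a bits-equivalent and
#' an e-value-like quantity \eqn{K m n e^{-\lambda S}} using fixed bundled
#' constants. A hit is significant when \code{evalue_like <= max_evalue} and
#' \code{bits > min_score}.
#'
#' @param query,subject Amino-acid strings (subject may be a vector).
#' @param db_size Effective search-space subject length; defaults to the
#'   total subject length supplied.
#' @param max_evalue,min_score Significance gates.
#' @return data.frame with one row per subject: \code{subject_id},
#'   \code{raw_score}, \code{score} (bits), \code{evalue_like},
#'   \code{significant}.
#' @export
local_align <- function(query, subject, db_size = NULL,
                        max_evalue = 1e-5, min_score = 40) {
  if (!nzchar(query) || any(!nzchar(subject))) stop("empty sequence")
  ids <- names(subject)
  if (is.null(ids)) ids <- paste0("subject_", seq_along(subject))
  # one vectorised call: local score is symmetric in query/subject
  raw <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(unname(subject)),
    subject = Biostrings::AAString(query),
    substitutionMatrix = .blosum62(), gapOpening = 11, gapExtension = 1,
    type = "local", scoreOnly = TRUE)
  raw <- pmax(raw, 0)
  if (is.null(db_size)) db_size <- sum(nchar(subject))
  bits <- (.KA_LAMBDA * raw - log(.KA_K)) / log(2)
  bits[raw == 0] <- 0
  ev <- .KA_K * nchar(query) * db_size * exp(-.KA_LAMBDA * raw)
  data.frame(subject_id = ids, raw_score = unname(raw), score = unname(bits),
             evalue_like = unname(ev),
             significant = unname(ev <= max_evalue & bits > min_score & raw > 0),
             stringsAsFactors = FALSE)
}

#' Global amino-acid identity
#'
#' Needleman-Wunsch global alignment (BLOSUM62, affine 11/1); identity is
#' matches divided by alignment length (gapped columns included).
#'
#' @param a One amino-acid string.
#' @param b Character vector of amino-acid strings.
#' @return Numeric vector of identities in [0, 1].
#' @export
global_identity <- function(a, b) {
  if (!nzchar(a) || any(!nzchar(b))) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(unname(b)),
    subject = Biostrings::AAString(a),
    substitutionMatrix = .blosum62(), gapOpening = 11, gapExtension = 1,
    type = "global")
  Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

#' Local amino-acid identity relative to the shorter sequence
#'
#' Smith-Waterman matches divided by the shorter sequence length; suited to
#' comparing fragments against full-length references.
#'
#' @param a One amino-acid string.
#' @param b Character vector of amino-acid strings.
#' @return Numeric vector in [0, 1].
#' @export
local_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(unname(b)),
    subject = Biostrings::AAString(a),
    substitutionMatrix = .blosum62(), gapOpening = 11, gapExtension = 1,
    type = "local")
  Biostrings::nmatch(aln) / pmin(nchar(a), nchar(b))
}

#' Global nucleotide alignment
#'
#' Needleman-Wunsch with match +2, mismatch -3, gap open 5, gap extend 2, so
#' a mismatch is always preferred over a gap pair at equal arrangements;
#' traceback is deterministic.
#'
#' @param a,b Nucleotide strings.
#' @return list with \code{pattern}, \code{subject} (gapped aligned strings,
#'   pattern = \code{a}), and \code{score}.
#' @export
global_align_nt <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(a), subject = Biostrings::DNAString(b),
    substitutionMatrix = mat, gapOpening = 5, gapExtension = 2, type = "global")
  list(pattern = as.character(Biostrings::alignedPattern(aln)),
       subject = as.character(Biostrings::alignedSubject(aln)),
       score = Biostrings::score(aln))
}

#' Codon-aware alignment of two coding sequences
#'
#' Aligns the translations globally and threads the gaps back onto codons,
#' yielding equal-length codon alignments with \code{---} gaps, suitable for
#' Nei-Gojobori counting. Trailing stop codons are stripped first.
#'
#' @param cds1,cds2 In-frame coding nucleotide strings.
#' @return list with \code{cds1}, \code{cds2} (gapped, equal length,
#'   multiple of 3).
#' @export
codon_align <- function(cds1, cds2) {
  strip_stop <- function(x) {
    n <- nchar(x) - nchar(x) %% 3
    x <- substr(x, 1, n)
    last <- substr(x, n - 2, n)
    if (last %in% c("TAA", "TAG", "TGA")) x <- substr(x, 1, n - 3)
    x
  }
  cds1 <- strip_stop(toupper(cds1)); cds2 <- strip_stop(toupper(cds2))
  aa1 <- translate_nt(cds1, 1L); aa2 <- translate_nt(cds2, 1L)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(aa1), subject = Biostrings::AAString(aa2),
    substitutionMatrix = .blosum62(), gapOpening = 11, gapExtension = 1,
    type = "global")
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  thread <- function(gapped_aa, cds) {
    cod <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    out <- character(length(gapped_aa)); j <- 1L
    for (i in seq_along(gapped_aa)) {
      if (gapped_aa[i] == "-") out[i] <- "---" else { out[i] <- cod[j]; j <- j + 1L }
    }
    paste(out, collapse = "")
  }
  list(cds1 = thread(p, cds1), cds2 = thread(s, cds2))
}
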