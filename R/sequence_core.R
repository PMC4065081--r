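#' Reverse complement of nucleotide strings
#'
#' @param x Character vector of A/C/G/T/N strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# cached standard genetic code lookup (codon -> one-letter aa, stops as "*")
.codon_aa <- local({
  env <- new.env()
  function() {
    if (is.null(env$t)) {
      gc <- Biostrings::GENETIC_CODE
      env$t <- stats::setNames(as.character(gc), names(gc))
    }
    env$t
  }
})

#' Translate a nucleotide sequence in a given frame
#'
#' Frames +1/+2/+3 read the forward strand with offsets 0/1/2; -1/-2/-3 read
#' the reverse complement likewise. Stop codons render as \code{*}; codons
#' containing \code{N} (or any non-ACGT character) render as \code{X}.
#' Trailing incomplete codons are dropped.
#'
#' @param nt Nucleotide string.
#' @param frame One of +1, +2, +3, -1, -2, -3 (integer).
#' @return Amino-acid string.
#' @export
translate_nt <- function(nt, frame = 1L) {
  if (!nzchar(nt)) stop("empty input sequence")
  if (!frame %in% c(1L, 2L, 3L, -1L, -2L, -3L)) stop("invalid frame")
  s <- toupper(nt)
  if (frame < 0) s <- revcomp(s)
  off <- abs(frame) - 1L
  s <- substr(s, off + 1L, nchar(s))
  n <- nchar(s) - nchar(s) %% 3L
  if (n < 3L) stop("sequence too short after frame offset")
  cods <- substring(s, seq.int(1L, n, 3L), seq.int(3L, n, 3L))
  aa <- .codon_aa()[cods]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Map amino-acid positions [aa_from, aa_to] in a frame back to 1-based
# inclusive forward-strand nucleotide coordinates.
.aa_to_nt_coords <- function(aa_from, aa_to, frame, seq_len) {
  off <- abs(frame) - 1L
  p1 <- off + (aa_from - 1L) * 3L + 1L
  p2 <- off + aa_to * 3L
  if (frame > 0) c(p1, p2) else c(seq_len - p2 + 1L, seq_len - p1 + 1L)
}

#' Find open reading frames in all six frames
#'
#' Reports ATG-to-stop spans of at least \code{min_aa} codons, plus
#' 5'-partial spans (frame start to first stop, flagged \code{missing_start})
#' in segments that contain no qualifying ATG-initiated ORF, and 3'-partial
#' spans lacking a stop (flagged \code{missing_stop}). Coordinates are
#' 1-based inclusive on the forward strand.
#'
#' @param seq Nucleotide string.
#' @param id Parent sequence id recorded in the output.
#' @param min_aa Minimum ORF length in amino acids (stop excluded).
#' @return data.frame with columns \code{parent_id}, \code{frame},
#'   \code{start}, \code{end}, \code{aa}, \code{missing_start},
#'   \code{missing_stop}, sorted by amino-acid length descending,
#'   ties by (frame, start).
#' @export
find_orfs <- function(seq, id = "seq", min_aa = 40L) {
  stopifnot(min_aa >= 1L)
  seq <- toupper(seq)
  L <- nchar(seq)
  out <- list()
  for (frame in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    if (L - (abs(frame) - 1L) < 3L) next
    aa <- translate_nt(seq, frame)
    # segments between stops; track 1-based aa offsets
    segs <- strsplit(aa, "*", fixed = TRUE)[[1]]
    pos <- 1L
    stops <- c(gregexpr("*", aa, fixed = TRUE)[[1]])
    n_seg <- length(segs)
    for (k in seq_len(max(n_seg, 0))) {
      seg <- segs[k]
      seg_start <- pos                      # aa coordinate of first residue
      pos <- pos + nchar(seg) + 1L
      has_stop <- (seg_start + nchar(seg)) <= nchar(aa) &&
        substr(aa, seg_start + nchar(seg), seg_start + nchar(seg)) == "*"
      if (!nzchar(seg)) next
      m_rel <- regexpr("M", seg, fixed = TRUE)[1]
      emitted <- FALSE
      if (m_rel > 0) {
        orf_aa <- substr(seg, m_rel, nchar(seg))
        if (nchar(orf_aa) >= min_aa) {
          a_from <- seg_start + m_rel - 1L
          a_to <- seg_start + nchar(seg) - 1L
          cc <- .aa_to_nt_coords(a_from, a_to + if (has_stop) 1L else 0L, frame, L)
          out[[length(out) + 1L]] <- data.frame(
            parent_id = id, frame = frame, start = cc[1], end = cc[2],
            aa = orf_aa, missing_start = FALSE, missing_stop = !has_stop,
            stringsAsFactors = FALSE)
          emitted <- TRUE
        }
      }
      if (!emitted && k == 1L && nchar(seg) >= min_aa) {
        # 5'-partial: no qualifying internal start, sequence may be truncated
        cc <- .aa_to_nt_coords(seg_start, seg_start + nchar(seg) - 1L +
                                 if (has_stop) 1L else 0L, frame, L)
        out[[length(out) + 1L]] <- data.frame(
          parent_id = id, frame = frame, start = cc[1], end = cc[2],
          aa = seg, missing_start = TRUE, missing_stop = !has_stop,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(parent_id = character(0), frame = integer(0),
                      start = integer(0), end = integer(0), aa = character(0),
                      missing_start = logical(0), missing_stop = logical(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(-nchar(res$aa), res$frame, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Order an ORF table for coding-region selection
#'
#' Complete ORFs (start and stop present) are preferred over 3'-partial ones,
#' which are preferred over 5'-partial spans; within each class longer ORFs
#' come first. This matters because shifted frames of low-entropy coding
#' sequence can produce long stop-free spans that would otherwise outrank
#' the true reading frame.
#'
#' @param orfs data.frame from [find_orfs()].
#' @return The reordered data.frame.
#' @export
prefer_orfs <- function(orfs) {
  if (!nrow(orfs)) return(orfs)
  cls <- ifelse(!orfs$missing_start & !orfs$missing_stop, 0L,
                ifelse(!orfs$missing_start, 1L, 2L))
  orfs[order(cls, -nchar(orfs$aa), orfs$frame, orfs$start), , drop = FALSE]
}

#' Read a FASTA or FASTQ file into a data.frame
#'
#' @param path File path.
#' @param format \code{"fasta"} or \code{"fastq"} (qualities are ignored).
#' @return data.frame with columns \code{id}, \code{desc}, \code{seq}.
#' @export
read_fasta <- function(path, format = "fasta") {
  ss <- Biostrings::readBStringSet(path, format = format)
  nm <- names(ss)
  id <- sub("\\s.*$", "", nm)
  desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "")
  data.frame(id = id, desc = desc, seq = toupper(as.character(ss)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write sequences to FASTA (wrapped at 60 columns)
#'
#' @param seqs Named character vector, or unnamed with \code{ids} given.
#' @param path Output path.
#' @param ids Sequence ids (defaults to \code{names(seqs)}).
#' @param desc Optional description strings appended after the id.
#' @export
write_fasta <- function(seqs, path, ids = names(seqs), desc = NULL) {
  if (is.null(ids)) stop("sequence ids required")
  nm <- ids
  if (!is.null(desc)) nm <- ifelse(nzchar(desc), paste(ids, desc), ids)
  ss <- Biostrings::BStringSet(stats::setNames(unname(seqs), nm))
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}
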