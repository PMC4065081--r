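# Precursor annotation: cysteine framework extraction, signal/propeptide/
# mature segmentation driven by the signal-peptide catalog and the processing
# quadruplet motif (PQM, X[ED][ED]R, e.g. GEER/SEER), and the five-category
# transcript classifier.

#' Extract the cysteine framework of a mature peptide
#'
#' Adjacent cysteines render as \code{CC}, isolated cysteines as \code{-C-},
#' with flanking dashes for leading/trailing non-cysteine stretches. The
#' scaffold is looked up against the eleven catalog patterns; anything else
#' is \code{NOVEL}.
#'
#' @param mature Amino-acid string (non-empty).
#' @return list with \code{scaffold}, \code{n_cys}, \code{pattern_class},
#'   \code{parity} ("even"/"odd").
#' @export
extract_framework <- function(mature) {
  if (!nzchar(mature)) stop("mature peptide must be non-empty")
  scaffold <- gsub("[^C]+", "-", toupper(mature))
  if (!startsWith(scaffold, "-")) scaffold <- paste0("-", scaffold)
  if (!endsWith(scaffold, "-")) scaffold <- paste0(scaffold, "-")
  n_cys <- nchar(gsub("[^C]", "", scaffold))
  pats <- framework_patterns()
  hit <- names(pats)[match(scaffold, pats)]
  list(scaffold = scaffold, n_cys = n_cys,
       pattern_class = if (is.na(hit)) "NOVEL" else hit,
       parity = if (n_cys %% 2 == 0) "even" else "odd")
}

# hydrophobic / small residue sets for the signal-peptide heuristic
.HYDRO <- c("A", "C", "F", "I", "L", "M", "V", "W")
.SMALL <- c("A", "G", "S", "C")

.hamming_prefix <- function(aa, ref) {
  k <- nchar(ref)
  if (nchar(aa) < k) return(Inf)
  sum(strsplit(substr(aa, 1, k), "")[[1]] != strsplit(ref, "")[[1]])
}

#' Segment a toxin precursor into signal, propeptide and mature peptide
#'
#' The signal end is taken from the best catalog signal-peptide match (at
#' most \code{max_mismatch} mismatches over the catalog signal length);
#' failing that, a hydrophobicity heuristic proposes a 15-30 residue signal
#' ending at a small residue (A/G/S/C). Catalog entries without a signal
#' (superfamily XXV) are matched by their stored propeptide. The propeptide
#' ends at the rightmost PQM match (\code{X[ED][ED]R}) after the signal and
#' before the first post-signal cysteine; with no PQM the propeptide is empty
#' and the mature peptide starts right after the signal. With no signal
#' evidence at all, the mature peptide is the whole sequence (or everything
#' after a PQM when one is present, which covers known signal-less
#' propeptide-anchored precursors).
#'
#' @param aa Precursor amino-acid string (leading M unless
#'   \code{missing_start}).
#' @param catalog Reference catalog, see [toxin_catalog()].
#' @param missing_start Whether the precursor is 5'-truncated.
#' @param max_mismatch Mismatch allowance for catalog signal matching.
#' @return list with character spans \code{signal}, \code{propeptide},
#'   \code{mature}, integer \code{signal_end}, \code{pro_end},
#'   \code{signal_evidence} (catalog_match/heuristic/missing) and
#'   \code{cleavage_motifs}.
#' @export
segment_precursor <- function(aa, catalog = toxin_catalog(),
                              missing_start = FALSE, max_mismatch = 2L) {
  aa <- sub("\\*+$", "", toupper(aa))
  if (!nzchar(aa)) stop("empty precursor")
  if (!startsWith(aa, "M") && !missing_start)
    warning("precursor does not begin with M and is not flagged 5'-partial")
  motifs <- character(0)
  signal_end <- 0L
  evidence <- "missing"

  sigs <- catalog[nzchar(catalog$signal_peptide), ]
  if (nrow(sigs) && !missing_start) {
    mm <- vapply(sigs$signal_peptide, function(s) .hamming_prefix(aa, s), numeric(1))
    if (min(mm) <= max_mismatch) {
      best <- which.min(mm)
      signal_end <- nchar(sigs$signal_peptide[best])
      evidence <- "catalog_match"
    }
  }
  # propeptide-anchored entries (no signal peptide in the catalog)
  if (evidence == "missing") {
    anch <- catalog[!nzchar(catalog$signal_peptide) & nzchar(catalog$propeptide_anchor), ]
    for (k in seq_len(nrow(anch))) {
      if (.hamming_prefix(aa, anch$propeptide_anchor[k]) <= max_mismatch) {
        pe <- nchar(anch$propeptide_anchor[k])
        if (pe < nchar(aa)) {
          pro <- substr(aa, 1, pe)
          return(list(signal = "", propeptide = pro,
                      mature = substr(aa, pe + 1, nchar(aa)),
                      signal_end = 0L, pro_end = pe,
                      signal_evidence = "catalog_match",
                      cleavage_motifs = substr(pro, pe - 3, pe)))
        }
      }
    }
  }
  if (evidence == "missing" && !missing_start) {
    # heuristic: hydrophobic N-terminal window ending near a small residue
    res <- strsplit(aa, "")[[1]]
    upper <- min(30L, length(res) - 10L)
    if (upper >= 15L) {
      for (e in upper:15L) {
        win <- res[1:e]
        if (mean(win %in% .HYDRO) >= 0.5) {
          small_at <- which(res[max(1, e - 4):e] %in% .SMALL)
          if (length(small_at)) {
            signal_end <- max(1, e - 4) + max(small_at) - 1L
            evidence <- "heuristic"
            break
          }
        }
      }
    }
  }

  if (signal_end >= 3L &&
      substr(aa, signal_end - 2, signal_end + 2) == "CYASE")
    motifs <- c(motifs, "CYASE")

  rest_start <- signal_end + 1L
  rest <- substr(aa, rest_start, nchar(aa))
  first_c <- regexpr("C", rest, fixed = TRUE)[1]
  search_end <- if (first_c > 0) first_c - 1L else nchar(rest)
  pro_end <- signal_end
  if (search_end >= 4L) {
    region <- substr(rest, 1, search_end)
    m <- gregexpr("[A-Z][ED][ED]R", region)[[1]]
    if (m[1] != -1L) {
      last <- max(m)
      motif_end_rel <- last + 3L
      if (motif_end_rel < nchar(rest)) {   # mature must be non-empty
        pro_end <- signal_end + motif_end_rel
        motifs <- c(motifs, substr(region, last, last + 3L))
      }
    }
  }
  list(signal = if (signal_end > 0) substr(aa, 1, signal_end) else "",
       propeptide = if (pro_end > signal_end)
         substr(aa, signal_end + 1, pro_end) else "",
       mature = substr(aa, pro_end + 1, nchar(aa)),
       signal_end = signal_end, pro_end = pro_end,
       signal_evidence = evidence, cleavage_motifs = motifs)
}

#' Refine a precursor start against the signal-peptide catalog
#'
#' Open-reading-frame discovery starts at the first methionine of a
#' stop-free segment, which can lie upstream of the true initiator when an
#' in-frame ATG occurs in the 5' UTR. Among the methionines in the
#' N-terminal region, this picks the one whose following residues best match
#' a catalog signal peptide (at most \code{max_mismatch} mismatches) and
#' trims the precursor there; with no such match the sequence is returned
#' unchanged.
#'
#' @param aa Candidate precursor amino-acid string.
#' @param catalog Reference catalog.
#' @param max_offset How far into the sequence initiator candidates are
#'   considered.
#' @param max_mismatch Mismatch allowance for the catalog comparison.
#' @return The (possibly trimmed) amino-acid string.
#' @export
refine_precursor_start <- function(aa, catalog = toxin_catalog(),
                                   max_offset = 30L, max_mismatch = 2L) {
  res <- strsplit(aa, "")[[1]]
  ms <- which(res == "M")
  ms <- ms[ms <= max_offset]
  if (!length(ms)) return(aa)
  refs <- c(catalog$signal_peptide[nzchar(catalog$signal_peptide)],
            catalog$propeptide_anchor[nzchar(catalog$propeptide_anchor)])
  best_pos <- NA_integer_; best_mm <- Inf
  for (p in ms) {
    tail_aa <- substr(aa, p, nchar(aa))
    mm <- min(vapply(refs, function(s) .hamming_prefix(tail_aa, s), numeric(1)))
    if (mm < best_mm) { best_mm <- mm; best_pos <- p }
  }
  if (best_mm <= max_mismatch && best_pos > 1L)
    substr(aa, best_pos, nchar(aa)) else aa
}

#' Cysteine-richness rule for putative toxins
#'
#' An ORF qualifies when it is 30-130 aa long and its post-signal region has
#' at least 4 cysteines at a cysteine fraction of at least 6\%.
#'
#' @param aa ORF amino-acid string (trailing stop stripped).
#' @param catalog Reference catalog used for the signal segmentation.
#' @return logical.
#' @export
cysteine_rich <- function(aa, catalog = toxin_catalog()) {
  aa <- sub("\\*+$", "", aa)
  n <- nchar(aa)
  if (n < 30 || n > 130) return(FALSE)
  seg <- suppressWarnings(segment_precursor(aa, catalog,
                                            missing_start = !startsWith(aa, "M")))
  region <- paste0(seg$propeptide, seg$mature)
  if (!nzchar(region)) region <- aa
  nc <- nchar(gsub("[^C]", "", region))
  nc >= 4 && nc / nchar(region) >= 0.06
}

#' Classify a transcript into the five-category scheme
#'
#' Rule order: significant toxin-database hit gives \code{Toxin_like}; else a
#' significant hit to an annotated non-toxin reference gives
#' \code{Cellular_Proteins}; else a significant hit to an unannotated
#' reference gives \code{Unknown_function}; else a cysteine-rich ORF gives
#' \code{Putative_toxin}; else \code{No_Hit}.
#'
#' @param seq Transcript nucleotide string.
#' @param toxin_db Named character vector of toxin reference proteins.
#' @param cellular_db data.frame (\code{id}, \code{seq}, \code{annotated}) of
#'   non-toxin references, see [nontoxin_references()].
#' @param orfs Optional precomputed ORF table from [find_orfs()].
#' @param catalog Reference catalog.
#' @param max_evalue,min_score Significance gates for the similarity search.
#' @param min_aa Minimum ORF length scanned.
#' @return One-row data.frame: \code{category}, \code{best_hit},
#'   \code{score}, \code{evalue_like}.
#' @export
classify_transcript <- function(seq, toxin_db, cellular_db = nontoxin_references(),
                                orfs = NULL, catalog = toxin_catalog(),
                                max_evalue = 1e-5, min_score = 40, min_aa = 40L) {
  if (is.null(orfs)) orfs <- find_orfs(seq, min_aa = min_aa)
  res <- function(category, hit = NULL, orf_row = NA_integer_) {
    out <- data.frame(category = category,
                      best_hit = if (is.null(hit)) NA_character_ else hit$subject_id,
                      score = if (is.null(hit)) NA_real_ else hit$score,
                      evalue_like = if (is.null(hit)) NA_real_ else hit$evalue_like,
                      orf_frame = NA_integer_, orf_start = NA_integer_,
                      orf_end = NA_integer_, stringsAsFactors = FALSE)
    if (!is.na(orf_row)) {
      out$orf_frame <- orfs$frame[orf_row]
      out$orf_start <- orfs$start[orf_row]
      out$orf_end <- orfs$end[orf_row]
    }
    out
  }
  if (!nrow(orfs)) return(res("No_Hit"))
  orfs <- utils::head(prefer_orfs(orfs), 4L)   # complete ORFs carry the signal
  db <- c(toxin_db, stats::setNames(cellular_db$seq, cellular_db$id))
  is_tox <- c(rep(TRUE, length(toxin_db)), rep(FALSE, nrow(cellular_db)))
  best_tox <- NULL; best_cell <- NULL
  tox_k <- NA_integer_; cell_k <- NA_integer_
  for (k in seq_len(nrow(orfs))) {
    aa <- sub("\\*+$", "", orfs$aa[k])
    h <- local_align(aa, db, max_evalue = max_evalue, min_score = min_score)
    ht <- h[h$significant & is_tox, , drop = FALSE]
    if (nrow(ht)) {
      ht <- ht[which.max(ht$score), ]
      if (is.null(best_tox) || ht$score > best_tox$score) { best_tox <- ht; tox_k <- k }
    }
    hc <- h[h$significant & !is_tox, , drop = FALSE]
    if (nrow(hc)) {
      hc <- hc[which.max(hc$score), ]
      if (is.null(best_cell) || hc$score > best_cell$score) { best_cell <- hc; cell_k <- k }
    }
  }
  if (!is.null(best_tox)) return(res("Toxin_like", best_tox, tox_k))
  if (!is.null(best_cell)) {
    annotated <- cellular_db$annotated[match(best_cell$subject_id, cellular_db$id)]
    return(res(if (annotated) "Cellular_Proteins" else "Unknown_function",
               best_cell, cell_k))
  }
  rich <- vapply(orfs$aa, cysteine_rich, logical(1), catalog = catalog)
  if (any(rich)) return(res("Putative_toxin", orf_row = which(rich)[1]))
  res("No_Hit")
}
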