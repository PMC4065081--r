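# Variant-event calling: align each low-abundance isoform to its family's
# highest-abundance reference CDS and classify the mutational events, plus
# expression-tier assignment.

.STOPS <- c("TAA", "TAG", "TGA")

#' Assign an expression tier from a read count
#'
#' rare = 1 read, low = 2-10 reads, high = more than 10 reads.
#'
#' @param read_count Positive integer.
#' @return "high", "low" or "rare".
#' @export
assign_tier <- function(read_count) {
  if (!is.numeric(read_count) || is.na(read_count) || read_count < 1)
    stop("read_count must be >= 1")
  if (read_count > 10) "high" else if (read_count >= 2) "low" else "rare"
}

#' Pick the family reference member
#'
#' The member with the highest read count; ties broken by longest CDS, then
#' lexicographically smallest id.
#'
#' @param members data.frame with \code{precursor_id}, \code{cds},
#'   \code{read_count}.
#' @return The reference \code{precursor_id}.
#' @export
family_reference <- function(members) {
  ord <- order(-members$read_count, -nchar(members$cds), members$precursor_id)
  members$precursor_id[ord[1]]
}

.codon_at <- function(s, i) substr(s, (i - 1) * 3 + 1, i * 3)

#' Classify mutational events from a variant/reference CDS alignment
#'
#' Mismatches and gaps in the global nucleotide alignment are mapped to
#' events on reference CDS coordinates: synonymous / nonsynonymous point
#' substitutions (with cysteine loss/gain emitted alongside), in-frame
#' insertions/deletions, frameshifts (indel length not divisible by 3; all
#' downstream apparent substitutions collapse into the single frameshift
#' event, annotated with the variant's new stop), point-created premature
#' stops, and stop-loss elongation when the reference stop codon is read
#' through.
#'
#' @param variant_cds,reference_cds In-frame CDS strings including the stop
#'   codon.
#' @param reference_mature_start Optional 1-based aa position of the mature
#'   region start on the reference, used to re-extract truncated frameworks
#'   for premature stops.
#' @param min_identity Pairs below this alignment identity are flagged and
#'   produce no events.
#' @return list with \code{events} (data.frame \code{kind},
#'   \code{nt_position}, \code{detail}) and \code{flagged}.
#' @export
classify_variant_events <- function(variant_cds, reference_cds,
                                    reference_mature_start = NULL,
                                    min_identity = 0.30) {
  if (!nzchar(variant_cds) || !nzchar(reference_cds)) stop("empty sequence")
  aln <- global_align_nt(reference_cds, variant_cds)
  p <- strsplit(aln$pattern, "")[[1]]   # reference with gaps
  s <- strsplit(aln$subject, "")[[1]]   # variant with gaps
  ident <- mean(p == s)
  empty <- data.frame(kind = character(0), nt_position = integer(0),
                      detail = character(0), stringsAsFactors = FALSE)
  if (ident < min_identity)
    return(list(events = empty, flagged = TRUE))

  ref_len <- nchar(reference_cds)
  ref_stop_codon <- (ref_len %/% 3L)
  events <- list()
  add <- function(kind, pos, detail = "")
    events[[length(events) + 1L]] <<- data.frame(kind = kind, nt_position = pos,
                                                 detail = detail,
                                                 stringsAsFactors = FALSE)
  # reference coordinate per alignment column (position of last ref base seen)
  ref_pos <- cumsum(p != "-")
  # indel runs
  runs <- function(is_gap) {
    r <- rle(is_gap)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    cbind(starts[r$values], ends[r$values])
  }
  shift <- 0L
  frameshift_at <- NA_integer_
  gap_runs <- rbind(
    if (any(p == "-")) cbind(runs(p == "-"), 1L) else NULL,  # insertion in variant
    if (any(s == "-")) cbind(runs(s == "-"), 2L) else NULL)  # deletion
  if (!is.null(gap_runs) && nrow(gap_runs))
    gap_runs <- gap_runs[order(gap_runs[, 1]), , drop = FALSE]
  trailing_ins <- NA_integer_
  if (!is.null(gap_runs)) for (k in seq_len(nrow(gap_runs))) {
    st <- gap_runs[k, 1]; en <- gap_runs[k, 2]; type <- gap_runs[k, 3]
    len <- en - st + 1L
    if (type == 1L && en == length(p)) { trailing_ins <- st; next }  # 3' overhang
    rp <- if (type == 1L) ref_pos[st] else ref_pos[st]  # position at/after which
    if (!is.na(frameshift_at) && st > frameshift_at) next
    if (len %% 3L == 0L) {
      add(if (type == 1L) "inframe_insertion" else "inframe_deletion",
          max(rp, 1L), sprintf("%d nt", len))
    } else {
      shift <- shift + if (type == 1L) len else -len
      if (is.na(frameshift_at)) {
        frameshift_at <- st
        vs <- gsub("-", "", aln$subject)
        new_stop <- .first_stop_codon(vs)
        add("frameshift", max(rp, 1L),
            sprintf("%+d nt; new stop at variant codon %s", if (type == 1L) len else -len,
                    if (is.na(new_stop)) "none" else new_stop))
      }
    }
  }

  # codon-wise comparison upstream of any frameshift
  limit_col <- if (!is.na(frameshift_at)) frameshift_at - 1L else length(p)
  n_cod <- ref_stop_codon
  col_of_ref <- match(seq_len(ref_len), ref_pos)  # first column per ref base
  for (ci in seq_len(n_cod)) {
    b <- (ci - 1L) * 3L + 1L
    cols <- col_of_ref[b:(b + 2L)]
    if (any(is.na(cols)) || any(cols > limit_col)) next
    if (any(p[cols] == "-") || any(s[cols] == "-")) next
    ref_cod <- paste(p[cols], collapse = "")
    var_cod <- paste(s[cols], collapse = "")
    if (ref_cod == var_cod) next
    diff_pos <- b + which(p[cols] != s[cols]) - 1L
    if (ci == ref_stop_codon && ref_cod %in% .STOPS && !var_cod %in% .STOPS) {
      overhang <- if (!is.na(trailing_ins)) length(p) - trailing_ins + 1L else 0L
      add("stop_loss_elongation", diff_pos[1],
          sprintf("%s>%s; elongated by %d nt", ref_cod, var_cod, overhang))
      next
    }
    if (!ref_cod %in% .STOPS && var_cod %in% .STOPS) {
      add("premature_stop", b, sprintf("%s>%s at codon %d", ref_cod, var_cod, ci))
      next
    }
    ref_aa <- .translate_codon(ref_cod); var_aa <- .translate_codon(var_cod)
    kind <- if (identical(ref_aa, var_aa)) "point_synonymous" else "point_nonsynonymous"
    for (dp in diff_pos)
      add(kind, dp, sprintf("%s>%s (%s>%s)",
                            substr(reference_cds, dp, dp), s[col_of_ref[dp]],
                            ref_aa, var_aa))
    if (ref_aa == "C" && var_aa != "C") add("cysteine_loss", diff_pos[1],
                                            sprintf("C%d lost", ci))
    if (ref_aa != "C" && var_aa == "C") add("cysteine_gain", diff_pos[1],
                                            sprintf("C gained at codon %d", ci))
  }
  ev <- if (length(events)) do.call(rbind, events) else empty
  ev <- ev[order(ev$nt_position), , drop = FALSE]
  rownames(ev) <- NULL
  # annotate truncated framework for premature stops
  if (!is.null(reference_mature_start) && any(ev$kind == "premature_stop")) {
    stop_cod <- min((ev$nt_position[ev$kind == "premature_stop"] - 1L) %/% 3L + 1L)
    if (stop_cod > reference_mature_start) {
      trunc_aa <- translate_nt(substr(reference_cds,
                                      (reference_mature_start - 1L) * 3L + 1L,
                                      (stop_cod - 1L) * 3L), 1L)
      if (nzchar(trunc_aa)) {
        fw <- extract_framework(trunc_aa)
        ev$detail[ev$kind == "premature_stop"] <-
          paste0(ev$detail[ev$kind == "premature_stop"],
                 "; truncated framework ", fw$scaffold)
      }
    }
  }
  list(events = ev, flagged = FALSE)
}

.translate_codon <- function(cod) {
  aa <- .codon_aa()[cod]
  if (is.na(aa)) "X" else unname(aa)
}

.first_stop_codon <- function(cds) {
  n <- nchar(cds) %/% 3L
  for (i in seq_len(n)) if (.codon_at(cds, i) %in% .STOPS) return(i)
  NA_integer_
}
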