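# Ground-truth evaluation of a synthetic pipeline run: superfamily recovery,
# segmentation recovery and single-mutation event-kind recovery.

#' Superfamily recovery against the synthetic truth ledger
#'
#' For every simulated variant, the transcripts carrying its reads are looked
#' up via the assembly membership table; the variant's assigned superfamily
#' is that of the transcript holding most of its reads (ties to the longer
#' transcript). Variants whose transcripts were never annotated count as
#' failures.
#'
#' @param out_dir Pipeline output directory.
#' @return list with \code{recovery} (fraction correct), \code{n} and the
#'   per-variant data.frame.
#' @export
evaluate_superfamily_recovery <- function(out_dir) {
  truth <- .read_tsv(file.path(out_dir, "truth.tsv"))
  read_map <- .read_tsv(file.path(out_dir, "read_map.tsv"))
  membership <- .read_tsv(file.path(out_dir, "membership.tsv"))
  tax <- .read_tsv(file.path(out_dir, "taxonomy.tsv"))
  rm2 <- merge(read_map, membership, by = "read_id")
  rm2 <- merge(rm2, tax[, c("precursor_id", "superfamily")],
               by.x = "contig_id", by.y = "precursor_id", all.x = TRUE)
  assigned <- vapply(truth$variant_id, function(v) {
    x <- rm2[rm2$variant_id == v & !is.na(rm2$superfamily), , drop = FALSE]
    if (!nrow(x)) return(NA_character_)
    votes <- sort(table(x$superfamily), decreasing = TRUE)
    names(votes)[1]
  }, character(1))
  correct <- !is.na(assigned) & assigned == truth$superfamily
  list(recovery = mean(correct), n = nrow(truth),
       detail = data.frame(variant_id = truth$variant_id,
                           true_superfamily = truth$superfamily,
                           assigned = assigned, correct = correct,
                           stringsAsFactors = FALSE))
}

# map an injected mutation spec to the event kinds the classifier may report
.expected_kinds <- function(spec) {
  switch(spec$kind,
    point = c("point_synonymous", "point_nonsynonymous"),
    insertion = if (spec$length %% 3 == 0) "inframe_insertion" else "frameshift",
    deletion = if (spec$length %% 3 == 0) "inframe_deletion" else "frameshift",
    premature_stop = "premature_stop",
    stop_loss = "stop_loss_elongation")
}

#' Single-mutation event recovery on synthetic variants
#'
#' Generates variants carrying exactly one mutation of each kind per
#' template and checks that [classify_variant_events()] recovers the event
#' kind, and position (exact for substitutions, within a placement window
#' for indels, since gap placement is only defined up to the repeat
#' structure of the context).
#'
#' @param templates Reference templates.
#' @param n_per_kind Variants per template and mutation kind.
#' @param seed Integer seed.
#' @param indel_window Position tolerance for indels (nt).
#' @return list with \code{recovery}, \code{n}, and the per-case
#'   data.frame.
#' @export
evaluate_event_recovery <- function(templates = reference_templates(),
                                    n_per_kind = 3L, seed = 1L,
                                    indel_window = 15L) {
  kinds <- c("point", "insertion", "deletion", "premature_stop", "stop_loss")
  rows <- list()
  for (ki in seq_along(kinds)) {
    kind <- kinds[ki]
    rates <- stats::setNames(as.numeric(kinds == kind), kinds)
    vars <- generate_variants(templates, n_variants_per_template = n_per_kind,
                              mutation_rates = rates,
                              seed = seed * 100L + ki)
    ref_cds <- stats::setNames(
      vapply(templates$precursor, reverse_translate, character(1)),
      templates$template_id)
    for (v in seq_along(vars$cds)) {
      spec <- vars$specs[[v]][[1]]
      tid <- vars$truth$template_id[v]
      res <- classify_variant_events(vars$cds[[v]], ref_cds[[tid]])
      expect <- .expected_kinds(spec)
      hit <- res$events[res$events$kind %in% expect, , drop = FALSE]
      ok <- FALSE
      if (nrow(hit)) {
        tol <- if (spec$kind %in% c("insertion", "deletion")) indel_window else 2L
        ok <- any(abs(hit$nt_position - spec$position) <= tol)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        kind = kind, template_id = tid, position = spec$position,
        recovered = ok, stringsAsFactors = FALSE)
    }
  }
  det <- do.call(rbind, rows)
  list(recovery = mean(det$recovered), n = nrow(det), detail = det)
}

#' Mutation-free segmentation recovery
#'
#' With all mutation rates zero, downstream segmentation of each variant's
#' precursor must reproduce the template's signal/propeptide/mature split
#' exactly.
#'
#' @param templates Reference templates.
#' @param catalog Reference catalog.
#' @return Fraction of templates segmented exactly.
#' @export
evaluate_segmentation_recovery <- function(templates = reference_templates(),
                                           catalog = toxin_catalog()) {
  ok <- vapply(seq_len(nrow(templates)), function(i) {
    tpl <- templates[i, ]
    seg <- suppressWarnings(segment_precursor(tpl$precursor, catalog))
    identical(seg$signal, tpl$signal_peptide) &&
      identical(seg$propeptide, tpl$propeptide) &&
      identical(seg$mature, tpl$mature_peptide)
  }, logical(1))
  mean(ok)
}
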