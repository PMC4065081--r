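# End-to-end pipeline: simulate -> assemble -> annotate -> taxonomy ->
# variants -> evolve -> report, with per-stage manifests (parameter echo +
# input/output checksums) enabling resume, and structured logging.

#' Default pipeline configuration
#'
#' Parameter defaults follow the analysis conventions this pipeline
#' emulates: exact 50-nt overlap assembly, e-value 1e-5 with bit score > 40
#' significance, signal/precursor/mature identity thresholds 0.70/0.60/0.90,
#' and 500 bootstrap replicates.
#'
#' @param seed Master integer seed (mandatory; all stochastic stages derive
#'   from it).
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(seed = as.integer(seed),
       # skewed superfamily sizes (a few dominant families, a long tail),
       # scaled to ~208 variants in total
       n_variants_per_template = c(I = 66L, II = 44L, XVIII = 38L, XVI = 22L,
                                   XIV = 13L, X = 5L, XXV = 3L, XI = 3L,
                                   XXIV = 3L, XVII = 2L, XV = 2L, XX = 2L,
                                   XXI = 2L, XXIII = 1L, XXII = 1L, XIII = 1L),
       total_reads = 5000L,
       n_background = 300L,
       mutation_rates = c(point = 0.35, insertion = 0.08, deletion = 0.08,
                          premature_stop = 0.05, stop_loss = 0.03),
       read_model = list(mean_length = 327, min_length = 40, max_length = 836,
                         abundance_exponent = 1.5, full_length_prob = 0.9),
       assembly = list(min_overlap = 50L, use_revcomp = TRUE),
       singleton_passthrough = TRUE,
       min_singleton_len = 120L,
       annotation = list(max_evalue = 1e-5, min_score = 40, min_orf_aa = 40L),
       taxonomy = list(superfamily = 0.70, family = 0.60, subfamily = 0.90),
       evolution = list(bootstrap = 500L, superfamilies = c("I", "II", "XVIII"),
                        min_members = 3L))
}

.stage_order <- c("simulate", "assemble", "annotate", "taxonomy",
                  "variants", "evolve", "report")

.log_msg <- function(stage, level, msg)
  message(sprintf("[%s] %s: %s", stage, level, msg))

.manifest_path <- function(out_dir, stage)
  file.path(out_dir, "manifests", paste0(stage, ".json"))

.md5s <- function(paths) {
  paths <- paths[file.exists(paths)]
  if (!length(paths)) return(list())
  as.list(tools::md5sum(paths))
}

.write_manifest <- function(out_dir, stage, params, inputs, outputs) {
  dir.create(file.path(out_dir, "manifests"), showWarnings = FALSE, recursive = TRUE)
  man <- list(stage = stage, params = params,
              inputs = .md5s(inputs), outputs = .md5s(outputs))
  jsonlite::write_json(man, .manifest_path(out_dir, stage), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

.stage_up_to_date <- function(out_dir, stage, params, inputs, outputs) {
  mp <- .manifest_path(out_dir, stage)
  if (!file.exists(mp)) return(FALSE)
  man <- jsonlite::read_json(mp)
  same_params <- identical(jsonlite::toJSON(params, auto_unbox = TRUE, digits = NA),
                           jsonlite::toJSON(man$params, auto_unbox = TRUE, digits = NA))
  if (!isTRUE(same_params)) return(FALSE)
  cur_in <- .md5s(inputs); cur_out <- .md5s(outputs)
  identical(cur_in, lapply(man$inputs, identity)) &&
    length(cur_out) == length(man$outputs) &&
    identical(cur_out, lapply(man$outputs, identity)) &&
    all(file.exists(outputs))
}

.read_tsv <- function(path) utils::read.delim(path, stringsAsFactors = FALSE,
                                              na.strings = "NA")
.write_tsv <- function(df, path) utils::write.table(df, path, sep = "\t",
                                                    quote = FALSE, row.names = FALSE)

# ---- stages -----------------------------------------------------------------

.stage_simulate <- function(config, out_dir) {
  templates <- reference_templates()
  vars <- generate_variants(templates, config$n_variants_per_template,
                            config$mutation_rates, seed = config$seed)
  rm_args <- config$read_model
  model <- read_model(mean_length = rm_args$mean_length,
                      min_length = rm_args$min_length,
                      max_length = rm_args$max_length,
                      abundance_exponent = rm_args$abundance_exponent,
                      full_length_prob = rm_args$full_length_prob,
                      seed = config$seed)
  rr <- generate_reads(vars, model, config$total_reads)
  all_reads <- rr$reads
  bg_cats <- data.frame(id = character(0), category = character(0))
  if (config$n_background > 0) {
    bg <- generate_background(config$n_background, seed = config$seed + 1L)
    bg_cats <- attr(bg, "categories")
    all_reads <- c(all_reads, bg)
  }
  write_fasta(all_reads, file.path(out_dir, "reads.fasta"))
  .write_tsv(rr$truth, file.path(out_dir, "truth.tsv"))
  .write_tsv(data.frame(read_id = names(rr$read_map), variant_id = rr$read_map,
                        stringsAsFactors = FALSE),
             file.path(out_dir, "read_map.tsv"))
  .write_tsv(data.frame(variant_id = names(vars$cds), cds = vars$cds,
                        stringsAsFactors = FALSE),
             file.path(out_dir, "variant_cds.tsv"))
  .write_tsv(bg_cats, file.path(out_dir, "background_categories.tsv"))
  jsonlite::write_json(config, file.path(out_dir, "config_echo.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .log_msg("simulate", "info",
           sprintf("%d variants, %d reads, %d background transcripts",
                   nrow(rr$truth), length(rr$reads), config$n_background))
}

.stage_assemble <- function(config, out_dir) {
  reads_df <- read_fasta(file.path(out_dir, "reads.fasta"))
  if (any(grepl("[^ACGTN]", reads_df$seq)))
    stop("corrupt reads FASTA: non-nucleotide characters")
  reads <- stats::setNames(reads_df$seq, reads_df$id)
  res <- assemble(reads, assembly_params(min_overlap = config$assembly$min_overlap,
                                         use_revcomp = config$assembly$use_revcomp))
  all_tr <- rbind(res$contigs, res$singletons)
  keep <- all_tr$read_count > 1 |
    (config$singleton_passthrough & nchar(all_tr$seq) >= config$min_singleton_len)
  transcripts <- all_tr[keep, , drop = FALSE]
  write_fasta(stats::setNames(transcripts$seq, transcripts$contig_id),
              file.path(out_dir, "transcripts.fasta"),
              desc = sprintf("read_count=%d", transcripts$read_count))
  .write_tsv(res$membership, file.path(out_dir, "membership.tsv"))
  .log_msg("assemble", "info",
           sprintf("%d contigs, %d singletons, %d transcripts kept",
                   nrow(res$contigs), nrow(res$singletons), nrow(transcripts)))
}

.stage_annotate <- function(config, out_dir) {
  tr <- read_fasta(file.path(out_dir, "transcripts.fasta"))
  read_counts <- as.integer(sub("^read_count=", "", tr$desc))
  templates <- reference_templates()
  toxin_db <- stats::setNames(templates$precursor, templates$template_id)
  cellular_db <- nontoxin_references()
  catalog <- toxin_catalog()
  cats <- vector("list", nrow(tr)); precs <- list(); fws <- list()
  for (i in seq_len(nrow(tr))) {
    orfs <- find_orfs(tr$seq[i], id = tr$id[i],
                      min_aa = config$annotation$min_orf_aa)
    cl <- classify_transcript(tr$seq[i], toxin_db, cellular_db, orfs = orfs,
                              catalog = catalog,
                              max_evalue = config$annotation$max_evalue,
                              min_score = config$annotation$min_score)
    cats[[i]] <- cbind(data.frame(id = tr$id[i], read_count = read_counts[i],
                                  stringsAsFactors = FALSE),
                       cl[, c("category", "best_hit", "score", "evalue_like")])
    if (cl$category %in% c("Toxin_like", "Putative_toxin") && nrow(orfs)) {
      o <- if (!is.na(cl$orf_start)) {
        hit <- which(orfs$frame == cl$orf_frame & orfs$start == cl$orf_start &
                       orfs$end == cl$orf_end)
        if (length(hit)) orfs[hit[1], ] else prefer_orfs(orfs)[1, ]
      } else prefer_orfs(orfs)[1, ]
      aa0 <- sub("\\*+$", "", o$aa)
      aa <- if (!o$missing_start) refine_precursor_start(aa0, catalog) else aa0
      trim_nt <- 3L * (nchar(aa0) - nchar(aa))
      seg <- suppressWarnings(segment_precursor(aa, catalog,
                                                missing_start = o$missing_start))
      cds <- if (o$frame > 0) substr(tr$seq[i], o$start + trim_nt, o$end) else
        revcomp(substr(tr$seq[i], o$start, o$end - trim_nt))
      precs[[length(precs) + 1L]] <- data.frame(
        precursor_id = tr$id[i], read_count = read_counts[i],
        signal = seg$signal, propeptide = seg$propeptide, mature = seg$mature,
        signal_evidence = seg$signal_evidence,
        cleavage_motifs = paste(seg$cleavage_motifs, collapse = ","),
        precursor = aa, cds = cds, missing_start = o$missing_start,
        stringsAsFactors = FALSE)
      fw <- extract_framework(if (nzchar(seg$mature)) seg$mature else aa)
      fws[[length(fws) + 1L]] <- data.frame(
        precursor_id = tr$id[i], scaffold = fw$scaffold, n_cys = fw$n_cys,
        pattern_class = fw$pattern_class, parity = fw$parity,
        stringsAsFactors = FALSE)
    }
  }
  .write_tsv(do.call(rbind, cats), file.path(out_dir, "categories.tsv"))
  prec_df <- if (length(precs)) do.call(rbind, precs) else
    data.frame(precursor_id = character(0))
  .write_tsv(prec_df, file.path(out_dir, "precursors.tsv"))
  .write_tsv(if (length(fws)) do.call(rbind, fws) else
    data.frame(precursor_id = character(0)),
    file.path(out_dir, "frameworks.tsv"))
  .log_msg("annotate", "info",
           sprintf("%d transcripts classified, %d precursors segmented",
                   nrow(tr), length(precs)))
}

.stage_taxonomy <- function(config, out_dir) {
  prec <- .read_tsv(file.path(out_dir, "precursors.tsv"))
  if (!nrow(prec)) {
    .write_tsv(data.frame(precursor_id = character(0)),
               file.path(out_dir, "taxonomy.tsv"))
    return(invisible())
  }
  for (cc in c("signal", "propeptide", "mature", "precursor"))
    prec[[cc]][is.na(prec[[cc]])] <- ""
  sfa <- assign_superfamily(prec, threshold = config$taxonomy$superfamily)
  out <- merge(sfa, prec[, c("precursor_id", "precursor", "mature")],
               by = "precursor_id")
  out$family <- NA_character_; out$subfamily <- NA_character_
  for (sf in unique(out$superfamily)) {
    sel <- which(out$superfamily == sf)
    fams <- cluster_families(out[sel, c("precursor_id", "precursor", "mature")],
                             family_threshold = config$taxonomy$family,
                             subfamily_threshold = config$taxonomy$subfamily)
    out$family[sel] <- paste0(sf, ":", fams$family[match(out$precursor_id[sel],
                                                         fams$precursor_id)])
    out$subfamily[sel] <- paste0(sf, ":", fams$subfamily[match(out$precursor_id[sel],
                                                               fams$precursor_id)])
  }
  .write_tsv(out[, c("precursor_id", "superfamily", "family", "subfamily",
                     "identity_to_nearest", "flagged")],
             file.path(out_dir, "taxonomy.tsv"))
  .log_msg("taxonomy", "info",
           sprintf("%d precursors in %d superfamilies", nrow(out),
                   length(unique(out$superfamily))))
}

.stage_variants <- function(config, out_dir) {
  prec <- .read_tsv(file.path(out_dir, "precursors.tsv"))
  tax <- .read_tsv(file.path(out_dir, "taxonomy.tsv"))
  if (!nrow(prec) || !nrow(tax)) {
    .write_tsv(data.frame(), file.path(out_dir, "events.tsv"))
    .write_tsv(data.frame(), file.path(out_dir, "tiers.tsv"))
    return(invisible())
  }
  m <- merge(prec, tax, by = "precursor_id")
  m$tier <- vapply(m$read_count, assign_tier, character(1))
  .write_tsv(m[order(m$precursor_id), c("precursor_id", "read_count", "tier")],
             file.path(out_dir, "tiers.tsv"))
  events <- list()
  for (fam in unique(m$family)) {
    mem <- m[m$family == fam & !is.na(m$cds) & nzchar(m$cds), , drop = FALSE]
    if (nrow(mem) < 2) next
    ref_id <- family_reference(mem)
    ref <- mem[mem$precursor_id == ref_id, ]
    mat_start <- nchar(ref$signal) + nchar(ref$propeptide) + 1L
    for (k in which(mem$precursor_id != ref_id)) {
      res <- classify_variant_events(mem$cds[k], ref$cds,
                                     reference_mature_start = mat_start)
      if (res$flagged || !nrow(res$events)) next
      ev <- res$events
      ev$variant_id <- mem$precursor_id[k]; ev$reference_id <- ref_id
      events[[length(events) + 1L]] <-
        ev[, c("variant_id", "reference_id", "kind", "nt_position", "detail")]
    }
  }
  .write_tsv(if (length(events)) do.call(rbind, events) else
    data.frame(variant_id = character(0), reference_id = character(0),
               kind = character(0), nt_position = integer(0),
               detail = character(0)),
    file.path(out_dir, "events.tsv"))
  .log_msg("variants", "info", sprintf("%d variant events",
           if (length(events)) sum(vapply(events, nrow, 1L)) else 0L))
}

.stage_evolve <- function(config, out_dir) {
  prec <- .read_tsv(file.path(out_dir, "precursors.tsv"))
  tax <- .read_tsv(file.path(out_dir, "taxonomy.tsv"))
  dir.create(file.path(out_dir, "trees"), showWarnings = FALSE)
  dnds_rows <- list(); sel_rows <- list()
  if (nrow(prec) && nrow(tax)) {
    m <- merge(prec, tax, by = "precursor_id")
    for (sf in config$evolution$superfamilies) {
      mem <- m[m$superfamily == sf & !m$flagged & nzchar(m$cds), , drop = FALSE]
      if (nrow(mem) < config$evolution$min_members) next
      ref_id <- family_reference(mem)
      ref_cds <- mem$cds[mem$precursor_id == ref_id]
      proj <- vapply(seq_len(nrow(mem)), function(k)
        .project_onto_reference(mem$cds[k], ref_cds), character(1))
      names(proj) <- mem$precursor_id
      ok <- !is.na(proj)
      proj <- proj[ok]
      if (length(proj) < config$evolution$min_members) next
      ids <- names(proj)
      for (a in seq_len(length(proj) - 1)) for (b in (a + 1):length(proj)) {
        cn <- ng_counts(proj[[a]], proj[[b]])
        if (cn$N <= 0 || cn$S <= 0) next
        dd <- dnds(cn)
        zone <- classify_selection(dd)
        pval <- fisher_positive_selection(cn)
        dnds_rows[[length(dnds_rows) + 1L]] <- data.frame(
          superfamily = sf, id1 = ids[a], id2 = ids[b],
          Nd = cn$Nd, Sd = cn$Sd, N = cn$N, S = cn$S,
          Dn = dd$Dn, Ds = dd$Ds, ratio = dd$ratio, fisher_p = pval,
          stringsAsFactors = FALSE)
        sel_rows[[length(sel_rows) + 1L]] <- data.frame(
          superfamily = sf, id1 = ids[a], id2 = ids[b], zone = zone,
          stringsAsFactors = FALSE)
      }
      aa_mat <- t(vapply(proj, .codon_string_to_aa, character(nchar(proj[[1]]) %/% 3)))
      rownames(aa_mat) <- ids
      bt <- nj_bootstrap(aa_mat, replicates = config$evolution$bootstrap,
                         seed = config$seed)
      ape::write.tree(bt$tree, file.path(out_dir, "trees", paste0(sf, ".nwk")))
    }
  }
  dn_df <- if (length(dnds_rows)) do.call(rbind, dnds_rows) else
    data.frame(superfamily = character(0), id1 = character(0),
               id2 = character(0), Dn = numeric(0), Ds = numeric(0),
               ratio = numeric(0), fisher_p = numeric(0))
  .write_tsv(dn_df, file.path(out_dir, "dnds.tsv"))
  .write_tsv(if (length(sel_rows)) do.call(rbind, sel_rows) else
    data.frame(superfamily = character(0), zone = character(0)),
    file.path(out_dir, "selection.tsv"))
  scatter <- dn_df[!is.na(dn_df$Dn) & !is.na(dn_df$Ds),
                   c("superfamily", "Ds", "Dn"), drop = FALSE]
  .write_tsv(scatter, file.path(out_dir, "dnds_scatter.tsv"))
  .log_msg("evolve", "info", sprintf("%d pairwise Dn/Ds comparisons",
                                     nrow(dn_df)))
}

# codon-align a CDS to the reference and keep only reference codon columns
.project_onto_reference <- function(cds, ref_cds) {
  ca <- codon_align(ref_cds, cds)
  p <- ca$cds1; s <- ca$cds2
  n <- nchar(p) %/% 3
  keep <- vapply(seq_len(n), function(i) .codon_at(p, i) != "---", logical(1))
  out <- paste(vapply(which(keep), function(i) .codon_at(s, i), character(1)),
               collapse = "")
  if (!nzchar(out)) NA_character_ else out
}

.codon_string_to_aa <- function(cds) {
  n <- nchar(cds) %/% 3
  vapply(seq_len(n), function(i) {
    cod <- .codon_at(cds, i)
    if (cod == "---") "-" else if (grepl("[^ACGT]", cod)) "X"
    else .translate_codon(cod)
  }, character(1))
}

.stage_report <- function(config, out_dir) {
  cats <- .read_tsv(file.path(out_dir, "categories.tsv"))
  tax <- .read_tsv(file.path(out_dir, "taxonomy.tsv"))
  tiers <- .read_tsv(file.path(out_dir, "tiers.tsv"))
  fws <- .read_tsv(file.path(out_dir, "frameworks.tsv"))
  ev <- tryCatch(.read_tsv(file.path(out_dir, "events.tsv")),
                 error = function(e) NULL)
  sel <- tryCatch(.read_tsv(file.path(out_dir, "selection.tsv")),
                  error = function(e) NULL)
  rep <- build_report(cats, tax, tiers, fws, events = ev, selection = sel)
  write_report(rep, out_dir)
  .log_msg("report", "info", "report written")
}

# ---- orchestration ----------------------------------------------------------

.stage_io <- function(stage, out_dir) {
  f <- function(...) file.path(out_dir, ...)
  switch(stage,
    simulate = list(inputs = character(0),
                    outputs = f(c("reads.fasta", "truth.tsv", "read_map.tsv",
                                  "variant_cds.tsv", "background_categories.tsv",
                                  "config_echo.json"))),
    assemble = list(inputs = f("reads.fasta"),
                    outputs = f(c("transcripts.fasta", "membership.tsv"))),
    annotate = list(inputs = f("transcripts.fasta"),
                    outputs = f(c("categories.tsv", "precursors.tsv",
                                  "frameworks.tsv"))),
    taxonomy = list(inputs = f("precursors.tsv"),
                    outputs = f("taxonomy.tsv")),
    variants = list(inputs = f(c("precursors.tsv", "taxonomy.tsv")),
                    outputs = f(c("events.tsv", "tiers.tsv"))),
    evolve = list(inputs = f(c("precursors.tsv", "taxonomy.tsv")),
                  outputs = f(c("dnds.tsv", "selection.tsv", "dnds_scatter.tsv"))),
    report = list(inputs = f(c("categories.tsv", "taxonomy.tsv", "tiers.tsv",
                               "frameworks.tsv", "events.tsv", "selection.tsv")),
                  outputs = f(c("report.json", "superfamilies.tsv"))))
}

.stage_params <- function(stage, config) {
  switch(stage,
    simulate = config[c("seed", "n_variants_per_template", "total_reads",
                        "n_background", "mutation_rates", "read_model")],
    assemble = config[c("assembly", "singleton_passthrough", "min_singleton_len")],
    annotate = config["annotation"],
    taxonomy = config["taxonomy"],
    variants = list(),
    evolve = config[c("seed", "evolution")],
    report = list())
}

#' Run the full pipeline
#'
#' Stages run in dependency order; each stage writes a manifest (parameter
#' echo plus input/output checksums) under \code{out_dir/manifests} and is
#' skipped when up-to-date. A stage failure halts with an error naming the
#' stage, preserving partial outputs.
#'
#' @param config Configuration list, see [default_config()].
#' @param out_dir Output directory.
#' @param force Re-run stages even when up-to-date.
#' @param stages Subset of stages to run (in pipeline order).
#' @return Invisibly, a data.frame of stages and their status.
#' @export
run_pipeline <- function(config = default_config(), out_dir, force = FALSE,
                         stages = .stage_order) {
  if (missing(out_dir)) stop("out_dir is required")
  if (is.null(config$seed)) stop("config$seed is mandatory")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- .stage_order[.stage_order %in% stages]
  funs <- list(simulate = .stage_simulate, assemble = .stage_assemble,
               annotate = .stage_annotate, taxonomy = .stage_taxonomy,
               variants = .stage_variants, evolve = .stage_evolve,
               report = .stage_report)
  status <- character(0)
  for (stage in stages) {
    io <- .stage_io(stage, out_dir)
    params <- .stage_params(stage, config)
    if (!force && .stage_up_to_date(out_dir, stage, params, io$inputs, io$outputs)) {
      .log_msg(stage, "info", "up-to-date, skipped")
      status[stage] <- "skipped"
      next
    }
    missing_in <- io$inputs[!file.exists(io$inputs)]
    if (length(missing_in))
      stop(sprintf("stage '%s': missing dependency input(s): %s", stage,
                   paste(basename(missing_in), collapse = ", ")))
    ok <- tryCatch({ funs[[stage]](config, out_dir); TRUE },
                   error = function(e)
                     stop(sprintf("stage '%s' failed: %s", stage,
                                  conditionMessage(e)), call. = FALSE))
    .write_manifest(out_dir, stage, params, io$inputs, io$outputs)
    status[stage] <- "ran"
  }
  invisible(data.frame(stage = names(status), status = unname(status),
                       stringsAsFactors = FALSE))
}
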