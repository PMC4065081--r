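# Synthetic venom-gland transcriptome generator. Emulates the statistical
# structure the downstream analysis assumes: precursor architecture
# signal+propeptide+mature with conserved cleavage motifs, cysteine scaffolds
# of 4-12 residues, the observed mutation classes, a Zipf-like per-precursor
# read abundance with a long singleton tail, and 454-style read lengths.

#' Read model for the synthetic sequencer
#'
#' Lengths are drawn from a lognormal truncated to [min_length, max_length],
#' with the location chosen so the truncated mean equals \code{mean_length}
#' (327 nt emulates 454 pyrosequencing reads ranging 40-836 nt). With
#' probability \code{full_length_prob} a read is anchored at the cDNA 5' end,
#' emulating a full-length-enriched library; otherwise its start is uniform.
#'
#' @param mean_length,min_length,max_length Read-length parameters (nt).
#' @param abundance_exponent Zipf exponent for the per-variant read counts.
#' @param full_length_prob Probability a read is 5'-anchored.
#' @param seed Integer seed; fixed seed implies byte-identical output.
#' @return list of class \code{read_model}.
#' @export
read_model <- function(mean_length = 327, min_length = 40, max_length = 836,
                       abundance_exponent = 1.5, full_length_prob = 0.9,
                       seed = 1L) {
  if (!(min_length <= mean_length && mean_length <= max_length))
    stop("need min_length <= mean_length <= max_length")
  structure(list(mean_length = mean_length, min_length = min_length,
                 max_length = max_length,
                 # truncation to [40,836] raises the mean ~6% at sdlog 0.35
                 meanlog = log(mean_length) - 0.060, sdlog = 0.35,
                 abundance_exponent = abundance_exponent,
                 full_length_prob = full_length_prob, seed = as.integer(seed)),
            class = "read_model")
}

#' Sample read lengths from a read model
#'
#' @param model A [read_model()].
#' @param n Number of lengths.
#' @return Integer vector in [min_length, max_length].
#' @export
sample_read_lengths <- function(model, n) {
  L <- round(stats::rlnorm(n, model$meanlog, model$sdlog))
  pmin(pmax(L, model$min_length), model$max_length)
}

#' Zipf-like per-variant read counts with a singleton tail
#'
#' \code{round(rare_fraction * n)} variants receive exactly one read; the
#' remainder receive counts proportional to \code{rank^-exponent} scaled to
#' \code{total_reads} minus the singletons (each at least 2). Ranks are
#' randomly permuted over the variants.
#'
#' @param n Number of variants.
#' @param total_reads Approximate total read budget.
#' @param exponent Zipf exponent.
#' @param rare_fraction Fraction of variants receiving a single read.
#' @return Integer vector of length \code{n} (all >= 1).
#' @export
zipf_read_counts <- function(n, total_reads, exponent = 1.5, rare_fraction = 2/3) {
  stopifnot(n >= 1, total_reads >= n)
  n_rare <- round(rare_fraction * n)
  m <- n - n_rare
  head_counts <- integer(0)
  if (m > 0) {
    w <- (seq_len(m))^(-exponent)
    head_counts <- pmax(2L, as.integer(round(w / sum(w) * (total_reads - n_rare))))
  }
  counts <- c(head_counts, rep(1L, n_rare))
  counts[sample.int(n)]
}

.mutation_kinds <- c("point", "insertion", "deletion", "premature_stop", "stop_loss")

# draw one mutation spec of the given kind against a CDS; positions are
# 1-based on the unmutated CDS. Indels, premature stops and stop losses
# target the mature-coding region (C-terminal variability dominates the
# observed isoforms); points land anywhere in codons 2..(last-1).
.draw_mutation <- function(kind, cds, mature_start_nt) {
  L <- nchar(cds)
  n_codon <- L %/% 3L
  if (kind == "point") {
    repeat {
      pos <- sample(4:(L - 3L), 1)
      base <- substr(cds, pos, pos)
      new <- sample(setdiff(c("A", "C", "G", "T"), base), 1)
      cod_i <- (pos - 1L) %/% 3L
      cod <- substr(cds, cod_i * 3L + 1L, cod_i * 3L + 3L)
      ncod <- cod
      substr(ncod, pos - cod_i * 3L, pos - cod_i * 3L) <- new
      if (!ncod %in% c("TAA", "TAG", "TGA")) # stop creation is its own class
        return(list(kind = kind, position = pos, payload = new, length = 0L))
    }
  }
  lo <- max(mature_start_nt, 4L)
  hi <- L - 6L
  if (kind == "insertion") {
    pos <- sample(lo:hi, 1)
    len <- sample(1:6, 1)
    payload <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    return(list(kind = kind, position = pos, payload = payload, length = len))
  }
  if (kind == "deletion") {
    len <- sample(1:6, 1)
    pos <- sample(lo:(hi - len), 1)
    return(list(kind = kind, position = pos, payload = "", length = len))
  }
  if (kind == "premature_stop") {
    cod_i <- sample((((lo - 1L) %/% 3L) + 2L):(n_codon - 2L), 1)
    return(list(kind = kind, position = (cod_i - 1L) * 3L + 1L,
                payload = "TAA", length = 0L))
  }
  # stop_loss: first base of the terminal stop codon becomes C (TAA -> CAA)
  list(kind = "stop_loss", position = L - 2L, payload = "C", length = 0L)
}

.apply_mutations <- function(cds, specs) {
  if (!length(specs)) return(cds)
  ord <- order(vapply(specs, `[[`, 0, "position"), decreasing = TRUE)
  for (sp in specs[ord]) {
    p <- sp$position
    cds <- switch(sp$kind,
      point = , stop_loss = {
        substr(cds, p, p) <- sp$payload; cds
      },
      premature_stop = paste0(substr(cds, 1, p - 1), "TAA",
                              substr(cds, p + 3, nchar(cds))),
      insertion = paste0(substr(cds, 1, p), sp$payload,
                         substr(cds, p + 1, nchar(cds))),
      deletion = paste0(substr(cds, 1, p - 1),
                        substr(cds, p + sp$length, nchar(cds))))
  }
  cds
}

#' Apply a list of mutation specs to a CDS
#'
#' Specs are lists with \code{kind} (point, insertion, deletion,
#' premature_stop, stop_loss), 1-based \code{position} on the unmutated CDS,
#' \code{payload} and (for deletions) \code{length}. Applied right-to-left so
#' recorded positions stay valid.
#'
#' @param cds Coding nucleotide string (with stop codon).
#' @param specs list of mutation specs.
#' @return Mutated nucleotide string.
#' @export
apply_mutation_specs <- function(cds, specs) .apply_mutations(cds, specs)

.spec_string <- function(specs) {
  if (!length(specs)) return("")
  paste(vapply(specs, function(sp) {
    sprintf("%s@%d:%s%s", sp$kind, sp$position, sp$payload,
            if (sp$length > 0 && sp$kind == "deletion") sprintf("(%d)", sp$length) else "")
  }, character(1)), collapse = ";")
}

# random UTRs; 3' UTR carries an in-frame stop shortly downstream so
# stop-loss variants terminate within the cDNA
.make_utrs <- function() {
  utr5 <- paste(sample(c("A", "C", "G", "T"), sample(10:30, 1), replace = TRUE),
                collapse = "")
  tail3 <- paste(sample(c("A", "C", "G", "T"), sample(20:50, 1), replace = TRUE),
                 collapse = "")
  utr3 <- paste0("GCAGCTGCAGCT", "TAA", tail3)  # 12 nt then in-frame TAA
  list(utr5 = utr5, utr3 = utr3)
}

#' Generate mutated toxin variants with a ground-truth ledger
#'
#' Each template precursor is reverse-translated to a CDS (fixed codon table,
#' TAA stop) and \code{n_variants_per_template} variants are drawn. For each
#' variant every mutation kind is included independently with its configured
#' probability; the applied specs are recorded so each variant cDNA derives
#' from its template CDS by exactly the recorded list.
#'
#' @param templates data.frame as from [reference_templates()].
#' @param n_variants_per_template Variants per template: a single count, an
#'   unnamed vector recycled over templates, or a vector named by
#'   superfamily (unnamed superfamilies default to 1).
#' @param mutation_rates Named per-kind probabilities in [0,1]
#'   (\code{point}, \code{insertion}, \code{deletion}, \code{premature_stop},
#'   \code{stop_loss}).
#' @param seed Integer seed.
#' @return list with \code{cdna} (named vector), \code{cds} (named vector,
#'   mutated CDS without UTRs), \code{truth} (data.frame), \code{specs}
#'   (named list of per-variant mutation lists).
#' @export
generate_variants <- function(templates,
                              n_variants_per_template = 13L,
                              mutation_rates = c(point = 0.35, insertion = 0.08,
                                                 deletion = 0.08,
                                                 premature_stop = 0.05,
                                                 stop_loss = 0.03),
                              seed = 1L) {
  if (!nrow(templates)) stop("templates must be non-empty")
  rates <- mutation_rates[.mutation_kinds]
  names(rates) <- .mutation_kinds
  rates[is.na(rates)] <- 0
  if (any(rates < 0 | rates > 1)) stop("mutation rates must lie in [0,1]")
  n_per <- n_variants_per_template
  if (!is.null(names(n_per))) {
    n_per <- n_per[templates$superfamily]
    n_per[is.na(n_per)] <- 1L
  } else {
    n_per <- rep_len(n_per, nrow(templates))
  }
  n_per <- as.integer(n_per)
  if (any(n_per < 1)) stop("n_variants_per_template must be >= 1")
  set.seed(as.integer(seed))
  cdna <- character(0); cds_out <- character(0)
  truth <- list(); specs_out <- list()
  for (i in seq_len(nrow(templates))) {
    tpl <- templates[i, ]
    cds0 <- reverse_translate(tpl$precursor, add_stop = TRUE)
    mature_start_nt <- (nchar(tpl$signal_peptide) + nchar(tpl$propeptide)) * 3L + 1L
    for (j in seq_len(n_per[i])) {
      vid <- sprintf("%s_v%02d", tpl$template_id, j)
      specs <- list()
      for (kind in .mutation_kinds) {
        if (stats::runif(1) < rates[[kind]])
          specs[[length(specs) + 1L]] <- .draw_mutation(kind, cds0, mature_start_nt)
      }
      cds <- .apply_mutations(cds0, specs)
      u <- .make_utrs()
      cdna[vid] <- paste0(u$utr5, cds, u$utr3)
      cds_out[vid] <- cds
      specs_out[[vid]] <- specs
      truth[[length(truth) + 1L]] <- data.frame(
        variant_id = vid, template_id = tpl$template_id,
        superfamily = tpl$superfamily, mutations = .spec_string(specs),
        n_mutations = length(specs), cds_offset = nchar(u$utr5) + 1L,
        stringsAsFactors = FALSE)
    }
  }
  list(cdna = cdna, cds = cds_out, truth = do.call(rbind, truth),
       specs = specs_out)
}

#' Emit error-free reads from variant cDNAs
#'
#' The read budget is split across superfamilies in proportion to their
#' variant counts (each superfamily hosts its own expression hierarchy, so
#' read totals track precursor counts), and per-variant counts within each
#' superfamily come from [zipf_read_counts()]; everything is recorded in the
#' returned truth table together with the expression tier. Every read is an
#' exact substring of its source cDNA, clipped to the model's length range
#' and to the cDNA length.
#'
#' @param variants Output of [generate_variants()] (or a named cDNA vector).
#' @param model A [read_model()].
#' @param total_reads Approximate total read budget.
#' @return list with \code{reads} (named vector), \code{truth} (ledger with
#'   \code{read_count} and \code{tier}), \code{read_map} (read id -> variant).
#' @export
generate_reads <- function(variants, model = read_model(), total_reads = 5000L) {
  cdna <- if (is.list(variants)) variants$cdna else variants
  if (!length(cdna)) stop("empty variant set")
  truth <- if (is.list(variants) && !is.null(variants$truth)) variants$truth else
    data.frame(variant_id = names(cdna), stringsAsFactors = FALSE)
  set.seed(model$seed)
  groups <- if (!is.null(truth$superfamily))
    truth$superfamily[match(names(cdna), truth$variant_id)]
  else rep("all", length(cdna))
  counts <- integer(length(cdna))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    budget <- max(length(idx), round(total_reads * length(idx) / length(cdna)))
    counts[idx] <- zipf_read_counts(length(idx), budget,
                                    model$abundance_exponent)
  }
  reads <- character(0); read_map <- character(0)
  for (i in seq_along(cdna)) {
    src <- cdna[[i]]; vid <- names(cdna)[i]
    Ls <- sample_read_lengths(model, counts[i])
    for (k in seq_len(counts[i])) {
      L <- min(Ls[k], nchar(src))
      start <- if (stats::runif(1) < model$full_length_prob || L >= nchar(src)) 1L
               else sample.int(nchar(src) - L + 1L, 1)
      rid <- sprintf("%s_r%03d", vid, k)
      reads[rid] <- substr(src, start, start + L - 1L)
      read_map[rid] <- vid
    }
  }
  truth$read_count <- counts[match(truth$variant_id, names(cdna))]
  truth$tier <- vapply(truth$read_count, assign_tier, character(1))
  list(reads = reads, truth = truth, read_map = read_map)
}

#' Generate background (non-toxin) transcripts
#'
#' Categories: \code{cellular} are residue-shuffled housekeeping-style ORFs
#' (shuffling guarantees no similarity hits while preserving low cysteine
#' content); \code{no_hit} are random-composition sequences with no ORF of
#' \code{min_orf_aa}+; \code{unknown} are lightly mutated copies of the
#' bundled unannotated reference proteins; \code{toxin_like_decoy} are
#' lightly mutated copies of toxin reference precursors.
#'
#' @param n Number of sequences.
#' @param category_mix Named proportions summing to 1 (within 1e-9).
#' @param seed Integer seed.
#' @param min_orf_aa ORF threshold used when constructing \code{no_hit}.
#' @return Named character vector with attribute \code{categories}
#'   (data.frame id, category).
#' @export
generate_background <- function(n,
                                category_mix = c(cellular = 0.44, no_hit = 0.20,
                                                 unknown = 0.07,
                                                 toxin_like_decoy = 0.29),
                                seed = 1L, min_orf_aa = 40L) {
  if (any(category_mix < 0)) stop("negative proportion")
  if (abs(sum(category_mix) - 1) > 1e-9) stop("proportions must sum to 1")
  set.seed(as.integer(seed))
  refs <- nontoxin_references()
  cellular <- refs[refs$annotated, ]
  unknown <- refs[!refs$annotated, ]
  tpls <- reference_templates()
  cats <- sample(names(category_mix), n, replace = TRUE, prob = category_mix)
  mutate_aa <- function(aa, rate = 0.03) {
    res <- strsplit(aa, "")[[1]]
    hit <- which(stats::runif(length(res)) < rate & res != "M" & res != "C")
    if (length(hit))
      res[hit] <- sample(setdiff(LETTERS[LETTERS %in% names(codon_table())], "C"),
                         length(hit), replace = TRUE)
    paste(res, collapse = "")
  }
  out <- character(n)
  for (i in seq_len(n)) {
    out[i] <- switch(cats[i],
      cellular = {
        aa <- cellular$seq[sample.int(nrow(cellular), 1)]
        body <- strsplit(substr(aa, 2, nchar(aa)), "")[[1]]
        aa <- paste0("M", paste(sample(body), collapse = ""))
        u <- .make_utrs()
        paste0(u$utr5, reverse_translate(aa), u$utr3)
      },
      no_hit = {
        repeat {
          s <- paste(sample(c("A", "C", "G", "T"), sample(250:500, 1),
                            replace = TRUE), collapse = "")
          if (!nrow(find_orfs(s, min_aa = min_orf_aa))) break
        }
        s
      },
      unknown = {
        aa <- mutate_aa(unknown$seq[sample.int(nrow(unknown), 1)])
        u <- .make_utrs()
        paste0(u$utr5, reverse_translate(aa), u$utr3)
      },
      toxin_like_decoy = {
        aa <- mutate_aa(tpls$precursor[sample.int(nrow(tpls), 1)])
        u <- .make_utrs()
        paste0(u$utr5, reverse_translate(aa), u$utr3)
      })
  }
  ids <- sprintf("bg_%s_%04d", cats, seq_len(n))
  names(out) <- ids
  attr(out, "categories") <- data.frame(id = ids, category = cats,
                                        stringsAsFactors = FALSE)
  out
}
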