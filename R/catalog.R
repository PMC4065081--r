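#' Cysteine framework patterns I-XI
#'
#' Named character vector mapping pattern labels to scaffold strings, where
#' isolated cysteines render as \code{-C-} and adjacent pairs as \code{CC}.
#' These are the eleven scaffolds observed in HWTX-type venom peptides.
#'
#' @return Named character vector of scaffold strings.
#' @export
framework_patterns <- function() {
  c(I    = "-C-C-CC-C-C-",
    II   = "-C-C-C-C-C-C-",
    III  = "-C-C-CC-C-C-C-C-",
    IV   = "-C-C-C-CC-C-C-C-",
    V    = "-C-C-C-C-C-C-C-C-",
    VI   = "-C-C-CC-C-C-C-C-C-C-",
    VII  = "-C-C-CC-C-C-C-C-CC-C-C-",
    VIII = "-C-C-C-C-C-",
    IX   = "-C-C-C-C-",
    X    = "-C-C-C-C-C-C-C-",
    XI   = "-C-C-C-CC-C-C-")
}

#' Load the bundled toxin superfamily reference catalog
#'
#' The catalog holds the 16 HWTX gene superfamilies with their conserved
#' signal peptides, representative cysteine framework pattern and known
#' family labels. Superfamily XXV carries no signal peptide and is matched
#' by its conserved propeptide instead. Superfamilies XI, XIV, XXIII and
#' XXIV lack a propeptide region.
#'
#' @param path Optional path to a catalog TSV; defaults to the bundled file.
#' @return A data.frame with columns \code{superfamily}, \code{signal_peptide},
#'   \code{propeptide_anchor}, \code{framework}, \code{families},
#'   \code{has_propeptide}.
#' @export
toxin_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "superfamily_catalog.tsv", package = "venomics")
  }
  cat_df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL)
  cat_df$signal_peptide[is.na(cat_df$signal_peptide)] <- ""
  cat_df$propeptide_anchor[is.na(cat_df$propeptide_anchor)] <- ""
  cat_df$has_propeptide <- as.logical(cat_df$has_propeptide)
  stopifnot(nrow(cat_df) == 16L)
  cat_df
}

#' Fixed reverse-translation codon table
#'
#' One codon per amino acid (a fixed, versioned high-usage codon choice),
#' used when reverse-translating peptide templates to CDS. \code{*} maps to
#' the stop codon used for template CDSs.
#'
#' @return Named character vector, names are one-letter amino acids.
#' @export
codon_table <- function() {
  path <- system.file("extdata", "codon_table.tsv", package = "venomics")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(tab$codon, tab$aa)
}

#' Reverse-translate an amino-acid string with the fixed codon table
#'
#' @param aa Amino-acid string (no stops except optional trailing \code{*}).
#' @param add_stop Append the stop codon.
#' @return Nucleotide string.
#' @export
reverse_translate <- function(aa, add_stop = TRUE) {
  tab <- codon_table()
  res <- strsplit(aa, "")[[1]]
  bad <- setdiff(res, names(tab))
  if (length(bad)) stop("no codon for residue(s): ", paste(bad, collapse = ","))
  nt <- paste(tab[res], collapse = "")
  if (add_stop) nt <- paste0(nt, tab[["*"]])
  nt
}

# Deterministic spacer string for mature-peptide construction. The region
# before the first cysteine avoids E/D/R so no spurious processing-quadruplet
# motif can precede the mature cysteine scaffold.
.spacer <- function(n, pre_first_cys = FALSE) {
  pool <- c("A", "S", "G", "T", "N", "L", "V", "F", "W", "Y", "K", "Q", "H", "I", "P")
  if (!pre_first_cys) pool <- c(pool, "E", "D", "R")
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

# Build a mature peptide realising a framework scaffold string such as
# "-C-C-CC-C-C-". Spacer lengths are drawn from the active RNG stream.
.mature_from_scaffold <- function(scaffold) {
  parts <- strsplit(scaffold, "")[[1]]
  out <- character(0)
  first_c_done <- FALSE
  for (p in parts) {
    if (p == "C") {
      out <- c(out, "C")
      first_c_done <- TRUE
    } else {
      n <- sample(3:7, 1)
      out <- c(out, .spacer(n, pre_first_cys = !first_c_done))
    }
  }
  paste(out, collapse = "")
}

#' Reference toxin precursor templates
#'
#' Deterministically generated precursor templates, one per catalog
#' superfamily: the catalog signal peptide, an acidic propeptide ending in a
#' processing quadruplet motif (GEER/SEER class) where the superfamily has a
#' propeptide, and a synthetic mature peptide realising the superfamily's
#' cysteine framework. These synthetic templates serve both as the ground
#' truth for the read simulator and as the toxin reference proteins for
#' similarity search.
#'
#' @param catalog Reference catalog data.frame, see [toxin_catalog()].
#' @return data.frame with columns \code{template_id}, \code{superfamily},
#'   \code{signal_peptide}, \code{propeptide}, \code{mature_peptide},
#'   \code{framework_pattern}, \code{precursor}.
#' @export
reference_templates <- function(catalog = toxin_catalog()) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(20140620L)  # fixed: templates are a versioned resource
  fw <- framework_patterns()
  propep_known <- c(
    I   = "SELEEESQLMEVGMPDTELEAVDEER",
    XXV = "MTREETQSLGEHEKDEEVTGSEER"
  )
  rows <- lapply(seq_len(nrow(catalog)), function(i) {
    sf <- catalog$superfamily[i]
    signal <- catalog$signal_peptide[i]
    if (catalog$has_propeptide[i]) {
      if (sf %in% names(propep_known)) {
        propep <- propep_known[[sf]]
      } else {
        # acidic linker ending in a PQM; no cysteines
        body <- paste(sample(c("E", "D", "S", "A", "L", "V", "G", "T", "Q", "K", "P"),
                             sample(12:20, 1), replace = TRUE), collapse = "")
        propep <- paste0(body, sample(c("GEER", "SEER"), 1))
      }
    } else {
      propep <- ""
    }
    mature <- .mature_from_scaffold(fw[[catalog$framework[i]]])
    fam <- strsplit(catalog$families[i], ",")[[1]][1]
    data.frame(template_id = fam, superfamily = sf, signal_peptide = signal,
               propeptide = propep, mature_peptide = mature,
               framework_pattern = catalog$framework[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$precursor <- paste0(out$signal_peptide, out$propeptide, out$mature_peptide)
  out
}

#' Bundled non-toxin reference proteins
#'
#' Small synthetic protein sets used by the transcript classifier as the
#' cellular ("annotated") and unknown-function ("unannotated") reference
#' databases, and by the background generator. All sequences are synthetic
#' stand-ins constructed for this package, not real database entries.
#'
#' @return data.frame with columns \code{id}, \code{seq}, \code{annotated}.
#' @export
nontoxin_references <- function() {
  f1 <- system.file("extdata", "cellular_refs_synthetic.fasta", package = "venomics")
  f2 <- system.file("extdata", "unknown_refs_synthetic.fasta", package = "venomics")
  a <- read_fasta(f1)
  b <- read_fasta(f2)
  data.frame(id = c(a$id, b$id), seq = c(a$seq, b$seq),
             annotated = c(rep(TRUE, nrow(a)), rep(FALSE, nrow(b))),
             stringsAsFactors = FALSE)
}
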