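# Nei-Gojobori (original, equal-weight pathway averaging) synonymous /
# nonsynonymous counting with Jukes-Cantor correction, Fig-8-style selection
# zones, and a Fisher exact test for positive selection.

.GC <- local({
  env <- new.env()
  function() {
    if (is.null(env$gc)) {
      gc <- Biostrings::GENETIC_CODE
      env$gc <- stats::setNames(as.character(gc), names(gc))
    }
    env$gc
  }
})

.BASES <- c("A", "C", "G", "T")

# synonymous-site count of one codon: per position, the fraction of the 3
# possible changes that are synonymous (changes to stop codons count as
# nonsynonymous, keeping N + S = 3 per codon)
.syn_sites_one <- function(codon) {
  gc <- .GC()
  aa <- gc[[codon]]
  total <- 0
  for (pos in 1:3) {
    b <- substr(codon, pos, pos)
    for (nb in setdiff(.BASES, b)) {
      alt <- codon
      substr(alt, pos, pos) <- nb
      if (gc[[alt]] != "*" && gc[[alt]] == aa) total <- total + 1 / 3
    }
  }
  total
}

.syn_sites_table <- local({
  env <- new.env()
  function() {
    if (is.null(env$t)) {
      cods <- names(.GC())
      env$t <- stats::setNames(vapply(cods, .syn_sites_one, numeric(1)), cods)
    }
    env$t
  }
})

# all permutations of a small index vector
.perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in .perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# average (syn, nonsyn) difference counts over all minimal substitution
# pathways between two sense codons; pathways through stops are excluded.
# Returns c(sd, nd) or NULL when every pathway passes a stop.
# Results are memoised per codon pair.
.pathway_memo <- new.env(parent = emptyenv())

.pathway_diffs <- function(c1, c2) {
  key <- paste0(c1, c2)
  hit <- .pathway_memo[[key]]
  if (!is.null(hit)) {
    if (identical(hit, "blocked")) return(NULL)
    return(hit)
  }
  val <- .pathway_diffs_compute(c1, c2)
  .pathway_memo[[key]] <- if (is.null(val)) "blocked" else val
  val
}

.pathway_diffs_compute <- function(c1, c2) {
  gc <- .GC()
  dpos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(dpos)) return(c(0, 0))
  tot_s <- 0; tot_n <- 0; n_valid <- 0L
  for (ord in .perms(dpos)) {
    cur <- c1; s <- 0; n <- 0; ok <- TRUE
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (gc[[nxt]] == "*") { ok <- FALSE; break }
      if (gc[[cur]] == gc[[nxt]]) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    if (ok) { tot_s <- tot_s + s; tot_n <- tot_n + n; n_valid <- n_valid + 1L }
  }
  if (!n_valid) return(NULL)
  c(tot_s / n_valid, tot_n / n_valid)
}

#' Nei-Gojobori site and difference counts for an aligned codon pair
#'
#' Synonymous site fractions are averaged across the two sequences;
#' multi-difference codons are resolved by equal-weight averaging over all
#' minimal substitution pathways, excluding pathways through stop codons.
#' Codons containing gaps or N, stop codons, and codon pairs whose pathways
#' all pass a stop are skipped pairwise.
#'
#' @param cds1,cds2 Aligned coding sequences (equal length, multiple of 3;
#'   \code{-} for gaps).
#' @return list with \code{N}, \code{S}, \code{Nd}, \code{Sd},
#'   \code{codons_compared}.
#' @export
ng_counts <- function(cds1, cds2) {
  cds1 <- toupper(cds1); cds2 <- toupper(cds2)
  if (nchar(cds1) != nchar(cds2)) stop("aligned sequences must have equal length")
  if (nchar(cds1) %% 3 != 0) stop("length must be a multiple of 3")
  st <- .syn_sites_table()
  n_cod <- nchar(cds1) %/% 3
  S <- 0; N <- 0; Sd <- 0; Nd <- 0; used <- 0L
  for (i in seq_len(n_cod)) {
    a <- .codon_at(cds1, i); b <- .codon_at(cds2, i)
    if (grepl("[^ACGT]", a) || grepl("[^ACGT]", b)) next
    if (a %in% .STOPS || b %in% .STOPS) next
    d <- .pathway_diffs(a, b)
    if (is.null(d)) next
    s_sites <- (st[[a]] + st[[b]]) / 2
    S <- S + s_sites; N <- N + (3 - s_sites)
    Sd <- Sd + d[1]; Nd <- Nd + d[2]
    used <- used + 1L
  }
  list(N = N, S = S, Nd = Nd, Sd = Sd, codons_compared = used)
}

#' Jukes-Cantor-corrected Dn/Ds from Nei-Gojobori counts
#'
#' pN = Nd/N and pS = Sd/S are corrected by
#' \eqn{D = -\frac{3}{4}\ln(1 - \frac{4}{3}p)}; a proportion at or above 3/4
#' yields an undefined distance, and the ratio is undefined when Ds is 0 or
#' either distance is undefined.
#'
#' @param counts list from [ng_counts()] (requires N > 0 and S > 0).
#' @return list with \code{pN}, \code{pS}, \code{Dn}, \code{Ds},
#'   \code{ratio}, \code{undefined} (logical).
#' @export
dnds <- function(counts) {
  if (counts$N <= 0 || counts$S <= 0) stop("need N > 0 and S > 0")
  jc <- function(p) if (p >= 3 / 4) NA_real_ else -0.75 * log(1 - 4 / 3 * p)
  pN <- counts$Nd / counts$N
  pS <- counts$Sd / counts$S
  Dn <- jc(pN); Ds <- jc(pS)
  undef <- is.na(Dn) || is.na(Ds) || Ds == 0
  list(pN = pN, pS = pS, Dn = Dn, Ds = Ds,
       ratio = if (undef) NA_real_ else Dn / Ds, undefined = undef)
}

#' Selection-zone classification of a Dn/Ds ratio
#'
#' Dn/Ds above 1 indicates positive (diversifying) selection, between 0.27
#' and 1 a lack of constraints, and at or below 0.27 purifying selection.
#' Boundary ratios fall in the lower zone; undefined ratios return
#' \code{undefined}.
#'
#' @param result list from [dnds()] (or a list with \code{ratio}).
#' @return One of "positive", "lack_of_constraints", "purifying",
#'   "undefined".
#' @export
classify_selection <- function(result) {
  r <- result$ratio
  if (is.null(r) || is.na(r)) return("undefined")
  if (r > 1) "positive" else if (r > 0.27) "lack_of_constraints" else "purifying"
}

#' Fisher exact test for positive selection
#'
#' One-sided test that nonsynonymous differences are enriched relative to
#' synonymous ones, on the 2x2 table {Nd, N-Nd; Sd, S-Sd} with fractional
#' counts rounded to the nearest integer (ties to even). Degenerate margins
#' give p = 1.
#'
#' @param counts list from [ng_counts()].
#' @return p-value in [0, 1].
#' @export
fisher_positive_selection <- function(counts) {
  a <- round(counts$Nd); b <- round(counts$N) - a
  c_ <- round(counts$Sd); d <- round(counts$S) - c_
  if (min(a, b, c_, d) < 0) stop("invalid counts")
  if ((a + c_) == 0 || (a + b) == 0 || (c_ + d) == 0) return(1)
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE)
  stats::fisher.test(tab, alternative = "greater")$p.value
}
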