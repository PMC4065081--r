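# Independent brute-force oracles used to pin expected values. These stay
# deliberately naive (plain recursion / exhaustive enumeration) and share no
# code with the implementations they check.

GENCODE <- local({
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
})

oracle_translate_codon <- function(cod) GENCODE[[cod]]

# ---- affine-gap alignment by plain recursion --------------------------------
# score of the best global alignment of x vs y; gaps cost open+ext for the
# first symbol and ext for each further symbol (Biostrings convention).
oracle_global_score <- function(x, y, submat, open, ext) {
  xs <- strsplit(x, "")[[1]]; ys <- strsplit(y, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, state) {
    if (i > length(xs) && j > length(ys)) return(0)
    key <- paste(i, j, state)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- -Inf
    if (i <= length(xs) && j <= length(ys))
      best <- max(best, submat[xs[i], ys[j]] + rec(i + 1, j + 1, "m"))
    if (i <= length(xs))   # gap in y
      best <- max(best, -(if (state == "x") ext else open + ext) + rec(i + 1, j, "x"))
    if (j <= length(ys))   # gap in x
      best <- max(best, -(if (state == "y") ext else open + ext) + rec(i, j + 1, "y"))
    memo[[key]] <- best
    best
  }
  rec(1, 1, "m")
}

# best local alignment score: maximum over all substring pairs (and 0)
oracle_local_score <- function(x, y, submat, open, ext) {
  best <- 0
  nx <- nchar(x); ny <- nchar(y)
  for (i1 in 1:nx) for (i2 in i1:nx) for (j1 in 1:ny) for (j2 in j1:ny) {
    sc <- oracle_global_score(substr(x, i1, i2), substr(y, j1, j2),
                              submat, open, ext)
    if (sc > best) best <- sc
  }
  best
}

# ---- Nei-Gojobori by exhaustive pathway enumeration -------------------------
oracle_syn_sites <- function(codon) {
  aa <- GENCODE[[codon]]
  s <- 0
  for (pos in 1:3) for (b in setdiff(c("A", "C", "G", "T"),
                                     substr(codon, pos, pos))) {
    alt <- codon; substr(alt, pos, pos) <- b
    if (GENCODE[[alt]] != "*" && GENCODE[[alt]] == aa) s <- s + 1 / 3
  }
  s
}

oracle_all_orderings <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (r in oracle_all_orderings(v[-i])) out[[length(out) + 1]] <- c(v[i], r)
  out
}

# returns list(sd, nd, n_valid) or NULL when all pathways are blocked
oracle_pathway_counts <- function(c1, c2) {
  dpos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(dpos)) return(list(sd = 0, nd = 0))
  tot_s <- 0; tot_n <- 0; valid <- 0
  for (ord in oracle_all_orderings(dpos)) {
    cur <- c1; s <- 0; n <- 0; ok <- TRUE
    for (p in ord) {
      nxt <- cur; substr(nxt, p, p) <- substr(c2, p, p)
      if (GENCODE[[nxt]] == "*") { ok <- FALSE; break }
      if (GENCODE[[cur]] == GENCODE[[nxt]]) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    if (ok) { tot_s <- tot_s + s; tot_n <- tot_n + n; valid <- valid + 1 }
  }
  if (!valid) return(NULL)
  list(sd = tot_s / valid, nd = tot_n / valid)
}

oracle_ng_one_codon <- function(c1, c2) {
  pw <- oracle_pathway_counts(c1, c2)
  if (is.null(pw)) return(NULL)
  s_sites <- (oracle_syn_sites(c1) + oracle_syn_sites(c2)) / 2
  list(S = s_sites, N = 3 - s_sites, Sd = pw$sd, Nd = pw$nd)
}

SENSE_CODONS <- setdiff(names(GENCODE), c("TAA", "TAG", "TGA"))

# ---- hypergeometric tail for the Fisher test --------------------------------
oracle_fisher_greater <- function(a, b, c_, d) {
  # P(A >= a) over tables with margins fixed
  r1 <- a + b; c1 <- a + c_; n <- a + b + c_ + d
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  p <- 0
  for (aa in lo:hi) if (aa >= a) p <- p + stats::dhyper(aa, r1, n - r1, c1)
  p
}

# ---- single linkage by transitive closure -----------------------------------
oracle_single_linkage <- function(idmat, threshold) {
  adj <- idmat >= threshold
  diag(adj) <- TRUE
  reach <- adj
  for (k in seq_len(nrow(adj))) reach <- reach | (reach %*% reach > 0)
  labels <- integer(nrow(adj)); cur <- 0
  for (i in seq_len(nrow(adj))) {
    if (labels[i] == 0) { cur <- cur + 1; labels[which(reach[i, ])] <- cur }
  }
  labels
}

# ---- random additive trees --------------------------------------------------
random_additive_tree <- function(n_taxa) {
  tr <- ape::rtree(n_taxa)
  tr$edge.length <- stats::runif(length(tr$edge.length), 0.05, 1)
  tr
}

# ---- misc -------------------------------------------------------------------
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
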