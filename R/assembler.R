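# High-stringency exact-overlap assembly: reads merge only on 100%-identical
# suffix-prefix overlaps of at least min_overlap nt (containment counts as a
# full-length overlap). Greedy longest-overlap-first with a deterministic
# tie-break; reverse-complement overlaps are considered.

#' Assembly parameters
#'
#' @param min_overlap Minimum exact overlap in nucleotides (default 50).
#' @param identity Required overlap identity; only 1.0 (exact) is supported.
#' @param use_revcomp Consider reverse-complement overlaps.
#' @return list of class \code{assembly_params}.
#' @export
assembly_params <- function(min_overlap = 50L, identity = 1.0, use_revcomp = TRUE) {
  if (min_overlap < 1) stop("min_overlap must be >= 1")
  if (identity != 1.0) stop("only exact assembly (identity = 1.0) is supported")
  structure(list(min_overlap = as.integer(min_overlap), identity = identity,
                 use_revcomp = isTRUE(use_revcomp)), class = "assembly_params")
}

# longest L >= min_ov with suffix(a, L) == prefix(b, L); 0 if none.
.best_overlap <- function(a, b, min_ov) {
  la <- nchar(a); lb <- nchar(b)
  if (la < min_ov || lb < min_ov) return(0L)
  p <- substr(b, 1L, min_ov)
  occ <- gregexpr(p, a, fixed = TRUE)[[1]]
  if (occ[1] == -1L) return(0L)
  for (i in occ) {                      # leftmost valid occurrence = longest L
    L <- la - i + 1L
    if (L > lb) next                    # b would be contained; handled separately
    if (substr(a, i, la) == substr(b, 1L, L)) return(L)
  }
  0L
}

# all candidate merges of contig i with contig j (and orientations); returns
# a matrix with rows (i, j, L, mode) where mode encodes orientation/order.
.pair_overlaps <- function(seqs, i, j, min_ov, use_rc) {
  a <- seqs[[i]]; b <- seqs[[j]]
  out <- list()
  add <- function(L, mode) if (L >= min_ov) out[[length(out) + 1L]] <<- c(i, j, L, mode)
  # containment
  if (nchar(b) <= nchar(a)) {
    if (grepl(b, a, fixed = TRUE)) add(nchar(b), 1L)  # j inside i
    else if (use_rc && grepl(revcomp(b), a, fixed = TRUE)) add(nchar(b), 2L)
  }
  if (nchar(a) < nchar(b)) {
    if (grepl(a, b, fixed = TRUE)) add(nchar(a), 3L)  # i inside j
    else if (use_rc && grepl(revcomp(a), b, fixed = TRUE)) add(nchar(a), 4L)
  }
  add(.best_overlap(a, b, min_ov), 5L)                # a then b
  add(.best_overlap(b, a, min_ov), 6L)                # b then a
  if (use_rc) {
    rb <- revcomp(b)
    add(.best_overlap(a, rb, min_ov), 7L)             # a then rc(b)
    add(.best_overlap(rb, a, min_ov), 8L)             # rc(b) then a
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# unordered candidate pairs (i < j) between index sets A and B such that some
# orientation of one sequence's leading min_ov-mer occurs in the other.
.candidate_pairs <- function(seqs, A, B, min_ov, use_rc) {
  rcseqs <- if (use_rc) revcomp(seqs) else NULL
  p50 <- substr(seqs, 1L, min_ov)
  p50rc <- if (use_rc) substr(rcseqs, 1L, min_ov) else NULL
  out <- list()
  scan_from <- if (identical(A, B)) A else union(A, B)
  for (j in scan_from) {
    if (nchar(seqs[j]) < min_ov) next
    hits <- grepl(p50[j], seqs, fixed = TRUE)
    if (use_rc) {
      hits <- hits | grepl(p50rc[j], seqs, fixed = TRUE) |
        grepl(p50[j], rcseqs, fixed = TRUE)
    }
    hits[j] <- FALSE
    ii <- which(hits)
    if (length(ii))
      out[[length(out) + 1L]] <- cbind(pmin(ii, j), pmax(ii, j))
  }
  if (!length(out)) return(matrix(integer(0), ncol = 2))
  m <- unique(do.call(rbind, out))
  if (!identical(A, B)) {
    keep <- (m[, 1] %in% A & m[, 2] %in% B) | (m[, 1] %in% B & m[, 2] %in% A)
    m <- m[keep, , drop = FALSE]
  }
  m
}

# candidate pairs between one new contig k and the alive set: one vectorised
# scan of k's leading min_ov-mer against the alive sequences, plus cheap
# scalar scans of each alive contig's leading min_ov-mer against k.
.candidate_pairs_one <- function(seqs, alive_idx, k, min_ov, use_rc) {
  sk <- seqs[k]
  if (nchar(sk) < min_ov) return(matrix(integer(0), ncol = 2))
  rck <- if (use_rc) revcomp(sk) else NULL
  p50k <- substr(sk, 1L, min_ov)
  p50k_rc <- if (use_rc) substr(rck, 1L, min_ov) else NULL
  sub <- seqs[alive_idx]
  hits <- grepl(p50k, sub, fixed = TRUE)
  if (use_rc) {
    rcsub <- revcomp(sub)
    hits <- hits | grepl(p50k_rc, sub, fixed = TRUE) |
      grepl(p50k, rcsub, fixed = TRUE)
  }
  back <- vapply(alive_idx, function(t) {
    if (nchar(seqs[t]) < min_ov) return(FALSE)
    p <- substr(seqs[t], 1L, min_ov)
    grepl(p, sk, fixed = TRUE) || (use_rc && grepl(p, rck, fixed = TRUE))
  }, logical(1))
  ii <- alive_idx[hits | back]
  if (!length(ii)) return(matrix(integer(0), ncol = 2))
  cbind(ii, k)
}

.merged_seq <- function(seqs, row) {
  i <- row[1]; j <- row[2]; L <- row[3]; mode <- row[4]
  a <- seqs[[i]]; b <- seqs[[j]]
  switch(mode,
         a,                                            # 1: j contained in i
         a,                                            # 2: rc(j) contained in i
         b,                                            # 3: i contained in j
         b,                                            # 4: rc(i) contained in j
         paste0(a, substr(b, L + 1L, nchar(b))),       # 5: a + b
         paste0(b, substr(a, L + 1L, nchar(a))),       # 6: b + a
         { rb <- revcomp(b); paste0(a, substr(rb, L + 1L, nchar(rb))) },
         { rb <- revcomp(b); paste0(rb, substr(a, L + 1L, nchar(a))) })
}

#' Assemble reads into contigs by greedy exact-overlap merging
#'
#' Repeatedly joins the pair with the longest exact suffix-prefix overlap of
#' at least \code{min_overlap} nt (containments count as full-length
#' overlaps), breaking ties by the lexicographically smaller merged sequence,
#' then by the smaller member read id. Contigs are reported in the
#' orientation of their first-merged read.
#'
#' @param reads Named character vector of read sequences.
#' @param params An [assembly_params()].
#' @return list with \code{contigs} and \code{singletons}, each a data.frame
#'   (\code{contig_id}, \code{seq}, \code{read_count}, \code{members}
#'   semicolon-joined), sorted by read count then length descending. A
#'   \code{membership} data.frame maps each read id to its contig.
#' @export
assemble <- function(reads, params = assembly_params()) {
  if (!length(reads)) stop("reads must be non-empty")
  if (is.null(names(reads))) names(reads) <- sprintf("read_%05d", seq_along(reads))
  reads <- toupper(reads)
  min_ov <- params$min_overlap; use_rc <- params$use_revcomp

  # phase 0: collapse exact duplicates / containments into the longest read
  # (processing longest-first means a containing sequence is always seen
  # before anything it contains)
  ord <- order(-nchar(reads), names(reads))
  seqs <- character(0); members <- list()
  for (idx in ord) {
    r <- reads[[idx]]; rid <- names(reads)[idx]
    hit <- integer(0)
    if (length(seqs)) {
      hit <- which(grepl(r, seqs, fixed = TRUE))
      if (!length(hit) && use_rc) hit <- which(grepl(revcomp(r), seqs, fixed = TRUE))
    }
    if (!length(hit)) {
      seqs[length(seqs) + 1L] <- r
      members[[length(members) + 1L]] <- rid
    } else {
      members[[hit[1]]] <- c(members[[hit[1]]], rid)
    }
  }

  # phase 1: greedy suffix-prefix merging; candidate table kept as a matrix.
  # An overlap or containment of >= min_ov nt requires one sequence's leading
  # min_ov-mer to occur in the other (in some orientation), so candidate
  # pairs are prefiltered by vectorised fixed-string search.
  n <- length(seqs)
  chunks <- list()
  if (n > 1) {
    pairs <- .candidate_pairs(seqs, seq_len(n), seq_len(n), min_ov, use_rc)
    for (k in seq_len(nrow(pairs))) {
      m <- .pair_overlaps(seqs, pairs[k, 1], pairs[k, 2], min_ov, use_rc)
      if (!is.null(m)) chunks[[length(chunks) + 1L]] <- m
    }
  }
  tab <- if (length(chunks)) do.call(rbind, chunks) else
    matrix(integer(0), ncol = 4)
  alive <- rep(TRUE, n)
  repeat {
    if (nrow(tab)) tab <- tab[alive[tab[, 1]] & alive[tab[, 2]], , drop = FALSE]
    if (!nrow(tab)) break
    maxL <- max(tab[, 3])
    best <- which(tab[, 3] == maxL)
    if (length(best) > 1) {
      ms <- vapply(best, function(k) .merged_seq(seqs, tab[k, ]), character(1))
      mem <- vapply(best, function(k)
        min(c(members[[tab[k, 1]]], members[[tab[k, 2]]])), character(1))
      best <- best[order(ms, mem)][1]
    }
    row <- tab[best, ]
    new_seq <- .merged_seq(seqs, row)
    i <- row[1]; j <- row[2]
    alive[c(i, j)] <- FALSE
    seqs[length(seqs) + 1L] <- new_seq
    members[[length(members) + 1L]] <- c(members[[i]], members[[j]])
    alive <- c(alive, TRUE)
    k <- length(seqs)
    new_chunks <- list()
    others <- which(alive); others <- others[others != k]
    if (length(others)) {
      pr <- .candidate_pairs_one(seqs, others, k, min_ov, use_rc)
      for (q in seq_len(nrow(pr))) {
        m <- .pair_overlaps(seqs, pr[q, 1], pr[q, 2], min_ov, use_rc)
        if (!is.null(m)) new_chunks[[length(new_chunks) + 1L]] <- m
      }
    }
    if (length(new_chunks)) tab <- rbind(tab, do.call(rbind, new_chunks))
  }

  keep <- which(alive)
  df <- data.frame(seq = seqs[keep],
                   read_count = vapply(members[keep], length, integer(1)),
                   members = vapply(members[keep], function(m)
                     paste(sort(m), collapse = ";"), character(1)),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$read_count, -nchar(df$seq), df$members), , drop = FALSE]
  df$contig_id <- sprintf("contig_%04d", seq_len(nrow(df)))
  df <- df[, c("contig_id", "seq", "read_count", "members")]
  rownames(df) <- NULL
  membership <- do.call(rbind, lapply(seq_len(nrow(df)), function(k)
    data.frame(read_id = strsplit(df$members[k], ";")[[1]],
               contig_id = df$contig_id[k], stringsAsFactors = FALSE)))
  list(contigs = df[df$read_count > 1, , drop = FALSE],
       singletons = df[df$read_count == 1, , drop = FALSE],
       membership = membership)
}
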