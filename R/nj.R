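# Neighbor-joining (Saitou & Nei Q-criterion) with a deterministic tie-break
# and column-resampling bootstrap support.

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Q-criterion joins; ties are broken by the smallest (row, column)
#' index pair. Negative branch lengths are clamped to zero on output (the
#' unclamped values are kept in the \code{raw.edge.length} attribute).
#'
#' @param d Symmetric numeric matrix with zero diagonal and dimnames, or a
#'   \code{dist} object; at least 3 taxa.
#' @return An \code{ape} \code{phylo} tree (unrooted, trifurcating root
#'   node).
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix must have zero diagonal")
  n <- nrow(d)
  if (n < 3) stop("need at least 3 taxa")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))

  node_id <- seq_len(n)          # phylo ids of active nodes (tips 1..n)
  next_node <- n + 2L            # n+1 reserved for the final (root) node
  edges <- NULL; lens <- NULL
  D <- unname(d)
  while (length(node_id) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    idx <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    f <- idx[1, 1]; g <- idx[1, 2]
    bf <- 0.5 * D[f, g] + (r[f] - r[g]) / (2 * (m - 2))
    bg <- D[f, g] - bf
    new <- next_node; next_node <- next_node + 1L
    edges <- rbind(edges, c(new, node_id[f]), c(new, node_id[g]))
    lens <- c(lens, bf, bg)
    dn <- 0.5 * (D[f, ] + D[g, ] - D[f, g])
    keep <- setdiff(seq_len(m), c(f, g))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dn[keep]), c(dn[keep], 0))
    node_id <- c(node_id[keep], new)
  }
  # resolve the final three nodes with the three-point formulas
  root <- n + 1L
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  edges <- rbind(edges, c(root, node_id[1]), c(root, node_id[2]), c(root, node_id[3]))
  lens <- c(lens, b1, b2, b3)

  tr <- list(edge = edges, edge.length = pmax(lens, 0), tip.label = labels,
             Nnode = n - 2L)
  class(tr) <- "phylo"
  attr(tr, "order") <- NULL
  tr <- ape::read.tree(text = ape::write.tree(tr))
  attr(tr, "raw.edge.length") <- lens
  tr
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree for
#' each replicate, and reports the percentage of replicates containing each
#' internal edge (bipartition) of the original tree.
#'
#' @param aln Character matrix (taxa in rows, aligned columns), rownames are
#'   taxon labels. Gap characters are allowed and ignored pairwise by the
#'   default distance.
#' @param replicates Number of bootstrap replicates (default 500).
#' @param seed Mandatory integer seed.
#' @param dist_fun Function mapping an alignment matrix to a distance matrix
#'   (default: pairwise-deletion p-distance).
#' @return list with \code{tree} (phylo, \code{node.label} holding percent
#'   support) and \code{support} (numeric vector per internal node).
#' @export
nj_bootstrap <- function(aln, replicates = 500L, seed, dist_fun = p_distance) {
  if (missing(seed)) stop("a bootstrap seed is required")
  stopifnot(is.matrix(aln), nrow(aln) >= 3)
  set.seed(as.integer(seed))
  tree <- nj_tree(dist_fun(aln))
  boot <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    cols <- sample.int(ncol(aln), replace = TRUE)
    boot[[r]] <- nj_tree(dist_fun(aln[, cols, drop = FALSE]))
  }
  counts <- ape::prop.clades(tree, boot, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- 100 * counts / replicates
  tree$node.label <- formatC(support, format = "f", digits = 0)
  list(tree = tree, support = support)
}

#' Pairwise-deletion p-distance of an alignment matrix
#'
#' @param aln Character matrix (taxa x columns); positions where either
#'   sequence has a gap (or N/X) are skipped for that pair.
#' @return Symmetric distance matrix.
#' @export
p_distance <- function(aln) {
  n <- nrow(aln)
  lbl <- rownames(aln)
  if (is.null(lbl)) lbl <- paste0("t", seq_len(n))
  bad <- aln %in% c("-", "N", "X", ".")
  dim(bad) <- dim(aln)
  D <- matrix(0, n, n, dimnames = list(lbl, lbl))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !bad[i, ] & !bad[j, ]
    D[i, j] <- D[j, i] <- if (any(ok)) mean(aln[i, ok] != aln[j, ok]) else 0
  }
  D
}
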