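# Superfamily / family / subfamily taxonomy: superfamilies by signal-peptide
# identity against the catalog, then nested single-linkage clustering on
# precursor and mature-peptide identity.

#' Single-linkage cluster labels from an identity matrix
#'
#' Members are linked when identity >= threshold; clusters are connected
#' components under single linkage. Labels are integers ordered by
#' descending cluster size, ties by the lexicographically smallest member
#' name.
#'
#' @param idmat Symmetric identity matrix with dimnames.
#' @param threshold Identity threshold in (0, 1].
#' @return Named integer vector of cluster labels.
#' @export
single_linkage_clusters <- function(idmat, threshold) {
  n <- nrow(idmat)
  nm <- rownames(idmat)
  if (is.null(nm)) nm <- paste0("m", seq_len(n))
  if (n == 1L) return(stats::setNames(1L, nm))
  d <- stats::as.dist(1 - idmat)
  hc <- stats::hclust(d, method = "single")
  raw <- stats::cutree(hc, h = 1 - threshold)
  sizes <- table(raw)
  reps <- vapply(names(sizes), function(cl) min(nm[raw == as.integer(cl)]),
                 character(1))
  ord <- order(-as.integer(sizes), reps)
  relab <- stats::setNames(seq_along(ord), names(sizes)[ord])
  stats::setNames(as.integer(relab[as.character(raw)]), nm)
}

#' Assign precursors to gene superfamilies by signal-peptide identity
#'
#' Each precursor's signal peptide is compared (global identity) with every
#' catalog signal; the best identity at or above \code{threshold} assigns the
#' superfamily. Precursors with no signal evidence fall back to
#' mature-peptide nearest-neighbour matching against the reference templates
#' (flagged), and catalog entries without a signal are matched by their
#' stored propeptide. Remaining precursors are clustered into NEW-k
#' superfamilies by single linkage at the same threshold, numbered in input
#' order of their first member.
#'
#' @param segments data.frame with columns \code{precursor_id},
#'   \code{signal}, \code{mature}, \code{signal_evidence}.
#' @param catalog Reference catalog.
#' @param templates Reference templates (for the mature fallback).
#' @param threshold Signal identity threshold (default 0.70).
#' @param mature_floor Minimum local identity for the mature fallback.
#' @return data.frame \code{precursor_id}, \code{superfamily},
#'   \code{identity_to_nearest}, \code{flagged}.
#' @export
assign_superfamily <- function(segments, catalog = toxin_catalog(),
                               templates = reference_templates(),
                               threshold = 0.70, mature_floor = 0.5) {
  stopifnot(threshold > 0, threshold <= 1)
  n <- nrow(segments)
  sf <- rep(NA_character_, n); idn <- rep(NA_real_, n); flag <- rep(FALSE, n)
  sigs <- catalog[nzchar(catalog$signal_peptide), ]
  anch <- catalog[!nzchar(catalog$signal_peptide) & nzchar(catalog$propeptide_anchor), ]
  for (i in seq_len(n)) {
    sig <- segments$signal[i]
    if (nzchar(sig) && segments$signal_evidence[i] != "missing") {
      ids <- global_identity(sig, sigs$signal_peptide)
      best <- which.max(ids)
      idn[i] <- ids[best]
      if (ids[best] >= threshold) sf[i] <- sigs$superfamily[best]
    } else {
      # propeptide-anchored catalog entries, then mature nearest-neighbour
      assigned <- FALSE
      pro <- if (!is.null(segments$propeptide) && !is.na(segments$propeptide[i]))
        segments$propeptide[i] else ""
      full <- paste0(pro, segments$mature[i])
      for (k in seq_len(nrow(anch))) {
        idp <- local_identity(substr(full, 1, nchar(anch$propeptide_anchor[k]) + 5),
                              anch$propeptide_anchor[k])
        if (idp >= threshold) {
          sf[i] <- anch$superfamily[k]; idn[i] <- idp; assigned <- TRUE
          break
        }
      }
      if (!assigned && nzchar(segments$mature[i])) {
        ids <- local_identity(segments$mature[i], templates$mature_peptide)
        best <- which.max(ids)
        idn[i] <- ids[best]
        if (ids[best] >= mature_floor) {
          sf[i] <- templates$superfamily[best]
          flag[i] <- TRUE
        }
      }
    }
  }
  # NEW clusters among the unassigned, in input order
  un <- which(is.na(sf))
  if (length(un)) {
    key <- ifelse(nzchar(segments$signal[un]), segments$signal[un],
                  segments$mature[un])
    k <- length(un)
    idmat <- diag(1, k)
    dimnames(idmat) <- list(segments$precursor_id[un], segments$precursor_id[un])
    if (k > 1) {
      for (a in seq_len(k - 1)) {
        ids <- global_identity(key[a], key[(a + 1):k])
        idmat[a, (a + 1):k] <- ids; idmat[(a + 1):k, a] <- ids
      }
    }
    comp <- .components_at(idmat, threshold)
    first_seen <- tapply(seq_len(k), comp, min)
    relab <- stats::setNames(rank(first_seen), names(first_seen))
    sf[un] <- sprintf("NEW-%d", as.integer(relab[as.character(comp)]))
  }
  data.frame(precursor_id = segments$precursor_id, superfamily = sf,
             identity_to_nearest = idn, flagged = flag, stringsAsFactors = FALSE)
}

# connected components of (idmat >= threshold), preserving input order
.components_at <- function(idmat, threshold) {
  k <- nrow(idmat)
  comp <- integer(k); cur <- 0L
  for (i in seq_len(k)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    stack <- i
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (comp[v] > 0L) next
      comp[v] <- cur
      nb <- which(idmat[v, ] >= threshold & comp == 0L)
      stack <- c(stack, nb)
    }
  }
  comp
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Split one superfamily into families and subfamilies
#'
#' Single-linkage clustering on full-precursor identity at
#' \code{family_threshold}, then within each family on mature-peptide
#' identity at \code{subfamily_threshold}. Labels are ordered by descending
#' cluster size, ties by smallest member id.
#'
#' @param members data.frame with \code{precursor_id}, \code{precursor},
#'   \code{mature}.
#' @param family_threshold,subfamily_threshold Identity thresholds
#'   (defaults 0.60 and 0.90).
#' @return data.frame \code{precursor_id}, \code{family}, \code{subfamily}.
#' @export
cluster_families <- function(members, family_threshold = 0.60,
                             subfamily_threshold = 0.90) {
  stopifnot(nrow(members) >= 1)
  idm <- .identity_matrix(members$precursor, members$precursor_id)
  fam <- single_linkage_clusters(idm, family_threshold)
  out <- data.frame(precursor_id = members$precursor_id,
                    family = sprintf("fam%d", fam[members$precursor_id]),
                    subfamily = NA_character_, stringsAsFactors = FALSE)
  for (f in unique(out$family)) {
    sel <- out$family == f
    sub <- members[sel, , drop = FALSE]
    idm2 <- .identity_matrix(sub$mature, sub$precursor_id)
    sf <- single_linkage_clusters(idm2, subfamily_threshold)
    out$subfamily[sel] <- sprintf("%s_sub%d", f, sf[sub$precursor_id])
  }
  out
}

.identity_matrix <- function(seqs, ids) {
  k <- length(seqs)
  m <- diag(1, k)
  dimnames(m) <- list(ids, ids)
  if (k > 1) {
    for (a in seq_len(k - 1)) {
      keep <- nzchar(seqs[(a + 1):k]) & nzchar(seqs[a])
      vals <- rep(0, k - a)
      if (nzchar(seqs[a]) && any(keep))
        vals[keep] <- global_identity(seqs[a], seqs[(a + 1):k][keep])
      m[a, (a + 1):k] <- vals; m[(a + 1):k, a] <- vals
    }
  }
  m
}
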