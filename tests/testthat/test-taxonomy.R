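catalog <- toxin_catalog()
templates <- reference_templates()

test_that("each catalog signal assigns to its own superfamily at identity 1", {
  sigs <- catalog[nzchar(catalog$signal_peptide), ]
  segs <- data.frame(precursor_id = sigs$superfamily,
                     signal = sigs$signal_peptide,
                     mature = templates$mature_peptide[
                       match(sigs$superfamily, templates$superfamily)],
                     signal_evidence = "catalog_match",
                     stringsAsFactors = FALSE)
  out <- assign_superfamily(segs, catalog, templates)
  expect_identical(out$superfamily, sigs$superfamily)
  expect_true(all(abs(out$identity_to_nearest - 1) < 1e-12))
})

test_that("an unrelated signal seeds a NEW superfamily", {
  segs <- data.frame(precursor_id = "px",
                     signal = "MWWWHHWWHHWWHHWWHHWWH",
                     mature = "AAACAAACAAACAAACAAA",
                     signal_evidence = "heuristic", stringsAsFactors = FALSE)
  out <- assign_superfamily(segs, catalog, templates)
  expect_identical(out$superfamily, "NEW-1")
})

test_that("missing signal falls back to mature nearest-neighbour, flagged", {
  tpl <- templates[3, ]
  segs <- data.frame(precursor_id = "frag",
                     signal = "",
                     mature = tpl$mature_peptide,
                     signal_evidence = "missing", stringsAsFactors = FALSE)
  out <- assign_superfamily(segs, catalog, templates)
  expect_identical(out$superfamily, tpl$superfamily)
  expect_true(out$flagged)
})

test_that("single linkage labels match the brute-force transitive closure", {
  set.seed(21)
  for (rep in 1:20) {
    k <- sample(3:8, 1)
    m <- matrix(runif(k * k, 0, 1), k)
    m <- (m + t(m)) / 2; diag(m) <- 1
    dimnames(m) <- list(paste0("s", 1:k), paste0("s", 1:k))
    thr <- runif(1, 0.3, 0.9)
    mine <- single_linkage_clusters(m, thr)
    oracle <- oracle_single_linkage(m, thr)
    # same partition (labels may differ)
    expect_identical(outer(mine, mine, "=="), outer(oracle, oracle, "=="),
                     ignore_attr = TRUE)
  }
})

test_that("toy identity structure yields two families and three subfamilies", {
  # precursor identities link only a-b at the family threshold; mature
  # identities keep a and b apart at the subfamily threshold
  prec_id <- matrix(c(1, .70, .40,
                      .70, 1, .45,
                      .40, .45, 1), 3, byrow = TRUE,
                    dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  mat_id <- matrix(c(1, .70, .95,
                     .70, 1, .40,
                     .95, .40, 1), 3, byrow = TRUE,
                   dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  fam <- single_linkage_clusters(prec_id, 0.60)
  expect_identical(length(unique(fam)), 2L)
  expect_identical(fam[["a"]], fam[["b"]])
  # subfamilies nested within families
  subs <- character(3); names(subs) <- names(fam)
  for (f in unique(fam)) {
    mem <- names(fam)[fam == f]
    sl <- single_linkage_clusters(mat_id[mem, mem, drop = FALSE], 0.90)
    subs[mem] <- paste0(f, ".", sl)
  }
  expect_identical(length(unique(subs)), 3L)
  # oracle agreement on both levels
  expect_identical(length(unique(oracle_single_linkage(prec_id, 0.60))), 2L)
})

test_that("nested clustering on real sequences produces nested partitions", {
  # two clearly separated sequence groups within one superfamily
  base1 <- templates$precursor[1]
  base2 <- paste0(templates$signal_peptide[1], "GGKNQTWHKNQTWHKNQTWH",
                  "AAACAAWWCAAKKCCAAWNCAAHHCAA")
  near1 <- sub("A", "G", base1)
  members <- data.frame(
    precursor_id = c("m1", "m2", "m3"),
    precursor = c(base1, near1, base2),
    mature = c(templates$mature_peptide[1],
               templates$mature_peptide[1], "AAACAAWWCAAKKCCAAWNCAAHHCAA"),
    stringsAsFactors = FALSE)
  out <- cluster_families(members)
  expect_identical(nrow(out), 3L)
  # subfamily labels refine family labels
  for (f in unique(out$family)) {
    subs <- out$subfamily[out$family == f]
    expect_true(all(startsWith(subs, f)))
  }
  expect_identical(out$family[1], out$family[2])
  expect_false(out$family[1] == out$family[3])
})

test_that("raising the subfamily threshold never decreases subfamily count", {
  set.seed(22)
  k <- 6
  m <- matrix(runif(k * k, 0.5, 1), k)
  m <- (m + t(m)) / 2; diag(m) <- 1
  dimnames(m) <- list(paste0("s", 1:k), paste0("s", 1:k))
  n_prev <- 0
  for (thr in c(0.6, 0.7, 0.8, 0.9, 0.99)) {
    n_now <- length(unique(single_linkage_clusters(m, thr)))
    expect_gte(n_now, n_prev)
    n_prev <- n_now
  }
})
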