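test_that("identical coding sequences give zero differences and full sites", {
  cds <- "ATGGCCAAAGGGTTT"
  cn <- ng_counts(cds, cds)
  expect_equal(cn$Nd, 0); expect_equal(cn$Sd, 0)
  expect_equal(cn$N + cn$S, 3 * cn$codons_compared, tolerance = 1e-9)
  expect_identical(cn$codons_compared, 5L)
})

test_that("the worked single-codon pair reproduces its exact counts", {
  cn <- ng_counts("TTT", "CTT")
  expect_equal(cn$S, 2 / 3, tolerance = 1e-12)
  expect_equal(cn$N, 7 / 3, tolerance = 1e-12)
  expect_equal(cn$Nd, 1); expect_equal(cn$Sd, 0)
  dd <- dnds(cn)
  expect_equal(dd$pN, 3 / 7, tolerance = 1e-12)
  expect_equal(dd$Dn, -0.75 * log(3 / 7), tolerance = 1e-12)
  expect_equal(dd$Ds, 0)
  expect_true(dd$undefined)
})

test_that("two-difference codons average over substitution orderings", {
  # TTT -> GTA: via GTT (nonsyn, then syn) or via TTA (nonsyn, then nonsyn)
  o <- oracle_ng_one_codon("TTT", "GTA")
  expect_equal(o$Sd, 0.5); expect_equal(o$Nd, 1.5)
  cn <- ng_counts("TTT", "GTA")
  expect_equal(cn$Sd, o$Sd, tolerance = 1e-12)
  expect_equal(cn$Nd, o$Nd, tolerance = 1e-12)
  expect_equal(cn$S, o$S, tolerance = 1e-12)
})

test_that("gap and N codons are deleted pairwise", {
  cn <- ng_counts("ATG---AAATTN", "ATGGCCAAGTTT")
  expect_identical(cn$codons_compared, 2L)
  expect_equal(cn$N + cn$S, 6, tolerance = 1e-9)
  expect_error(ng_counts("ATG", "ATGGCC"), "equal length")
  expect_error(ng_counts("ATGC", "ATGC"), "multiple of 3")
})

test_that("site counts conserve N + S = 3 codons on random pairs", {
  set.seed(61)
  for (i in 1:300) {
    c1 <- paste(sample(SENSE_CODONS, 8, replace = TRUE), collapse = "")
    c2 <- paste(sample(SENSE_CODONS, 8, replace = TRUE), collapse = "")
    cn <- ng_counts(c1, c2)
    expect_equal(cn$N + cn$S, 3 * cn$codons_compared, tolerance = 1e-9)
    # symmetry
    cn2 <- ng_counts(c2, c1)
    expect_equal(cn$Nd, cn2$Nd, tolerance = 1e-12)
    expect_equal(cn$Sd, cn2$Sd, tolerance = 1e-12)
  }
})

test_that("Jukes-Cantor correction behaves at the limits", {
  # p -> 0: Dn/pN -> 1
  cn <- list(N = 1000, S = 500, Nd = 1, Sd = 1)
  dd <- dnds(cn)
  expect_equal(dd$Dn / dd$pN, 1, tolerance = 1e-2)
  # saturation: p >= 3/4 undefined, no exception
  sat <- dnds(list(N = 4, S = 4, Nd = 3.5, Sd = 0))
  expect_true(is.na(sat$Dn))
  expect_true(sat$undefined)
  expect_error(dnds(list(N = 0, S = 1, Nd = 0, Sd = 0)), "N > 0")
})

test_that("selection zones split at 1 and 0.27 with boundaries going down", {
  expect_identical(classify_selection(list(ratio = 2)), "positive")
  expect_identical(classify_selection(list(ratio = 0.5)), "lack_of_constraints")
  expect_identical(classify_selection(list(ratio = 0.1)), "purifying")
  expect_identical(classify_selection(list(ratio = 1)), "lack_of_constraints")
  expect_identical(classify_selection(list(ratio = 0.27)), "purifying")
  expect_identical(classify_selection(list(ratio = NA_real_)), "undefined")
  # worked example: Dn = 0.5, Ds = 0.25
  expect_identical(classify_selection(list(ratio = 0.5 / 0.25)), "positive")
})

test_that("the Fisher test equals the hypergeometric tail sum", {
  p <- fisher_positive_selection(list(Nd = 8, N = 10, Sd = 1, S = 10))
  expect_equal(p, oracle_fisher_greater(8, 2, 1, 9), tolerance = 1e-12)
  # no differences at all -> p = 1
  expect_identical(fisher_positive_selection(list(Nd = 0, N = 10, Sd = 0, S = 5)), 1)
  set.seed(62)
  for (i in 1:50) {
    N <- sample(5:40, 1); S <- sample(5:40, 1)
    cn <- list(N = N, S = S, Nd = runif(1, 0, N / 2), Sd = runif(1, 0, S / 2))
    p <- fisher_positive_selection(cn)
    expect_gte(p, 0); expect_lte(p, 1)
  }
})

test_that("codon-aware alignment preserves frames for Nei-Gojobori input", {
  tpl <- reference_templates()
  cds1 <- reverse_translate(tpl$precursor[1])
  # 3-codon deletion plus a point change
  cds2 <- paste0(substr(cds1, 1, 29), substr(cds1, 39, nchar(cds1)))
  substr(cds2, 80, 80) <- "A"
  ca <- codon_align(cds1, cds2)
  expect_identical(nchar(ca$cds1), nchar(ca$cds2))
  expect_identical(nchar(ca$cds1) %% 3L, 0L)
  cn <- ng_counts(ca$cds1, ca$cds2)
  expect_gte(cn$codons_compared, 3L)
})
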