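templates <- reference_templates()

test_that("templates realise catalog architecture and framework invariants", {
  cat_df <- toxin_catalog()
  expect_identical(nrow(templates), 16L)
  expect_identical(templates$precursor,
                   paste0(templates$signal_peptide, templates$propeptide,
                          templates$mature_peptide))
  for (i in seq_len(nrow(templates))) {
    fw <- extract_framework(templates$mature_peptide[i])
    expect_identical(fw$pattern_class, templates$framework_pattern[i])
    expect_true(fw$n_cys >= 4 && fw$n_cys <= 12)
    if (nzchar(templates$propeptide[i]))
      expect_match(templates$propeptide[i], "[A-Z][ED][ED]R$")
  }
  # no-propeptide superfamilies follow the catalog
  no_pro <- cat_df$superfamily[!cat_df$has_propeptide]
  expect_identical(sort(templates$superfamily[!nzchar(templates$propeptide)]),
                   sort(no_pro))
})

test_that("zero mutation rates reproduce the template CDS exactly", {
  rates0 <- c(point = 0, insertion = 0, deletion = 0, premature_stop = 0,
              stop_loss = 0)
  v <- generate_variants(templates[1:2, ], n_variants_per_template = 3,
                         mutation_rates = rates0, seed = 5)
  expect_identical(length(v$cds), 6L)
  for (i in seq_along(v$cds)) {
    tpl <- templates[templates$template_id == v$truth$template_id[i], ]
    expect_identical(unname(v$cds[i]), reverse_translate(tpl$precursor))
    expect_identical(v$truth$n_mutations[i], 0L)
  }
  # translating an unmutated variant reproduces signal+propeptide+mature
  aa <- sub("\\*$", "", translate_nt(v$cds[[1]], 1L))
  tpl <- templates[templates$template_id == v$truth$template_id[1], ]
  expect_identical(aa, tpl$precursor)
})

test_that("a premature stop at codon k truncates translation to k-1 residues", {
  cds <- reverse_translate(templates$precursor[1])
  k <- 20L
  spec <- list(kind = "premature_stop", position = (k - 1L) * 3L + 1L,
               payload = "TAA", length = 0L)
  mut <- apply_mutation_specs(cds, list(spec))
  aa <- translate_nt(mut, 1L)
  expect_identical(as.integer(regexpr("*", aa, fixed = TRUE)), k)
  expect_identical(nchar(sub("\\*.*$", "", aa)), k - 1L)
})

test_that("variant generation is byte-identical under a fixed seed", {
  a <- generate_variants(templates, 4, seed = 7)
  b <- generate_variants(templates, 4, seed = 7)
  expect_identical(a$cdna, b$cdna)
  expect_identical(a$truth, b$truth)
  r1 <- generate_reads(a, read_model(seed = 7), total_reads = 500)
  r2 <- generate_reads(b, read_model(seed = 7), total_reads = 500)
  expect_identical(r1$reads, r2$reads)
})

test_that("invalid mutation rates are rejected", {
  expect_error(generate_variants(templates, 2, mutation_rates = c(point = 1.2),
                                 seed = 1), "rates")
  expect_error(generate_variants(templates[0, ], 2, seed = 1), "non-empty")
})

test_that("emitted reads honour the truth ledger and the length bounds", {
  v <- generate_variants(templates, 5, seed = 3)
  rr <- generate_reads(v, read_model(seed = 3), total_reads = 1500)
  counts <- table(rr$read_map)
  expect_identical(sum(rr$truth$read_count), length(rr$reads))
  for (vid in rr$truth$variant_id)
    expect_identical(unname(counts[vid]),
                     rr$truth$read_count[rr$truth$variant_id == vid])
  # every read is an exact substring of its source cDNA
  idx <- sample(length(rr$reads), 200)
  for (i in idx) {
    src <- v$cdna[[rr$read_map[[i]]]]
    expect_true(grepl(rr$reads[[i]], src, fixed = TRUE))
  }
  expect_true(all(nchar(rr$reads) >= 40 & nchar(rr$reads) <= 836))
  # a truth count of 1 emits exactly one read
  singles <- rr$truth$variant_id[rr$truth$read_count == 1]
  expect_true(length(singles) > 0)
  expect_true(all(counts[singles] == 1))
})

test_that("read-length sampler hits the configured mean within 5%", {
  model <- read_model(seed = 1)
  set.seed(1)
  L <- sample_read_lengths(model, 10000)
  expect_true(all(L >= 40 & L <= 836))
  expect_lt(abs(mean(L) - 327) / 327, 0.05)
})

test_that("read counts show a Zipf head with a singleton tail", {
  counts <- local({ set.seed(2); zipf_read_counts(200, 5000) })
  expect_identical(length(counts), 200L)
  expect_true(all(counts >= 1))
  frac1 <- mean(counts == 1)
  expect_gt(frac1, 0.55); expect_lt(frac1, 0.75)
})

test_that("background categories match requested proportions and construction", {
  bg1 <- generate_background(60, category_mix = c(cellular = 1), seed = 1)
  tox_db <- stats::setNames(templates$precursor, templates$template_id)
  refs <- nontoxin_references()
  for (s in bg1[1:10]) {
    cl <- classify_transcript(s, tox_db, refs)
    expect_false(cl$category == "Toxin_like")
  }
  bg2 <- generate_background(40, category_mix = c(no_hit = 1), seed = 2)
  for (s in bg2) expect_identical(nrow(find_orfs(s, min_aa = 40)), 0L)
  expect_error(generate_background(10, category_mix = c(cellular = -0.2,
                                                        no_hit = 1.2), seed = 1),
               "negative")
})

test_that("background category draws fall in the binomial 99% interval", {
  mix <- c(cellular = 0.44, no_hit = 0.20, unknown = 0.07,
           toxin_like_decoy = 0.29)
  n <- 10000
  bg <- generate_background(n, category_mix = mix, seed = 9)
  counts <- table(attr(bg, "categories")$category)
  for (nm in names(mix)) {
    lo <- qbinom(0.005, n, mix[[nm]]); hi <- qbinom(0.995, n, mix[[nm]])
    expect_gte(counts[[nm]], lo)
    expect_lte(counts[[nm]], hi)
  }
})
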