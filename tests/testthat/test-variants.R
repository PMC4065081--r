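templates <- reference_templates()

test_that("expression tiers have breakpoints exactly at 1/2 and 10/11", {
  expect_identical(assign_tier(1), "rare")
  expect_identical(assign_tier(2), "low")
  expect_identical(assign_tier(10), "low")
  expect_identical(assign_tier(11), "high")
  expect_identical(assign_tier(500), "high")
  expect_error(assign_tier(0), ">= 1")
})

test_that("family reference picks max read count, ties by CDS length then id", {
  mem <- data.frame(precursor_id = c("b", "a", "c"),
                    cds = c("AAATTT", "AAATTTGGG", "AAATTTGGG"),
                    read_count = c(5, 5, 5), stringsAsFactors = FALSE)
  expect_identical(family_reference(mem), "a")
  mem$read_count <- c(9, 5, 5)
  expect_identical(family_reference(mem), "b")
})

test_that("global nucleotide alignment handles identity and clean indels", {
  aln <- global_align_nt("ACGTACGTAC", "ACGTACGTAC")
  expect_identical(aln$pattern, aln$subject)
  set.seed(51)
  ref <- random_dna(60)
  del <- paste0(substr(ref, 1, 29), substr(ref, 33, 60))
  aln2 <- global_align_nt(ref, del)
  expect_identical(nchar(gsub("[^-]", "", aln2$subject)), 3L)
  expect_false(grepl("-", aln2$pattern))
  expect_error(global_align_nt("", "ACGT"), "empty")
})

test_that("global alignment score matches exhaustive enumeration on a toy pair", {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  x <- "ACGTTGCAGGTA"; y <- "ACGTGCAGGA"
  expected <- oracle_global_score(x, y, mat, open = 5, ext = 2)
  expect_equal(global_align_nt(x, y)$score, expected)
})

test_that("a cysteine codon substitution yields nonsynonymous plus cysteine loss", {
  ref <- paste0("ATG", "TGC", "AAA", "TGC", "TAA")
  var <- paste0("ATG", "GGC", "AAA", "TGC", "TAA")
  ev <- classify_variant_events(var, ref)$events
  expect_true("point_nonsynonymous" %in% ev$kind)
  expect_true("cysteine_loss" %in% ev$kind)
  expect_identical(ev$nt_position[ev$kind == "point_nonsynonymous"], 4L)
})

test_that("a mid-CDS stop codon is reported as premature stop", {
  ref <- paste0("ATG", "CAA", "AAA", "GGG", "TTT", "TAA")
  var <- paste0("ATG", "TAA", "AAA", "GGG", "TTT", "TAA")
  ev <- classify_variant_events(var, ref)$events
  expect_identical(ev$kind, "premature_stop")
  expect_identical(ev$nt_position, 4L)
})

test_that("single-base deletion is one frameshift event with downstream collapse", {
  set.seed(52)
  ref <- reverse_translate(templates$precursor[2])
  pos <- nchar(ref) - 60L
  var <- paste0(substr(ref, 1, pos - 1), substr(ref, pos + 1, nchar(ref)))
  res <- classify_variant_events(var, ref)
  expect_identical(sum(res$events$kind == "frameshift"), 1L)
  expect_false(any(res$events$kind %in% c("point_synonymous",
                                          "point_nonsynonymous") &
                     res$events$nt_position > pos))
})

test_that("a read-through reference stop is stop-loss elongation", {
  ref <- paste0("ATG", "TGC", "AAA", "TAA")
  var <- paste0("ATG", "TGC", "AAA", "CAA")
  ev <- classify_variant_events(var, ref)$events
  expect_identical(ev$kind, "stop_loss_elongation")
})

test_that("an unalignable pair is flagged with no events", {
  res <- classify_variant_events(strrep("ACGT", 30), strrep("GGTA", 35),
                                 min_identity = 0.9)
  expect_true(res$flagged)
  expect_identical(nrow(res$events), 0L)
})

test_that("cysteine-loss count matches framework difference for point variants", {
  tpl <- templates[1, ]
  ref <- reverse_translate(tpl$precursor)
  mat_start <- nchar(tpl$signal_peptide) + nchar(tpl$propeptide) + 1L
  # knock out the first two mature cysteines (TGC -> GGC at codon starts)
  aa <- strsplit(tpl$mature_peptide, "")[[1]]
  cys <- which(aa == "C")[1:2] + mat_start - 1L
  var <- ref
  for (cp in cys) substr(var, (cp - 1) * 3 + 1, (cp - 1) * 3 + 1) <- "G"
  ev <- classify_variant_events(var, ref)$events
  expect_identical(sum(ev$kind == "cysteine_loss"), 2L)
  ref_fw <- extract_framework(tpl$mature_peptide)
  var_mat <- translate_nt(substr(var, (mat_start - 1) * 3 + 1,
                                 nchar(var) - 3), 1L)
  var_fw <- extract_framework(var_mat)
  expect_identical(ref_fw$n_cys - var_fw$n_cys,
                   sum(ev$kind == "cysteine_loss"))
})

test_that("injected single mutations are recovered at 99%+ by kind and position", {
  er <- evaluate_event_recovery(templates, n_per_kind = 2, seed = 11)
  expect_gte(er$recovery, 0.99)
  expect_gte(er$n, 100)
})
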