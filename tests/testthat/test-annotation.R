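catalog <- toxin_catalog()
templates <- reference_templates()

test_that("framework extraction renders scaffolds and pattern classes", {
  fw <- extract_framework("ACAACAACCAACAACA")
  expect_identical(fw$scaffold, "-C-C-CC-C-C-")
  expect_identical(fw$n_cys, 6L)
  expect_identical(fw$pattern_class, "I")

  fw9 <- extract_framework("AACAAACAAACAAACAA")
  expect_identical(fw9$scaffold, "-C-C-C-C-")
  expect_identical(fw9$pattern_class, "IX")
  expect_identical(fw9$n_cys, 4L)

  m7 <- paste0("AA", "C", "AAA", "C", "AAA", "CC", "AAA", "C", "AAA", "C",
               "AAA", "C", "AAA", "C", "AAA", "CC", "AAA", "C", "AAA", "C", "AA")
  fw7 <- extract_framework(m7)
  expect_identical(fw7$pattern_class, "VII")
  expect_identical(fw7$n_cys, 12L)
  expect_identical(fw7$parity, "even")

  fw0 <- extract_framework("AAAA")
  expect_identical(fw0$scaffold, "-")
  expect_identical(fw0$pattern_class, "NOVEL")
  expect_identical(fw0$n_cys, 0L)
})

test_that("every catalog pattern reproduces its scaffold bit-exactly", {
  pats <- framework_patterns()
  expect_identical(length(pats), 11L)
  for (nm in names(pats)) {
    # build a mature realising the scaffold, then re-extract
    mature <- gsub("-", "AAA", pats[[nm]])
    fw <- extract_framework(mature)
    expect_identical(fw$scaffold, pats[[nm]])
    expect_identical(fw$pattern_class, nm)
  }
})

test_that("framework is invariant under non-cysteine substitutions", {
  set.seed(7)
  pool <- setdiff(strsplit("ARNDQEGHILKMFPSTWYV", "")[[1]], "C")
  for (i in 1:25) {
    m <- templates$mature_peptide[sample(nrow(templates), 1)]
    fw0 <- extract_framework(m)
    res <- strsplit(m, "")[[1]]
    idx <- which(res != "C")
    pick <- sample(idx, min(4, length(idx)))
    res[pick] <- sample(pool, length(pick), replace = TRUE)
    fw1 <- extract_framework(paste(res, collapse = ""))
    expect_identical(fw1$scaffold, fw0$scaffold)
    expect_identical(fw1$pattern_class, fw0$pattern_class)
  }
})

test_that("local alignment scores identical and disjoint sequences correctly", {
  b62 <- local({ e <- new.env(); utils::data("BLOSUM62", package = "Biostrings",
                                             envir = e); e$BLOSUM62 })
  q <- "MKASMFLAFAGLVLLFVVCY"   # 20-mer
  hit <- local_align(q, c(self = q))
  expect_equal(hit$raw_score, sum(diag(b62[strsplit(q, "")[[1]],
                                           strsplit(q, "")[[1]]])))
  # disjoint alphabets, all pairwise substitution scores negative
  none <- local_align("IIIIII", c(x = "DDDDDD"))
  expect_identical(none$raw_score, 0)
  expect_false(none$significant)
  expect_error(local_align("", c(x = "A")), "empty")
})

test_that("local alignment equals exhaustive enumeration on a toy pair", {
  b62 <- local({ e <- new.env(); utils::data("BLOSUM62", package = "Biostrings",
                                             envir = e); e$BLOSUM62 })
  x <- "MKCWGH"; y <- "AKCWGHND"
  expected <- oracle_local_score(x, y, b62, open = 11, ext = 1)
  hit <- local_align(x, c(y = y))
  expect_equal(hit$raw_score, expected)
})

test_that("segmentation finds catalog signal, CYASE junction and PQM", {
  tpl <- templates[templates$superfamily == "I", ]
  seg <- segment_precursor(tpl$precursor, catalog)
  expect_identical(seg$signal, tpl$signal_peptide)
  expect_identical(seg$propeptide, tpl$propeptide)
  expect_identical(seg$mature, tpl$mature_peptide)
  expect_identical(seg$signal_evidence, "catalog_match")
  expect_true("CYASE" %in% seg$cleavage_motifs)
  expect_true(any(grepl("EER$", seg$cleavage_motifs)))
  # conservation: spans cover the precursor exactly
  expect_identical(nchar(seg$signal) + nchar(seg$propeptide) + nchar(seg$mature),
                   nchar(tpl$precursor))
})

test_that("segmentation recovers all templates and signal-less precursors", {
  expect_identical(evaluate_segmentation_recovery(templates, catalog), 1)
  # superfamily XXV: no signal, matched by its propeptide anchor
  tpl25 <- templates[templates$superfamily == "XXV", ]
  seg <- segment_precursor(tpl25$precursor, catalog)
  expect_identical(seg$signal, "")
  expect_identical(seg$propeptide, "MTREETQSLGEHEKDEEVTGSEER")
  expect_identical(seg$signal_evidence, "catalog_match")
})

test_that("no PQM between signal and first cysteine leaves propeptide empty", {
  sig <- catalog$signal_peptide[catalog$superfamily == "XIV"]
  mature <- "ATAGCATCAAACAAACCAAACAAACAAACAAACAAACA"
  seg <- segment_precursor(paste0(sig, mature), catalog)
  expect_identical(seg$propeptide, "")
  expect_identical(seg$mature, mature)
})

test_that("precursor without any signal evidence degrades to full mature", {
  aa <- "MSTKNQPLTKNQPLWWTKNQPLHHTKNQPLKKCAAACAAAC"
  seg <- suppressWarnings(segment_precursor(aa, catalog))
  expect_identical(seg$signal_evidence, "missing")
  expect_identical(seg$mature, aa)
  expect_identical(nchar(seg$signal) + nchar(seg$propeptide) + nchar(seg$mature),
                   nchar(aa))
})

test_that("transcript classification follows the five-category rule order", {
  tox_db <- stats::setNames(templates$precursor, templates$template_id)
  refs <- nontoxin_references()
  # template-derived transcript -> Toxin_like
  cdna <- paste0("GGACTGAGCAT", reverse_translate(templates$precursor[1]),
                 "GCAGCTGCAGCTTAAGCAGT")
  cl <- classify_transcript(cdna, tox_db, refs)
  expect_identical(cl$category, "Toxin_like")
  expect_identical(cl$best_hit, "HWTX-I")
  # random sequence without ORFs -> No_Hit
  s <- paste(rep("TAATGATAG", 30), collapse = "")
  expect_identical(classify_transcript(s, tox_db, refs)$category, "No_Hit")
  # annotated housekeeping reference -> Cellular_Proteins
  cell <- paste0("ACGATC", reverse_translate(refs$seq[refs$annotated][1]), "ACGT")
  expect_identical(classify_transcript(cell, tox_db, refs)$category,
                   "Cellular_Proteins")
  # unannotated reference -> Unknown_function
  unk <- paste0("ACGATC", reverse_translate(refs$seq[!refs$annotated][1]), "ACGT")
  expect_identical(classify_transcript(unk, tox_db, refs)$category,
                   "Unknown_function")
  # cysteine-rich ORF with no catalog hit -> Putative_toxin
  mat <- "MSTKNQPLTKNQPLWWTKNQPLHHCAAKNCAAKNCCKNQAAKNCAAKWC"
  rich <- paste0("AGT", reverse_translate(mat), "CGTA")
  expect_identical(classify_transcript(rich, tox_db, refs)$category,
                   "Putative_toxin")
})

test_that("classification is total: every transcript gets exactly one category", {
  tox_db <- stats::setNames(templates$precursor, templates$template_id)
  refs <- nontoxin_references()
  set.seed(31)
  for (i in 1:10) {
    cl <- classify_transcript(random_dna(200), tox_db, refs)
    expect_identical(nrow(cl), 1L)
    expect_true(cl$category %in% c("Toxin_like", "Putative_toxin",
                                   "Cellular_Proteins", "Unknown_function",
                                   "No_Hit"))
  }
})
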