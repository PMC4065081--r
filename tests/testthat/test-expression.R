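test_that("regression is exact on collinear points and two points", {
  pts <- data.frame(n_precursors = c(1, 2, 3, 4), n_reads = c(10, 20, 30, 40))
  fit <- regress_abundance(pts)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$slope, 10, tolerance = 1e-12)
  two <- regress_abundance(data.frame(n_precursors = c(2, 5),
                                      n_reads = c(7, 90)))
  expect_equal(two$r_squared, 1, tolerance = 1e-12)
})

test_that("five-point fit matches the closed-form normal equations", {
  pts <- data.frame(n_precursors = c(2, 4, 5, 9, 12),
                    n_reads = c(30, 90, 110, 220, 260))
  x <- pts$n_precursors; y <- pts$n_reads
  slope <- (sum(x * y) - length(x) * mean(x) * mean(y)) /
    (sum(x^2) - length(x) * mean(x)^2)
  intercept <- mean(y) - slope * mean(x)
  pred <- intercept + slope * x
  r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  fit <- regress_abundance(pts)
  expect_equal(fit$slope, slope, tolerance = 1e-12)
  expect_equal(fit$intercept, intercept, tolerance = 1e-12)
  expect_equal(fit$r_squared, r2, tolerance = 1e-12)
  expect_true(fit$r_squared >= 0 && fit$r_squared <= 1)
})

test_that("degenerate abscissae raise an error", {
  expect_error(regress_abundance(data.frame(n_precursors = c(3, 3, 3),
                                            n_reads = c(1, 2, 3))),
               "degenerate")
})

test_that("report censuses conserve their universes", {
  categories <- data.frame(id = sprintf("t%d", 1:6),
                           category = c("Toxin_like", "Toxin_like", "No_Hit",
                                        "Putative_toxin", "Toxin_like",
                                        "Unknown_function"))
  taxonomy <- data.frame(precursor_id = c("t1", "t2", "t4", "t5"),
                         superfamily = c("I", "I", "II", "XVIII"))
  tiers <- data.frame(precursor_id = c("t1", "t2", "t4", "t5"),
                      read_count = c(40, 2, 1, 1),
                      tier = c("high", "low", "rare", "rare"))
  frameworks <- data.frame(precursor_id = c("t1", "t2", "t4", "t5"),
                           pattern_class = c("I", "I", "II", "NOVEL"))
  rep <- build_report(categories, taxonomy, tiers, frameworks)
  expect_equal(sum(rep$category_proportions), 1, tolerance = 1e-9)
  expect_identical(sum(rep$tier_census), 4L)
  expect_identical(unname(rep$tier_census["high"] + rep$tier_census["low"] +
                            rep$tier_census["rare"]), nrow(tiers))
  expect_identical(sum(rep$framework_census), 4L)
  expect_identical(sum(rep$superfamilies$n_precursors), 4L)
  out <- capture.output(print(rep))
  expect_true(any(grepl("precursors: 4", out)))
})

test_that("a toxin-only run reports a pure Toxin_like mix", {
  categories <- data.frame(id = c("a", "b"), category = c("Toxin_like",
                                                          "Toxin_like"))
  taxonomy <- data.frame(precursor_id = c("a", "b"), superfamily = c("I", "I"))
  tiers <- data.frame(precursor_id = c("a", "b"), read_count = c(3, 1),
                      tier = c("low", "rare"))
  frameworks <- data.frame(precursor_id = c("a", "b"),
                           pattern_class = c("I", "I"))
  rep <- build_report(categories, taxonomy, tiers, frameworks)
  expect_identical(unname(rep$category_proportions[["Toxin_like"]]), 1)
})
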