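reg <- mcid_registry()
mhhs <- prom_lookup(reg, "mHHS")

test_that("sd_from_range applies the quarter-range rule", {
  expect_identical(sd_from_range(0, 4), 1)
  expect_identical(sd_from_range(10, 10), 0)
  expect_equal(sd_from_range(55.5, 99.9), 11.1)
  expect_error(sd_from_range(5, 4), "range_min")
})

test_that("missing SDs borrow the largest donor SD", {
  donors <- data.frame(prom = "mHHS", timepoint = "post",
                       sd = c(10.2, 12.5, 9.8))
  target <- list(prom = "mHHS", timepoint = "post")
  expect_identical(impute_missing_sd(target, donors), 12.5)
  expect_identical(impute_missing_sd(target, donors[2, ]), 12.5)
  expect_equal(impute_missing_sd(target, donors, rule = "mean"),
               mean(donors$sd))
  # donors from another instrument or timepoint are ineligible
  expect_error(impute_missing_sd(list(prom = "NAHS", timepoint = "post"),
                                 donors), "no donor")
  expect_error(impute_missing_sd(list(prom = "mHHS", timepoint = "pre"),
                                 donors), "no donor")
})

test_that("mean and SD normalization divide by the MCID", {
  expect_equal(normalize_mean(84.7, mhhs), 84.7 / 9.5)
  expect_equal(round_half_up(normalize_mean(84.7, mhhs), 1), 8.9)
  expect_equal(round_half_up(normalize_sd(11.4, mhhs), 1), 1.2)
  ihot33 <- prom_lookup(reg, "iHOT-33")
  expect_equal(round_half_up(normalize_mean(76.4, ihot33), 1), 7.1)
  expect_equal(round_half_up(normalize_sd(16.8, ihot33), 1), 1.6)
  expect_identical(normalize_sd(0, mhhs), 0)
  expect_error(normalize_sd(-1, mhhs))
  # an instrument without an MCID is an error, not a silent skip
  expect_error(normalize_mean(50, prom_lookup(reg, "HOOS")), "no adopted MCID")
})

test_that("normalization is linear and inverts exactly", {
  means <- c(0, 12.5, 84.7, 100)
  for (a in c(0, 0.5, 2)) {
    expect_equal(normalize_mean(a * means, mhhs),
                 a * normalize_mean(means, mhhs))
  }
  expect_equal(normalize_mean(means, mhhs) * mhhs$mcid, means,
               tolerance = 1e-15)
})

test_that("change scores always count improvement as positive", {
  expect_equal(change_mcid(70, 79.5, mhhs), 1)
  expect_identical(change_mcid(55, 55, mhhs), 0)
  womac_like <- structure(list(name = "WOMAC", scale_min = 0, scale_max = 96,
                               orientation = "higher_worse", mcid = 10,
                               normalizable = TRUE),
                          class = "prom_definition")
  expect_identical(change_mcid(40, 20, womac_like), 2)
})

test_that("sd_change follows the paired-difference formula", {
  for (s in c(0.5, 3, 12)) expect_equal(sd_change(s, s, 1), 0)
  expect_identical(sd_change(3, 4, 0), 5)
  expect_equal(sd_change(12, 10, 0.5), sqrt(124))
  expect_error(sd_change(3, 4, 1.5), "\\[-1, 1\\]")
  # monotone non-increasing in r
  rs <- seq(-1, 1, by = 0.1)
  vals <- sd_change(12, 10, rs)
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("sd_change matches an empirical paired-normal oracle", {
  set.seed(11)
  n <- 2e5
  r <- 0.5
  pre <- rnorm(n, sd = 12)
  post <- r * (10 / 12) * pre + rnorm(n, sd = 10 * sqrt(1 - r^2))
  expect_equal(sd(post - pre), sd_change(12, 10, r), tolerance = 0.01)
})

test_that("table normalization resolves SDs with recorded provenance", {
  m <- data.frame(
    study_id = "s", arm_id = c("1", "1", "2"), prom = "mHHS",
    timepoint = "post", n = c(30L, 30L, 28L),
    mean = c(80, 75, 70), sd = c(10, NA, NA),
    range_min = c(NA, 40, NA), range_max = c(NA, 100, NA))
  norm <- normalize_measurements(m, reg)
  expect_identical(norm$sd_provenance, c("reported", "from_range", "imputed"))
  expect_equal(norm$sd_mcid, c(10, 15, 15) / 9.5)  # imputed = max donor (15)
  audit <- attr(norm, "audit")
  expect_identical(sum(audit$action == "sd_imputed"), 1L)
  expect_identical(sum(audit$action == "sd_from_range"), 1L)
})

test_that("unresolvable SDs drop the record with warning and audit entry", {
  m <- data.frame(study_id = "s", arm_id = "1", prom = c("mHHS", "NAHS"),
                  timepoint = "post", n = 30L, mean = c(80, 75),
                  sd = c(10, NA))
  expect_warning(norm <- normalize_measurements(m, reg), "no donor")
  expect_identical(norm$prom, "mHHS")
  expect_identical(attr(norm, "audit")$action, "excluded_no_sd")
})

test_that("instruments without MCIDs are excluded with an audit trail", {
  m <- data.frame(study_id = "s", arm_id = "1", prom = c("mHHS", "HOOS"),
                  timepoint = "post", n = 30L, mean = c(80, 60),
                  sd = c(10, 12))
  norm <- normalize_measurements(m, reg)
  expect_identical(norm$prom, "mHHS")
  expect_identical(attr(norm, "audit")$action, "excluded_no_mcid")
})

test_that("out-of-scale means warn but are kept", {
  m <- data.frame(study_id = "s", arm_id = "1", prom = "mHHS",
                  timepoint = "post", n = 30L, mean = 105, sd = 10)
  expect_warning(norm <- normalize_measurements(m, reg), "outside scale")
  expect_identical(nrow(norm), 1L)
  expect_identical(attr(norm, "audit")$action, "out_of_scale")
})

test_that("every cell of the demonstration table reproduces at one decimal", {
  norm <- normalize_measurements(demo_hip_studies(), reg)
  expected <- demo_expected_cells()
  expect_identical(nrow(norm), nrow(expected))  # 22 records, 44 cells
  key <- function(s, a, p) paste(s, a, p, sep = "|")
  idx <- match(key(expected$study, expected$arm, expected$prom),
               key(norm$study_id, norm$arm_id, norm$prom))
  expect_false(anyNA(idx))
  expect_identical(round_half_up(norm$mean_mcid[idx], 1), expected$mean)
  expect_identical(round_half_up(norm$sd_mcid[idx], 1), expected$sd)
  expect_true(all(norm$sd_provenance == "reported"))
})

test_that("change outcomes pair pre/post and sweep r", {
  m <- data.frame(
    study_id = "s", arm_id = "1", prom = "mHHS",
    timepoint = c("pre", "post"), n = 30L,
    mean = c(51.0, 79.5), sd = c(12, 10))
  ch <- change_outcomes(m, reg, r = c(0.2, 0.5, 0.8))
  expect_identical(nrow(ch), 3L)
  expect_equal(unique(ch$delta_mcid), (79.5 - 51.0) / 9.5)
  expect_equal(ch$sd_delta_mcid,
               sd_change(12, 10, c(0.2, 0.5, 0.8)) / 9.5)
  expect_identical(ch$r_used, c(0.2, 0.5, 0.8))
})
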