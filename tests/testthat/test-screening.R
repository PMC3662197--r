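test_that("absorbance converts to nkat/mL by blank correction, calibration and unit arithmetic", {
  cfg <- assay_config(calib_slope = 0.01)
  expect_identical(activity_from_absorbance(0.3, blank = 0.3, cfg), 0)
  # 0.5 AU / 0.01 AU/nmol = 50 nmol pNP over 900 s from 0.05 mL sample
  expect_equal(activity_from_absorbance(0.5, 0, cfg), 50 / 900 / 0.05,
               tolerance = 1e-12)
  expect_equal(activity_from_absorbance(0.9, 0.1, cfg),
               2 * activity_from_absorbance(0.5, 0.1, cfg))
  # below-blank readings clamp to zero rather than going negative
  expect_identical(activity_from_absorbance(0.1, 0.2, cfg), 0)
  expect_error(assay_config(calib_slope = 0), "positive")
})

test_that("liquid classification distinguishes none / low / significant on published strains", {
  s <- santorini_screen()
  cls <- classify_liquid(s)
  pick <- function(id) as.character(cls[s$strain == id])
  expect_identical(pick("SP14"), "significant")  # 1.070 / 2.367
  expect_identical(pick("SP47"), "low")          # mean 0.0415
  expect_identical(pick("SP1"), "none")          # - / -
  # measured 0.000 enters the mean; ND contributes nothing
  expect_identical(pick("SP56"), "low")          # (0.052 + 0.000)/2 = 0.026
  expect_identical(pick("SP101"), "significant") # (0.000 + 0.122)/2 = 0.061
})

test_that("halo positivity counts a partial or full halo at either time point", {
  s <- santorini_screen()
  halo <- classify_halo(s)
  expect_true(halo[s$strain == "SP4"])    # (-, +)
  expect_true(halo[s$strain == "SP93"])   # (++, ++)
  expect_false(halo[s$strain == "SP14"])  # (-, -)
})

test_that("the packaged screen reproduces the published partition and percentages", {
  sm <- summarize_screen(santorini_screen())
  expect_identical(sm$n_total, 101L)
  expect_identical(sm$n_halo, 17L)
  expect_identical(sm$n_significant, 56L)
  expect_identical(sm$n_low, 19L)
  expect_identical(sm$n_none, 26L)
  expect_identical(sm$pct_halo, 16.8)
  expect_identical(sm$pct_significant, 55.4)
  expect_identical(sm$pct_detectable, 74.3)
})

test_that("the three liquid classes partition any screening table", {
  for (s in list(santorini_screen(),
                 simulate_screen(60, c(0.3, 0.3, 0.4), seed = 4),
                 simulate_screen(5, c(0, 0, 1), seed = 5))) {
    sm <- summarize_screen(s)
    expect_identical(sm$n_significant + sm$n_low + sm$n_none, sm$n_total)
  }
  single <- screening_table("A", "-", "-", 0.4, 0.5)
  sm1 <- summarize_screen(single)
  expect_identical(c(sm1$n_significant, sm1$n_low, sm1$n_none), c(1L, 0L, 0L))
  expect_identical(sm1$pct_significant, 100)
})

test_that("classification is monotone in either activity value", {
  base <- screening_table("A", "-", "-", 0.03, 0.04)
  expect_identical(as.character(classify_liquid(base)), "low")
  rank <- c(none = 0, low = 1, significant = 2)
  for (bump in c(0.01, 0.05, 1)) {
    up48 <- screening_table("A", "-", "-", 0.03 + bump, 0.04)
    up72 <- screening_table("A", "-", "-", 0.03, 0.04 + bump)
    expect_gte(rank[as.character(classify_liquid(up48))], rank["low"])
    expect_gte(rank[as.character(classify_liquid(up72))], rank["low"])
  }
})

test_that("every halo producer in the packaged screen has detectable liquid activity", {
  s <- santorini_screen()
  expect_true(all(classify_liquid(s)[classify_halo(s)] != "none"))
})

test_that("selection returns the nine follow-up strains plus the SP95 rule anomaly", {
  s <- santorini_screen()
  sel <- select_strains(s)
  expect_true(all(SELECTED_NINE %in% sel))
  # the stated rule (> 0.75 nkat/mL mean, or full halo) also captures SP95
  expect_identical(sel, sort(c(SELECTED_NINE, "SP95")))
  expect_identical(select_strains(s, activity_threshold = Inf),
                   c("SP73", "SP75", "SP93"))
})

test_that("screening CSV round trip preserves ND/zero distinction and halo scores", {
  s <- santorini_screen()
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_screening_csv(s, tmp)
  s2 <- read_screening_csv(tmp)
  expect_equal(s2$olm_48h, s$olm_48h)
  expect_identical(is.na(s2$olm_72h), is.na(s$olm_72h))
  expect_identical(as.character(s2$roa_48h), as.character(s$roa_48h))
})

test_that("duplicate strain ids are rejected", {
  expect_error(screening_table(c("A", "A"), c("-", "-"), c("-", "-"),
                               c(0.1, 0.2), c(0.1, 0.2)), "duplicate")
  s <- santorini_screen()
  s2 <- rbind(s, s[1, ])
  expect_error(summarize_screen(s2), "duplicate")
})
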