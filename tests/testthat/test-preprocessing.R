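test_that("range size is max minus min and rejects inverted records", {
  r <- rec_df(c(1200, 900, 0), c(3400, 900, 6500))
  expect_equal(compute_range_size(r), c(2200, 0, 6500))
  expect_error(compute_range_size(rec_df(2500, 1800)), "validate")
})

test_that("validation rejects impossible elevations with reason codes", {
  r <- rec_df(c(2500, 100, 500, NA, 1000), c(1800, 6700, 2000, 1500, 2500))
  v <- validate_records(r)
  expect_equal(nrow(v$records), 2)
  expect_setequal(v$records$species_id, c("sp003", "sp005"))
  expect_equal(v$rejected$reason[v$rejected$species_id == "sp001"], "min_gt_max")
  expect_equal(v$rejected$reason[v$rejected$species_id == "sp002"], "above_6500")
  expect_equal(v$rejected$reason[v$rejected$species_id == "sp004"], "non_finite")
  all_ok <- rec_df(c(100, 200), c(300, 200))
  v2 <- validate_records(all_ok)
  expect_equal(nrow(v2$rejected), 0)
  expect_equal(v2$records, all_ok)
})

test_that("singleton fraction is the share of zero-width ranges", {
  r <- rec_df(c(rep(100, 25), seq(200, 990, length.out = 75)),
              c(rep(100, 25), seq(300, 1090, length.out = 75)))
  expect_equal(singleton_fraction(r), 0.25)
  expect_equal(singleton_fraction(rec_df(1:5 * 100, 1:5 * 100 + 50)), 0)
  expect_equal(singleton_fraction(rec_df(1:4 * 100, 1:4 * 100)), 1)
  expect_error(singleton_fraction(rec_df(numeric(0), numeric(0))), "records")
})

test_that("sampling gaps are maximal holes in the interval union", {
  r <- rec_df(c(0, 1600), c(1000, 3000))
  g <- detect_sampling_gaps(r)
  expect_equal(nrow(g), 1)
  expect_equal(c(g$gap_lower, g$gap_upper, g$width), c(1000, 1600, 600))
  expect_equal(nrow(detect_sampling_gaps(rec_df(c(0, 1400), c(1000, 3000)))), 0)
  expect_equal(nrow(detect_sampling_gaps(rec_df(0, 3000))), 0)
  # overlapping and nested ranges merge before gaps are measured
  r2 <- rec_df(c(0, 200, 500, 2000, 2100), c(800, 900, 900, 2600, 2200))
  g2 <- detect_sampling_gaps(r2, gap_threshold = 1000)
  expect_equal(nrow(g2), 1)
  expect_equal(g2$width, 1100)
})

test_that("mountain filters apply the singleton and continuity rules", {
  mk <- function(id, n_single, n_total, gap = FALSE) {
    n_reg <- n_total - n_single
    lo <- seq(0, 2400, length.out = n_reg)
    hi <- lo + 400
    if (gap) { lo <- lo + ifelse(lo > 1200, 1000, 0); hi <- lo + 300 }
    rec_df(c(rep(500, n_single), lo), c(rep(500, n_single), hi),
           mountain_id = id,
           species_id = sprintf("%s_s%03d", id, seq_len(n_total)))
  }
  recs <- rbind(mk("m26", 26, 100), mk("m25", 25, 100), mk("mgap", 5, 100, gap = TRUE))
  mtns <- data.frame(mountain_id = c("m26", "m25", "mgap"),
                     land_type = "continental", domain_min = 0,
                     domain_max = 3000)
  out <- filter_mountains(recs, mtns)
  expect_setequal(out$mountains$mountain_id, "m25")
  expect_equal(out$exclusions$reason[out$exclusions$mountain_id == "m26"],
               "singleton_fraction")
  expect_equal(out$exclusions$reason[out$exclusions$mountain_id == "mgap"],
               "sampling_gap")
})

test_that("gradient standardization anchors, truncates and drops as specified", {
  r <- rec_df(c(2500, 1200, 3500, 4000), c(3600, 2900, 4800, 5100))
  std <- standardize_gradient(r, c(0, 5100), standardization_config(2000, 250, "top"))
  expect_equal(std$domain, c(3100, 5100))
  expect_equal(std$domain[2] - std$domain[1], 2000)
  s1 <- std$records[std$records$species_id == "sp001", ]
  expect_equal(c(s1$min_elev, s1$max_elev), c(3100, 3600))
  expect_false("sp002" %in% std$records$species_id)
  expect_equal(nrow(std$records), 3)
  # bottom anchoring mirrors the rule
  stdb <- standardize_gradient(r, c(0, 5100),
                               standardization_config(2000, 250, "bottom"))
  expect_equal(stdb$domain, c(0, 2000))
  expect_error(standardize_gradient(r, c(0, 1800),
                                    standardization_config(2000, 250)),
               "shorter")
})

test_that("standardization is idempotent and never grows ranges or counts", {
  set.seed(21)
  cfg <- standardization_config(1500, 250, "top")
  for (i in 1:20) {
    n <- sample(5:40, 1)
    dom <- c(0, sample(seq(1600, 6000, 100), 1))
    lo <- runif(n, dom[1], dom[2]); hi <- pmin(lo + rexp(n, 1 / 500), dom[2])
    r <- rec_df(lo, hi)
    once <- standardize_gradient(r, dom, cfg)
    twice <- standardize_gradient(once$records, once$domain, cfg)
    expect_equal(twice$records, once$records)
    expect_equal(twice$domain, once$domain)
    expect_lte(nrow(once$records), n)
    expect_true(all(once$records$min_elev >= once$domain[1]))
    expect_true(all(once$records$max_elev <= once$domain[2]))
    expect_true(all(once$records$max_elev >= once$records$min_elev))
  }
})

test_that("exclusion zones drop only ranges strictly inside an edge zone", {
  dom <- c(3100, 5100)
  r <- rec_df(c(4900, 3200, 3100, 3150, 4000), c(5050, 3500, 3350, 3250, 4500))
  out <- apply_exclusion_zones(r, dom, 250)
  expect_false("sp001" %in% out$species_id)  # entirely in top zone
  expect_true("sp002" %in% out$species_id)   # crosses zone boundary
  expect_true("sp003" %in% out$species_id)   # touches inner edge: kept
  expect_false("sp004" %in% out$species_id)  # strictly inside bottom zone
  expect_true("sp005" %in% out$species_id)
  expect_identical(apply_exclusion_zones(r, dom, 0), r)
  expect_error(apply_exclusion_zones(r, dom, 1000), "exclusion_zone")
  expect_error(apply_exclusion_zones(rec_df(100, 200), dom, 250), "domain")
})

test_that("exclusion zones match a brute-force containment oracle", {
  set.seed(33)
  for (i in 1:20) {
    dom <- c(0, 3000); E <- sample(c(100, 250, 500), 1)
    lo <- runif(30, 0, 3000); hi <- pmin(lo + rexp(30, 1 / 400), 3000)
    r <- rec_df(lo, hi)
    keep_oracle <- !((lo >= dom[1] & hi < dom[1] + E) |
                       (lo > dom[2] - E & hi <= dom[2]))
    out <- apply_exclusion_zones(r, dom, E)
    expect_setequal(out$species_id, r$species_id[keep_oracle])
  }
})

test_that("log transform floors singletons at 10 m", {
  expect_equal(transform_range_sizes(0), log(10))
  expect_equal(transform_range_sizes(10), log(10))
  expect_equal(transform_range_sizes(1000), log(1000))
  expect_equal(transform_range_sizes(c(0, 10)), rep(log(10), 2))
  expect_true(all(is.finite(transform_range_sizes(c(0, 5, 10000)))))
  expect_error(transform_range_sizes(-1), ">= 0")
})

test_that("the preprocessing pipeline runs stages in order and logs attrition", {
  w <- small_world(n_mountains = 10, n_species = 80, seed = 4,
                   span_range = c(1500, 4000))
  pp <- preprocess_dataset(w$species, w$mountains$meta,
                           standardization_config(2500, 250, "top"))
  expect_true(all(grepl("validate|filter|standardize|exclusion|transform",
                        pp$stage_log)))
  # stage order as written
  expect_equal(grep("validate", pp$stage_log), 1L)
  expect_lt(grep("filter", pp$stage_log), grep("standardize", pp$stage_log))
  short <- w$mountains$meta$mountain_id[
    w$mountains$meta$domain_max - w$mountains$meta$domain_min < 2500]
  expect_true(all(short %in%
    pp$mountain_exclusions$mountain_id[
      pp$mountain_exclusions$reason == "span_too_short"]))
  expect_true(all(pp$mountains$domain_max - pp$mountains$domain_min == 2500))
  expect_lte(nrow(pp$records), nrow(w$species))
  expect_true(all(is.finite(pp$records$log_range)))
})
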