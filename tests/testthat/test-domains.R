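test_that("height binning counts lower-inclusive 5-cm bins", {
  ud <- bin_heights(c(2, 3, 7))
  expect_equal(ud$counts[1:2], c(2, 1))
  expect_equal(ud$p[1:2], c(2 / 3, 1 / 3))
  expect_equal(sum(ud$p), 1)
  expect_equal(ud$n_obs, 3)

  one <- bin_heights(rep(12, 8))
  expect_equal(sum(one$p > 0), 1)
  expect_equal(max(one$p), 1)

  # boundary: 5 belongs to [5, 10), canopy top belongs to the last bin
  b <- bin_heights(c(5, 88))
  expect_equal(which(b$counts > 0), c(2, 18))

  expect_error(bin_heights(numeric(0)), "no observations")
  expect_error(bin_heights(c(-1, 3)), "outside")
})

test_that("uniform heights give near-uniform bin frequencies", {
  set.seed(10)
  h <- runif(1000, 0, 80)
  ud <- bin_heights(h, canopy_max = 80)
  expect_equal(length(ud$p), 16)
  expect_lt(max(abs(ud$p - 1 / 16)), 0.05)
})

test_that("boundary-reflected KDE integrates to one and finds structure", {
  set.seed(2)
  h <- pmin(pmax(rnorm(500, 30, 8), 0), 88)
  ud <- kde_ud(h)
  step <- diff(ud$grid)[1]
  trapz <- sum(step * (head(ud$density, -1) + tail(ud$density, -1)) / 2)
  expect_equal(trapz, 1, tolerance = 1e-6)

  # two well-separated clusters -> bimodal density
  hb <- c(rnorm(300, 10, 2), rnorm(300, 70, 2))
  hb <- pmin(pmax(hb, 0), 88)
  udb <- kde_ud(hb)
  d <- udb$density
  n_max <- sum(d[2:(length(d) - 1)] > d[1:(length(d) - 2)] &
                 d[2:(length(d) - 1)] > d[3:length(d)])
  expect_gte(n_max, 2)

  # consistency: mode near the true mean
  set.seed(3)
  hn <- pmin(pmax(rnorm(5000, 40, 10), 0), 88)
  udn <- kde_ud(hn)
  # grid resolution is 1 cm, so the mode can land exactly 2 cm away
  expect_lte(abs(udn$grid[which.max(udn$density)] - 40), 2)

  expect_warning(kde_ud(rep(10, 5)), "1 cm bandwidth")
})

test_that("isopleths are highest-density regions with correct normal-limit endpoints", {
  set.seed(7)
  h <- rnorm(20000, 40, 10)
  h <- h[h >= 0 & h <= 88]
  ud <- kde_ud(h)
  core <- isopleth(ud, 0.5)
  broad <- isopleth(ud, 0.95)
  expect_equal(nrow(core$intervals), 1)
  expect_lt(abs(core$intervals[1, 1] - (40 - 6.745)), 1.5)
  expect_lt(abs(core$intervals[1, 2] - (40 + 6.745)), 1.5)
  expect_lt(abs(broad$intervals[1, 1] - (40 - 19.6)), 2)
  expect_lt(abs(broad$intervals[1, 2] - (40 + 19.6)), 2)

  # nesting and mass bounds
  expect_true(all(core$cells %in% broad$cells))
  expect_gte(core$mass, 0.5)
  step_mass <- max(ud$density) / sum(ud$density)
  expect_lte(core$mass, 0.5 + step_mass)
  expect_gte(broad$mass, 0.95)

  expect_error(isopleth(ud, 0), "level")
  expect_error(isopleth(ud, 1.2), "level")
})

test_that("a bimodal density yields a disjoint isopleth region", {
  set.seed(11)
  hb <- pmin(pmax(c(rnorm(400, 10, 2), rnorm(400, 70, 2)), 0), 88)
  ud <- kde_ud(hb)
  core <- isopleth(ud, 0.5)
  expect_gte(nrow(core$intervals), 2)
})

test_that("Bhattacharyya affinity matches analytic cases and is symmetric", {
  a <- bin_heights(c(2, 7), canopy_max = 10)
  expect_equal(bhattacharyya(a, a), 1)

  disj_a <- bin_heights(c(2, 2), canopy_max = 20)
  disj_b <- bin_heights(c(17, 18), canopy_max = 20)
  expect_equal(bhattacharyya(disj_a, disj_b), 0)

  p_half <- bin_heights(c(2, 7), canopy_max = 10)        # (0.5, 0.5)
  q_quarter <- bin_heights(c(2, 7, 7, 7), canopy_max = 10) # (0.25, 0.75)
  expect_equal(bhattacharyya(p_half, q_quarter), 0.9659258262890682,
               tolerance = 1e-7)
  expect_equal(bhattacharyya(p_half, q_quarter),
               bhattacharyya(q_quarter, p_half))
  # documented non-radical variant
  expect_equal(bhattacharyya(p_half, q_quarter, radical = FALSE), 0.5)

  expect_error(bhattacharyya(a, bin_heights(c(2, 7), canopy_max = 20)),
               "different bin edges")
})

test_that("isopleth-restricted affinity discounts non-core bins", {
  set.seed(13)
  a <- kde_ud(pmin(pmax(rnorm(2000, 30, 8), 0), 88))
  b <- kde_ud(pmin(pmax(rnorm(2000, 55, 8), 0), 88))
  ba_full <- bhattacharyya(a, b, level = "full")
  ba_core <- bhattacharyya(a, b, level = 0.5)
  expect_true(ba_full >= 0 && ba_full <= 1)
  expect_true(ba_core >= 0 && ba_core <= 1)
  expect_lt(ba_core, ba_full)
  expect_equal(bhattacharyya(a, a, level = 0.5), 1)
})

test_that("chi-square contrast reproduces hand-computed statistics", {
  same <- domain_chi2(c(4, 6, 2), c(4, 6, 2))
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)

  diag <- domain_chi2(c(10, 0), c(0, 10))
  expect_equal(diag$chi2, 20)
  expect_equal(diag$df, 1)

  # 2 x 6 fixture against an independently computed Pearson statistic
  ca <- c(12, 5, 9, 0, 3, 7)
  cb <- c(4, 8, 2, 6, 1, 10)
  res <- domain_chi2(ca, cb)
  expect_equal(res$chi2, 16.394433957882722, tolerance = 1e-9)
  expect_equal(res$df, 5)
  # group swap invariance
  swap <- domain_chi2(cb, ca)
  expect_equal(swap$chi2, res$chi2)

  # zero-total bins are dropped before testing
  drop0 <- domain_chi2(c(10, 0, 0), c(0, 0, 10))
  expect_equal(drop0$df, 1)
  expect_error(domain_chi2(c(0, 0), c(0, 0)), "all counts are zero")
})

test_that("domain report assembles the standard overlap comparisons", {
  cfg <- domain_sim_config(n_per_type = 30, height_mean_shy = 40,
                           height_mean_bold = 40, predator_shift_shy = -8,
                           predator_shift_bold = -8, seed = 19)
  obs <- gen_height_observations(cfg)
  rep1 <- domain_report(obs)
  expect_equal(nrow(rep1$overlaps), 4)
  expect_setequal(rep1$overlaps$comparison,
                  c("full_extent", "core", "core_predator", "core_solidago"))
  # identically distributed types: near-total overlap
  expect_gt(rep1$overlaps$ba[rep1$overlaps$comparison == "full_extent"], 0.95)
  expect_gt(rep1$overlaps$ba[rep1$overlaps$comparison == "core"], 0.9)

  # opposite predator shifts separate the predator-context cores
  cfg2 <- domain_sim_config(n_per_type = 30, predator_shift_shy = -20,
                            predator_shift_bold = 15, seed = 23)
  obs2 <- gen_height_observations(cfg2)
  ba_np <- bhattacharyya(
    kde_ud(obs2$height_cm[obs2$personality == "shy" &
                            obs2$context == "no_predator"]),
    kde_ud(obs2$height_cm[obs2$personality == "bold" &
                            obs2$context == "no_predator"]),
    level = 0.5)
  ba_pred <- bhattacharyya(
    kde_ud(obs2$height_cm[obs2$personality == "shy" &
                            obs2$context == "predator"]),
    kde_ud(obs2$height_cm[obs2$personality == "bold" &
                            obs2$context == "predator"]),
    level = 0.5)
  expect_lt(ba_pred, ba_np)

  # missing group -> partial report with a warning per comparison
  w <- capture_warnings(rep2 <- domain_report(obs[obs$personality == "shy", ]))
  expect_true(length(w) >= 1 && all(grepl("missing group", w)))
  expect_lt(nrow(rep2$overlaps), 4)
})
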