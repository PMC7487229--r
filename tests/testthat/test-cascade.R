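make_records <- function(grass_ctrl = 12, grass_trt = 10) {
  treatments <- c("control", "shy", "bold", "shy_pred", "bold_pred")
  d <- expand.grid(block_id = 1:2, treatment = treatments,
                   stringsAsFactors = FALSE)
  d$survival <- ifelse(d$treatment == "control", NA, 3L)
  d$biomass_grass <- ifelse(d$treatment == "control", grass_ctrl, grass_trt)
  d$biomass_forb <- 5
  d
}

test_that("biomass standardization subtracts the block control", {
  imp <- standardize_biomass(make_records(12, 10))
  expect_true(all(imp$delta_g[imp$group == "grass"] == -2))
  expect_true(all(imp$delta_g[imp$group == "forb"] == 0))
  expect_equal(nrow(imp), 2 * 4 * 2) # blocks x treatments x groups
  expect_equal(levels(imp$personality), c("shy", "bold"))
  expect_equal(sort(unique(imp$predation)), c(0, 1))

  rec <- make_records()
  rec <- rec[!(rec$treatment == "control" & rec$block_id == 2), ]
  expect_error(standardize_biomass(rec), "without a control")
})

test_that("impacts are invariant to block-wide biomass offsets", {
  cfg <- null_mesocosm_cfg(seed = 44, residual_sd = 5, block_sd = 0)
  rec <- gen_mesocosm_dataset(cfg)
  imp1 <- standardize_biomass(rec)
  rec2 <- rec
  bump <- rec2$block_id * 3.5
  for (bc in grep("^biomass_", names(rec2), value = TRUE)) {
    rec2[[bc]] <- rec2[[bc]] + bump
  }
  imp2 <- standardize_biomass(rec2)
  expect_equal(imp1$delta_g, imp2$delta_g)
})

test_that("zero-noise mesocosm data give exact coefficient recovery", {
  cfg <- mesocosm_sim_config(
    herbivory_effects = list(
      grass = c(herbivory = -20, personality = -23.73, predation = -4.75,
                interaction = 34.31),
      solidago = c(herbivory = -8, personality = 0, predation = 0,
                   interaction = 0),
      forb = c(herbivory = -3, personality = 0, predation = 0,
               interaction = 0)),
    block_sd = 0, residual_sd = 0, survival_rate = 0.6, seed = 17)
  imp <- standardize_biomass(gen_mesocosm_dataset(cfg))
  m <- fit_trophic_model(imp, "grass")
  est <- setNames(m$terms$estimate, m$terms$term)
  expect_equal(est[["personalitybold"]], -23.73, tolerance = 1e-6)
  expect_equal(est[["predation"]], -4.75, tolerance = 1e-6)
  expect_equal(est[["personalitybold:predation"]], 34.31, tolerance = 1e-6)
  expect_equal(est[["survival"]], 0, tolerance = 1e-6)
  expect_equal(est[["(Intercept)"]], -20, tolerance = 1e-6)
})

test_that("shared control noise appears as block-level variance", {
  v_block <- vapply(c(2, 25), function(s) {
    cfg <- null_mesocosm_cfg(seed = 50, residual_sd = s, block_sd = 8)
    imp <- standardize_biomass(gen_mesocosm_dataset(cfg))
    fit_trophic_model(imp, "grass")$random_block_variance
  }, numeric(1))
  expect_gt(v_block[2], v_block[1])
})

test_that("interaction test keeps nominal type-I error under the null", {
  set.seed(61)
  seeds <- sample.int(1e6, 200)
  pvals <- vapply(seeds, function(s) {
    imp <- standardize_biomass(gen_mesocosm_dataset(null_mesocosm_cfg(s)))
    m <- fit_trophic_model(imp, "grass")
    m$terms$p[m$terms$term == "personalitybold:predation"]
  }, numeric(1))
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.08)
})

test_that("label permutation is reproducible, bounded, and exact for identity", {
  imp <- standardize_biomass(gen_mesocosm_dataset(null_mesocosm_cfg(71)))
  p1 <- permute_labels(imp, "grass", n_perm = 30, seed = 5)
  p2 <- permute_labels(imp, "grass", n_perm = 30, seed = 5)
  expect_identical(p1$perm_estimates, p2$perm_estimates)
  expect_identical(p1$p_perm, p2$p_perm)
  expect_true(p1$p_perm > 0 && p1$p_perm <= 1)

  n_units <- sum(imp$group == "grass")
  ident <- matrix(seq_len(n_units), nrow = 1)
  p_id <- permute_labels(imp, "grass", permutations = ident)
  expect_equal(p_id$p_perm, 1)
  expect_equal(p_id$perm_estimates, p_id$observed)

  for (sch in c("block_predation", "block", "none")) {
    ps <- permute_labels(imp, "grass", n_perm = 10, seed = 6, strata = sch)
    expect_true(ps$p_perm > 0 && ps$p_perm <= 1)
  }
  expect_error(permute_labels(imp, "grass", strata = "cage"),
               "block_predation")

  expect_error(permute_labels(imp, "grass", term = "nope"), "term must be")
})

test_that("permutation test detects a strong interaction", {
  set.seed(81)
  seeds <- sample.int(1e6, 20)
  hits <- vapply(seeds, function(s) {
    cfg <- mesocosm_sim_config(
      herbivory_effects = list(
        grass = c(herbivory = -20, personality = -23.73, predation = -4.75,
                  interaction = 34.31),
        solidago = c(herbivory = -8, personality = 0, predation = 0,
                     interaction = 0),
        forb = c(herbivory = -3, personality = 0, predation = 0,
                 interaction = 0)),
      block_sd = 8, residual_sd = 10, seed = s)
    imp <- standardize_biomass(gen_mesocosm_dataset(cfg))
    pt <- permute_labels(imp, "grass", term = "personality:predation",
                         n_perm = 99, seed = s + 1)
    pt$p_perm <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("interaction recovery stays within 2 SE at the configured effect", {
  set.seed(91)
  seeds <- sample.int(1e6, 60)
  ok <- vapply(seeds, function(s) {
    imp <- standardize_biomass(gen_mesocosm_dataset(
      mesocosm_sim_config(seed = s)))
    m <- fit_trophic_model(imp, "grass")
    row <- m$terms[m$terms$term == "personalitybold:predation", ]
    abs(row$estimate - 34.31) <= 2 * row$se
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("respiration rate follows the flow-through arithmetic", {
  expect_equal(respiration_rate(10, mass_g = 0.1, flow_ml_min = 200,
                                temp_c = 0), 20)
  expect_equal(respiration_rate(0, mass_g = 0.1), 0)
  r1 <- respiration_rate(10, mass_g = 0.1, temp_c = 25)
  r2 <- respiration_rate(10, mass_g = 0.2, temp_c = 25)
  expect_equal(r1 / 2, r2)
  expect_lt(r1, 20) # warm air holds less CO2 per volume at standard T
  expect_error(respiration_rate(10, mass_g = 0), "mass")
  expect_error(respiration_rate(10, mass_g = 0.1, flow_ml_min = -1), "flow")
})

test_that("risk contrast is a paired test equivalent to repeated-measures ANOVA", {
  mk <- function(base, risk) {
    data.frame(individual_id = rep(sprintf("g%02d", seq_along(base)), 2),
               context = rep(c("baseline", "risk"), each = length(base)),
               rate = c(base, risk))
  }
  same <- risk_contrast(mk(c(4, 5, 6, 7), c(4, 5, 6, 7)))
  expect_equal(same$mean_diff, 0)
  expect_equal(same$p, 1)

  shift <- risk_contrast(mk(c(4, 5, 6, 7) + 2, c(4, 5, 6, 7)))
  expect_equal(shift$mean_diff, 2)

  set.seed(15)
  base <- rnorm(20, 10, 2)
  risk <- base - 1 + rnorm(20, 0, 1)
  rc <- risk_contrast(mk(base, risk))
  expect_equal(rc$F, rc$t^2, tolerance = 1e-9)
  # cross-check against aov-based repeated-measures F
  long <- mk(base, risk)
  af <- summary(aov(rate ~ context + Error(individual_id), data = long))
  F_aov <- af[["Error: Within"]][[1]]["context", "F value"]
  expect_equal(rc$F, F_aov, tolerance = 1e-9)

  unpaired <- mk(base, risk)[-1, ]
  expect_warning(rc2 <- risk_contrast(unpaired), "unpaired")
  expect_equal(rc2$n, 19)
})

test_that("paired contrast recovers a simulated risk suppression", {
  set.seed(25)
  seeds <- sample.int(1e6, 200)
  ok <- vapply(seeds, function(s) {
    set.seed(s)
    base <- rnorm(32, 12, 2)
    risk <- base - 1 + rnorm(32, 0, 1)
    d <- data.frame(individual_id = rep(sprintf("g%02d", 1:32), 2),
                    context = rep(c("baseline", "risk"), each = 32),
                    rate = c(base, risk))
    rc <- risk_contrast(d)
    se <- (rc$ci[2] - rc$ci[1]) / (2 * qt(0.975, rc$df))
    abs(rc$mean_diff - 1) <= 2 * se
  }, logical(1))
  expect_gte(mean(ok), 0.92)
})
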