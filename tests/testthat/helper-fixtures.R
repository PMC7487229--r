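# Deterministic fixtures used across test files.

# 15-position assay trajectory; distances were verified against an
# independent spreadsheet-style computation and are frozen in
# fixture_distances().
fixture_trajectory <- function() {
  pos <- rbind(
    c(0, 0), c(3, 4), c(3, 4), c(6, 8), c(10, 8), c(10, 13), c(12, 13),
    c(12, 16), c(9, 16), c(9, 12), c(5, 12), c(5, 7), c(2, 7), c(2, 3),
    c(0, 0))
  data.frame(individual_id = "fix001", context = "forage", minute = 0:14,
             x = pos[, 1], y = pos[, 2], assay_round = 1L)
}

fixture_distances <- function() {
  c(5, 0, 5, 4, 5, 2, 3, 3, 4, 4, 5, 3, 4, 3.605551275463989)
}

# balanced one-way layout: 6 individuals x 4 observations, chosen so the
# ANOVA variance components are well inside the parameter space
balanced_icc_df <- function() {
  y <- c(2.3, 1.5, 2.1, 2.2, 5.3, 5.9, 5.4, 6.1, 3.7, 3.4, 2.8, 2.9,
         6.5, 7.2, 7.4, 6.9, 4.6, 4.1, 4.9, 4.5, 5.9, 6.6, 5.8, 6.4)
  data.frame(individual_id = rep(sprintf("i%02d", 1:6), each = 4),
             activity = y)
}

# closed-form one-way ANOVA ICC: (MSB - MSW) / (MSB + (k - 1) MSW)
anova_icc <- function(d) {
  groups <- split(d$activity, d$individual_id)
  k <- length(groups[[1]])
  n <- length(groups)
  means <- vapply(groups, mean, numeric(1))
  grand <- mean(d$activity)
  msb <- k * sum((means - grand)^2) / (n - 1)
  msw <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                    numeric(1))) / (n * k - n)
  (msb - msw) / (msb + (k - 1) * msw)
}

# mesocosm config with no personality / predation / interaction effects
null_mesocosm_cfg <- function(seed, residual_sd = 15, block_sd = 8) {
  mesocosm_sim_config(
    herbivory_effects = list(
      grass = c(herbivory = -20, personality = 0, predation = 0,
                interaction = 0),
      solidago = c(herbivory = -8, personality = 0, predation = 0,
                   interaction = 0),
      forb = c(herbivory = -3, personality = 0, predation = 0,
               interaction = 0)),
    residual_sd = residual_sd, block_sd = block_sd, seed = seed)
}

sample_skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / mean((x - m)^2)^1.5
}
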