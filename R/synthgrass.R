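#' Configuration for synthetic personality-assay trajectories
#'
#' Defines the statistical structure of simulated assay data: each
#' individual receives a Gaussian random intercept on the log scale of
#' per-minute step length, so that the intraclass correlation (ICC) of
#' log step length across an individual's observations equals
#' `icc_target`. Per-minute steps are lognormal; trajectories live on a
#' 1-cm integer grid inside a 24 x 16 cm arena, matching the assay
#' terrarium footprint.
#'
#' Rounding positions to the integer grid adds measurement variance to
#' the realized log step lengths (delta-method approximation
#' `(1/6) * E[1/d^2]`). The individual-intercept variance is inflated
#' analytically to compensate, so the ICC of the step lengths actually
#' recoverable from the emitted trajectories matches `icc_target`.
#'
#' @param n_individuals Number of individuals (>= 2).
#' @param icc_target Target latent-scale ICC of log step length, in
#'   `[0, 1)`. Values near 1 are unattainable on a finite grid; an error
#'   is raised when the target exceeds the grid-limited maximum.
#' @param mean_log_step Mean of log step length (log cm per minute) in
#'   the baseline (forage) context.
#' @param context_shifts Named numeric of length 3: additive log-scale
#'   offsets for the `forage`, `explore` and `predator` contexts.
#' @param skew Total behavioral standard deviation of log step length
#'   (individual + residual), > 0. Larger values produce a more
#'   right-skewed trait distribution on the original scale.
#' @param seed Integer seed; the generator uses one local RNG stream.
#' @return An object of class `assay_sim_config`.
#' @export
assay_sim_config <- function(n_individuals = 100,
                             icc_target = 0.6,
                             mean_log_step = log(3),
                             context_shifts = c(forage = 0, explore = 0.15,
                                                predator = -0.35),
                             skew = 0.7,
                             seed = 1L) {
  if (!is.numeric(icc_target) || length(icc_target) != 1 ||
      icc_target < 0 || icc_target >= 1) {
    stop("`icc_target` must be a single value in [0, 1)", call. = FALSE)
  }
  if (n_individuals < 2) stop("`n_individuals` must be >= 2", call. = FALSE)
  if (length(context_shifts) != 3) {
    stop("`context_shifts` must have exactly 3 elements", call. = FALSE)
  }
  if (is.null(names(context_shifts))) {
    names(context_shifts) <- c("forage", "explore", "predator")
  }
  if (!is.numeric(skew) || skew <= 0) stop("`skew` must be > 0", call. = FALSE)
  cfg <- list(n_individuals = as.integer(n_individuals),
              icc_target = icc_target,
              mean_log_step = mean_log_step,
              context_shifts = context_shifts,
              skew = skew,
              seed = as.integer(seed))
  class(cfg) <- "assay_sim_config"
  cfg
}

# grid-rounding variance of log step length, delta method:
# Var(log d_rounded - log d) ~ Var(eps)/d^2 with Var(eps) = 2 * 2 * (1/12)
# projected on the step direction = 1/6; expectation over the lognormal
# step distribution, averaged across contexts.
.grid_log_variance <- function(cfg) {
  mu <- cfg$mean_log_step + cfg$context_shifts
  mean(exp(-2 * mu + 2 * cfg$skew^2)) / 6
}

.arena_w <- 24
.arena_h <- 16

#' Generate synthetic assay trajectories
#'
#' Simulates, for every individual and each of the three assay contexts
#' (forage, explore, predator), one 15-position trajectory at 1-minute
#' spacing on the integer-cm grid of a 24 x 16 cm arena. Step lengths
#' are lognormal with a per-individual random intercept sized so that
#' the ICC of log step length equals `cfg$icc_target`; step directions
#' are uniform, redrawn until the step fits inside the arena (wall
#' reflection is used only in the rare case no direction fits).
#'
#' @param cfg An [assay_sim_config()].
#' @param assay_round Integer tag for the assay round (used by the
#'   lifetime-repeatability design); default 1.
#' @return A data frame with columns `individual_id`, `context`,
#'   `minute` (0-14), `x`, `y`, `assay_round`. The per-individual latent
#'   intercepts and variance components are attached as attributes
#'   `intercepts`, `sigma_a2` and `sigma_e2`.
#' @export
gen_assay_dataset <- function(cfg, assay_round = 1L) {
  stopifnot(inherits(cfg, "assay_sim_config"))
  v_round <- .grid_log_variance(cfg)
  sigma_a2 <- cfg$icc_target * (cfg$skew^2 + v_round)
  sigma_e2 <- cfg$skew^2 - sigma_a2
  if (sigma_e2 <= 0) {
    stop("icc_target exceeds the maximum attainable on the 1-cm grid (",
         round(cfg$skew^2 / (cfg$skew^2 + v_round), 3), ")", call. = FALSE)
  }
  rng <- .local_rng(cfg$seed)
  on.exit(rng$restore())
  n <- cfg$n_individuals
  intercepts <- stats::rnorm(n, 0, sqrt(sigma_a2))
  contexts <- names(cfg$context_shifts)
  out <- vector("list", n * 3L)
  k <- 0L
  for (i in seq_len(n)) {
    for (cx in contexts) {
      mu <- cfg$mean_log_step + cfg$context_shifts[[cx]] + intercepts[i]
      steps <- stats::rlnorm(14, mu, sqrt(sigma_e2))
      pos <- .walk_arena(steps)
      k <- k + 1L
      out[[k]] <- data.frame(individual_id = sprintf("ind%04d", i),
                             context = cx,
                             minute = 0:14,
                             x = pos[, 1], y = pos[, 2],
                             assay_round = as.integer(assay_round))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "intercepts") <- intercepts
  attr(res, "sigma_a2") <- sigma_a2
  attr(res, "sigma_e2") <- sigma_e2
  res
}

# random walk with lognormal step lengths inside [0, w] x [0, h];
# directions resampled until the step fits, reflecting walls as fallback
.walk_arena <- function(steps, w = .arena_w, h = .arena_h) {
  p <- c(stats::runif(1, 0, w), stats::runif(1, 0, h))
  pos <- matrix(0, nrow = length(steps) + 1L, ncol = 2)
  pos[1, ] <- round(p)
  for (s in seq_along(steps)) {
    d <- steps[s]
    ok <- FALSE
    for (try in 1:100) {
      ang <- stats::runif(1, 0, 2 * pi)
      q <- p + d * c(cos(ang), sin(ang))
      if (q[1] >= 0 && q[1] <= w && q[2] >= 0 && q[2] <= h) {
        ok <- TRUE
        break
      }
    }
    if (!ok) { # step longer than any straight line from p: reflect
      ang <- stats::runif(1, 0, 2 * pi)
      q <- .reflect(p + d * c(cos(ang), sin(ang)), w, h)
    }
    p <- q
    pos[s + 1L, ] <- round(p)
  }
  pos
}

.reflect <- function(q, w, h) {
  refl1 <- function(z, lim) {
    z <- z %% (2 * lim)
    ifelse(z > lim, 2 * lim - z, z)
  }
  c(refl1(q[1], w), refl1(q[2], h))
}

#' Configuration for synthetic habitat-domain observations
#'
#' Emulates the benchtop microcosm protocol: vertical canopy heights
#' recorded every 30 min for 12 h (25 scans) in an 88-cm canopy, for shy
#' and bold individuals under a no-predator and a predator-cue context.
#' Heights are truncated normal within `[0, canopy_max]`; the predator
#' context shifts each personality type's mean by its own signed offset.
#'
#' @param n_per_type Individuals per personality type.
#' @param height_mean_shy,height_mean_bold Mean canopy height (cm) in
#'   the no-predator context.
#' @param height_sd Within-individual height SD (cm).
#' @param predator_shift_shy,predator_shift_bold Signed mean shift (cm)
#'   applied in the predator context.
#' @param n_obs_per_individual Scans per individual per context
#'   (default 25 = 12 h at 30-min intervals).
#' @param canopy_max Canopy ceiling in cm (default 88, the microcosm
#'   height).
#' @param solidago_refuge_cm Height (cm) around which the probability of
#'   being recorded on Solidago substrate rises.
#' @param seed Integer seed.
#' @return An object of class `domain_sim_config`.
#' @export
domain_sim_config <- function(n_per_type = 16,
                              height_mean_shy = 35,
                              height_mean_bold = 45,
                              height_sd = 12,
                              predator_shift_shy = -15,
                              predator_shift_bold = 10,
                              n_obs_per_individual = 25,
                              canopy_max = 88,
                              solidago_refuge_cm = 60,
                              seed = 1L) {
  means <- c(height_mean_shy, height_mean_bold)
  if (any(means < 0 | means > canopy_max)) {
    stop("height means must lie in [0, canopy_max]", call. = FALSE)
  }
  if (n_obs_per_individual < 2) {
    stop("`n_obs_per_individual` must be >= 2", call. = FALSE)
  }
  cfg <- list(n_per_type = as.integer(n_per_type),
              height_mean_shy = height_mean_shy,
              height_mean_bold = height_mean_bold,
              height_sd = height_sd,
              predator_shift_shy = predator_shift_shy,
              predator_shift_bold = predator_shift_bold,
              n_obs_per_individual = as.integer(n_obs_per_individual),
              canopy_max = canopy_max,
              solidago_refuge_cm = solidago_refuge_cm,
              seed = as.integer(seed))
  class(cfg) <- "domain_sim_config"
  cfg
}

# truncated normal by rejection sampling on [lo, hi]
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lo & draw <= hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Generate synthetic habitat-domain height observations
#'
#' @param cfg A [domain_sim_config()].
#' @return A data frame with columns `individual_id`, `personality`,
#'   `context` (`no_predator` / `predator`), `time_index`, `height_cm`,
#'   `substrate` (`grass` / `solidago` / `other`) and `foraging`.
#' @export
gen_height_observations <- function(cfg) {
  stopifnot(inherits(cfg, "domain_sim_config"))
  rng <- .local_rng(cfg$seed)
  on.exit(rng$restore())
  types <- c(shy = cfg$height_mean_shy, bold = cfg$height_mean_bold)
  shifts <- c(shy = cfg$predator_shift_shy, bold = cfg$predator_shift_bold)
  rows <- list()
  for (ty in names(types)) {
    for (i in seq_len(cfg$n_per_type)) {
      id <- sprintf("%s%03d", ty, i)
      for (cx in c("no_predator", "predator")) {
        mu <- types[[ty]] + if (cx == "predator") shifts[[ty]] else 0
        mu <- min(max(mu, 0), cfg$canopy_max)
        h <- .rtruncnorm(cfg$n_obs_per_individual, mu, cfg$height_sd,
                         0, cfg$canopy_max)
        p_sol <- 0.8 * stats::plogis((h - cfg$solidago_refuge_cm) / 10)
        sol <- stats::runif(length(h)) < p_sol
        other <- !sol & stats::runif(length(h)) < 0.15
        substrate <- ifelse(sol, "solidago", ifelse(other, "other", "grass"))
        rows[[length(rows) + 1L]] <- data.frame(
          individual_id = id, personality = ty, context = cx,
          time_index = seq_along(h), height_cm = h,
          substrate = substrate,
          foraging = stats::runif(length(h)) < 0.45)
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Configuration for synthetic mesocosm harvests
#'
#' Emulates the randomized block field design: `n_blocks` blocks, each
#' containing the five treatments (control, shy, bold, shy_pred,
#' bold_pred) exactly once. Dry biomass per plant functional group is
#' baseline + block effect + treatment effect + residual, truncated at
#' zero; survival out of 5 stocked individuals is binomial.
#'
#' Treatment effects are parameterized per group as
#' `c(herbivory, personality, predation, interaction)`: `herbivory` is
#' the deficit common to all grasshopper treatments (relative to
#' control), `personality` adds for bold populations, `predation` for
#' spider treatments, and `interaction` for bold x spider. Default grass
#' effects follow the coefficient scale reported for this system
#' (personality -23.73 g, predation -4.75 g, interaction +34.31 g).
#'
#' @param n_blocks Number of blocks (default 10).
#' @param baseline_biomass Named numeric: mean control dry biomass (g)
#'   per functional group.
#' @param herbivory_effects Named list of length-4 numerics per group,
#'   see Details.
#' @param block_sd,residual_sd Block and residual SD in g.
#' @param survival_rate Per-capita survival probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return An object of class `mesocosm_sim_config`.
#' @export
mesocosm_sim_config <- function(n_blocks = 10,
                                baseline_biomass = c(grass = 55, solidago = 40,
                                                     forb = 18),
                                herbivory_effects = list(
                                  grass = c(herbivory = -20, personality = -23.73,
                                            predation = -4.75, interaction = 34.31),
                                  solidago = c(herbivory = -8, personality = 0,
                                               predation = 0, interaction = 0),
                                  forb = c(herbivory = -3, personality = 0,
                                           predation = 0, interaction = 0)),
                                block_sd = 8,
                                residual_sd = 15,
                                survival_rate = 0.484,
                                seed = 1L) {
  if (survival_rate < 0 || survival_rate > 1) {
    stop("`survival_rate` must be in [0, 1]", call. = FALSE)
  }
  groups <- names(baseline_biomass)
  if (!setequal(groups, names(herbivory_effects))) {
    stop("`herbivory_effects` must name the same groups as `baseline_biomass`",
         call. = FALSE)
  }
  cfg <- list(n_blocks = as.integer(n_blocks),
              treatments = c("control", "shy", "bold", "shy_pred", "bold_pred"),
              baseline_biomass = baseline_biomass,
              herbivory_effects = herbivory_effects,
              block_sd = block_sd,
              residual_sd = residual_sd,
              survival_rate = survival_rate,
              seed = as.integer(seed))
  class(cfg) <- "mesocosm_sim_config"
  cfg
}

#' Generate a synthetic mesocosm harvest table
#'
#' @param cfg A [mesocosm_sim_config()].
#' @return A data frame with one row per block x treatment: `block_id`,
#'   `treatment`, `survival` (NA for controls, which hold no
#'   grasshoppers) and one `biomass_<group>` column per functional
#'   group (dry g, truncated at 0).
#' @export
gen_mesocosm_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "mesocosm_sim_config"))
  rng <- .local_rng(cfg$seed)
  on.exit(rng$restore())
  groups <- names(cfg$baseline_biomass)
  block_eff <- stats::rnorm(cfg$n_blocks, 0, cfg$block_sd)
  grid <- expand.grid(block_id = seq_len(cfg$n_blocks),
                      treatment = cfg$treatments,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  bold <- as.numeric(grid$treatment %in% c("bold", "bold_pred"))
  pred <- as.numeric(grid$treatment %in% c("shy_pred", "bold_pred"))
  herb <- as.numeric(grid$treatment != "control")
  res <- grid
  res$survival <- ifelse(grid$treatment == "control", NA_integer_,
                         stats::rbinom(nrow(grid), 5, cfg$survival_rate))
  for (g in groups) {
    ef <- cfg$herbivory_effects[[g]]
    mu <- cfg$baseline_biomass[[g]] + block_eff[grid$block_id] +
      herb * (ef[["herbivory"]] + bold * ef[["personality"]] +
                pred * ef[["predation"]] + bold * pred * ef[["interaction"]])
    b <- mu + if (cfg$residual_sd > 0) {
      stats::rnorm(nrow(grid), 0, cfg$residual_sd)
    } else 0
    res[[paste0("biomass_", g)]] <- pmax(b, 0)
  }
  res
}

# isolate a seeded RNG stream so generators leave the global RNG intact
.local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  list(restore = function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
}
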