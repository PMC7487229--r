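#' Control-standardized trophic impacts
#'
#' Standardizes harvested plant biomass relative to the control
#' treatment of the same block: `delta = treatment biomass - control
#' biomass`, per block, grasshopper treatment and plant functional
#' group. Negative values indicate less plant biomass and thus more
#' herbivory.
#'
#' @param records Mesocosm harvest table: columns `block_id`,
#'   `treatment` (including `"control"`), `survival`, and one
#'   `biomass_<group>` column per functional group (see
#'   [gen_mesocosm_dataset()]).
#' @return Long data frame of class `trophic_impacts`: `block_id`,
#'   `treatment`, `personality` (factor shy/bold), `predation` (0/1),
#'   `survival`, `group`, `delta_g`.
#' @export
standardize_biomass <- function(records) {
  bio_cols <- grep("^biomass_", names(records), value = TRUE)
  if (!length(bio_cols)) stop("no biomass_<group> columns found", call. = FALSE)
  ctrl <- records[records$treatment == "control", ]
  miss <- setdiff(unique(records$block_id), ctrl$block_id)
  if (length(miss)) {
    stop("blocks without a control record: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  trt <- records[records$treatment != "control", ]
  ctrl_idx <- match(trt$block_id, ctrl$block_id)
  out <- list()
  for (bc in bio_cols) {
    g <- sub("^biomass_", "", bc)
    out[[g]] <- data.frame(
      block_id = trt$block_id,
      treatment = trt$treatment,
      personality = factor(ifelse(grepl("^bold", trt$treatment),
                                  "bold", "shy"),
                           levels = c("shy", "bold")),
      predation = as.numeric(grepl("_pred$", trt$treatment)),
      survival = trt$survival,
      group = g,
      delta_g = trt[[bc]] - ctrl[[bc]][ctrl_idx])
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  class(res) <- c("trophic_impacts", class(res))
  res
}

#' Linear mixed model for trophic impact on one plant group
#'
#' Fits `delta ~ personality + predation + personality:predation +
#' survival + (1 | block)` by REML with treatment (dummy) coding
#' (shy = 0, bold = 1; predator absent = 0, present = 1), so the
#' interaction estimate is a single-df contrast. Wald t tests use
#' Satterthwaite degrees of freedom. Convergence or singularity
#' messages are captured into a `converged` flag rather than raised;
#' if the mixed fit fails outright (e.g. zero-variance degenerate
#' input), a fixed-effects fallback supplies the coefficients with
#' `converged = FALSE`.
#'
#' @param impacts Output of [standardize_biomass()].
#' @param group Plant functional group to model (e.g. `"grass"`).
#' @return Object of class `trophic_model`: `terms` data frame
#'   (estimate, se, df, t, p per fixed effect), `random_block_variance`,
#'   `sigma2`, `converged`, `group` and the underlying model object.
#' @export
fit_trophic_model <- function(impacts, group) {
  d <- impacts[impacts$group == group, , drop = FALSE]
  if (!nrow(d)) stop("no impacts for group ", group, call. = FALSE)
  if (length(unique(d$block_id)) < 2) stop("need >= 2 blocks", call. = FALSE)
  d$block_id <- factor(d$block_id)
  d$personality <- factor(d$personality, levels = c("shy", "bold"))
  converged <- TRUE
  m <- withCallingHandlers(
    tryCatch(
      lmerTest::lmer(delta_g ~ personality * predation + survival +
                       (1 | block_id),
                     data = d, REML = TRUE,
                     control = lme4::lmerControl(
                       check.conv.singular = "ignore")),
      error = function(e) e),
    warning = function(w) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage"))
  if (inherits(m, "error")) {
    lm_fit <- stats::lm(delta_g ~ personality * predation + survival, data = d)
    cs <- stats::coef(summary(lm_fit))
    terms <- data.frame(term = rownames(cs), estimate = cs[, 1],
                        se = cs[, 2], df = lm_fit$df.residual,
                        t = cs[, 3], p = cs[, 4], row.names = NULL)
    out <- list(terms = terms, random_block_variance = 0,
                sigma2 = summary(lm_fit)$sigma^2, converged = FALSE,
                group = group, model = lm_fit)
    class(out) <- "trophic_model"
    return(out)
  }
  cs <- stats::coef(summary(m))
  terms <- data.frame(term = rownames(cs), estimate = cs[, "Estimate"],
                      se = cs[, "Std. Error"], df = cs[, "df"],
                      t = cs[, "t value"], p = cs[, "Pr(>|t|)"],
                      row.names = NULL)
  vc <- lme4::VarCorr(m)
  out <- list(terms = terms,
              random_block_variance = as.numeric(vc$block_id),
              sigma2 = attr(vc, "sc")^2,
              converged = converged,
              group = group, model = m)
  class(out) <- "trophic_model"
  out
}

#' @export
print.trophic_model <- function(x, ...) {
  cat("Trophic-impact mixed model (", x$group, ")",
      if (!x$converged) "  [flagged: convergence/singularity]", "\n",
      sep = "")
  print(x$terms, row.names = FALSE, digits = 4)
  cat(sprintf("  block variance = %.3f, residual variance = %.3f\n",
              x$random_block_variance, x$sigma2))
  invisible(x)
}

# modular lme4 refit: reuse the parsed model structure, swapping the
# personality and interaction columns of X for the permuted labels.
# Verified to reproduce fixef() of a full lmer() call.
.perm_refit <- function(parsed, bold, predation, coef_name) {
  p2 <- parsed
  p2$X[, "personalitybold"] <- bold
  p2$X[, "personalitybold:predation"] <- bold * predation
  devfun <- do.call(lme4::mkLmerDevfun, p2)
  opt <- lme4::optimizeLmer(devfun)
  beta <- environment(devfun)$pp$beta(1)
  names(beta) <- colnames(p2$X)
  beta[[coef_name]]
}

#' Label-permutation test for a personality fixed effect
#'
#' Permutes the personality labels across the non-control mesocosms
#' (predation status, block and survival stay attached to their
#' mesocosms), refits the trophic-impact mixed model for each
#' permutation, and computes a two-sided permutation p value for the
#' chosen coefficient with the add-one correction
#' `p = (1 + #{|perm| >= |obs|}) / (n_perm + 1)`. This is the check
#' against regression-to-the-mean artifacts in extreme-group designs.
#'
#' By default labels are exchanged only between mesocosms that share a
#' block and a predation status (`strata = "block_predation"`). That is
#' the scheme under which personality labels are exchangeable when the
#' personality effect is null: control-standardized impacts are
#' correlated within blocks (every delta in a block subtracts the same
#' noisy control harvest), and freer schemes produce permuted designs
#' whose personality contrast is unbalanced across blocks or predation
#' levels, widening the permutation null and making the test
#' conservative. The freer schemes remain available for sensitivity
#' analysis.
#'
#' @param impacts Output of [standardize_biomass()].
#' @param group Plant functional group to model.
#' @param term Coefficient tested: `"personality"` or
#'   `"personality:predation"`.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed for the permutation stream.
#' @param strata Exchangeability constraint on the label shuffles:
#'   `"block_predation"` (default; labels move only within a block x
#'   predation-status pair), `"block"` (within blocks), or `"none"`
#'   (freely across all mesocosms).
#' @param permutations Optional integer matrix (`n_perm` x number of
#'   mesocosms) of explicit row orderings, overriding random draws
#'   (e.g. the identity ordering reproduces the observed statistic).
#' @return Object of class `permutation_test`: `term`, `observed`,
#'   `perm_estimates`, `p_perm`, `n_perm`, `seed`.
#' @export
permute_labels <- function(impacts, group, term = "personality",
                           n_perm = 199, seed = 1L,
                           strata = c("block_predation", "block", "none"),
                           permutations = NULL) {
  strata <- match.arg(strata)
  coef_name <- switch(term,
                      personality = "personalitybold",
                      `personality:predation` = "personalitybold:predation",
                      stop("term must be \"personality\" or \"personality:predation\"",
                           call. = FALSE))
  if (n_perm < 1) stop("`n_perm` must be >= 1", call. = FALSE)
  d <- impacts[impacts$group == group, , drop = FALSE]
  if (!nrow(d)) stop("no impacts for group ", group, call. = FALSE)
  d$block_id <- factor(d$block_id)
  d$personality <- factor(d$personality, levels = c("shy", "bold"))
  parsed <- suppressMessages(suppressWarnings(
    lme4::lFormula(delta_g ~ personality * predation + survival +
                     (1 | block_id),
                   data = d, REML = TRUE,
                   control = lme4::lmerControl(
                     check.conv.singular = "ignore",
                     calc.derivs = FALSE))))
  bold0 <- as.numeric(d$personality == "bold")
  observed <- suppressWarnings(
    .perm_refit(parsed, bold0, d$predation, coef_name))
  if (!is.null(permutations)) {
    n_perm <- nrow(permutations)
    draw <- function(i) permutations[i, ]
  } else {
    rng <- .local_rng(seed)
    on.exit(rng$restore())
    if (strata == "none") {
      draw <- function(i) sample.int(nrow(d))
    } else {
      grp <- if (strata == "block") {
        d$block_id
      } else {
        interaction(d$block_id, d$predation, drop = TRUE)
      }
      strata_idx <- split(seq_len(nrow(d)), grp)
      draw <- function(i) {
        idx <- seq_len(nrow(d))
        for (w in strata_idx) {
          idx[w] <- w[sample.int(length(w))]
        }
        idx
      }
    }
  }
  perm_estimates <- vapply(seq_len(n_perm), function(i) {
    suppressWarnings(
      .perm_refit(parsed, bold0[draw(i)], d$predation, coef_name))
  }, numeric(1))
  p_perm <- (1 + sum(abs(perm_estimates) >= abs(observed))) / (n_perm + 1)
  out <- list(term = term, observed = observed,
              perm_estimates = perm_estimates, p_perm = p_perm,
              n_perm = n_perm, seed = seed, group = group)
  class(out) <- "permutation_test"
  out
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("Permutation test (%s on %s): observed = %.3f, p = %.4f (%d permutations)\n",
              x$term, x$group, x$observed, x$p_perm, x$n_perm))
  invisible(x)
}

#' Mass-specific respiration rate from flow-through CO2 readings
#'
#' `rate = flow (ul/min) x (delta CO2 ppm x 1e-6) x f_T / mass (g)`,
#' in ul CO2 per g per min, where `f_T = 273.15 / (273.15 + temp_c)` is
#' the ideal-gas volumetric correction to the 0 degree C standard.
#'
#' @param co2_ppm_delta CO2 enrichment of the excurrent air (ppm).
#' @param mass_g Body mass in g (> 0).
#' @param flow_ml_min Airflow in ml/min (> 0; the analyzer convention
#'   here is 200).
#' @param temp_c Ambient temperature in degrees C (0 gives `f_T = 1`).
#' @return Respiration rate(s) in ul CO2 g^-1 min^-1.
#' @export
respiration_rate <- function(co2_ppm_delta, mass_g, flow_ml_min = 200,
                             temp_c = 0) {
  if (any(mass_g <= 0)) stop("`mass_g` must be positive", call. = FALSE)
  if (any(flow_ml_min <= 0)) stop("`flow_ml_min` must be positive",
                                  call. = FALSE)
  f_t <- 273.15 / (273.15 + temp_c)
  flow_ml_min * 1000 * co2_ppm_delta * 1e-6 * f_t / mass_g
}

#' Within-subject respiration contrast between baseline and risk
#'
#' Paired mean difference (baseline - risk) in respiration rate with a
#' t-based confidence interval; for two conditions this is equivalent to
#' a repeated-measures ANOVA, with `F = t^2`. Individuals lacking either
#' condition are excluded with a warning.
#'
#' @param measures Data frame with columns `individual_id`, `context`
#'   (`"baseline"` / `"risk"`) and `rate`.
#' @param conf_level Confidence level (default 0.95).
#' @return List of class `risk_contrast`: `mean_diff`, `ci`, `t`, `df`,
#'   `p`, `F`, `n`.
#' @export
risk_contrast <- function(measures, conf_level = 0.95) {
  need <- c("individual_id", "context", "rate")
  if (!all(need %in% names(measures))) {
    stop("measures must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  wide <- stats::reshape(measures[, need], idvar = "individual_id",
                         timevar = "context", direction = "wide")
  ok <- stats::complete.cases(wide[, c("rate.baseline", "rate.risk")])
  if (any(!ok)) {
    warning(sum(!ok), " unpaired individual(s) excluded", call. = FALSE)
    wide <- wide[ok, ]
  }
  if (nrow(wide) < 2) stop("need >= 2 paired individuals", call. = FALSE)
  diffs <- wide$rate.baseline - wide$rate.risk
  if (stats::sd(diffs) == 0) {
    # degenerate: all differences identical; t test is undefined
    out <- list(mean_diff = mean(diffs), ci = c(mean(diffs), mean(diffs)),
                t = if (mean(diffs) == 0) 0 else Inf,
                df = nrow(wide) - 1,
                p = if (mean(diffs) == 0) 1 else 0,
                F = if (mean(diffs) == 0) 0 else Inf,
                n = nrow(wide))
    class(out) <- "risk_contrast"
    return(out)
  }
  tt <- stats::t.test(diffs, conf.level = conf_level)
  out <- list(mean_diff = unname(tt$estimate), ci = as.numeric(tt$conf.int),
              t = unname(tt$statistic), df = unname(tt$parameter),
              p = tt$p.value, F = unname(tt$statistic)^2, n = nrow(wide))
  class(out) <- "risk_contrast"
  out
}

#' @export
print.risk_contrast <- function(x, ...) {
  cat(sprintf("Paired baseline - risk contrast (n = %d):\n", x$n))
  cat(sprintf("  mean difference = %.3f  CI = [%.3f, %.3f]  t(%.1f) = %.3f  p = %.3g  (F = %.3f)\n",
              x$mean_diff, x$ci[1], x$ci[2], x$df, x$t, x$p, x$F))
  invisible(x)
}
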