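#' Per-minute Euclidean step distances of one assay trajectory
#'
#' A 15-minute assay records the occupied 1-cm grid cell once per
#' minute; activity is the Euclidean distance moved between consecutive
#' scans, giving 14 distances per assay.
#'
#' @param trajectory A data frame with columns `x`, `y` and (optionally)
#'   `minute` holding exactly 15 positions, or a 15 x 2 numeric matrix.
#' @return Numeric vector of 14 nonnegative distances (cm/min).
#' @export
step_distances <- function(trajectory) {
  if (is.data.frame(trajectory)) {
    if (!all(c("x", "y") %in% names(trajectory))) {
      stop("trajectory must have `x` and `y` columns", call. = FALSE)
    }
    if ("minute" %in% names(trajectory)) {
      trajectory <- trajectory[order(trajectory$minute), ]
    }
    m <- cbind(trajectory$x, trajectory$y)
  } else {
    m <- as.matrix(trajectory)
  }
  if (nrow(m) != 15) {
    stop("malformed trajectory: expected 15 positions, got ", nrow(m),
         call. = FALSE)
  }
  sqrt(diff(m[, 1])^2 + diff(m[, 2])^2)
}

#' Partition an assay's distances into three 4-minute blocks
#'
#' Drops the first two distances (extending the acclimation period to a
#' total of 4 minutes) and splits the remaining 12 into three
#' consecutive blocks of four: minutes 3-6, 7-10 and 11-14.
#'
#' @param distances Numeric vector of exactly 14 step distances.
#' @return A 3 x 4 numeric matrix; row `i` is block `i`.
#' @export
partition_assay <- function(distances) {
  if (length(distances) != 14) {
    stop("expected 14 distances, got ", length(distances), call. = FALSE)
  }
  matrix(distances[3:14], nrow = 3, byrow = TRUE,
         dimnames = list(paste0("block", 1:3), NULL))
}

#' Activity score of one assay
#'
#' The default score is the total path length (sum of the 14 per-minute
#' distances, cm); `method = "mean"` gives the per-minute average
#' instead.
#'
#' @param distances Numeric vector of 14 step distances.
#' @param method `"sum"` (default) or `"mean"`.
#' @return Single nonnegative activity score.
#' @export
assay_score <- function(distances, method = c("sum", "mean")) {
  method <- match.arg(method)
  if (length(distances) != 14) {
    stop("expected 14 distances, got ", length(distances), call. = FALSE)
  }
  if (method == "sum") sum(distances) else mean(distances)
}

#' Tabulate assay scores and 4-minute block activities
#'
#' Turns a long trajectory table (one row per individual x context x
#' minute) into per-assay activity scores and per-block activity sums.
#'
#' @param trajectories Data frame with columns `individual_id`,
#'   `context`, `minute`, `x`, `y` and optionally `assay_round`.
#' @param method Aggregation passed to [assay_score()].
#' @return A list with `scores` (individual_id, context, assay_round,
#'   assay_score) and `blocks` (individual_id, context, assay_round,
#'   block, activity), where block activity is the sum of its four
#'   distances.
#' @export
activity_table <- function(trajectories, method = c("sum", "mean")) {
  method <- match.arg(method)
  req <- c("individual_id", "context", "minute", "x", "y")
  if (!all(req %in% names(trajectories))) {
    stop("trajectories must have columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  if (!"assay_round" %in% names(trajectories)) trajectories$assay_round <- 1L
  key <- interaction(trajectories$individual_id, trajectories$context,
                     trajectories$assay_round, drop = TRUE)
  pieces <- split(trajectories, key)
  scores <- vector("list", length(pieces))
  blocks <- vector("list", length(pieces))
  for (i in seq_along(pieces)) {
    p <- pieces[[i]]
    d <- step_distances(p)
    bl <- partition_assay(d)
    scores[[i]] <- data.frame(individual_id = p$individual_id[1],
                              context = p$context[1],
                              assay_round = p$assay_round[1],
                              assay_score = assay_score(d, method))
    blocks[[i]] <- data.frame(individual_id = p$individual_id[1],
                              context = p$context[1],
                              assay_round = p$assay_round[1],
                              block = 1:3,
                              activity = rowSums(bl))
  }
  list(scores = do.call(rbind, c(scores, make.row.names = FALSE)),
       blocks = do.call(rbind, c(blocks, make.row.names = FALSE)))
}

#' Minute-level step distances in long format
#'
#' Expands a trajectory table into one row per per-minute movement, the
#' unit on which latent-scale repeatability of log step length is
#' defined. `log_floor_cm` keeps log distances finite when a step rounds
#' to the same grid cell (distance 0): such steps are treated as half
#' the 1-cm grid resolution.
#'
#' @inheritParams activity_table
#' @param trim Drop the first two distances of each assay (acclimation),
#'   default `TRUE`.
#' @param log_floor_cm Floor applied inside `log_distance` (default
#'   0.5 cm).
#' @return Data frame: `individual_id`, `context`, `assay_round`,
#'   `minute`, `distance`, `log_distance`.
#' @export
step_table <- function(trajectories, trim = TRUE, log_floor_cm = 0.5) {
  if (!"assay_round" %in% names(trajectories)) trajectories$assay_round <- 1L
  key <- interaction(trajectories$individual_id, trajectories$context,
                     trajectories$assay_round, drop = TRUE)
  rows <- lapply(split(trajectories, key), function(p) {
    d <- step_distances(p)
    keep <- if (trim) 3:14 else 1:14
    data.frame(individual_id = p$individual_id[1],
               context = p$context[1],
               assay_round = p$assay_round[1],
               minute = keep,
               distance = d[keep])
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out$log_distance <- log(pmax(out$distance, log_floor_cm))
  out
}

#' Personality trait values from assay scores
#'
#' The personality trait of an individual is the mean of its three
#' 15-minute assay scores (forage, explore, predator contexts).
#'
#' @param scores Data frame with `individual_id` and `assay_score`
#'   (e.g. the `scores` element of [activity_table()]).
#' @return Data frame with `individual_id` and `trait_value`.
#' @export
personality_scores <- function(scores) {
  agg <- stats::aggregate(assay_score ~ individual_id, data = scores,
                          FUN = mean)
  names(agg)[2] <- "trait_value"
  agg[order(agg$individual_id), , drop = FALSE]
}

#' Classify individuals into shy / intermediate / bold quartile groups
#'
#' Shy individuals fall strictly below the first quartile of the trait
#' distribution and bold individuals strictly above the third quartile
#' (quartiles by linear interpolation, quantile type 7); boundary ties
#' are classified intermediate.
#'
#' @param scores Data frame with `trait_value` (and usually
#'   `individual_id`), or a numeric vector of trait values.
#' @return The input with a `klass` factor column added (levels shy,
#'   intermediate, bold) and an attribute `quartiles = c(q1, q3)`. For
#'   numeric input, a data frame is returned.
#' @export
classify_quartiles <- function(scores) {
  if (is.numeric(scores)) scores <- data.frame(trait_value = scores)
  v <- scores$trait_value
  if (length(v) < 4) stop("need at least 4 individuals", call. = FALSE)
  q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
  klass <- ifelse(v < q[1], "shy", ifelse(v > q[2], "bold", "intermediate"))
  scores$klass <- factor(klass, levels = c("shy", "intermediate", "bold"))
  attr(scores, "quartiles") <- c(q1 = q[1], q3 = q[2])
  scores
}

#' Repeatability (intraclass correlation) from a random-intercept model
#'
#' Fits a mixed model with individual as random intercept and returns
#' the fraction of variance attributable to among-individual
#' differences, `R = s2_ind / (s2_ind + s2_res + s2_dist)`, with
#' parametric-bootstrap SE and percentile CI.
#'
#' For `distribution = "gaussian"` the response is modeled as-is (use
#' e.g. `log1p(activity)` for right-skewed activity) and `s2_dist = 0`.
#' For `distribution = "poisson"` the response must be counts (integer);
#' a log-link GLMM with an observation-level random effect models
#' overdispersion, and the latent-scale distribution variance is
#' `log(1/lambda + 1)` with `lambda = exp(b0 + (s2_ind + s2_olre)/2)`.
#' The observation-scale transformation of the Poisson repeatability is
#' reported alongside.
#'
#' @param data Long data frame: one row per observation.
#' @param value Name of the response column (default `"activity"`).
#' @param individual Name of the grouping column (default
#'   `"individual_id"`).
#' @param grouping Label recording the design the rows represent:
#'   `"within_assay"`, `"across_contexts"` or `"across_time"`.
#' @param n_boot Parametric bootstrap replicates (>= 1; the study's
#'   convention is 500). `n_boot = 0` skips the bootstrap.
#' @param distribution `"gaussian"` or `"poisson"`.
#' @param seed Integer; bootstrap replicate seeds are derived as
#'   `seed + replicate index`.
#' @return An object of class `repeatability_estimate`: fields `R`,
#'   `se`, `ci`, `n_boot`, `grouping`, `scale`, variance components,
#'   `R_original` (Poisson only), `singular` flag and the bootstrap
#'   draws.
#' @export
estimate_repeatability <- function(data,
                                   value = "activity",
                                   individual = "individual_id",
                                   grouping = c("across_contexts",
                                                "within_assay", "across_time"),
                                   n_boot = 500,
                                   distribution = c("gaussian", "poisson"),
                                   seed = 1L) {
  grouping <- match.arg(grouping)
  distribution <- match.arg(distribution)
  y <- data[[value]]
  id <- data[[individual]]
  if (is.null(y) || is.null(id)) {
    stop("columns `", value, "` and `", individual, "` are required",
         call. = FALSE)
  }
  if (length(unique(id)) < 2) stop("need >= 2 individuals", call. = FALSE)
  if (min(table(id)) < 2) stop("each individual needs >= 2 observations",
                               call. = FALSE)
  if (distribution == "poisson" && any(y != round(y))) {
    stop("poisson repeatability requires integer responses", call. = FALSE)
  }
  d <- data.frame(.y = y, .id = factor(id))
  fit <- .fit_rpt(d, distribution)
  est <- .rpt_from_fit(fit$model, distribution)

  boot_R <- numeric(0)
  se <- NA_real_
  ci <- c(NA_real_, NA_real_)
  if (n_boot >= 1) {
    boot_R <- vapply(seq_len(n_boot), function(b) {
      ysim <- stats::simulate(fit$model, nsim = 1, seed = seed + b)[[1]]
      db <- d
      db$.y <- ysim
      fb <- tryCatch(.fit_rpt(db, distribution),
                     error = function(e) NULL)
      if (is.null(fb)) return(NA_real_)
      .rpt_from_fit(fb$model, distribution)$R
    }, numeric(1))
    boot_R <- boot_R[is.finite(boot_R)]
    if (length(boot_R) >= 2) {
      se <- stats::sd(boot_R)
      ci <- unname(stats::quantile(boot_R, c(0.025, 0.975)))
    }
  }
  out <- list(R = est$R, se = se, ci = ci, n_boot = n_boot,
              grouping = grouping,
              scale = if (distribution == "gaussian") "original" else "latent",
              distribution = distribution,
              var_individual = est$var_individual,
              var_residual = est$var_residual,
              var_distribution = est$var_distribution,
              R_original = est$R_original,
              singular = fit$singular,
              boot_R = boot_R)
  class(out) <- "repeatability_estimate"
  out
}

.fit_rpt <- function(d, distribution) {
  if (distribution == "gaussian") {
    m <- suppressMessages(suppressWarnings(
      lme4::lmer(.y ~ 1 + (1 | .id), data = d, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             calc.derivs = FALSE))))
  } else {
    d$.obs <- factor(seq_len(nrow(d)))
    m <- suppressMessages(suppressWarnings(
      lme4::glmer(.y ~ 1 + (1 | .id) + (1 | .obs), data = d,
                  family = stats::poisson(link = "log"),
                  control = lme4::glmerControl(
                    check.conv.singular = "ignore"))))
  }
  list(model = m, singular = lme4::isSingular(m))
}

.rpt_from_fit <- function(m, distribution) {
  vc <- lme4::VarCorr(m)
  s2_id <- as.numeric(vc$.id)
  if (distribution == "gaussian") {
    s2_res <- attr(vc, "sc")^2
    R <- if (s2_id + s2_res <= 0) 0 else s2_id / (s2_id + s2_res)
    list(R = R, var_individual = s2_id, var_residual = s2_res,
         var_distribution = 0, R_original = R)
  } else {
    s2_olre <- as.numeric(vc$.obs)
    beta0 <- unname(lme4::fixef(m)[1])
    lambda <- exp(beta0 + (s2_id + s2_olre) / 2)
    s2_dist <- log(1 / lambda + 1)
    denom <- s2_id + s2_olre + s2_dist
    R <- if (denom <= 0) 0 else s2_id / denom
    # observation-scale transformation for log-link Poisson
    R_orig <- lambda * (exp(s2_id) - 1) /
      (lambda * (exp(s2_id + s2_olre) - 1) + 1)
    list(R = R, var_individual = s2_id, var_residual = s2_olre,
         var_distribution = s2_dist, R_original = R_orig)
  }
}

#' @export
print.repeatability_estimate <- function(x, ...) {
  cat("Repeatability (", x$grouping, ", ", x$distribution, ")\n", sep = "")
  cat(sprintf("  R = %.3f", x$R))
  if (is.finite(x$se)) {
    cat(sprintf("  SE = %.3f  CI95 = [%.3f, %.3f]  (%d bootstrap reps)",
                x$se, x$ci[1], x$ci[2], x$n_boot))
  }
  cat("\n")
  if (x$singular) cat("  note: variance components at boundary (singular fit)\n")
  invisible(x)
}

#' Lifetime repeatability across repeated assay rounds
#'
#' Estimates repeatability across assay rounds (time as context),
#' including only individuals observed in at least two rounds.
#'
#' @param blocks Long block-activity table with columns
#'   `individual_id`, `assay_round` and the response column.
#' @param value Response column name (default `"activity"`).
#' @param ... Passed to [estimate_repeatability()].
#' @return A `repeatability_estimate` with `grouping = "across_time"`.
#' @export
lifetime_repeatability <- function(blocks, value = "activity", ...) {
  rounds <- tapply(blocks$assay_round, blocks$individual_id,
                   function(r) length(unique(r)))
  keep <- names(rounds)[rounds >= 2]
  if (!length(keep)) {
    stop("no individuals with >= 2 assay rounds", call. = FALSE)
  }
  estimate_repeatability(blocks[blocks$individual_id %in% keep, ],
                         value = value, grouping = "across_time", ...)
}
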