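#' Coefficient of relative plasticity
#'
#' `CRP_i = V_i / V_p`: an individual's behavioral variance relative to
#' the variance of its population, a standardized index of intraspecific
#' behavioral variation.
#'
#' @param v_i Nonnegative individual variance(s) (sample variance of the
#'   individual's assay scores).
#' @param v_p Positive population variance (sample variance of trait
#'   values across the population's individuals).
#' @return `v_i / v_p`, vectorized over `v_i`.
#' @export
crp <- function(v_i, v_p) {
  if (!is.numeric(v_p) || length(v_p) != 1 || v_p <= 0) {
    stop("undefined CRP: `v_p` must be a single positive variance",
         call. = FALSE)
  }
  if (any(v_i < 0)) stop("`v_i` must be nonnegative", call. = FALSE)
  v_i / v_p
}

#' Per-individual CRP records for one population
#'
#' `V_i` is the sample variance (n-1 denominator) of an individual's
#' assay scores; `V_p` is the sample variance of trait values (mean
#' score per individual) across the population.
#'
#' @param scores Data frame with `individual_id` and `assay_score`, one
#'   row per assay.
#' @return Data frame with `individual_id`, `v_i`, `v_p`, `crp`.
#' @export
crp_records <- function(scores) {
  if (!all(c("individual_id", "assay_score") %in% names(scores))) {
    stop("`scores` must have individual_id and assay_score", call. = FALSE)
  }
  v_i <- tapply(scores$assay_score, scores$individual_id, stats::var)
  traits <- tapply(scores$assay_score, scores$individual_id, mean)
  v_p <- stats::var(as.numeric(traits))
  data.frame(individual_id = names(v_i),
             v_i = as.numeric(v_i),
             v_p = v_p,
             crp = crp(as.numeric(v_i), v_p),
             row.names = NULL)
}

#' Population summary: mean personality and CRP variance
#'
#' Summarizes one mesocosm population in one phase by (a) the mean
#' personality trait value and (b) the sample variance of the
#' individuals' coefficients of relative plasticity, which represents
#' the range of behavioral plasticity within the population.
#'
#' @param scores Assay scores for the population (columns
#'   `individual_id`, `assay_score`; >= 2 assays per individual).
#' @param mesocosm_id Identifier of the mesocosm population.
#' @param phase `"pre"` (stocking) or `"post"` (harvest).
#' @return An object of class `population_summary` with `mesocosm_id`,
#'   `phase`, `mean_personality`, `crp_variance`, `n` and `extinct`.
#'   An empty `scores` table returns an extinct-flagged summary with NA
#'   metrics.
#' @export
population_summary <- function(scores, mesocosm_id, phase = c("pre", "post")) {
  phase <- match.arg(phase)
  if (is.null(scores) || !nrow(scores)) {
    out <- list(mesocosm_id = mesocosm_id, phase = phase,
                mean_personality = NA_real_, crp_variance = NA_real_,
                n = 0L, extinct = TRUE)
    class(out) <- "population_summary"
    return(out)
  }
  per_ind <- table(scores$individual_id)
  if (min(per_ind) < 2) {
    stop("each individual needs >= 2 assay scores", call. = FALSE)
  }
  rec <- crp_records(scores)
  traits <- tapply(scores$assay_score, scores$individual_id, mean)
  out <- list(mesocosm_id = mesocosm_id, phase = phase,
              mean_personality = mean(as.numeric(traits)),
              crp_variance = if (nrow(rec) > 1) stats::var(rec$crp) else 0,
              n = nrow(rec), extinct = FALSE)
  class(out) <- "population_summary"
  out
}

#' @export
print.population_summary <- function(x, ...) {
  if (x$extinct) {
    cat("Population", x$mesocosm_id, "(", x$phase, "): extinct\n")
  } else {
    cat(sprintf("Population %s (%s): n = %d, mean personality = %.2f, CRP variance = %.3f\n",
                x$mesocosm_id, x$phase, x$n, x$mean_personality,
                x$crp_variance))
  }
  invisible(x)
}

#' Pre-to-post change in population personality metrics
#'
#' @param pre,post `population_summary` objects for the same mesocosm,
#'   phases `"pre"` and `"post"`.
#' @return Named numeric: `d_mean_personality` and `d_crp_variance`
#'   (post minus pre).
#' @export
change_scores <- function(pre, post) {
  stopifnot(inherits(pre, "population_summary"),
            inherits(post, "population_summary"))
  if (!identical(pre$mesocosm_id, post$mesocosm_id)) {
    stop("mismatched mesocosm ids: ", pre$mesocosm_id, " vs ",
         post$mesocosm_id, call. = FALSE)
  }
  if (!(pre$phase == "pre" && post$phase == "post")) {
    stop("arguments must be the pre and post summaries, in that order",
         call. = FALSE)
  }
  c(d_mean_personality = post$mean_personality - pre$mean_personality,
    d_crp_variance = post$crp_variance - pre$crp_variance)
}
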