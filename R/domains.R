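#' Bin vertical heights into a utilization distribution histogram
#'
#' Counts observations in lower-inclusive, half-open 5-cm height bins
#' `[k*w, (k+1)*w)` from the ground and converts them to relative
#' frequencies `p_i` (count per bin / total observations).
#'
#' @param obs Numeric heights (cm), or a data frame with a `height_cm`
#'   column.
#' @param bin_width Bin width in cm (default 5).
#' @param canopy_max Canopy ceiling in cm; bins cover `[0, canopy_max]`
#'   (a height exactly at the ceiling falls in the top bin). Default 88.
#' @return An object of class `utilization_distribution` with fields
#'   `bin_edges`, `counts`, `p`, `n_obs`; KDE fields are `NULL` until
#'   [kde_ud()] is used.
#' @export
bin_heights <- function(obs, bin_width = 5, canopy_max = 88) {
  h <- if (is.data.frame(obs)) obs$height_cm else obs
  if (!length(h)) stop("no observations to bin", call. = FALSE)
  if (any(h < 0 | h > canopy_max)) {
    stop("heights outside [0, canopy_max]", call. = FALSE)
  }
  n_bins <- ceiling(canopy_max / bin_width)
  edges <- seq(0, n_bins * bin_width, by = bin_width)
  idx <- pmin(floor(h / bin_width) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  ud <- list(bin_edges = edges, counts = counts, p = counts / sum(counts),
             n_obs = length(h), canopy_max = canopy_max,
             kde_bandwidth = NULL, grid = NULL, density = NULL)
  class(ud) <- "utilization_distribution"
  ud
}

#' Kernel-density utilization distribution with boundary reflection
#'
#' Builds the full utilization distribution: the 5-cm histogram part
#' (via [bin_heights()]) plus a Gaussian kernel density evaluated on a
#' 1-cm grid over `[0, canopy_max]`, boundary-corrected by reflecting
#' the data at 0 and at the canopy ceiling and renormalized to integrate
#' to 1.
#'
#' @inheritParams bin_heights
#' @param bandwidth Kernel bandwidth in cm, or `"auto"` for Silverman's
#'   rule of thumb ([stats::bw.nrd0()]). Zero-variance data under
#'   `"auto"` fall back to a 1-cm minimum bandwidth with a warning.
#' @param grid_step Evaluation grid spacing in cm (default 1).
#' @return A `utilization_distribution` with `grid`, `density` and
#'   `kde_bandwidth` filled in.
#' @export
kde_ud <- function(obs, bandwidth = "auto", bin_width = 5, canopy_max = 88,
                   grid_step = 1) {
  h <- if (is.data.frame(obs)) obs$height_cm else obs
  if (length(h) < 2) stop("need >= 2 observations for a KDE", call. = FALSE)
  ud <- bin_heights(h, bin_width = bin_width, canopy_max = canopy_max)
  if (identical(bandwidth, "auto")) {
    bw <- if (stats::sd(h) == 0) {
      warning("zero-variance data: falling back to 1 cm bandwidth",
              call. = FALSE)
      1
    } else {
      max(stats::bw.nrd0(h), 1e-8)
    }
  } else {
    bw <- bandwidth
    if (!is.numeric(bw) || bw <= 0) stop("bandwidth must be > 0", call. = FALSE)
  }
  grid <- seq(0, canopy_max, by = grid_step)
  # reflect at both boundaries so mass does not leak outside the canopy
  refl <- c(h, -h, 2 * canopy_max - h)
  dens <- vapply(grid, function(g) mean(stats::dnorm(g, refl, bw)) * 3,
                 numeric(1))
  total <- .trapz(grid, dens)
  dens <- dens / total
  ud$kde_bandwidth <- bw
  ud$grid <- grid
  ud$density <- dens
  ud
}

.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' @export
print.utilization_distribution <- function(x, ...) {
  cat("Utilization distribution: ", x$n_obs, " observations, ",
      sum(x$counts > 0), " occupied ", diff(x$bin_edges)[1],
      "-cm bins\n", sep = "")
  if (!is.null(x$density)) {
    cat("  KDE bandwidth ", round(x$kde_bandwidth, 2), " cm on [0, ",
        x$canopy_max, "] cm\n", sep = "")
  }
  invisible(x)
}

#' Highest-density isopleth of a utilization distribution
#'
#' Finds the smallest region containing at least `level` of the UD's
#' probability mass (50% = core utilization, 95% = broad utilization):
#' grid cells (or histogram bins, if no KDE is present) are added in
#' decreasing density order until the enclosed mass reaches `level`,
#' then merged into height intervals.
#'
#' @param ud A `utilization_distribution`.
#' @param level Fraction in (0, 1).
#' @return An object of class `isopleth_region`: `level`, `intervals`
#'   (two-column matrix of `[lo, hi]` cm), `mass` actually enclosed,
#'   and the indices of the retained cells.
#' @export
isopleth <- function(ud, level) {
  stopifnot(inherits(ud, "utilization_distribution"))
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    stop("`level` must be in (0, 1)", call. = FALSE)
  }
  if (!is.null(ud$density)) {
    step <- diff(ud$grid)[1]
    mass <- ud$density * step
    mass <- mass / sum(mass)
    centers <- ud$grid
    half <- step / 2
  } else {
    mass <- ud$p
    w <- diff(ud$bin_edges)[1]
    centers <- ud$bin_edges[-length(ud$bin_edges)] + w / 2
    half <- w / 2
  }
  ord <- order(mass, decreasing = TRUE)
  cum <- cumsum(mass[ord])
  k <- which(cum >= level)[1]
  keep <- sort(ord[seq_len(k)])
  lo <- pmax(centers[keep] - half, 0)
  hi <- pmin(centers[keep] + half, ud$canopy_max)
  # merge contiguous cells
  breaks <- which(lo[-1] > hi[-length(hi)] + 1e-9)
  starts <- c(1, breaks + 1)
  ends <- c(breaks, length(keep))
  intervals <- cbind(lo = lo[starts], hi = hi[ends])
  out <- list(level = level, intervals = intervals,
              mass = sum(mass[keep]), cells = keep)
  class(out) <- "isopleth_region"
  out
}

#' @export
print.isopleth_region <- function(x, ...) {
  cat(sprintf("%.0f%% isopleth (mass enclosed %.3f):\n", 100 * x$level,
              x$mass))
  apply(x$intervals, 1, function(r) {
    cat(sprintf("  [%.1f, %.1f] cm\n", r[1], r[2]))
  })
  invisible(x)
}

# bins (edges) intersecting a set of intervals with positive overlap
.bins_in_region <- function(bin_edges, intervals) {
  lo <- bin_edges[-length(bin_edges)]
  hi <- bin_edges[-1]
  hit <- rep(FALSE, length(lo))
  for (r in seq_len(nrow(intervals))) {
    ov <- pmin(hi, intervals[r, 2]) - pmax(lo, intervals[r, 1])
    hit <- hit | ov > 1e-9
  }
  which(hit)
}

#' Bhattacharyya affinity between two utilization distributions
#'
#' Computes `BA = sum_i sqrt(p_i q_i)` over the 5-cm height bins: 1 for
#' identical distributions, 0 for disjoint ones. With a numeric
#' `level`, each UD is first restricted to the bins intersecting its own
#' highest-density isopleth at that level (KDE-based when a density is
#' present, histogram-based otherwise) and renormalized; the sum then
#' runs over the union of retained bins.
#'
#' @param ud_a,ud_b `utilization_distribution` objects on identical bin
#'   edges.
#' @param level `"full"` (all bins) or a fraction in (0, 1), e.g. 0.5
#'   for core-utilization overlap.
#' @param radical If `FALSE`, computes the plain cross-product sum
#'   `sum_i p_i q_i` instead of the standard affinity (documented
#'   variant; not an overlap index bounded by 1 in the same way).
#' @return A single value in `[0, 1]` (for `radical = TRUE`).
#' @export
bhattacharyya <- function(ud_a, ud_b, level = "full", radical = TRUE) {
  stopifnot(inherits(ud_a, "utilization_distribution"),
            inherits(ud_b, "utilization_distribution"))
  if (!isTRUE(all.equal(ud_a$bin_edges, ud_b$bin_edges))) {
    stop("utilization distributions are on different bin edges",
         call. = FALSE)
  }
  p <- ud_a$p
  q <- ud_b$p
  if (!identical(level, "full")) {
    ra <- isopleth(ud_a, level)
    rb <- isopleth(ud_b, level)
    keep_a <- .bins_in_region(ud_a$bin_edges, ra$intervals)
    keep_b <- .bins_in_region(ud_b$bin_edges, rb$intervals)
    p2 <- q2 <- numeric(length(p))
    p2[keep_a] <- p[keep_a] / sum(p[keep_a])
    q2[keep_b] <- q[keep_b] / sum(q[keep_b])
    p <- p2
    q <- q2
  }
  if (radical) sum(sqrt(p * q)) else sum(p * q)
}

#' Chi-square test of independence between two binned height profiles
#'
#' Pearson chi-square on the 2 x k table of height-bin counts for two
#' groups; bins with zero total count are dropped first. Optionally,
#' adjacent bins are pooled until all expected counts reach 5.
#'
#' @param counts_a,counts_b Integer count vectors on the same bins.
#' @param pool_sparse Pool adjacent bins with expected counts < 5
#'   (default `FALSE`).
#' @return A list of class `overlap_chisq`: `chi2`, `df`, `p`,
#'   `observed`, `expected`.
#' @export
domain_chi2 <- function(counts_a, counts_b, pool_sparse = FALSE) {
  if (length(counts_a) != length(counts_b)) {
    stop("count vectors differ in length", call. = FALSE)
  }
  O <- rbind(a = counts_a, b = counts_b)
  O <- O[, colSums(O) > 0, drop = FALSE]
  if (!ncol(O)) stop("all counts are zero", call. = FALSE)
  if (pool_sparse) O <- .pool_sparse(O)
  if (ncol(O) < 2) stop("need >= 2 non-empty bins", call. = FALSE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  chi2 <- sum((O - E)^2 / E)
  df <- ncol(O) - 1
  out <- list(chi2 = chi2, df = df,
              p = stats::pchisq(chi2, df, lower.tail = FALSE),
              observed = O, expected = E)
  class(out) <- "overlap_chisq"
  out
}

.pool_sparse <- function(O) {
  repeat {
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    bad <- which(apply(E, 2, min) < 5)
    if (!length(bad) || ncol(O) <= 2) return(O)
    j <- bad[1]
    nb <- if (j == ncol(O)) j - 1 else j + 1
    O[, nb] <- O[, nb] + O[, j]
    O <- O[, -j, drop = FALSE]
  }
}

#' @export
print.overlap_chisq <- function(x, ...) {
  cat(sprintf("Chi-square independence: X2 = %.2f, df = %d, p = %.3g\n",
              x$chi2, x$df, x$p))
  invisible(x)
}

#' Habitat-domain report for shy vs bold personality types
#'
#' Reproduces the standard comparison set for vertical habitat domains:
#' utilization distributions per personality type (and per predation
#' context), 50%/95% isopleths, and shy-vs-bold overlap via
#' Bhattacharyya affinity plus a chi-square contrast on core-utilization
#' bin counts, for (1) the full extent (95% isopleth, contexts pooled),
#' (2) core utilization (50%, pooled), (3) core utilization in the
#' predator context, and (4) core utilization on Solidago substrate.
#'
#' @param obs Height-observation data frame (see
#'   [gen_height_observations()] for the columns).
#' @param bandwidth,bin_width,canopy_max Passed to [kde_ud()].
#' @return An object of class `domain_report`: `uds` (per personality x
#'   context), `isopleths`, and `overlaps` (data frame with comparison,
#'   level, ba, chi2, df, p). Missing groups produce a partial report
#'   with a warning.
#' @export
domain_report <- function(obs, bandwidth = "auto", bin_width = 5,
                          canopy_max = 88) {
  need <- c("personality", "context", "height_cm", "substrate")
  if (!all(need %in% names(obs))) {
    stop("observations must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  mk_ud <- function(d) {
    if (nrow(d) < 2) return(NULL)
    kde_ud(d$height_cm, bandwidth = bandwidth, bin_width = bin_width,
           canopy_max = canopy_max)
  }
  types <- c("shy", "bold")
  uds <- list()
  for (ty in types) {
    uds[[ty]] <- mk_ud(obs[obs$personality == ty, ])
    for (cx in unique(obs$context)) {
      uds[[paste(ty, cx, sep = ".")]] <-
        mk_ud(obs[obs$personality == ty & obs$context == cx, ])
    }
    uds[[paste(ty, "solidago", sep = ".")]] <-
      mk_ud(obs[obs$personality == ty & obs$substrate == "solidago", ])
  }
  isopleths <- lapply(uds, function(u) {
    if (is.null(u)) NULL else list(core = isopleth(u, 0.5),
                                   broad = isopleth(u, 0.95))
  })
  cmp <- function(label, a, b, level) {
    if (is.null(a) || is.null(b)) {
      warning("missing group for comparison: ", label, call. = FALSE)
      return(NULL)
    }
    ba <- bhattacharyya(a, b, level = level)
    bins <- union(.bins_in_region(a$bin_edges, isopleth(a, level)$intervals),
                  .bins_in_region(b$bin_edges, isopleth(b, level)$intervals))
    chi <- tryCatch(domain_chi2(a$counts[bins], b$counts[bins]),
                    error = function(e) list(chi2 = NA, df = NA, p = NA))
    data.frame(comparison = label, level = level, ba = ba,
               chi2 = chi$chi2, df = chi$df, p = chi$p)
  }
  overlaps <- rbind(
    cmp("full_extent", uds$shy, uds$bold, 0.95),
    cmp("core", uds$shy, uds$bold, 0.5),
    cmp("core_predator", uds$shy.predator, uds$bold.predator, 0.5),
    cmp("core_solidago", uds$shy.solidago, uds$bold.solidago, 0.5))
  if (is.null(overlaps)) {
    overlaps <- data.frame(comparison = character(0), level = numeric(0),
                           ba = numeric(0), chi2 = numeric(0),
                           df = numeric(0), p = numeric(0))
  }
  out <- list(uds = uds, isopleths = isopleths, overlaps = overlaps)
  class(out) <- "domain_report"
  out
}

#' @export
print.domain_report <- function(x, ...) {
  cat("Habitat-domain overlap (shy vs bold):\n")
  print(x$overlaps, row.names = FALSE, digits = 3)
  invisible(x)
}
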