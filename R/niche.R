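# PCA-env niche-space analysis: gridded, kernel-smoothed occupancy in the
# plane of the first two principal components of the pooled environmental
# availability, corrected for that availability, compared by Schoener's D.

#' Fit the two-axis environmental space (PCA-env)
#'
#' Variables are standardized to zero mean / unit sd over the pooled valid
#' cells of all periods and the first two principal axes retained. Sign
#' convention: the largest-magnitude loading on each axis is positive.
#'
#' @param stacks List of [env_stack()] (all periods).
#' @param vars Variables entering the PCA (default: all eight layers).
#' @return Object of class `env_space`: `loadings` (p x 2), `explained`
#'   (variance fractions), `center`, `scale`.
#' @export
fit_env_space <- function(stacks, vars = names(stacks[[1]]$layers)) {
  if (length(vars) < 2) stop("need at least 2 variables")
  pooled <- do.call(rbind, lapply(stacks, function(s)
    extract_env(s, cells = which(s$mask), vars = vars)))
  sds <- apply(pooled, 2, stats::sd)
  if (any(sds == 0))
    stop("constant variable(s) must be dropped first: ",
         paste(vars[sds == 0], collapse = ", "))
  pc <- stats::prcomp(pooled, center = TRUE, scale. = TRUE)
  load <- pc$rotation[, 1:2, drop = FALSE]
  for (j in 1:2) if (load[which.max(abs(load[, j])), j] < 0)
    load[, j] <- -load[, j]
  ev <- pc$sdev^2
  structure(list(loadings = load, explained = (ev / sum(ev))[1:2],
                 eigenvalues = ev[1:2],
                 center = pc$center, scale = pc$scale, vars = vars),
            class = "env_space")
}

#' @rdname fit_env_space
#' @param space An `env_space`.
#' @param values Matrix of raw variable values (columns = `space$vars`).
#' @return `project_env()`: n x 2 matrix of axis scores.
#' @export
project_env <- function(space, values) {
  Z <- scale(values[, space$vars, drop = FALSE], space$center, space$scale)
  Z %*% space$loadings
}

#' Kernel-smoothed density on the environmental grid
#'
#' Gaussian kernel density of axis scores on an `R x R` lattice spanning
#' `bounds`, bandwidth per axis by the normal-reference rule, normalized to
#' sum 1.
#'
#' @param scores n x 2 matrix of axis scores (n >= 1).
#' @param bounds List `x = c(min, max)`, `y = c(min, max)`; typically the
#'   pooled availability extent.
#' @param R Grid resolution (default 100).
#' @return `R x R` matrix summing to 1, with attributes `xgrid`, `ygrid`.
#' @export
density_surface <- function(scores, bounds, R = 100) {
  if (is.null(dim(scores))) scores <- matrix(scores, ncol = 2)
  n <- nrow(scores)
  if (n == 0) stop("zero points: cannot build a density surface")
  bw <- function(v, lim) {
    h <- if (n > 1) MASS::bandwidth.nrd(v) else 0
    if (!is.finite(h) || h <= 0) h <- diff(lim) / 25  # degenerate spread
    h
  }
  d <- MASS::kde2d(scores[, 1], scores[, 2], n = R,
                   h = c(bw(scores[, 1], bounds$x), bw(scores[, 2], bounds$y)),
                   lims = c(bounds$x, bounds$y))
  z <- d$z / sum(d$z)
  attr(z, "xgrid") <- d$x; attr(z, "ygrid") <- d$y
  z
}

#' Availability-corrected occupancy
#'
#' `z_raw = z_occ / z_env` wherever availability exceeds a machine-safe
#' floor, 0 elsewhere; renormalized to sum 1. Occurrence density falling
#' where availability is zero is discarded (with a warning).
#'
#' @param z_occ Occurrence density grid (sums to 1).
#' @param z_env Availability density grid (sums to 1, same shape).
#' @param eps Availability floor relative to `max(z_env)`.
#' @return Occupancy grid summing to 1.
#' @export
occupancy <- function(z_occ, z_env, eps = 1e-12) {
  if (!identical(dim(z_occ), dim(z_env))) stop("grids differ in shape")
  floor_ <- eps * max(z_env)
  z_raw <- ifelse(z_env > floor_, z_occ / z_env, 0)
  lost <- sum(z_occ[z_env <= floor_])
  if (lost > 1e-3)
    warning(sprintf("%.2g of occurrence density falls outside available environmental space", lost))
  s <- sum(z_raw)
  if (s == 0) stop("occurrences lie entirely outside the available environmental space")
  z_raw / s
}

#' Schoener's D niche overlap
#'
#' `D = 1 - 0.5 * sum(|z1 - z2|)` between two normalized occupancy
#' surfaces; 0 = disjoint, 1 = identical.
#'
#' @param z1,z2 Grids of the same shape, each summing to 1 (tolerance 1e-6).
#' @return Scalar in \[0, 1\].
#' @export
schoeners_d <- function(z1, z2) {
  if (!identical(dim(z1), dim(z2))) stop("grids differ in shape")
  if (abs(sum(z1) - 1) > 1e-6 || abs(sum(z2) - 1) > 1e-6)
    stop("inputs must each be normalized to sum 1")
  max(0, min(1, 1 - 0.5 * sum(abs(z1 - z2))))
}

#' Partial-niche vs total-niche subsample test
#'
#' Compares one period's occupancy against the total (all-period) occupancy
#' by Schoener's D, against a null of `B` random subsamples of the pooled
#' occurrences of the period's sample size. The p-value is one-tailed with
#' the add-one convention: `p = (1 + #{null_d <= d_obs}) / (B + 1)` — small
#' when the period's niche is less similar to the total niche than a random
#' subsample of equal size would be.
#'
#' @param pool_scores Axis scores of all pooled occurrences.
#' @param period_scores Axis scores of the period's occurrences
#'   (`nrow <= nrow(pool_scores)`).
#' @param z_env Availability surface used for the occupancy correction
#'   (pooled availability).
#' @param bounds,R As in [density_surface()].
#' @param B Number of null subsamples (default 100).
#' @param seed RNG seed.
#' @param z_env_period Availability surface for the period's own occupancy
#'   (defaults to `z_env`).
#' @return Object of class `overlap_test`: `d_obs`, `null_d`, `p_value`.
#' @export
partial_vs_total_test <- function(pool_scores, period_scores, z_env, bounds,
                                  R = 100, B = 100, seed = 1,
                                  z_env_period = z_env) {
  n <- nrow(period_scores)
  if (n == 0) stop("period has no occurrences")
  if (n > nrow(pool_scores)) stop("period sample larger than the pool")
  z_total <- occupancy(density_surface(pool_scores, bounds, R), z_env)
  z_period <- occupancy(density_surface(period_scores, bounds, R), z_env_period)
  d_obs <- schoeners_d(z_period, z_total)
  null_d <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample(nrow(pool_scores), n)
      z_b <- occupancy(density_surface(pool_scores[idx, , drop = FALSE],
                                       bounds, R), z_env)
      schoeners_d(z_b, z_total)
    }, numeric(1))
  })
  structure(list(d_obs = d_obs, null_d = null_d,
                 p_value = (1 + sum(null_d <= d_obs)) / (B + 1)),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("<overlap_test> D = %.3f, p = %.2f (B = %d)\n",
              x$d_obs, x$p_value, length(x$null_d)))
  invisible(x)
}

#' Niche-change analysis over all periods of a scenario
#'
#' Fits the PCA-env space on pooled availability, builds per-period and
#' total occupancy surfaces, and runs the subsample test for every period.
#'
#' @param stacks List of per-period [env_stack()].
#' @param occurrences Data frame `period, x, y` over all periods.
#' @param vars PCA variables (default all eight).
#' @param R,B,seed As in [partial_vs_total_test()].
#' @return List `space`, `bounds`, `tests` (named per period), `summary`
#'   (data frame `period, n, d_obs, p_value`).
#' @export
niche_change_analysis <- function(stacks, occurrences,
                                  vars = names(stacks[[1]]$layers),
                                  R = 100, B = 100, seed = 1) {
  space <- fit_env_space(stacks, vars)
  avail <- do.call(rbind, lapply(stacks, function(s)
    project_env(space, extract_env(s, cells = which(s$mask), vars = vars))))
  bounds <- list(x = range(avail[, 1]), y = range(avail[, 2]))
  z_env <- density_surface(avail, bounds, R)

  periods <- vapply(stacks, `[[`, character(1), "period")
  occ_scores <- lapply(seq_along(stacks), function(t) {
    o <- occurrences[occurrences$period == periods[t], , drop = FALSE]
    project_env(space, extract_env(stacks[[t]], xy = cbind(o$x, o$y), vars = vars))
  })
  pool <- do.call(rbind, occ_scores)

  z_env_period <- lapply(stacks, function(s)
    density_surface(project_env(space,
      extract_env(s, cells = which(s$mask), vars = vars)), bounds, R))

  tests <- lapply(seq_along(stacks), function(t)
    partial_vs_total_test(pool, occ_scores[[t]], z_env, bounds, R = R, B = B,
                          seed = sub_seed(seed, 200 + t),
                          z_env_period = z_env_period[[t]]))
  names(tests) <- periods
  list(space = space, bounds = bounds, tests = tests,
       summary = data.frame(
         period = periods,
         n = vapply(occ_scores, nrow, integer(1)),
         d_obs = vapply(tests, function(x) x$d_obs, numeric(1)),
         p_value = vapply(tests, function(x) x$p_value, numeric(1))))
}
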