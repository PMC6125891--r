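# Synthetic multi-period landscapes with a known ground-truth contraction.
# Every generator is a pure function of (config, seed): RNG state is saved
# and restored around each draw.

with_seed <- function(seed, code) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# deterministic sub-stream seed, kept inside 32-bit integer range
sub_seed <- function(seed, tag) {
  as.integer((as.numeric(seed) %% 1e6 * 2039 + tag * 7919 + 13) %% 2147483646 + 1)
}

# smooth spatial field: 3-6 low-frequency sinusoids + white Gaussian noise,
# returned on [0, 1]
smooth_field <- function(spec, seed, n_waves = 5, noise_sd = 0.04) {
  with_seed(seed, {
    xs <- (seq_len(spec$n_cols) - 0.5) / spec$n_cols
    ys <- (seq_len(spec$n_rows) - 0.5) / spec$n_rows
    f <- matrix(0, spec$n_rows, spec$n_cols)
    for (h in seq_len(n_waves)) {
      fx <- stats::runif(1, 0.5, 2.5)
      fy <- stats::runif(1, 0.5, 2.5)
      ph <- stats::runif(1, 0, 2 * pi)
      amp <- stats::runif(1, 0.4, 1)
      f <- f + amp * sin(2 * pi * outer(ys * fy, xs * fx, `+`) + ph)
    }
    f <- f + stats::rnorm(length(f), sd = noise_sd * n_waves)
    (f - min(f)) / (max(f) - min(f))
  })
}

#' Ground-truth niche for the synthetic species
#'
#' Suitability is a product of Gaussian responses to elevation and mean
#' annual temperature and an exponential penalty on urban cover whose
#' strength `human_beta` grows over periods — the synthetic analogue of
#' intensifying anthropogenic pressure driving contraction and an upslope
#' shift.
#'
#' @param elev_opt,elev_sd Elevation optimum and breadth (m).
#' @param mat_opt,mat_sd Temperature optimum and breadth (deg C).
#' @param human_beta Non-negative, non-decreasing per-period sensitivity to
#'   urban cover.
#' @return Object of class `true_niche`.
#' @export
true_niche <- function(elev_opt = 600, elev_sd = 300,
                       mat_opt = 18, mat_sd = 5,
                       human_beta = c(0.5, 1.5, 3, 6)) {
  stopifnot(elev_sd > 0, mat_sd > 0, all(human_beta >= 0),
            !is.unsorted(human_beta))
  structure(list(elev_opt = elev_opt, elev_sd = elev_sd,
                 mat_opt = mat_opt, mat_sd = mat_sd,
                 human_beta = human_beta),
            class = "true_niche")
}

#' Scenario configuration for the synthetic study
#'
#' Defaults mirror the study conditions of the motivating analysis: four
#' decadal periods, per-period occurrence counts 714/561/322/117, 1 km
#' cells. The default 100 x 100 grid (10^4 km^2) is large enough to fit the
#' ensemble models yet small enough for the exact zonation ranking.
#' Range decline is not imposed on the counts; it emerges from the growing
#' urban field and the niche's non-decreasing `human_beta`
#' (scaled by `contraction_strength`; 0 switches the pressure off).
#'
#' @param n_rows,n_cols,cell_size,origin Grid geometry, see [grid_spec()].
#' @param periods Ordered period labels.
#' @param occurrences_per_period Occurrence counts, one per period.
#' @param seed Scenario RNG seed.
#' @param road_count Number of synthetic roads.
#' @param contraction_strength Multiplier (>= 0) on the niche's `human_beta`.
#' @param climate_trend Warming per period step (deg C) applied to MAT.
#' @param niche A [true_niche()].
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(n_rows = 100, n_cols = 100, cell_size = 1,
                            origin = c(0, 0),
                            periods = c("1970s", "1980s", "1990s", "2000s"),
                            occurrences_per_period = c(714, 561, 322, 117),
                            seed = 1, road_count = 6,
                            contraction_strength = 1,
                            climate_trend = 0.2,
                            niche = true_niche()) {
  stopifnot(length(occurrences_per_period) == length(periods),
            all(occurrences_per_period > 0),
            contraction_strength >= 0, road_count >= 0)
  if (length(niche$human_beta) != length(periods))
    niche$human_beta <- stats::approx(seq_along(niche$human_beta), niche$human_beta,
                                      n = length(periods))$y
  niche$human_beta <- contraction_strength * niche$human_beta
  names(niche$human_beta) <- periods
  structure(list(
    grid = grid_spec(n_rows, n_cols, cell_size, origin),
    periods = periods,
    occurrences_per_period = stats::setNames(occurrences_per_period, periods),
    seed = as.integer(seed), road_count = road_count,
    contraction_strength = contraction_strength,
    climate_trend = climate_trend, niche = niche),
    class = "scenario_config")
}

# shared deterministic pieces (elevation must be identical wherever used)
.synth_elevation <- function(config) {
  100 + 1400 * smooth_field(config$grid, sub_seed(config$seed, 1))
}

#' Generate synthetic road polylines
#'
#' Roads are seeded random walks across the grid biased toward low
#' elevation (valley-following), mimicking a historical main-road network.
#'
#' @param config A [scenario_config()].
#' @return Object of class `road_network`: a list of vertex matrices.
#' @export
generate_roads <- function(config) {
  spec <- config$grid
  elev <- .synth_elevation(config)
  lines <- list()
  if (config$road_count > 0) {
    lines <- with_seed(sub_seed(config$seed, 2), {
      lapply(seq_len(config$road_count), function(i) {
        horiz <- i %% 2 == 0
        n_step <- if (horiz) spec$n_cols else spec$n_rows
        # march across the grid one column (or row) at a time, drifting
        # toward the lowest neighbouring elevation
        pos <- sample.int(if (horiz) spec$n_rows else spec$n_cols, 1)
        verts <- matrix(NA_real_, n_step, 2)
        for (s in seq_len(n_step)) {
          cand <- pmin(pmax(pos + (-2:2), 1),
                       if (horiz) spec$n_rows else spec$n_cols)
          e <- if (horiz) elev[cand, s] else elev[s, cand]
          pos <- cand[which.min(e + stats::rnorm(length(cand), sd = 30))]
          verts[s, ] <- if (horiz)
            c(spec$origin[1] + (s - 0.5) * spec$cell_size,
              spec$origin[2] + (pos - 0.5) * spec$cell_size)
          else
            c(spec$origin[1] + (pos - 0.5) * spec$cell_size,
              spec$origin[2] + (s - 0.5) * spec$cell_size)
        }
        colnames(verts) <- c("x", "y")
        verts
      })
    })
  }
  structure(list(lines = lines, crs = "planar-km"), class = "road_network")
}

#' @export
print.road_network <- function(x, ...) {
  cat("<road_network>", length(x$lines), "polyline(s)\n")
  invisible(x)
}

#' Generate the per-period environmental stacks
#'
#' Elevation is a smooth field fixed across periods; MAT decreases with
#' elevation (6.5 deg C/km lapse) plus smooth noise and an optional warming
#' trend; MAP, NFFD and Eref are smooth fields correlated with elevation and
#' MAT; urban cover grows monotonically over periods, concentrated near
#' roads and at low elevation; forest is the complement of urban minus
#' noise, clamped to \[0, 1\]; aspect is circular uniform noise (a nuisance
#' predictor carrying no signal).
#'
#' @param config A [scenario_config()].
#' @param roads Optional [generate_roads()] output; regenerated from the
#'   config (same seed, hence identical) when omitted.
#' @return List of [env_stack()], one per period, in period order.
#' @export
generate_landscape <- function(config, roads = NULL) {
  spec <- config$grid
  if (is.null(roads)) roads <- generate_roads(config)
  elev <- .synth_elevation(config)
  nz <- function(tag, waves = 4, sd = 0.03) smooth_field(spec, sub_seed(config$seed, tag), waves, sd)

  mat0 <- 26 - 6.5 * elev / 1000 + 3 * (nz(3) - 0.5)
  map0 <- 900 + 0.4 * elev + 500 * nz(4)
  nffd0 <- 330 - 80 * (elev - 100) / 1400 - 15 * (nz(5) - 0.5)
  eref0 <- 800 + 25 * (mat0 - 18) + 120 * nz(6)
  aspect <- with_seed(sub_seed(config$seed, 7),
                      matrix(stats::runif(spec$n_rows * spec$n_cols, 0, 360),
                             spec$n_rows, spec$n_cols))

  d_road <- distance_to_roads(roads, spec)
  if (all(!is.finite(d_road))) d_road[] <- max(spec$n_rows, spec$n_cols) * spec$cell_size
  # urban potential in [0,1]; per-period exponent < 1 shrinks toward 1 over
  # time, so urban_t grows cell-wise monotonically
  upot <- stats::plogis(1.2 - 0.6 * d_road / (5 * spec$cell_size) -
                          2.0 * (elev - 100) / 1400 + 2.5 * (nz(8) - 0.5))
  p <- length(config$periods)
  gamma <- seq(3, 1, length.out = max(p, 2))[seq_len(p)]
  forest_noise <- 0.3 * nz(9)

  lapply(seq_len(p), function(t) {
    urban <- upot^gamma[t]
    layers <- list(
      MAT = mat0 + config$climate_trend * (t - 1),
      MAP = map0,
      NFFD = nffd0,
      Eref = eref0,
      elevation = elev,
      aspect = aspect,
      forest = pmin(pmax(1 - urban - forest_noise, 0), 1),
      urban = urban)
    env_stack(config$periods[t], layers, spec)
  })
}

#' Ground-truth suitability surface
#'
#' `s = exp(-(elev - elev_opt)^2 / (2 elev_sd^2)) *
#'      exp(-(MAT - mat_opt)^2 / (2 mat_sd^2)) * exp(-beta * urban)`,
#' with `beta` the niche's `human_beta` for the stack's period.
#'
#' @param stack An [env_stack()].
#' @param niche A [true_niche()].
#' @param beta Urban-penalty coefficient; defaults to
#'   `niche$human_beta[[stack$period]]` when the betas are period-named.
#' @return Matrix of suitabilities in \[0, 1\].
#' @export
true_suitability <- function(stack, niche, beta = NULL) {
  if (is.null(beta)) {
    if (is.null(names(niche$human_beta)) ||
        !(stack$period %in% names(niche$human_beta)))
      stop("beta not supplied and human_beta is not named for period ",
           stack$period)
    beta <- niche$human_beta[[stack$period]]
  }
  l <- stack$layers
  exp(-(l$elevation - niche$elev_opt)^2 / (2 * niche$elev_sd^2)) *
    exp(-(l$MAT - niche$mat_opt)^2 / (2 * niche$mat_sd^2)) *
    exp(-beta * l$urban)
}

#' Sample occurrence points from a suitability surface
#'
#' Cells are drawn without replacement with probability proportional to
#' suitability; each point is placed at its cell centre.
#'
#' @param suitability Suitability matrix (non-negative; must sum to > 0).
#' @param n Number of points.
#' @param seed RNG seed.
#' @param spec The [grid_spec()] of the surface.
#' @param period Period label attached to the points.
#' @return Data frame with columns `period, x, y` (an occurrence set).
#' @export
sample_occurrences <- function(suitability, n, seed, spec, period = "all") {
  if (n == 0)
    return(data.frame(period = character(), x = numeric(), y = numeric()))
  pos <- which(suitability > 0)
  if (sum(suitability) <= 0) stop("suitability sums to zero")
  if (n > length(pos))
    stop("n (", n, ") exceeds the ", length(pos),
         " cells with positive suitability")
  cells <- with_seed(seed, sample(pos, n, replace = FALSE, prob = suitability[pos]))
  xy <- cell_xy(spec, cells)
  data.frame(period = period, x = xy[, 1], y = xy[, 2])
}

#' Generate test polygons over the grid
#'
#' `strategy = "tile"` splits the grid into `k` disjoint rectangles covering
#' every cell (stand-ins for administrative units); `strategy = "random"`
#' draws `k` random rectangles (stand-ins for reserves; may overlap).
#'
#' @param config A [scenario_config()].
#' @param k Number of polygons (>= 1).
#' @param strategy `"tile"` or `"random"`.
#' @return Object of class `polygon_set`: list of `list(id, coords)` with
#'   closed rings.
#' @export
generate_polygons <- function(config, k, strategy = c("tile", "random")) {
  strategy <- match.arg(strategy)
  if (k < 1) stop("k must be >= 1")
  spec <- config$grid
  x0 <- spec$origin[1]; y0 <- spec$origin[2]
  W <- spec$n_cols * spec$cell_size; H <- spec$n_rows * spec$cell_size
  rect <- function(id, xa, xb, ya, yb)
    list(id = id, coords = cbind(x = c(xa, xb, xb, xa, xa),
                                 y = c(ya, ya, yb, yb, ya)))
  polys <- if (strategy == "tile") {
    nr <- floor(sqrt(k))
    while (k %% nr != 0) nr <- nr - 1  # largest factor <= sqrt(k); 1 for primes
    nc <- k / nr
    xs <- x0 + W * (0:nc) / nc
    ys <- y0 + H * (0:nr) / nr
    out <- list()
    for (i in seq_len(nr)) for (j in seq_len(nc))
      out[[length(out) + 1L]] <- rect(length(out) + 1L,
                                      xs[j], xs[j + 1], ys[i], ys[i + 1])
    out
  } else {
    with_seed(sub_seed(config$seed, 10), {
      lapply(seq_len(k), function(i) {
        w <- stats::runif(1, 0.1, 0.4) * W
        h <- stats::runif(1, 0.1, 0.4) * H
        xa <- stats::runif(1, x0, x0 + W - w)
        ya <- stats::runif(1, y0, y0 + H - h)
        rect(i, xa, xa + w, ya, ya + h)
      })
    })
  }
  structure(list(polygons = polys, crs = "planar-km"), class = "polygon_set")
}

#' Full synthetic scenario: landscape, roads, polygons and occurrences
#'
#' Convenience wrapper tying the generators together: builds the road
#' network and per-period stacks, evaluates the true suitability, and draws
#' the configured number of occurrences per period.
#'
#' @param config A [scenario_config()].
#' @return List with `config, roads, stacks, suitability, occurrences`
#'   (occurrences: one data frame with `period, x, y` over all periods).
#' @export
simulate_scenario <- function(config) {
  roads <- generate_roads(config)
  stacks <- generate_landscape(config, roads)
  suit <- lapply(stacks, true_suitability, niche = config$niche)
  names(suit) <- config$periods
  occ <- do.call(rbind, lapply(seq_along(stacks), function(t) {
    sample_occurrences(suit[[t]], config$occurrences_per_period[t],
                       sub_seed(config$seed, 100 + t), config$grid,
                       period = config$periods[t])
  }))
  list(config = config, roads = roads, stacks = stacks,
       suitability = suit, occurrences = occ)
}
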