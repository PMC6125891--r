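# Occurrence thinning, road-buffer pseudo-absence sampling, and
# collinearity-based predictor selection.

# distance from points to one segment (a, b), vectorized over points
.dist_point_segment <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  L2 <- dx^2 + dy^2
  t <- if (L2 == 0) rep(0, length(px)) else
    pmin(pmax(((px - ax) * dx + (py - ay) * dy) / L2, 0), 1)
  sqrt((px - (ax + t * dx))^2 + (py - (ay + t * dy))^2)
}

#' Distance from every cell centre to the nearest road
#'
#' @param roads A `road_network`.
#' @param spec A [grid_spec()].
#' @return Matrix of distances (map units, km); `Inf` when the network is
#'   empty.
#' @export
distance_to_roads <- function(roads, spec) {
  n <- spec$n_rows * spec$n_cols
  pts <- cell_xy(spec, seq_len(n))
  d <- rep(Inf, n)
  for (v in roads$lines) {
    if (nrow(v) < 2) next
    for (s in seq_len(nrow(v) - 1))
      d <- pmin(d, .dist_point_segment(pts[, 1], pts[, 2],
                                       v[s, 1], v[s, 2], v[s + 1, 1], v[s + 1, 2]))
  }
  matrix(d, spec$n_rows, spec$n_cols)
}

#' Road-buffer mask
#'
#' Cells whose centre lies within `buffer_km` of any road segment; the
#' background region from which pseudo-absences are drawn.
#'
#' @param roads A `road_network`.
#' @param spec A [grid_spec()].
#' @param buffer_km Buffer radius (default 15 km).
#' @return Logical matrix.
#' @export
road_buffer_mask <- function(roads, spec, buffer_km = 15) {
  distance_to_roads(roads, spec) <= buffer_km
}

#' Thin occurrences by home-range distance
#'
#' Greedy sequential thinning in input order: a point is kept iff its
#' distance to every already-kept point is at least
#' `d_min = max(2 * sqrt(A / pi), cell_size)` with `A` the home-range area
#' (default 6.97 ha, the home range used to deduplicate clustered records) —
#' i.e. the home-range circle's diameter floored at one raster cell. Kept
#' points are additionally deduplicated to one per raster cell.
#'
#' @param occ Data frame with columns `x, y` (and optionally `period`).
#' @param home_range_ha Home-range area in hectares (> 0).
#' @param cell_size Raster cell edge (km).
#' @param origin Grid origin for the cell-deduplication step.
#' @return The thinned subset of `occ`, original order preserved.
#' @export
thin_occurrences <- function(occ, home_range_ha = 6.97, cell_size = 1,
                             origin = c(0, 0)) {
  stopifnot(home_range_ha > 0, cell_size > 0)
  if (nrow(occ) == 0) return(occ)
  d_min <- max(2 * sqrt(home_range_ha * 1e4 / pi) / 1000, cell_size)  # km
  kx <- numeric(0); ky <- numeric(0); keep <- logical(nrow(occ))
  seen_cell <- character(0)
  for (i in seq_len(nrow(occ))) {
    x <- occ$x[i]; y <- occ$y[i]
    cell <- paste(floor((x - origin[1]) / cell_size),
                  floor((y - origin[2]) / cell_size))
    if (cell %in% seen_cell) next
    if (length(kx) == 0 || min(sqrt((kx - x)^2 + (ky - y)^2)) >= d_min) {
      keep[i] <- TRUE
      kx <- c(kx, x); ky <- c(ky, y)
      seen_cell <- c(seen_cell, cell)
    }
  }
  occ[keep, , drop = FALSE]
}

#' Sample pseudo-absence points from the road buffer
#'
#' Uniform draws over valid buffer cells, excluding any cell holding a
#' presence of the same set; points are placed at cell centres. When fewer
#' eligible cells than `n` exist, sampling falls back to with-replacement
#' with a warning.
#'
#' @param roads A `road_network` (must be non-empty).
#' @param spec A [grid_spec()].
#' @param presences Data frame with `x, y` of presence points (optional).
#' @param buffer_km Buffer radius (default 15 km).
#' @param n Number of points (default 10 000).
#' @param seed RNG seed.
#' @param mask Optional validity mask matrix.
#' @param period Label attached to the points.
#' @return Data frame `period, x, y` with attribute `n_requested`.
#' @export
sample_pseudo_absences <- function(roads, spec, presences = NULL,
                                   buffer_km = 15, n = 10000, seed = 1,
                                   mask = NULL, period = "all") {
  if (length(roads$lines) == 0)
    stop("cannot sample pseudo-absences: road network is empty, so the ",
         buffer_km, " km buffer contains no cells")
  elig <- road_buffer_mask(roads, spec, buffer_km)
  if (!is.null(mask)) elig <- elig & mask
  if (!any(elig))
    stop("cannot sample pseudo-absences: the ", buffer_km,
         " km road buffer intersects no valid cell")
  cells <- which(elig)
  if (!is.null(presences) && nrow(presences) > 0) {
    pres_cells <- unique(xy_cell(spec, presences$x, presences$y))
    cells <- setdiff(cells, pres_cells)
    if (length(cells) == 0)
      stop("cannot sample pseudo-absences: every buffer cell holds a presence")
  }
  drawn <- with_seed(seed, {
    if (length(cells) >= n) sample(cells, n)
    else {
      warning("only ", length(cells), " eligible cells for ", n,
              " pseudo-absences; sampling with replacement")
      sample(cells, n, replace = TRUE)
    }
  })
  xy <- cell_xy(spec, drawn)
  out <- data.frame(period = period, x = xy[, 1], y = xy[, 2])
  attr(out, "n_requested") <- n
  out
}

#' Stepwise predictor elimination by variance inflation factor
#'
#' Computes `VIF_k = 1 / (1 - R^2_k)` for each predictor regressed on the
#' others and, while the maximum VIF is at or above `threshold`, drops the
#' offending predictor and recomputes. Ties are broken by dropping the
#' later column in input order; a perfectly collinear predictor has
#' infinite VIF and is dropped first. Constant columns are rejected.
#'
#' @param design Data frame or matrix of predictor values (rows: presence +
#'   pseudo-absence cells).
#' @param threshold VIF threshold (default 10).
#' @return Object of class `predictor_selection`: `retained` (ordered
#'   names), `dropped` (data frame `name, vif` in removal order),
#'   `threshold`.
#' @export
vif_select <- function(design, threshold = 10) {
  X <- as.matrix(design)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (ncol(X) < 2) stop("need at least 2 predictors")
  if (nrow(X) < ncol(X) + 2) stop("need at least p + 2 rows")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ", paste(colnames(X)[sds == 0], collapse = ", "))
  vif_of <- function(M) {
    vapply(seq_len(ncol(M)), function(k) {
      y <- M[, k]
      fit <- stats::lm.fit(cbind(1, M[, -k, drop = FALSE]), y)
      rss <- sum(fit$residuals^2)
      tss <- sum((y - mean(y))^2)
      r2 <- 1 - rss / tss
      if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  keep <- colnames(X)
  dropped <- data.frame(name = character(), vif = numeric())
  repeat {
    if (length(keep) < 2) break
    v <- vif_of(X[, keep, drop = FALSE])
    mx <- max(v)
    if (mx < threshold) break
    at <- which(v == mx)
    at <- at[length(at)]  # later column on ties
    dropped <- rbind(dropped, data.frame(name = keep[at], vif = mx))
    keep <- keep[-at]
  }
  structure(list(retained = keep, dropped = dropped, threshold = threshold),
            class = "predictor_selection")
}

#' @export
print.predictor_selection <- function(x, ...) {
  cat("<predictor_selection> retained:", paste(x$retained, collapse = ", "), "\n")
  if (nrow(x$dropped))
    cat("  dropped (VIF >=", x$threshold, "):",
        paste(sprintf("%s (%.1f)", x$dropped$name, x$dropped$vif), collapse = ", "),
        "\n")
  invisible(x)
}
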