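# Core-area zonation prioritization: iterative cell removal minimizing the
# loss of the worst-off feature per unit cost, zone reclassification, and
# polygon (reserve / prefecture) summaries.

#' Disappearance cost layer from per-period binary ranges
#'
#' The disappearance index `d` counts, per cell, the run of trailing
#' periods (ending at the last) in which the cell is absent, divided by
#' `P - 1` and clamped to \[0, 1\]: present in the last period gives 0,
#' absent in all periods gives 1 (with four periods, values 0, 1/3, 2/3, 1).
#' The longer a cell has been lost, the harder recovery, hence the higher
#' the cost. Default cost transform `c = 1 + d` (strictly positive);
#' `"eps_plus"` gives `c = eps + d` for a stronger effect.
#'
#' @param binary_ranges List (in period order, >= 2) of logical presence
#'   matrices.
#' @param transform `"one_plus"` (default) or `"eps_plus"`.
#' @param eps Offset for `"eps_plus"`.
#' @param reverse Flip the index polarity (1 = extant in the last period).
#' @return Object of class `cost_layer`: `values` (cost matrix),
#'   `disappearance_index`.
#' @export
build_cost <- function(binary_ranges, transform = c("one_plus", "eps_plus"),
                       eps = 0.01, reverse = FALSE) {
  transform <- match.arg(transform)
  P <- length(binary_ranges)
  if (P < 2) stop("need at least 2 periods")
  dm <- dim(binary_ranges[[1]])
  if (!all(vapply(binary_ranges, function(b) identical(dim(b), dm), logical(1))))
    stop("binary grids are not co-registered")
  streak <- matrix(0, dm[1], dm[2])
  chain <- matrix(TRUE, dm[1], dm[2])
  for (t in P:1) {
    add <- chain & !binary_ranges[[t]]
    streak <- streak + add
    chain <- add
  }
  d <- pmin(streak / (P - 1), 1)
  if (reverse) d <- 1 - d
  values <- switch(transform, one_plus = 1 + d, eps_plus = eps + d)
  structure(list(values = values, disappearance_index = d,
                 transform = transform),
            class = "cost_layer")
}

#' Apply condition layers to a feature
#'
#' Habitat-quality multipliers: `p' = p * (1 - urban) * forest * vegetation`
#' (urban inverted so high urban cover lowers value). All conditions must
#' lie in \[0, 1\].
#'
#' @param feature Non-negative feature matrix (occurrence probability).
#' @param urban,forest Condition matrices in \[0, 1\].
#' @param vegetation Optional third condition (default 1 everywhere).
#' @return Effective feature matrix.
#' @export
apply_conditions <- function(feature, urban, forest, vegetation = NULL) {
  chk <- function(m, nm) {
    if (any(m < 0 | m > 1, na.rm = TRUE))
      stop("condition layer '", nm, "' outside [0, 1]")
    m
  }
  out <- feature * (1 - chk(urban, "urban")) * chk(forest, "forest")
  if (!is.null(vegetation)) out <- out * chk(vegetation, "vegetation")
  out
}

#' Core-area zonation priority ranking
#'
#' Iteratively removes the valid cell minimizing
#' `delta_i = max_j (w_j * q_ij) / c_i`, where `q_ij = p'_ij / sum(p'_j)`
#' over the cells still remaining — the marginal loss of the worst-off
#' feature per unit cost. After each removal the denominators are updated
#' (exact removal; no speed-up heuristics). Ties are broken by lower total
#' feature value, then row-major cell index. The rank of the cell removed
#' at position `i` of `N` is `i / N`; the last cell kept has rank 1.
#'
#' @param features One matrix or a list of non-negative feature matrices.
#' @param cost A `cost_layer` or a strictly positive cost matrix (default:
#'   unit cost).
#' @param weights Positive feature weights (default 1 each).
#' @param mask Logical validity mask (default: all finite feature cells).
#' @return Object of class `rank_map`: `rank` (matrix in (0, 1\], NA
#'   outside the mask) and `removal_order` (linear cell indices, first
#'   removed first).
#' @export
core_area_rank <- function(features, cost = NULL, weights = NULL, mask = NULL) {
  if (is.matrix(features)) features <- list(features)
  J <- length(features)
  if (J < 1) stop("need at least one feature")
  dm <- dim(features[[1]])
  if (is.null(weights)) weights <- rep(1, J)
  stopifnot(all(weights > 0))
  cvals <- if (is.null(cost)) matrix(1, dm[1], dm[2])
           else if (inherits(cost, "cost_layer")) cost$values else cost
  if (!identical(dim(cvals), dm)) stop("cost grid is not co-registered")
  if (is.null(mask)) mask <- Reduce(`&`, lapply(features, is.finite))
  valid <- which(mask)
  if (any(cvals[valid] <= 0)) stop("cost must be strictly positive on valid cells")
  N <- length(valid)
  P <- vapply(features, function(f) {
    v <- f[valid]
    if (any(v < 0)) stop("features must be non-negative")
    v
  }, numeric(N))
  P <- matrix(P, nrow = N)
  cv <- cvals[valid]
  psum <- rowSums(P)

  order_out <- integer(N)
  if (all(psum == 0)) {
    warning("all features are zero after conditioning; ranking by cost alone")
    # higher cost = lower priority = removed earlier; ties by cell index
    order_out <- order(-cv, valid)
  } else {
    rem <- seq_len(N)
    S <- colSums(P)
    W <- matrix(weights, nrow = N, ncol = J, byrow = TRUE)
    for (i in seq_len(N)) {
      if (length(rem) == 1L) { order_out[i] <- rem; break }
      Sg <- ifelse(S > 0, S, Inf)  # exhausted feature contributes 0
      num <- P[rem, , drop = FALSE] * W[rem, , drop = FALSE]
      num <- sweep(num, 2, Sg, `/`)
      cand <- if (J == 1) num[, 1] else do.call(pmax, asplit(num, 2))
      delta <- cand / cv[rem]
      best <- which(delta == min(delta))
      if (length(best) > 1) {
        ps <- psum[rem][best]
        best <- best[ps == min(ps)]
        if (length(best) > 1) best <- best[which.min(valid[rem][best])]
      }
      sel <- rem[best[1]]
      order_out[i] <- sel
      S <- S - P[sel, ]
      rem <- rem[-best[1]]
    }
  }
  rank <- matrix(NA_real_, dm[1], dm[2])
  rank[valid[order_out]] <- seq_len(N) / N
  structure(list(rank = rank, removal_order = valid[order_out]),
            class = "rank_map")
}

#' Reclassify a priority rank into conservation zones
#'
#' Zone rule: rank > 0.95 Mandatory Reserve; 0.90 < rank <= 0.95 Negotiated
#' Reserve; 0.80 < rank <= 0.90 Partial Reserve; rank <= 0.80 Other (the
#' published intervals leave 0.89-0.90 unassigned; half-open intervals at
#' the stated upper bounds close the gap, so rank exactly 0.90 is Partial).
#'
#' @param rank_map A `rank_map` or a rank matrix.
#' @param thresholds Upper bounds `c(mandatory, negotiated, partial)`.
#' @return Character matrix of zone labels (NA outside the mask).
#' @export
reclassify <- function(rank_map, thresholds = c(0.95, 0.90, 0.80)) {
  r <- if (inherits(rank_map, "rank_map")) rank_map$rank else rank_map
  z <- matrix(NA_character_, nrow(r), ncol(r))
  ok <- !is.na(r)
  z[ok] <- "Other"
  z[ok & r > thresholds[3]] <- "Partial"
  z[ok & r > thresholds[2]] <- "Negotiated"
  z[ok & r > thresholds[1]] <- "Mandatory"
  z
}

# even-odd ray-casting point-in-polygon (planar, closed ring); deliberate
# primitive, cross-checked in tests against tiling area bookkeeping
.point_in_poly <- function(px, py, ring) {
  vx <- ring[, 1]; vy <- ring[, 2]
  if (vx[1] == vx[length(vx)] && vy[1] == vy[length(vy)]) {
    vx <- vx[-length(vx)]; vy <- vy[-length(vy)]
  }
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    denom <- vy[j] - vy[i]
    crosses <- (vy[i] > py) != (vy[j] > py)
    if (any(crosses)) {
      xint <- vx[i] + (py - vy[i]) * (vx[j] - vx[i]) / denom
      inside <- xor(inside, crosses & px < xint)
    }
    j <- i
  }
  inside
}

#' Summarize priority rank by polygon (reserves / prefectures)
#'
#' Per polygon: mean rank over covered valid cells; the fraction of its
#' cells inside the top-`top_frac` priority area; its share of all priority
#' cells; and a conservation level from the mean rank (defaults: priority
#' >= 0.90, important >= 0.80, else normal). Polygons covering no valid
#' cell are excluded with a message.
#'
#' @param rank_map A `rank_map`.
#' @param polygons A `polygon_set`.
#' @param spec The [grid_spec()] of the rank grid.
#' @param top_frac Top fraction defining the priority area (default 0.10).
#' @param level_thresholds `c(priority, important)` mean-rank cut-offs.
#' @return Data frame `id, n_cells, mean_rank, fraction_priority,
#'   share_of_priority_area, level`.
#' @export
polygon_summary <- function(rank_map, polygons, spec, top_frac = 0.10,
                            level_thresholds = c(priority = 0.90, important = 0.80)) {
  if (length(polygons$polygons) == 0) stop("empty polygon set")
  r <- rank_map$rank
  cells <- which(!is.na(r))
  xy <- cell_xy(spec, cells)
  pr_cut <- 1 - top_frac
  total_priority <- sum(r[cells] > pr_cut)
  rows <- lapply(polygons$polygons, function(p) {
    inside <- .point_in_poly(xy[, 1], xy[, 2], p$coords)
    cc <- cells[inside]
    if (length(cc) == 0) {
      message("polygon ", p$id, " covers no valid cell; excluded")
      return(NULL)
    }
    mr <- mean(r[cc])
    npri <- sum(r[cc] > pr_cut)
    data.frame(id = p$id, n_cells = length(cc), mean_rank = mr,
               fraction_priority = npri / length(cc),
               share_of_priority_area =
                 if (total_priority > 0) npri / total_priority else 0,
               level = if (mr >= level_thresholds[1]) "priority"
                       else if (mr >= level_thresholds[2]) "important"
                       else "normal")
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no polygon covers any valid cell")
  out
}
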