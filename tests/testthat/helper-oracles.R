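# Independent oracles used across the suite. Each reimplements the checked
# rule by the most direct route available (brute force, enumeration, normal
# equations) and never calls the package's own code path.

# O(n^2) greedy thinning: keep a point iff it is >= d_min from every kept one
oracle_thin <- function(xy, d_min) {
  keep <- integer(0)
  for (i in seq_len(nrow(xy))) {
    ok <- TRUE
    for (j in keep) {
      if (sqrt(sum((xy[i, ] - xy[j, ])^2)) < d_min) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, i)
  }
  keep
}

# scalar point-to-segment distance, textbook projection
oracle_seg_dist <- function(p, a, b) {
  ab <- b - a
  L2 <- sum(ab^2)
  t <- if (L2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / L2))
  sqrt(sum((p - (a + t * ab))^2))
}

# VIF via normal equations: R^2 of column k on the others
oracle_vif <- function(X) {
  vapply(seq_len(ncol(X)), function(k) {
    A <- cbind(1, X[, -k, drop = FALSE])
    beta <- qr.solve(crossprod(A), crossprod(A, X[, k]))
    res <- X[, k] - A %*% beta
    r2 <- 1 - sum(res^2) / sum((X[, k] - mean(X[, k]))^2)
    1 / (1 - r2)
  }, numeric(1))
}

# max TSS by exhaustive enumeration of all score cut-points
oracle_max_tss <- function(scores, labels) {
  cuts <- sort(unique(c(-Inf, scores, 1)))
  best <- -Inf
  for (cc in cuts) {
    sens <- mean(scores[labels == 1] > cc)
    spec <- mean(scores[labels == 0] <= cc)
    best <- max(best, sens + spec - 1)
  }
  best
}

# step-by-step core-area removal simulator, recomputing every delta from
# scratch each step; same tie-break (lower total feature value, then index)
oracle_zonation <- function(P, cost, w = rep(1, ncol(P))) {
  N <- nrow(P)
  rem <- seq_len(N)
  ord <- integer(N)
  for (i in seq_len(N)) {
    S <- colSums(P[rem, , drop = FALSE])
    delta <- vapply(rem, function(cix) {
      contrib <- ifelse(S > 0, w * P[cix, ] / S, 0)
      max(contrib) / cost[cix]
    }, numeric(1))
    best <- which(delta == min(delta))
    if (length(best) > 1) {
      ps <- rowSums(P[rem[best], , drop = FALSE])
      best <- best[ps == min(ps)]
      best <- best[which.min(rem[best])]
    }
    ord[i] <- rem[best[1]]
    rem <- rem[-best[1]]
  }
  ord
}

# tiny env_stack with chosen values for a subset of layers; the remaining
# canonical layers are benign fillers
make_stack <- function(values, n_rows = NULL, period = "1970s", spec = NULL) {
  p <- nrow(values)
  if (is.null(n_rows)) n_rows <- max(2, floor(sqrt(p)))
  n_cols <- max(2, ceiling(p / n_rows))
  if (is.null(spec)) spec <- grid_spec(n_rows, n_cols)
  pad <- function(v, fill = 0) {
    out <- rep(fill, n_rows * n_cols)
    out[seq_along(v)] <- v
    matrix(out, n_rows, n_cols)
  }
  defaults <- list(MAT = 18, MAP = 1000, NFFD = 300, Eref = 800,
                   elevation = 600, aspect = 180, forest = 0.5, urban = 0)
  layers <- lapply(names(defaults), function(nm) {
    if (nm %in% colnames(values)) pad(values[, nm], defaults[[nm]])
    else matrix(defaults[[nm]], n_rows, n_cols)
  })
  names(layers) <- names(defaults)
  env_stack(period, layers, spec)
}

# one small scenario + fitted pipeline, computed once and shared
shared_scenario <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- simulate_scenario(scenario_config(n_rows = 60, n_cols = 60, seed = 3))
      pipe <- run_scenario_pipeline(sc, techniques = c("reglog", "gbt"),
                                    runs = 3, repetitions = 2, n_pa = 1500,
                                    keep_models = TRUE)
      cache <<- list(scenario = sc, pipe = pipe)
    }
    cache
  }
})
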