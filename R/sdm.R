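# Multi-technique ensemble distribution modelling with TSS-based member
# selection, cut-off binarization and per-period range statistics.
#
# The registry deliberately holds standard classifiers behind a uniform
# fit/predict surface; the ensemble logic (mean-TSS member selection,
# TSS-maximizing cut-off, >P binarization, repetition consensus) is the
# part replicated exactly.

.class_weights <- function(y) {
  # equal-total class weights: each class contributes half the total weight
  n <- length(y); n1 <- sum(y == 1); n0 <- n - n1
  ifelse(y == 1, n / (2 * n1), n / (2 * n0))
}

.registry <- list(
  reglog = list(  # ridge-regularized logistic regression
    fit = function(X, y, w, hyper, seed) {
      lam <- if (is.null(hyper$lambda)) 0.01 else hyper$lambda
      glmnet::glmnet(X, y, family = "binomial", alpha = 0, lambda = lam,
                     weights = w)
    },
    predict = function(model, X)
      as.numeric(stats::predict(model, X, type = "response")[, 1])),
  rf = list(      # random forest (probability trees)
    fit = function(X, y, w, hyper, seed) {
      nt <- if (is.null(hyper$num_trees)) 200 else hyper$num_trees
      d <- data.frame(X, .y = factor(y, levels = c(0, 1)))
      ranger::ranger(.y ~ ., data = d, probability = TRUE, num.trees = nt,
                     seed = seed, case.weights = w, num.threads = 1)
    },
    predict = function(model, X)
      as.numeric(stats::predict(model, data.frame(X),
                                num.threads = 1)$predictions[, "1"])),
  gbt = list(     # gradient-boosted trees
    fit = function(X, y, w, hyper, seed) {
      nr <- if (is.null(hyper$nrounds)) 50 else hyper$nrounds
      dtrain <- xgboost::xgb.DMatrix(X, label = y, weight = w, nthread = 1)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 3,
                      eta = 0.3, nthread = 1, seed = seed),
        data = dtrain, nrounds = nr, verbose = 0)
    },
    predict = function(model, X)
      as.numeric(stats::predict(model, xgboost::xgb.DMatrix(X, nthread = 1)))),
  spline = list(  # spline logistic (GAM with smooth terms)
    fit = function(X, y, w, hyper, seed) {
      k <- if (is.null(hyper$k)) 4 else hyper$k
      d <- data.frame(X, .y = y)
      rhs <- paste(sprintf("s(%s, k = %d)", colnames(X), k), collapse = " + ")
      suppressWarnings(
        mgcv::gam(stats::as.formula(paste(".y ~", rhs)),
                  family = stats::binomial(), data = d, weights = w))
    },
    predict = function(model, X)
      as.numeric(stats::predict(model, data.frame(X), type = "response"))),
  nnet = list(    # shallow neural network (one hidden layer)
    fit = function(X, y, w, hyper, seed) {
      size <- if (is.null(hyper$size)) 4 else hyper$size
      ctr <- colMeans(X); scl <- apply(X, 2, stats::sd); scl[scl == 0] <- 1
      Xs <- scale(X, ctr, scl)
      m <- with_seed(seed,
        nnet::nnet(Xs, y, size = size, decay = 0.01, maxit = 200,
                   weights = w, entropy = TRUE, trace = FALSE))
      list(net = m, center = ctr, scale = scl)
    },
    predict = function(model, X)
      as.numeric(stats::predict(model$net, scale(X, model$center, model$scale)))),
  constant = list(  # fixed-probability null baseline (diagnostics)
    fit = function(X, y, w, hyper, seed)
      list(value = if (is.null(hyper$value)) mean(y == 1) else hyper$value),
    predict = function(model, X) rep(model$value, nrow(X)))
)

#' Registered modelling techniques
#'
#' @return Character vector of technique names: ridge-regularized logistic
#'   (`reglog`), random forest (`rf`), gradient-boosted trees (`gbt`),
#'   spline logistic GAM (`spline`), shallow neural net (`nnet`).
#' @export
sdm_techniques <- function() names(.registry)

.default_techniques <- c("reglog", "rf", "gbt", "spline")

#' Stratified evaluation split
#'
#' 80/20 presence/pseudo-absence split, seeded by `(seed, run_index)` so
#' evaluation runs are reproducible and distinct.
#'
#' @param X Design matrix (presence rows then absence rows).
#' @param y 0/1 labels matching `X`.
#' @param run_index Evaluation-run number (1..runs).
#' @param seed Base seed.
#' @param frac Training fraction (default 0.8).
#' @return List `train = list(X, y)`, `test = list(X, y)`,
#'   `train_idx`, `test_idx`.
#' @export
split_evaluation <- function(X, y, run_index, seed, frac = 0.8) {
  if (sum(y == 1) < 10) stop("need at least 10 presences to split")
  idx1 <- which(y == 1); idx0 <- which(y == 0)
  tr <- with_seed(sub_seed(seed, 500 + run_index), {
    c(sample(idx1, round(frac * length(idx1))),
      sample(idx0, round(frac * length(idx0))))
  })
  te <- setdiff(seq_along(y), tr)
  list(train = list(X = X[tr, , drop = FALSE], y = y[tr]),
       test = list(X = X[te, , drop = FALSE], y = y[te]),
       train_idx = tr, test_idx = te)
}

#' Fit one modelling technique
#'
#' @param technique Registered technique name (see [sdm_techniques()]).
#' @param train List `X` (matrix with named columns), `y` (0/1).
#' @param hyper Named list of hyperparameters (technique-specific).
#' @param seed Seed for techniques with internal randomness.
#' @param weights Case weights; default equal-total class weights, so the
#'   large pseudo-absence set does not swamp the presences.
#' @return Object of class `sdm_fit`.
#' @export
fit_technique <- function(technique, train, hyper = list(), seed = 1,
                          weights = NULL) {
  if (!technique %in% names(.registry))
    stop("unknown technique '", technique, "'; see sdm_techniques()")
  if (length(unique(train$y)) < 2)
    stop("training data has a single class")
  if (is.null(weights)) weights <- .class_weights(train$y)
  model <- .registry[[technique]]$fit(train$X, train$y, weights, hyper, seed)
  structure(list(technique = technique, model = model,
                 predictors = colnames(train$X)),
            class = "sdm_fit")
}

#' @rdname fit_technique
#' @param fit An `sdm_fit`.
#' @param X New design matrix (same columns as training).
#' @export
predict_sdm <- function(fit, X) {
  p <- .registry[[fit$technique]]$predict(fit$model, X[, fit$predictors, drop = FALSE])
  pmin(pmax(p, 0), 1)
}

#' True skill statistic over a threshold grid
#'
#' Scans thresholds 0.00, 0.01, ..., 1.00; at each, presence is predicted
#' when score > threshold, and TSS = sensitivity + specificity - 1. Returns
#' the maximum and the lowest threshold attaining it.
#'
#' @param object An `sdm_fit` (then `test` must be `list(X, y)`) or a
#'   numeric score vector (then `test` is the 0/1 label vector).
#' @param test See `object`.
#' @return List `tss`, `threshold`.
#' @export
evaluate_tss <- function(object, test) {
  if (inherits(object, "sdm_fit")) {
    scores <- predict_sdm(object, test$X); labels <- test$y
  } else {
    scores <- object; labels <- test
  }
  if (length(unique(labels)) < 2) stop("test data has a single class")
  thr <- seq(0, 1, by = 0.01)
  s1 <- scores[labels == 1]; s0 <- scores[labels == 0]
  tss <- vapply(thr, function(t) mean(s1 > t) + mean(s0 <= t) - 1, numeric(1))
  i <- which.max(tss)  # ties: lowest threshold
  list(tss = tss[i], threshold = thr[i])
}

#' Select ensemble members above the mean TSS
#'
#' Members are the fits whose TSS is at or above the mean TSS of the full
#' fit set (so roughly the better half is retained).
#'
#' @param fits List of fit records: each `list(technique, run_index, tss,
#'   threshold, fit)`.
#' @return Object of class `ensemble_model`: `members`, `tss_mean`,
#'   `cutoff_P` (NA until calibrated).
#' @export
select_members <- function(fits) {
  if (length(fits) < 2) stop("need at least 2 fits")
  tss <- vapply(fits, `[[`, numeric(1), "tss")
  m <- mean(tss)
  structure(list(members = fits[tss >= m], tss_mean = m, cutoff_P = NA_real_),
            class = "ensemble_model")
}

.member_scores <- function(ensemble, X) {
  vapply(ensemble$members, function(f) predict_sdm(f$fit, X),
         numeric(nrow(X)))
}

#' Ensemble probability prediction
#'
#' Unweighted mean of member probabilities per cell by default; optionally
#' a TSS-weighted mean.
#'
#' @param ensemble An `ensemble_model`.
#' @param stack An [env_stack()] to project onto.
#' @param selection A `predictor_selection` (retained variables must all be
#'   stack layers).
#' @param weighted TSS-weighted mean instead of unweighted.
#' @return Probability matrix on the stack's grid (masked cells NA).
#' @export
ensemble_predict <- function(ensemble, stack, selection, weighted = FALSE) {
  vars <- selection$retained
  missing <- setdiff(vars, names(stack$layers))
  if (length(missing))
    stop("stack is missing predictor layer(s): ", paste(missing, collapse = ", "))
  cells <- which(stack$mask)
  X <- extract_env(stack, cells = cells, vars = vars)
  p <- .ensemble_scores(ensemble, X, weighted)
  out <- matrix(NA_real_, stack$spec$n_rows, stack$spec$n_cols)
  out[cells] <- p
  out
}

.ensemble_scores <- function(ensemble, X, weighted = FALSE) {
  S <- matrix(.member_scores(ensemble, X), nrow = nrow(X))
  if (weighted) {
    w <- vapply(ensemble$members, `[[`, numeric(1), "tss")
    w <- pmax(w, 0); if (sum(w) == 0) w <- rep(1, length(w))
    as.numeric(S %*% (w / sum(w)))
  } else rowMeans(S)
}

#' Calibrate the ensemble cut-off and binarize
#'
#' `calibrate_cutoff()` sets `P` to the TSS-maximizing threshold of the
#' ensemble scores on pooled evaluation data. `binarize()` applies the
#' strict rule: present iff probability > P.
#'
#' @param ensemble An `ensemble_model`.
#' @param X,y Pooled evaluation design and 0/1 labels.
#' @param weighted Passed through to the ensemble scores.
#' @return `calibrate_cutoff()`: the ensemble with `cutoff_P` set;
#'   `binarize()`: logical matrix (NA cells stay NA → treated absent).
#' @export
calibrate_cutoff <- function(ensemble, X, y, weighted = FALSE) {
  sc <- .ensemble_scores(ensemble, X, weighted)
  ensemble$cutoff_P <- evaluate_tss(sc, y)$threshold
  ensemble
}

#' @rdname calibrate_cutoff
#' @param probability Probability matrix.
#' @param cutoff_P Cut-off `P`; taken from the ensemble when omitted.
#' @export
binarize <- function(probability, ensemble = NULL, cutoff_P = NULL) {
  if (is.null(cutoff_P)) {
    if (is.null(ensemble) || is.na(ensemble$cutoff_P))
      stop("no cut-off: supply cutoff_P or a calibrated ensemble")
    cutoff_P <- ensemble$cutoff_P
  }
  b <- probability > cutoff_P
  b[is.na(b)] <- FALSE
  b
}

#' Range statistics from a binary distribution map
#'
#' @param binary Logical presence matrix.
#' @param elevation Elevation matrix (same grid).
#' @param cell_area_km2 Area of one cell (km^2).
#' @return List `range_km2`, `mean_elevation_m` (NA for an empty range),
#'   `n_cells`.
#' @export
range_stats <- function(binary, elevation, cell_area_km2 = 1) {
  if (!identical(dim(binary), dim(elevation)))
    stop("binary and elevation grids are not co-registered")
  n <- sum(binary)
  list(range_km2 = n * cell_area_km2,
       mean_elevation_m = if (n > 0) mean(elevation[binary]) else NA_real_,
       n_cells = n)
}

#' Permutation importance of predictors (diagnostic)
#'
#' Mean drop in ensemble TSS when one predictor column is permuted.
#'
#' @param ensemble A calibrated `ensemble_model`.
#' @param X,y Evaluation design and labels.
#' @param seed RNG seed.
#' @param n_perm Permutations per variable.
#' @return Named numeric vector (larger = more important).
#' @export
permutation_importance <- function(ensemble, X, y, seed = 1, n_perm = 3) {
  base <- evaluate_tss(.ensemble_scores(ensemble, X), y)$tss
  vapply(colnames(X), function(v) {
    drops <- vapply(seq_len(n_perm), function(b) {
      Xp <- X
      Xp[, v] <- with_seed(sub_seed(seed, 900 + b), sample(Xp[, v]))
      base - evaluate_tss(.ensemble_scores(ensemble, Xp), y)$tss
    }, numeric(1))
    mean(drops)
  }, numeric(1))
}

#' Run the full ensemble pipeline for one period
#'
#' For each of `repetitions` model repetitions: `runs` evaluation splits x
#' all `techniques` are fitted and scored by TSS; fits at or above the mean
#' TSS form the ensemble; the ensemble probability is projected over the
#' stack and binarized at the TSS-maximizing cut-off `P` calibrated on the
#' pooled presence/pseudo-absence data. The final binary map is a >= 50%
#' presence vote across repetitions and the consensus probability is their
#' mean.
#'
#' @param occ Thinned presences for the period (`x, y`).
#' @param pa Pseudo-absences (`x, y`).
#' @param stack The period's [env_stack()].
#' @param selection A `predictor_selection`.
#' @param techniques Technique names (default: four of the registry).
#' @param runs Evaluation runs per repetition (default 10).
#' @param repetitions Model repetitions (default 10).
#' @param seed Base seed.
#' @param hyper Per-technique hyperparameter lists, e.g.
#'   `list(rf = list(num_trees = 100))`.
#' @param weighted TSS-weighted ensemble mean.
#' @param keep_models Keep per-repetition ensembles (needed for
#'   counterfactual projection).
#' @param importance Also log permutation importance of each predictor.
#' @return Object of class `range_result`: consensus `probability`,
#'   `binary`, `range_km2`, `mean_elevation_m`, `tss_consensus` (mean member
#'   TSS), `tss_reeval` (TSS of the consensus probability re-evaluated on
#'   the pooled data), `cutoff_P` (mean across repetitions), `fits` (log
#'   table `technique, run, repetition, tss, threshold`), and optionally
#'   `ensembles`, `importance`.
#' @export
run_period <- function(occ, pa, stack, selection,
                       techniques = .default_techniques,
                       runs = 10, repetitions = 10, seed = 1,
                       hyper = list(), weighted = FALSE,
                       keep_models = FALSE, importance = FALSE) {
  vars <- selection$retained
  Xp <- extract_env(stack, xy = cbind(occ$x, occ$y), vars = vars)
  Xa <- extract_env(stack, xy = cbind(pa$x, pa$y), vars = vars)
  X <- rbind(Xp, Xa)
  y <- c(rep(1, nrow(Xp)), rep(0, nrow(Xa)))

  fit_log <- list(); ensembles <- list()
  prob_sum <- 0; vote_sum <- 0; cutoffs <- member_tss <- numeric(0)
  for (k in seq_len(repetitions)) {
    fits <- list()
    for (r in seq_len(runs)) {
      sp <- split_evaluation(X, y, r, sub_seed(seed, 1000 * k), frac = 0.8)
      for (tech in techniques) {
        f <- fit_technique(tech, sp$train, hyper = hyper[[tech]] %||% list(),
                           seed = sub_seed(seed, 1000 * k + 10 * r + match(tech, techniques)))
        ev <- evaluate_tss(f, sp$test)
        fits[[length(fits) + 1L]] <-
          list(technique = tech, run_index = r, tss = ev$tss,
               threshold = ev$threshold, fit = f)
        fit_log[[length(fit_log) + 1L]] <-
          data.frame(technique = tech, run = r, repetition = k,
                     tss = ev$tss, threshold = ev$threshold)
      }
    }
    ens <- select_members(fits)
    ens <- calibrate_cutoff(ens, X, y, weighted)
    prob <- ensemble_predict(ens, stack, selection, weighted)
    bin <- binarize(prob, ens)
    prob_sum <- prob_sum + ifelse(is.na(prob), 0, prob)
    vote_sum <- vote_sum + bin
    cutoffs <- c(cutoffs, ens$cutoff_P)
    member_tss <- c(member_tss, vapply(ens$members, `[[`, numeric(1), "tss"))
    if (keep_models) ensembles[[k]] <- ens
  }
  probability <- prob_sum / repetitions
  probability[!stack$mask] <- NA_real_
  binary <- vote_sum / repetitions >= 0.5
  st <- range_stats(binary, stack$layers$elevation, stack$spec$cell_size^2)
  cells <- which(stack$mask)
  reeval <- evaluate_tss(
    probability[xy_cell(stack$spec, c(occ$x, pa$x), c(occ$y, pa$y))], y)
  out <- list(period = stack$period, probability = probability,
              binary = binary, range_km2 = st$range_km2,
              mean_elevation_m = st$mean_elevation_m,
              tss_consensus = mean(member_tss), tss_reeval = reeval$tss,
              cutoff_P = mean(cutoffs),
              fits = do.call(rbind, fit_log), selection = selection)
  if (keep_models) out$ensembles <- ensembles
  if (importance) {
    ens1 <- if (keep_models) ensembles[[1]] else NULL
    if (!is.null(ens1)) out$importance <- permutation_importance(ens1, X, y, seed)
  }
  structure(out, class = "range_result")
}

#' @export
print.range_result <- function(x, ...) {
  cat(sprintf("<range_result> %s: range %.0f km^2, mean elev %.0f m, TSS %.3f (cutoff P=%.2f)\n",
              x$period, x$range_km2, x$mean_elevation_m, x$tss_consensus,
              x$cutoff_P))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
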