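make_toy_data <- function(n = 200, seed = 1, separable = FALSE, noise = FALSE) {
  withr::with_seed(seed, {
    X <- cbind(a = rnorm(n), b = rnorm(n))
    y <- if (noise) rbinom(n, 1, 0.5)
         else as.integer(X[, "a"] + 0.5 * X[, "b"] +
                           rnorm(n, sd = if (separable) 0 else 1) > 0)
    list(X = X, y = y)
  })
}

test_that("evaluation splits are stratified, deterministic partitions", {
  d <- make_toy_data(125)
  d$y <- c(rep(1, 100), rep(0, 25))
  sp <- split_evaluation(d$X, d$y, run_index = 1, seed = 9)
  expect_equal(sum(sp$train$y == 1), 80)
  expect_equal(sum(sp$test$y == 1), 20)
  expect_setequal(c(sp$train_idx, sp$test_idx), seq_along(d$y))
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)
  sp2 <- split_evaluation(d$X, d$y, run_index = 1, seed = 9)
  expect_identical(sp$train_idx, sp2$train_idx)
  sp3 <- split_evaluation(d$X, d$y, run_index = 2, seed = 9)
  expect_false(identical(sp$train_idx, sp3$train_idx))
  expect_error(split_evaluation(d$X, c(1, rep(0, 124)), 1, 1), "presences")
})

test_that("every registered technique fits, predicts in [0,1], and is seed-deterministic", {
  d <- make_toy_data(150, seed = 2)
  grid <- make_toy_data(50, seed = 3)$X
  for (tech in setdiff(sdm_techniques(), "constant")) {
    f1 <- fit_technique(tech, d, seed = 7)
    f2 <- fit_technique(tech, d, seed = 7)
    p1 <- predict_sdm(f1, grid); p2 <- predict_sdm(f2, grid)
    expect_true(all(p1 >= 0 & p1 <= 1), info = tech)
    expect_equal(p1, p2, tolerance = 1e-12, info = tech)
  }
  expect_error(fit_technique("nope", d), "unknown technique")
  expect_error(fit_technique("reglog", list(X = d$X, y = rep(1, 150))),
               "single class")
})

test_that("a separable problem is classified perfectly by the logistic technique", {
  d <- make_toy_data(200, seed = 4, separable = TRUE)
  f <- fit_technique("reglog", d, hyper = list(lambda = 1e-4))
  p <- predict_sdm(f, d$X)
  expect_equal(as.integer(p > 0.5), d$y)
  expect_equal(evaluate_tss(f, d)$tss, 1)
})

test_that("TSS grid search matches exhaustive cut-point enumeration", {
  # worked 6-point set: presences score (0.9, 0.8, 0.6), absences (0.7, 0.3, 0.1)
  scores <- c(0.9, 0.8, 0.6, 0.7, 0.3, 0.1)
  labels <- c(1, 1, 1, 0, 0, 0)
  # at threshold 0.5: sens 3/3, spec 2/3 -> TSS = 2/3
  sens <- mean(scores[labels == 1] > 0.5)
  spec <- mean(scores[labels == 0] <= 0.5)
  expect_equal(sens + spec - 1, 2 / 3)
  ev <- evaluate_tss(scores, labels)
  expect_equal(ev$tss, oracle_max_tss(scores, labels))
  expect_equal(ev$tss, 2 / 3)
  expect_equal(ev$threshold, 0.3)  # lowest threshold attaining the max

  # perfect ranking and label-independent scores
  expect_equal(evaluate_tss(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))$tss, 1)
  expect_equal(evaluate_tss(rep(0.5, 40), rep(c(0, 1), 20))$tss, 0)
  expect_error(evaluate_tss(c(0.1, 0.9), c(1, 1)), "single class")

  # bounds on random score/label sets; TSS = 1 only when separable
  for (i in 1:50) {
    withr::with_seed(i, {
      s <- round(runif(20), 2)
      l <- rbinom(20, 1, 0.5)
    })
    if (length(unique(l)) < 2) next
    ev <- evaluate_tss(s, l)
    expect_gte(ev$tss, -1); expect_lte(ev$tss, 1)
    if (ev$tss == 1) expect_gt(min(s[l == 1]), max(s[l == 0]))
  }
})

test_that("member selection keeps fits at or above the mean TSS (~half)", {
  fits <- lapply(c(0.2, 0.4, 0.6, 0.8), function(t) list(tss = t))
  ens <- select_members(fits)
  expect_equal(ens$tss_mean, 0.5)
  expect_equal(vapply(ens$members, `[[`, numeric(1), "tss"), c(0.6, 0.8))

  same <- lapply(rep(0.7, 5), function(t) list(tss = t))
  expect_length(select_members(same)$members, 5)

  frac <- vapply(1:50, function(i) {
    tss <- withr::with_seed(i, runif(80))
    length(select_members(lapply(tss, function(t) list(tss = t)))$members) / 80
  }, numeric(1))
  expect_equal(mean(frac), 0.5, tolerance = 0.05)
})

test_that("ensemble prediction averages members and stays within their envelope", {
  st <- make_stack(cbind(elevation = rep(600, 9)), n_rows = 3)
  sel <- structure(list(retained = c("elevation", "MAT"),
                        dropped = data.frame(), threshold = 10),
                   class = "predictor_selection")
  cm <- function(v, tss) list(technique = "constant", tss = tss,
                              fit = fit_technique("constant",
                                                  list(X = cbind(elevation = c(1, 2), MAT = c(1, 2)),
                                                       y = c(0, 1)),
                                                  hyper = list(value = v)))
  ens1 <- structure(list(members = list(cm(0.2, 0.5)), tss_mean = 0.5,
                         cutoff_P = NA_real_), class = "ensemble_model")
  expect_equal(unique(as.numeric(ensemble_predict(ens1, st, sel))), 0.2)

  ens2 <- structure(list(members = list(cm(0.2, 0.25), cm(0.8, 0.75)),
                         tss_mean = 0.5, cutoff_P = NA_real_),
                    class = "ensemble_model")
  expect_equal(unique(as.numeric(ensemble_predict(ens2, st, sel))), 0.5)
  # TSS-weighted: weights (0.25, 0.75) ~ (1, 3) -> 0.2*0.25 + 0.8*0.75 = 0.65
  pw <- as.numeric(ensemble_predict(ens2, st, sel, weighted = TRUE))
  expect_true(all(abs(pw - 0.65) < 1e-9))

  sel_bad <- structure(list(retained = c("elevation", "missingvar")),
                       class = "predictor_selection")
  expect_error(ensemble_predict(ens2, st, sel_bad), "missingvar")

  # real members: ensemble within the member envelope cell-wise
  d <- make_toy_data(200, seed = 5)
  f1 <- fit_technique("reglog", d); f2 <- fit_technique("gbt", d)
  ens3 <- structure(list(members = list(list(tss = 0.5, fit = f1),
                                        list(tss = 0.5, fit = f2)),
                         tss_mean = 0.5, cutoff_P = NA_real_),
                    class = "ensemble_model")
  S <- cbind(predict_sdm(f1, d$X), predict_sdm(f2, d$X))
  em <- rangerecon:::.ensemble_scores(ens3, d$X)
  expect_true(all(em >= apply(S, 1, min) - 1e-12))
  expect_true(all(em <= apply(S, 1, max) + 1e-12))
})

test_that("binarization uses the strict >P rule with a TSS-calibrated cut-off", {
  expect_true(all(binarize(matrix(1, 2, 2), cutoff_P = 0.5)))
  expect_false(any(binarize(matrix(0.5, 2, 2), cutoff_P = 0.5)))  # p = P -> absent

  scores <- c(0.9, 0.8, 0.6, 0.7, 0.3, 0.1)
  labels <- c(1, 1, 1, 0, 0, 0)
  cm <- fit_technique("constant", list(X = cbind(a = c(1, 2)), y = c(0, 1)),
                      hyper = list(value = 0.5))
  ens <- structure(list(members = list(list(tss = 0.5, fit = cm)),
                        tss_mean = 0.5, cutoff_P = NA_real_),
                   class = "ensemble_model")
  # calibration path must reproduce the oracle grid-search threshold
  ens$cutoff_P <- evaluate_tss(scores, labels)$threshold
  expect_equal(ens$cutoff_P, 0.3)
  # range is monotone non-increasing in the cut-off
  p <- matrix(runif(100), 10, 10)
  areas <- vapply(seq(0, 1, 0.1), function(ct) sum(binarize(p, cutoff_P = ct)),
                  numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("range statistics count presence cells and average their elevation", {
  b <- matrix(FALSE, 3, 3); b[c(1, 5, 7, 8, 9)] <- TRUE
  elev <- matrix(0, 3, 3); elev[c(1, 5)] <- c(600, 800)
  expect_equal(range_stats(b, elev, 1)$range_km2, 5)
  b2 <- matrix(FALSE, 2, 2); b2[1:2] <- TRUE
  e2 <- matrix(c(600, 800, 0, 0), 2, 2)
  expect_equal(range_stats(b2, e2, 1)$mean_elevation_m, 700)
  full <- matrix(TRUE, 4, 5)
  expect_equal(range_stats(full, matrix(1, 4, 5), 2^2)$range_km2, 4 * 5 * 4)
  empty <- matrix(FALSE, 2, 2)
  expect_true(is.na(range_stats(empty, matrix(1, 2, 2))$mean_elevation_m))
  expect_error(range_stats(b, matrix(0, 2, 2)), "co-registered")
})

test_that("run_period logs techniques x runs x repetitions fits and reduces at K = 1", {
  sh <- shared_scenario()
  res <- sh$pipe$results[["1970s"]]
  expect_equal(nrow(res$fits), 2 * 3 * 2)  # 2 techniques, 3 runs, 2 repetitions
  expect_true(all(res$fits$tss >= -1 & res$fits$tss <= 1))
  expect_true(res$range_km2 >= 0 &&
                res$range_km2 <= grid_area_km2(sh$scenario$config$grid))

  # K = 1 equals the single ensemble pipeline run with the same seeds
  occ <- sh$pipe$occurrences[["1970s"]]; pa <- sh$pipe$pseudo_absences[["1970s"]]
  st <- sh$scenario$stacks[[1]]; sel <- sh$pipe$selections[["1970s"]]
  r1 <- run_period(occ, pa, st, sel, techniques = "reglog", runs = 2,
                   repetitions = 1, seed = 42)
  expect_equal(nrow(r1$fits), 2)
  expect_equal(sum(r1$binary) * st$spec$cell_size^2, r1$range_km2)
})
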