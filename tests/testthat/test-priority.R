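test_that("the disappearance cost layer encodes trailing absence runs", {
  b <- function(...) matrix(c(...), 2, 2)
  periods <- list(b(TRUE, TRUE, FALSE, TRUE),    # 1970s
                  b(TRUE, FALSE, FALSE, TRUE),   # 1980s
                  b(FALSE, FALSE, FALSE, TRUE),  # 1990s
                  b(FALSE, FALSE, FALSE, TRUE))  # 2000s
  cl <- build_cost(periods)
  # cell 1: present 70s-80s, absent 90s-2000s -> d = 2/3, c = 5/3
  expect_equal(cl$disappearance_index[1, 1], 2 / 3)
  expect_equal(cl$values[1, 1], 5 / 3)
  # cell 3: absent in all four periods -> d = 1, c = 2
  expect_equal(cl$disappearance_index[1, 2], 1)
  expect_equal(cl$values[1, 2], 2)
  # cell 4: present in the 2000s -> d = 0, c = 1
  expect_equal(cl$disappearance_index[2, 2], 0)
  expect_true(all(cl$disappearance_index %in% c(0, 1 / 3, 2 / 3, 1)))
  expect_equal(build_cost(periods, "eps_plus", eps = 0.01)$values[2, 2], 0.01)
  expect_error(build_cost(periods[1]), "2 periods")
  expect_error(build_cost(list(periods[[1]], matrix(TRUE, 3, 3))),
               "co-registered")
})

test_that("condition layers multiply into the feature with urban inverted", {
  p <- matrix(0.8, 2, 2)
  one <- matrix(1, 2, 2); zero <- matrix(0, 2, 2)
  expect_equal(apply_conditions(p, urban = zero, forest = one), p)
  expect_equal(apply_conditions(p, urban = one, forest = one), zero)
  expect_equal(apply_conditions(p, urban = matrix(0.25, 2, 2),
                                forest = matrix(0.5, 2, 2),
                                vegetation = one)[1, 1], 0.3)
  expect_error(apply_conditions(p, urban = matrix(1.2, 2, 2), forest = one),
               "urban")
})

test_that("single-feature removal order equals ascending value/cost", {
  # 2x2 worked example: removal in ascending p' order, ranks i/N
  p <- matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2)
  rk <- core_area_rank(p)
  expect_equal(as.numeric(rk$rank), c(0.25, 0.5, 0.75, 1.0))
  expect_equal(rk$removal_order, order(as.numeric(p)))

  # cost halves the marginal loss: the costly cell goes first
  p2 <- matrix(c(0.2, 0.2), 1, 2)
  rk2 <- core_area_rank(p2, cost = matrix(c(1, 2), 1, 2))
  expect_equal(rk2$removal_order, c(2L, 1L))

  # uniform values and cost: tie-break removes in row-major cell order
  pu <- matrix(1, 3, 3)
  rku <- core_area_rank(pu)
  expect_equal(rku$removal_order, 1:9)
  expect_equal(rku$rank[3, 3], 1)

  # random grids: analytic single-feature oracle (ascending p/c)
  for (seed in 1:5) {
    vals <- withr::with_seed(seed, matrix(runif(64, 0.01, 1), 8, 8))
    cost <- withr::with_seed(seed + 100, matrix(runif(64, 0.5, 2), 8, 8))
    rk <- core_area_rank(vals, cost)
    expect_equal(rk$removal_order, order(as.numeric(vals / cost)))
  }
})

test_that("multi-feature ranking matches the brute-force step simulator", {
  for (seed in 1:4) {
    f1 <- withr::with_seed(seed, matrix(runif(16, 0.01, 1), 4, 4))
    f2 <- withr::with_seed(seed + 50, matrix(runif(16, 0.01, 1), 4, 4))
    cost <- withr::with_seed(seed + 90, matrix(runif(16, 0.5, 2), 4, 4))
    w <- c(1, 2.5)
    rk <- core_area_rank(list(f1, f2), cost, weights = w)
    ord <- oracle_zonation(cbind(as.numeric(f1), as.numeric(f2)),
                           as.numeric(cost), w)
    expect_equal(rk$removal_order, ord)
  }
})

test_that("rank is scale-invariant and monotone in a cell's cost", {
  vals <- withr::with_seed(7, matrix(runif(36, 0.01, 1), 6, 6))
  cost <- withr::with_seed(8, matrix(runif(36, 0.5, 2), 6, 6))
  base <- core_area_rank(vals, cost)
  expect_equal(core_area_rank(vals * 13.7, cost)$rank, base$rank)
  expect_equal(core_area_rank(vals, cost * 0.31)$rank, base$rank)
  # raising one cell's cost never raises its rank
  for (cell in c(1, 14, 30)) {
    c2 <- cost; c2[cell] <- c2[cell] * 5
    expect_lte(core_area_rank(vals, c2)$rank[cell], base$rank[cell])
  }
  # all-zero features: warned, ranked by cost alone (high cost removed first)
  expect_warning(rk0 <- core_area_rank(matrix(0, 3, 3),
                                       matrix(1:9 / 9, 3, 3)), "cost alone")
  expect_equal(rk0$removal_order, 9:1)
})

test_that("zone reclassification applies the documented half-open intervals", {
  vals <- matrix(withr::with_seed(9, runif(100)), 10, 10)  # distinct values
  rk <- core_area_rank(vals)
  z <- reclassify(rk)
  expect_equal(sum(z == "Mandatory"), 5)    # ranks 0.96..1.00
  expect_equal(sum(z == "Negotiated"), 5)
  expect_equal(sum(z == "Partial"), 10)
  expect_equal(sum(z == "Other"), 80)
  # boundary membership: rank exactly 0.90 is Partial, 0.95 Negotiated
  zb <- reclassify(matrix(c(0.90, 0.95, 0.9501, 0.8, NA, 1), 2, 3))
  expect_equal(as.character(zb[!is.na(zb)]),
               c("Partial", "Negotiated", "Mandatory", "Other", "Mandatory"))
})

test_that("polygon summaries aggregate rank, priority share and level", {
  cfg <- scenario_config(n_rows = 10, n_cols = 10, seed = 1,
                         occurrences_per_period = c(5, 5, 5, 5))
  vals <- matrix(withr::with_seed(10, runif(100)), 10, 10)
  rk <- core_area_rank(vals)
  halves <- generate_polygons(cfg, 2, "tile")
  ps <- polygon_summary(rk, halves, cfg$grid)
  expect_equal(sum(ps$share_of_priority_area), 1)
  expect_equal(sum(ps$n_cells), 100)

  # a polygon holding only the rank-1 cell
  top_cell <- which(rk$rank == 1)
  ctr <- cell_xy(cfg$grid, top_cell)
  tiny <- structure(list(polygons = list(list(id = 99L, coords = cbind(
    x = ctr[1] + c(-0.4, 0.4, 0.4, -0.4, -0.4),
    y = ctr[2] + c(-0.4, -0.4, 0.4, 0.4, -0.4)))), crs = "planar-km"),
    class = "polygon_set")
  pt <- polygon_summary(rk, tiny, cfg$grid)
  expect_equal(pt$mean_rank, 1)
  expect_equal(pt$level, "priority")
  expect_equal(pt$fraction_priority, 1)

  # a polygon entirely in the low-rank region has no priority overlap
  low_cell <- which(rk$rank == min(rk$rank))
  lc <- cell_xy(cfg$grid, low_cell)
  low <- structure(list(polygons = list(list(id = 1L, coords = cbind(
    x = lc[1] + c(-0.4, 0.4, 0.4, -0.4, -0.4),
    y = lc[2] + c(-0.4, -0.4, 0.4, 0.4, -0.4)))), crs = "planar-km"),
    class = "polygon_set")
  expect_equal(polygon_summary(rk, low, cfg$grid)$fraction_priority, 0)

  # polygons with no valid cells are excluded with a message
  off <- structure(list(polygons = list(
    list(id = 1L, coords = tiny$polygons[[1]]$coords),
    list(id = 2L, coords = cbind(x = c(50, 51, 51, 50, 50),
                                 y = c(50, 50, 51, 51, 50)))),
    crs = "planar-km"), class = "polygon_set")
  expect_message(po <- polygon_summary(rk, off, cfg$grid), "excluded")
  expect_equal(nrow(po), 1)
  expect_error(polygon_summary(rk, structure(list(polygons = list()),
                                             class = "polygon_set"),
                               cfg$grid), "empty")
})
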