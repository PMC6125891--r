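# Range-change accounting, the climate-vs-human counterfactual projection,
# and orchestration of the whole pipeline over a scenario.

#' Percent reduction between two range sizes
#'
#' `100 * (1 - range_b / range_a)`, reported to two decimals; negative
#' values (expansion) are permitted.
#'
#' @param range_a Baseline range (km^2, > 0).
#' @param range_b Later range (km^2).
#' @param digits Reporting precision (NULL for the raw value).
#' @return Percent reduction.
#' @export
range_change <- function(range_a, range_b, digits = 2) {
  if (range_a <= 0) stop("baseline range must be positive")
  out <- 100 * (1 - range_b / range_a)
  if (is.null(digits)) out else round(out, digits)
}

#' Range-change accounting table
#'
#' Per period: range (km^2), percent of the study area, percent reduction
#' versus the first period, and the inter-period reduction; plus the mean
#' decadal reduction (arithmetic mean of the consecutive inter-period
#' percentages — a simple mean of percentages on differing baselines, not
#' a compound rate). All derived columns are recomputed from the stored
#' ranges at build time.
#'
#' @param ranges_km2 Named (by period) numeric vector of range sizes, or a
#'   list of `range_result` objects.
#' @param study_area_km2 Total study area (default 512 684 km^2).
#' @param digits Reporting precision for percent columns.
#' @return Data frame with one row per period; attributes
#'   `mean_decadal_reduction` (reported precision), `raw` (unrounded
#'   columns), `study_area_km2`.
#' @export
build_table <- function(ranges_km2, study_area_km2 = 512684, digits = 2) {
  if (is.list(ranges_km2) && inherits(ranges_km2[[1]], "range_result"))
    ranges_km2 <- stats::setNames(
      vapply(ranges_km2, `[[`, numeric(1), "range_km2"),
      vapply(ranges_km2, `[[`, character(1), "period"))
  if (length(ranges_km2) < 2) stop("need at least 2 periods")
  r <- as.numeric(ranges_km2)
  share <- 100 * r / study_area_km2
  vs_base <- 100 * (1 - r / r[1])
  inter <- c(NA, 100 * (1 - r[-1] / r[-length(r)]))
  raw <- data.frame(period = names(ranges_km2), range_km2 = r,
                    percent_of_study_area = share,
                    percent_reduction_vs_baseline = vs_base,
                    inter_period_reduction = inter)
  out <- raw
  for (cc in 3:5) out[[cc]] <- round(out[[cc]], digits)
  attr(out, "raw") <- raw
  attr(out, "mean_decadal_reduction") <- round(mean(inter[-1]), digits)
  attr(out, "study_area_km2") <- study_area_km2
  out
}

#' Zone area from a ranked fraction
#'
#' @param fraction Fraction of ranked cells in (0, 1].
#' @param study_area_km2 Study area.
#' @return Area in km^2, reported to one decimal.
#' @export
zone_area <- function(fraction, study_area_km2 = 512684) {
  stopifnot(fraction > 0, fraction <= 1)
  round(fraction * study_area_km2, 1)
}

#' Mean consensus TSS across periods
#'
#' @param per_period_tss Numeric vector (length >= 1).
#' @return Arithmetic mean, reported to two decimals.
#' @export
mean_consensus_tss <- function(per_period_tss) {
  if (length(per_period_tss) < 1) stop("empty input")
  round(mean(per_period_tss), 2)
}

#' Hybrid environmental stack for counterfactual projection
#'
#' Climate (MAT, MAP, NFFD, Eref) plus topography (elevation, aspect) from
#' one period, human-influence layers (urban, forest) from another.
#'
#' @param stacks Named (by period) list of [env_stack()].
#' @param climate_period,human_period Period labels.
#' @return An [env_stack()] labelled `"<climate>|<human>"`.
#' @export
hybrid_stack <- function(stacks, climate_period, human_period) {
  if (is.null(names(stacks)))
    names(stacks) <- vapply(stacks, `[[`, character(1), "period")
  for (p in c(climate_period, human_period))
    if (!p %in% names(stacks)) stop("period '", p, "' not in the scenario")
  cs <- stacks[[climate_period]]; hs <- stacks[[human_period]]
  layers <- cs$layers
  layers$urban <- hs$layers$urban
  layers$forest <- hs$layers$forest
  env_stack(paste0(climate_period, "|", human_period), layers, cs$spec,
            cs$mask & hs$mask)
}

#' Counterfactual range under swapped climate / human layers
#'
#' Projects the per-period model fitted on `occurrence_period` occurrences
#' (with human layers from `human_period`) onto a hybrid stack taking
#' climate from `climate_period` and human influence from `human_period`,
#' then binarizes each repetition at its calibrated cut-off and takes the
#' >= 50% vote. With `human_period == occurrence_period` (the standard
#' scenarios: has human influence stayed at its old level?) the stored
#' per-period ensembles are reused directly — the training data are
#' identical by construction.
#'
#' @param results Named (by period) list of `range_result` objects fitted
#'   with `keep_models = TRUE`.
#' @param stacks Named (by period) list of [env_stack()].
#' @param occurrence_period,climate_period,human_period Period labels.
#' @param occ,pa,... Occurrences, pseudo-absences and [run_period()]
#'   arguments, needed only when `human_period != occurrence_period`
#'   (a fresh fit on a hybrid training stack).
#' @param weighted TSS-weighted ensemble mean.
#' @return List `range_km2`, `binary`, `probability`, `stack`.
#' @export
counterfactual_range <- function(results, stacks, occurrence_period,
                                 climate_period, human_period = occurrence_period,
                                 occ = NULL, pa = NULL, weighted = FALSE, ...) {
  if (is.null(names(stacks)))
    names(stacks) <- vapply(stacks, `[[`, character(1), "period")
  target <- hybrid_stack(stacks, climate_period, human_period)
  if (human_period == occurrence_period) {
    res <- results[[occurrence_period]]
    if (is.null(res) || is.null(res$ensembles))
      stop("results for ", occurrence_period,
           " must be fitted with keep_models = TRUE")
    sel <- res$selection
    ensembles <- res$ensembles
  } else {
    if (is.null(occ) || is.null(pa))
      stop("occ and pa are required when human_period differs from occurrence_period")
    train_stack <- hybrid_stack(stacks, occurrence_period, human_period)
    res <- run_period(occ, pa, train_stack, results[[occurrence_period]]$selection,
                      keep_models = TRUE, weighted = weighted, ...)
    sel <- res$selection
    ensembles <- res$ensembles
  }
  prob_sum <- 0; vote_sum <- 0
  for (ens in ensembles) {
    prob <- ensemble_predict(ens, target, sel, weighted)
    vote_sum <- vote_sum + binarize(prob, ens)
    prob_sum <- prob_sum + ifelse(is.na(prob), 0, prob)
  }
  K <- length(ensembles)
  binary <- vote_sum / K >= 0.5
  st <- range_stats(binary, target$layers$elevation, target$spec$cell_size^2)
  list(range_km2 = st$range_km2, mean_elevation_m = st$mean_elevation_m,
       binary = binary, probability = prob_sum / K, stack = target)
}

#' Run the whole range-reconstruction pipeline on a scenario
#'
#' Thins each period's occurrences by home-range distance, samples
#' road-buffer pseudo-absences (one draw per period, seeded by the period),
#' selects predictors by stepwise VIF on the pooled presence +
#' pseudo-absence design, fits the per-period ensembles, and assembles the
#' range-change table.
#'
#' @param scenario Output of [simulate_scenario()] (or a compatible list
#'   with `config, roads, stacks, occurrences`).
#' @param techniques,runs,repetitions,hyper,weighted,keep_models Passed to
#'   [run_period()].
#' @param n_pa Pseudo-absences per period (default 10 000).
#' @param buffer_km Road-buffer radius (default 15 km).
#' @param home_range_ha Thinning home range (default 6.97 ha).
#' @param vif_threshold Collinearity threshold (default 10).
#' @param seed Base seed (defaults to the scenario's).
#' @return List `results` (per period `range_result`), `table`
#'   (range-change accounting over the scenario's own area), `occurrences`
#'   (thinned), `pseudo_absences`, `selections`.
#' @export
run_scenario_pipeline <- function(scenario,
                                  techniques = .default_techniques,
                                  runs = 10, repetitions = 10,
                                  n_pa = 10000, buffer_km = 15,
                                  home_range_ha = 6.97, vif_threshold = 10,
                                  seed = NULL, hyper = list(),
                                  weighted = FALSE, keep_models = FALSE) {
  cfg <- scenario$config
  if (is.null(seed)) seed <- cfg$seed
  spec <- cfg$grid
  periods <- cfg$periods
  results <- list(); occs <- list(); pas <- list(); sels <- list()
  for (t in seq_along(periods)) {
    p <- periods[t]
    stack <- scenario$stacks[[t]]
    occ <- scenario$occurrences[scenario$occurrences$period == p, , drop = FALSE]
    occ <- thin_occurrences(occ, home_range_ha, spec$cell_size, spec$origin)
    pa <- sample_pseudo_absences(scenario$roads, spec, presences = occ,
                                 buffer_km = buffer_km, n = n_pa,
                                 seed = sub_seed(seed, 300 + t), period = p)
    design <- rbind(extract_env(stack, xy = cbind(occ$x, occ$y)),
                    extract_env(stack, xy = cbind(pa$x, pa$y)))
    sel <- vif_select(design, vif_threshold)
    results[[p]] <- run_period(occ, pa, stack, sel,
                               techniques = techniques, runs = runs,
                               repetitions = repetitions,
                               seed = sub_seed(seed, 400 + t),
                               hyper = hyper, weighted = weighted,
                               keep_models = keep_models)
    occs[[p]] <- occ; pas[[p]] <- pa; sels[[p]] <- sel
  }
  names(scenario$stacks) <- periods
  list(results = results,
       table = build_table(results, study_area_km2 = grid_area_km2(spec)),
       occurrences = occs, pseudo_absences = pas, selections = sels)
}

#' Read a scenario configuration from YAML
#'
#' Top-level keys mirror [scenario_config()] arguments; `niche:` holds
#' [true_niche()] arguments.
#'
#' @param path YAML file path.
#' @return A [scenario_config()].
#' @export
load_scenario_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read scenario files")
  y <- yaml::read_yaml(path)
  niche <- if (is.null(y$niche)) true_niche()
           else do.call(true_niche, y$niche)
  y$niche <- NULL
  do.call(scenario_config, c(y, list(niche = niche)))
}
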