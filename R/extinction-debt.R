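#' Configuration for species-area extinction projections
#'
#' @param z species-area-relationship exponent (default 0.25, the widely
#'   used value).
#' @param reference_fraction fraction of cells used as the reference
#'   sample in the persistence ratio (default 0.20; 1 enumerates all
#'   cells).
#' @param seed seed for the reference subsample.
#' @param geometric_mean_floor floor applied inside the log when
#'   aggregating persistence (guards `log(0)`; default 1e-9).
#' @param cell_weights optional per-cell weights for the aggregate
#'   geometric mean (default uniform).
#' @return An `extinction_config` list.
#' @export
extinction_config <- function(z = 0.25, reference_fraction = 0.20, seed = 1L,
                              geometric_mean_floor = 1e-9,
                              cell_weights = NULL) {
  stopifnot(z > 0, reference_fraction > 0, reference_fraction <= 1,
            geometric_mean_floor > 0)
  structure(list(z = z, reference_fraction = reference_fraction,
                 seed = seed, geometric_mean_floor = geometric_mean_floor,
                 cell_weights = cell_weights),
            class = "extinction_config")
}

#' Seeded uniform subsample of reference cells
#'
#' The same reference set indexes both the numerator and denominator of
#' the persistence ratio, so sampling error largely cancels.
#'
#' @param valid_cells integer vector of candidate cell indices.
#' @param fraction fraction in `(0, 1]`; size is `round(fraction * n)`,
#'   at least 1.
#' @param seed integer seed.
#' @return sorted integer vector of sampled cell indices.
#' @export
subsample_reference_cells <- function(valid_cells, fraction, seed = 1L) {
  if (length(valid_cells) == 0L) stop("empty valid-cell set", call. = FALSE)
  stopifnot(fraction > 0, fraction <= 1)
  n <- max(1L, round(fraction * length(valid_cells)))
  if (n >= length(valid_cells)) return(sort(valid_cells))
  sort(with_seed(seed, sample(valid_cells, n)))
}

#' Bioclimatic similarity between two transformed vectors
#'
#' `Sim = exp(-sum_p |f_a - f_b|)`, i.e. one minus the intercept-free
#' predicted dissimilarity: 1 for identical environments, decaying
#' exponentially with transformed-space separation.
#'
#' @param f_a,f_b transformed predictor vectors from the same model.
#' @return similarity in `(0, 1]`.
#' @export
bioclim_similarity <- function(f_a, f_b) {
  if (length(f_a) != length(f_b)) stop("length mismatch", call. = FALSE)
  exp(-sum(abs(f_a - f_b)))
}

#' Per-cell proportion of species persisting
#'
#' Species-area projection of persistence for every valid cell `i`:
#' `p_i = [ sum_j Sim(i_cur, j_fut) hab_fut[j] /
#'          sum_j Sim(i_cur, j_cur) hab_cur[j] ]^z`
#' over the reference cells `j`, where `Sim` is [bioclim_similarity()].
#' The numerator is the remaining future extent of habitat with a
#' bioclimate similar to cell `i`; the denominator is the potential extent
#' under the current climate, benchmarked against an intact landscape
#' (`hab_cur = 1` by default). Ratios above 1 (future similarity exceeding
#' current) are clipped before exponentiation, so `p_i` lies in `[0, 1]`.
#'
#' @param current,future [gdm_transform()] grids on the same cells.
#' @param hab_future per-cell future habitat condition in `[0, 1]` (a
#'   vector over all cells, or a [habitat_condition_map()] whose
#'   `slice_mean` is used).
#' @param config an [extinction_config()].
#' @param hab_current per-cell current habitat condition (default 1,
#'   the intact benchmark).
#' @return list with `p` (per-cell, `NA` where invalid), `reference_cells`
#'   and `config`.
#' @export
persistence_map <- function(current, future, hab_future,
                            config = extinction_config(),
                            hab_current = NULL) {
  check_same_cells(current, future)
  if (inherits(hab_future, "habitat_condition_map")) {
    hab_future <- hab_future$slice_mean
  }
  ok <- which(current$valid & future$valid)
  stopifnot(length(hab_future) >= max(ok))
  if (any(hab_future[ok] < 0 | hab_future[ok] > 1, na.rm = TRUE)) {
    stop("habitat condition must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(hab_current)) hab_current <- rep(1, length(hab_future))
  ref <- subsample_reference_cells(ok, config$reference_fraction, config$seed)
  sim_fut <- exp(-cross_manhattan(current$values[ok, , drop = FALSE],
                                  future$values[ref, , drop = FALSE]))
  sim_cur <- exp(-cross_manhattan(current$values[ok, , drop = FALSE],
                                  current$values[ref, , drop = FALSE]))
  num <- as.numeric(sim_fut %*% hab_future[ref])
  den <- as.numeric(sim_cur %*% hab_current[ref])
  if (any(den <= 0)) stop("zero denominator in persistence ratio", call. = FALSE)
  p <- rep(NA_real_, length(current$valid))
  p[ok] <- clamp(num / den, 0, 1)^config$z
  list(p = p, reference_cells = ref, config = config)
}

#' Proportion of species persisting in one grid cell
#'
#' Single-cell wrapper around the persistence computation; see
#' [persistence_map()] for the formula.
#'
#' @param cell cell index.
#' @inheritParams persistence_map
#' @return `p_i` in `[0, 1]`.
#' @export
species_persisting <- function(cell, current, future, hab_future,
                               config = extinction_config(),
                               hab_current = NULL) {
  persistence_map(current, future, hab_future, config, hab_current)$p[cell]
}

#' Aggregate persistence and species heading for extinction
#'
#' Regional persistence is the weighted geometric mean of per-cell
#' persistence, `P = exp(sum w_i log(max(p_i, eps)) / sum w_i)`; its
#' complement scaled by the regional species total gives the number of
#' species heading for extinction, `N = S (1 - P)` (reported unrounded and
#' rounded to the nearest integer).
#'
#' @param p per-cell persistence values (`NA` cells are dropped).
#' @param species_total regional species count `S`.
#' @param config an [extinction_config()] (floor `eps`, optional weights).
#' @param weights optional per-cell weights (overrides the config;
#'   default uniform).
#' @return A `persistence_result`: `p_bar`, `n_extinction` (unrounded),
#'   `n_extinction_rounded`, `species_total`, `percent_heading`.
#' @export
aggregate_persistence <- function(p, species_total,
                                  config = extinction_config(),
                                  weights = NULL) {
  ok <- !is.na(p)
  p <- p[ok]
  stopifnot(all(p >= 0 & p <= 1))
  if (is.null(weights)) weights <- config$cell_weights
  if (is.null(weights)) weights <- rep(1, length(p)) else weights <- weights[ok]
  stopifnot(length(weights) == length(p), all(weights >= 0))
  if (sum(weights) == 0) stop("all cell weights are zero", call. = FALSE)
  eps <- config$geometric_mean_floor
  p_bar <- exp(sum(weights * log(pmax(p, eps))) / sum(weights))
  n <- species_total * (1 - p_bar)
  structure(list(p_bar = p_bar, n_extinction = n,
                 n_extinction_rounded = round(n),
                 species_total = species_total,
                 percent_heading = 100 * (1 - p_bar)),
            class = "persistence_result")
}

#' @export
print.persistence_result <- function(x, ...) {
  cat(sprintf(
    "persistence_result: P = %.4f; %.1f of %d species heading for extinction (%.1f%%)\n",
    x$p_bar, x$n_extinction, x$species_total, x$percent_heading))
  invisible(x)
}

#' Compare species-heading-for-extinction counts across scenarios
#'
#' Presentation arithmetic over extinction counts: the percent reduction
#' from scenario A to scenario B, `100 (N_A - N_B) / N_A` (rounded to an
#' integer); the ratio of each count to historic extinctions (one
#' decimal); and each count as a percent of the regional fauna (integer).
#'
#' @param counts named numeric vector of extinction counts `N` per
#'   scenario.
#' @param species_total shared regional species count `S`.
#' @param historic_extinctions historic extinction count for the ratio
#'   (optional).
#' @param worst,best scenario names for the headline reduction (defaults:
#'   the largest and smallest counts).
#' @return list with `table` (per-scenario `N`, `percent_of_fauna`,
#'   `ratio_to_historic`) and `reduction_pct` (worst -> best; `NA` flagged
#'   when the worst count is 0).
#' @export
scenario_comparison <- function(counts, species_total,
                                historic_extinctions = NULL,
                                worst = NULL, best = NULL) {
  stopifnot(!is.null(names(counts)), all(counts >= 0))
  if (is.null(worst)) worst <- names(counts)[which.max(counts)]
  if (is.null(best)) best <- names(counts)[which.min(counts)]
  tab <- data.frame(
    scenario = names(counts), n_extinction = as.numeric(counts),
    percent_of_fauna = round(100 * counts / species_total))
  if (!is.null(historic_extinctions)) {
    tab$ratio_to_historic <- round(counts / historic_extinctions, 1)
  }
  reduction <- if (counts[[worst]] == 0) NA_real_ else
    round(100 * (counts[[worst]] - counts[[best]]) / counts[[worst]])
  list(table = tab, worst = worst, best = best, reduction_pct = reduction)
}
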