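#' Configuration for bioclimate projection metrics
#'
#' @param dissimilarity_threshold threshold `tau` above which a minimum
#'   dissimilarity marks a bioclimate as disappearing/novel (default 0.10,
#'   a balance between labelling every pair different and still detecting
#'   analogues).
#' @param include_intercept include the model intercept in predicted
#'   dissimilarities (default `FALSE`: no change is predicted when the
#'   environment does not change).
#' @param seed seed for any subsampling (unused by the exact scans).
#' @return A `metric_config` list.
#' @export
metric_config <- function(dissimilarity_threshold = 0.10,
                          include_intercept = FALSE, seed = 1L) {
  if (dissimilarity_threshold <= 0 || dissimilarity_threshold >= 1) {
    stop("`dissimilarity_threshold` must be in (0, 1)", call. = FALSE)
  }
  structure(list(dissimilarity_threshold = dissimilarity_threshold,
                 include_intercept = include_intercept, seed = seed),
            class = "metric_config")
}

check_same_cells <- function(current, future) {
  stopifnot(inherits(current, "transformed_grid"),
            inherits(future, "transformed_grid"))
  if (!identical(current$dims, future$dims) ||
      !identical(colnames(current$values), colnames(future$values))) {
    stop("current and future grids must share cells and model predictors",
         call. = FALSE)
  }
}

#' Per-cell compositional change between two epochs
#'
#' The predicted dissimilarity between each cell's current and future
#' transformed environment, with the intercept removed, so an unchanged
#' environment yields exactly zero change.
#'
#' @param model the shared `gdm_model`.
#' @param current,future [gdm_transform()] grids on the same cells.
#' @param config a [metric_config()].
#' @return list with `values` (per cell, `NA` where invalid), `median`,
#'   `iqr`, and `n_valid`.
#' @export
compositional_change <- function(model, current, future,
                                 config = metric_config()) {
  check_same_cells(current, future)
  ok <- current$valid & future$valid
  eta <- rowSums(abs(current$values - future$values))
  if (config$include_intercept) eta <- eta + model$intercept
  vals <- ifelse(ok, 1 - exp(-eta), NA_real_)
  q <- stats::quantile(vals[ok], c(0.25, 0.5, 0.75), names = FALSE)
  list(values = vals, median = q[2], iqr = c(lower = q[1], upper = q[3]),
       n_valid = sum(ok))
}

# Shared forward/backward minimum-dissimilarity scan. Exact double loop
# over all cells (no subsampling at package scale).
min_dissimilarity_scan <- function(model, from, to, config) {
  ok_from <- from$valid; ok_to <- to$valid
  if (!any(ok_to)) stop("no valid cells in the comparison grid", call. = FALSE)
  mins <- rep(NA_real_, length(ok_from))
  eta <- min_cross_manhattan(from$values[ok_from, , drop = FALSE],
                             to$values[ok_to, , drop = FALSE])
  if (config$include_intercept) eta <- eta + model$intercept
  mins[ok_from] <- 1 - exp(-eta)
  mask <- mins >= config$dissimilarity_threshold
  list(min_dissimilarity = mins, mask = mask,
       area_pct = 100 * sum(mask, na.rm = TRUE) / sum(ok_from))
}

#' Disappearing bioclimates
#'
#' For each current cell, the minimum predicted dissimilarity (intercept
#' removed) to any future cell. Cells whose minimum is at or above the
#' threshold have no close future analogue anywhere in the region: their
#' bioclimate disappears. The scan is exact over all cells.
#'
#' @inheritParams compositional_change
#' @return list with `min_dissimilarity` (per current cell), `mask`
#'   (logical, `>= tau`), `area_pct` (percent of valid cells masked).
#' @export
disappearing_bioclimates <- function(model, current, future,
                                     config = metric_config()) {
  check_same_cells(current, future)
  min_dissimilarity_scan(model, from = current, to = future, config = config)
}

#' Novel bioclimates
#'
#' Mirror image of [disappearing_bioclimates()]: for each future cell, the
#' minimum predicted dissimilarity to any current cell. Future cells with
#' no close current analogue are novel. Swapping the epochs swaps the two
#' metrics exactly.
#'
#' @inheritParams compositional_change
#' @return list as in [disappearing_bioclimates()], indexed by future cell.
#' @export
novel_bioclimates <- function(model, current, future,
                              config = metric_config()) {
  check_same_cells(current, future)
  min_dissimilarity_scan(model, from = future, to = current, config = config)
}

#' Overlap between disappearing and novel masks
#'
#' Jaccard index `J = |D intersect N| / |D union N|` (0 when the union is
#' empty) and the conditional probability that a disappearing cell is
#' replaced by a novel bioclimate, `P(novel | disappearing) =
#' |D intersect N| / |D|` (`NA` and flagged when no cell disappears).
#'
#' @param disappearing_mask,novel_mask logical vectors on the same cells
#'   (`NA` allowed for invalid cells).
#' @return list with `jaccard`, `conditional_replacement`, and the three
#'   cell counts.
#' @export
overlap_summary <- function(disappearing_mask, novel_mask) {
  if (length(disappearing_mask) != length(novel_mask)) {
    stop("masks must be on the same cells", call. = FALSE)
  }
  d <- which(disappearing_mask); n <- which(novel_mask)
  both <- length(intersect(d, n)); un <- length(union(d, n))
  list(jaccard = if (un == 0L) 0 else both / un,
       conditional_replacement = if (length(d) == 0L) NA_real_ else
         both / length(d),
       n_disappearing = length(d), n_novel = length(n), n_both = both)
}

#' Spearman rank correlation between two per-cell metric maps
#'
#' Reporting utility for cross-taxon (or cross-metric) spatial agreement;
#' uses average ranks for ties and drops cells invalid in either map.
#'
#' @param a,b numeric per-cell vectors (`NA` for invalid cells).
#' @return Spearman's rho.
#' @export
map_rank_correlation <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  stats::cor(a[ok], b[ok], method = "spearman")
}

#' Summarise projection metrics for one scenario x slice
#'
#' Bundles [compositional_change()], [disappearing_bioclimates()],
#' [novel_bioclimates()] and [overlap_summary()] into one report.
#'
#' @inheritParams compositional_change
#' @return list with the four component results plus the scenario tags.
#' @export
bioclimate_summary <- function(model, current, future,
                               config = metric_config()) {
  cc <- compositional_change(model, current, future, config)
  dis <- disappearing_bioclimates(model, current, future, config)
  nov <- novel_bioclimates(model, current, future, config)
  ov <- overlap_summary(dis$mask, nov$mask)
  list(scenario = future$scenario, slice = future$slice,
       compositional_change = cc, disappearing = dis, novel = nov,
       overlap = ov)
}
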