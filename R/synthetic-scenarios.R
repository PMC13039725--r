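#' Specification of a combined climate / land-use scenario
#'
#' Couples a per-decade additive climate trend with an annual Markov
#' land-use transition matrix over a span of years, in the style of paired
#' emission (RCP) and socioeconomic (SSP) storylines.
#'
#' @param name scenario label, e.g. `"RCP2.6-SSP1"`.
#' @param climate_shift_severity named numeric vector: additive shift per
#'   decade for each climate variable it names (unnamed variables stay
#'   unchanged).
#' @param landuse_transition square row-stochastic matrix of annual
#'   class-to-class transition probabilities, with matching row/col names.
#' @param years ordered integer vector of scenario years.
#' @param time_slices list of `c(start, end)` year windows within `years`.
#' @return A `scenario_spec` object.
#' @export
scenario_spec <- function(name, climate_shift_severity, landuse_transition,
                          years, time_slices) {
  years <- as.integer(years)
  stopifnot(length(years) >= 2L, !is.unsorted(years))
  landuse_transition <- as.matrix(landuse_transition)
  if (nrow(landuse_transition) != ncol(landuse_transition) ||
      is.null(rownames(landuse_transition)) ||
      !identical(rownames(landuse_transition), colnames(landuse_transition))) {
    stop("`landuse_transition` must be square with matching dimnames",
         call. = FALSE)
  }
  if (any(landuse_transition < 0) ||
      any(abs(rowSums(landuse_transition) - 1) > 1e-8)) {
    stop("`landuse_transition` rows must be probabilities summing to 1",
         call. = FALSE)
  }
  for (sl in time_slices) {
    if (length(sl) != 2L || sl[1] > sl[2] ||
        sl[1] < years[1] || sl[2] > years[length(years)]) {
      stop("each time slice must be (start, end) within the scenario years",
           call. = FALSE)
    }
  }
  structure(list(name = name,
                 climate_shift_severity = climate_shift_severity,
                 landuse_transition = landuse_transition,
                 years = years, time_slices = time_slices),
            class = "scenario_spec")
}

#' Project a landscape's climate into a future time slice
#'
#' Climate variables are shifted by `severity * decades elapsed` between the
#' scenario's first year and the slice midpoint; static variables are left
#' unchanged. This is the deliberately simple stand-in for bias-corrected
#' regional climate projections: smooth, monotone-in-time trends of tunable
#' severity.
#'
#' @param env a current-epoch [env_grid()].
#' @param scenario a [scenario_spec()].
#' @param slice `c(start, end)` years; must fall within the scenario years.
#' @return A future-epoch [env_grid()] tagged with the scenario and slice.
#' @export
generate_future_climate <- function(env, scenario, slice) {
  stopifnot(inherits(env, "env_grid"), inherits(scenario, "scenario_spec"))
  yr <- scenario$years
  if (slice[1] < yr[1] || slice[2] > yr[length(yr)]) {
    stop("slice outside scenario years", call. = FALSE)
  }
  decades <- (mean(slice) - yr[1]) / 10
  out <- env
  sev <- scenario$climate_shift_severity
  for (v in names(sev)) {
    if (!v %in% colnames(out$values)) next
    if (out$var_types[v] != "climate") next
    out$values[, v] <- out$values[, v] + sev[[v]] * decades
  }
  out$epoch <- "future"
  out$scenario <- scenario$name
  out$slice <- slice
  out
}

#' Evolve per-cell land-use classes as a Markov chain
#'
#' Each cell's class evolves independently year-on-year under the
#' scenario's annual transition matrix, starting from a seeded random (or
#' supplied) initial map. Deterministic under the seed.
#'
#' @param scenario a [scenario_spec()] (its transition matrix and years).
#' @param classes character vector of classes; must match the transition
#'   matrix dimnames.
#' @param n_cells number of cells.
#' @param seed integer seed.
#' @param init optional initial class vector (length `n_cells`); default is
#'   a uniform seeded draw.
#' @return character matrix, cells x years (column names are the years).
#' @export
generate_landuse <- function(scenario, classes, n_cells, seed = 1L,
                             init = NULL) {
  stopifnot(inherits(scenario, "scenario_spec"))
  P <- scenario$landuse_transition
  if (!identical(sort(classes), sort(rownames(P)))) {
    stop("`classes` must match the transition matrix classes", call. = FALSE)
  }
  years <- scenario$years
  with_seed(seed, {
    state <- if (is.null(init)) sample(classes, n_cells, replace = TRUE) else init
    stopifnot(length(state) == n_cells, all(state %in% classes))
    out <- matrix(NA_character_, n_cells, length(years),
                  dimnames = list(NULL, years))
    out[, 1] <- state
    for (t in seq_along(years)[-1]) {
      steps <- years[t] - years[t - 1]
      Pt <- P
      if (steps > 1) for (s in seq_len(steps - 1)) Pt <- Pt %*% P
      for (cl in classes) {
        idx <- which(state == cl)
        if (length(idx)) {
          state[idx] <- sample(colnames(P), length(idx), replace = TRUE,
                               prob = Pt[cl, ])
        }
      }
      out[, t] <- state
    }
    out
  })
}

#' Stationary distribution of a land-use transition matrix
#'
#' Left eigenvector of the transition matrix for eigenvalue 1, normalised
#' to sum to one. Used to check long-run class frequencies of
#' [generate_landuse()].
#' @param transition row-stochastic matrix.
#' @return named numeric vector of stationary class frequencies.
#' @export
landuse_stationary_distribution <- function(transition) {
  e <- eigen(t(transition))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  stats::setNames(v / sum(v), rownames(transition))
}

#' Generate a multi-study site x species abundance table
#'
#' Emulates a PREDICTS-style collation: `n_studies` independent studies,
#' each with its own species pool and reference community, sites assigned
#' to land-use classes (always at least one reference site per study),
#' varying sampling effort, and an NPP covariate elevated on agricultural
#' classes. Ground truth per class: an abundance factor (total abundance
#' relative to reference) and a compositional-similarity factor (fraction
#' of the reference community retained; the remainder is replaced by a
#' disturbance-associated species set). The generator returns its truth so
#' the BII estimator can be scored against it.
#'
#' @param classes character vector of land-use classes; the first is the
#'   reference class.
#' @param n_studies number of studies (default 30).
#' @param sites_per_study sites per study (default 12).
#' @param n_species species-pool size per study (default 40).
#' @param seed integer seed.
#' @param class_ab_truth,class_cs_truth named numeric vectors in `(0, 1]`
#'   per class (defaults decline away from the reference class).
#' @param noise_sd lognormal abundance noise (default 0.15).
#' @return list with `sites` (study, site, land_use, effort, npp, x, y,
#'   climate covariates), `abundance` (sites x species matrix),
#'   `reference_class` and `truth` (`ab`, `cs` vectors).
#' @export
generate_predicts_like <- function(classes, n_studies = 30L,
                                   sites_per_study = 12L, n_species = 40L,
                                   seed = 1L,
                                   class_ab_truth = NULL,
                                   class_cs_truth = NULL,
                                   noise_sd = 0.15) {
  stopifnot(length(classes) >= 2L, sites_per_study >= 2L)
  ref <- classes[1]
  k <- length(classes)
  if (is.null(class_ab_truth)) {
    class_ab_truth <- stats::setNames(seq(1, 0.45, length.out = k), classes)
  }
  if (is.null(class_cs_truth)) {
    class_cs_truth <- stats::setNames(seq(1, 0.55, length.out = k), classes)
  }
  stopifnot(all(classes %in% names(class_ab_truth)),
            all(classes %in% names(class_cs_truth)))
  ag_classes <- grep("agric|pastoral|arable", classes, value = TRUE)
  with_seed(seed, {
    sites <- list(); abund <- list()
    for (st in seq_len(n_studies)) {
      # reference community and a disjoint disturbance community
      a <- stats::rlnorm(n_species, meanlog = 1, sdlog = 1)
      b <- stats::rlnorm(n_species, meanlog = 1, sdlog = 1)
      lu <- c(ref, sample(classes, sites_per_study - 1L, replace = TRUE))
      effort <- stats::runif(sites_per_study, 0.5, 2)
      xy <- matrix(stats::runif(sites_per_study * 2, 0, 5), ncol = 2)
      npp_base <- stats::runif(1, 0.5, 1.5)
      npp <- npp_base + 0.5 * (lu %in% ag_classes) +
        stats::rnorm(sites_per_study, sd = 0.1)
      npp <- pmax(npp, 0.05)
      clim <- matrix(stats::rnorm(sites_per_study * 2), ncol = 2,
                     dimnames = list(NULL, c("temp", "precip")))
      ab_m <- matrix(0, sites_per_study, 2L * n_species)
      for (i in seq_len(sites_per_study)) {
        f_ab <- class_ab_truth[[lu[i]]]
        f_cs <- class_cs_truth[[lu[i]]]
        mix <- c(f_cs * a, (1 - f_cs) * b)
        noise <- stats::rlnorm(2L * n_species, sdlog = noise_sd)
        # observed counts are effort-sensitive; estimator divides back out
        ab_m[i, ] <- f_ab * mix * noise * effort[i]
      }
      sites[[st]] <- data.frame(study = paste0("study", st),
                                site = paste0("study", st, "_s",
                                              seq_len(sites_per_study)),
                                land_use = lu, effort = effort,
                                npp = npp, x = xy[, 1], y = xy[, 2],
                                temp = clim[, 1], precip = clim[, 2])
      abund[[st]] <- ab_m
    }
    list(sites = do.call(rbind, sites),
         abundance = do.call(rbind, abund),
         reference_class = ref,
         truth = list(ab = class_ab_truth, cs = class_cs_truth))
  })
}
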