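#' Standardise and rescale site abundances within studies
#'
#' Site total abundance is divided by sampling effort (so effort-sensitive
#' counts become comparable within a study), then divided by the study
#' maximum so the largest value in each study equals one. A study whose
#' sites are all zero is left unrescaled and flagged.
#'
#' @param abundance sites x species matrix (or a vector of site totals).
#' @param effort positive numeric per site.
#' @param study factor/character per site.
#' @return list with `rescaled` (per-site values in `[0, 1]`) and
#'   `flagged_studies` (all-zero studies skipped).
#' @export
standardise_and_rescale_abundance <- function(abundance, effort, study) {
  totals <- if (is.matrix(abundance)) rowSums(abundance) else as.numeric(abundance)
  stopifnot(length(effort) == length(totals), all(effort > 0),
            length(study) == length(totals))
  std <- totals / effort
  rescaled <- std
  flagged <- character(0)
  for (st in unique(study)) {
    idx <- study == st
    mx <- max(std[idx])
    if (mx <= 0) {
      flagged <- c(flagged, as.character(st))
    } else {
      rescaled[idx] <- std[idx] / mx
    }
  }
  list(rescaled = rescaled, flagged_studies = flagged)
}

#' Balanced-variation component of abundance-based Bray-Curtis
#'
#' With `A = sum_k min(x_k, y_k)`, `B = sum_k (x_k - min)`,
#' `C = sum_k (y_k - min)`, the balanced-variation dissimilarity is
#' `d_bal = min(B, C) / (A + min(B, C))` — the substitution part of
#' Bray-Curtis, insensitive to pure abundance-gradient differences.
#' Compositional similarity is `1 - d_bal`; by convention it is 0 when
#' either site has no individuals.
#'
#' @param x,y equal-length non-negative abundance vectors.
#' @return list with `A`, `B`, `C`, `d_bal`, `similarity`.
#' @export
bc_balanced_dissimilarity <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length", call. = FALSE)
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative", call. = FALSE)
  if (sum(x) == 0 || sum(y) == 0) {
    return(list(A = sum(pmin(x, y)), B = sum(x) - sum(pmin(x, y)),
                C = sum(y) - sum(pmin(x, y)), d_bal = 1, similarity = 0))
  }
  A <- sum(pmin(x, y))
  B <- sum(x) - A
  C <- sum(y) - A
  denom <- A + min(B, C)
  d_bal <- if (denom == 0) 0 else min(B, C) / denom
  list(A = A, B = B, C = C, d_bal = d_bal, similarity = 1 - d_bal)
}

#' Adjusted logit transform (and its inverse)
#'
#' Compresses `[0, 1]` similarities away from the boundaries by
#' `s' = adj + (1 - 2 adj) s` and then takes `log(s' / (1 - s'))`, so
#' zeros and ones remain finite. The inverse undoes both steps exactly.
#'
#' @param s similarity in `[0, 1]` (forward) or a transformed value
#'   (inverse).
#' @param adj adjustment in `(0, 0.5)` (default 0.05).
#' @return transformed (or back-transformed) numeric.
#' @export
logit_adjusted <- function(s, adj = 0.05) {
  if (adj <= 0 || adj >= 0.5) stop("`adj` must be in (0, 0.5)", call. = FALSE)
  sp <- adj + (1 - 2 * adj) * s
  log(sp / (1 - sp))
}

#' @rdname logit_adjusted
#' @export
inv_logit_adjusted <- function(s, adj = 0.05) {
  if (adj <= 0 || adj >= 0.5) stop("`adj` must be in (0, 0.5)", call. = FALSE)
  (stats::plogis(s) - adj) / (1 - 2 * adj)
}

#' Gower environmental distance between two sites
#'
#' Mean over variables of `|x_a - x_b| / range`; in `[0, 1]` when values
#' lie within the stated ranges. Zero-range variables are dropped with a
#' warning. `cube_root = TRUE` returns the cube-root transformed variant
#' used as the modelling covariate.
#'
#' @param site_a,site_b named numeric vectors of shared variables.
#' @param ranges named numeric vector of variable ranges.
#' @param cube_root return `distance^(1/3)` (default `FALSE`).
#' @return distance in `[0, 1]`.
#' @export
gower_env_distance <- function(site_a, site_b, ranges, cube_root = FALSE) {
  vars <- intersect(names(site_a), names(site_b))
  vars <- intersect(vars, names(ranges))
  if (length(vars) == 0L) stop("no shared variables", call. = FALSE)
  zero <- vars[ranges[vars] == 0]
  if (length(zero)) {
    warning("dropping zero-range variable(s): ", paste(zero, collapse = ", "),
            call. = FALSE)
    vars <- setdiff(vars, zero)
    if (length(vars) == 0L) stop("no variables with nonzero range", call. = FALSE)
  }
  d <- mean(abs(site_a[vars] - site_b[vars]) / ranges[vars])
  if (cube_root) d^(1/3) else d
}

#' Estimate per-class BII coefficients from a multi-study table
#'
#' Simplified fixed-effects version of the two-model Biodiversity
#' Intactness Index estimator. The abundance coefficient comes from a
#' least-squares fit of square-root rescaled abundance on land-use class
#' and square-root NPP with per-study intercepts; the predicted
#' class/reference ratio is squared (back-transform) and clipped to
#' `[0, 1]`. The compositional-similarity coefficient comes from a
#' least-squares fit of adjusted-logit similarity (balanced Bray-Curtis,
#' reference sites vs every other site within study) on the class
#' transition, third-degree polynomials of log geographic distance and
#' cube-root Gower environmental distance, and square-root NPP; the class
#' effect is back-transformed at zero distance and expressed relative to
#' the reference-to-reference prediction. The combined BII per class is
#' the product, clipped to `[0, 1]`; the reference class has BII 1 by
#' construction.
#'
#' @param predicts a [generate_predicts_like()] style list (`sites`,
#'   `abundance`, `reference_class`) or equivalent.
#' @param adj logit adjustment (default 0.05).
#' @return A `bii_table` data.frame: `class`, `ab_coef`, `cs_coef`, `bii`
#'   (`NA` and flagged for classes absent from the data).
#' @export
estimate_bii_coefficients <- function(predicts, adj = 0.05) {
  sites <- predicts$sites
  abund <- predicts$abundance
  ref <- predicts$reference_class
  classes <- unique(c(ref, sites$land_use))
  if (!any(sites$land_use == ref)) {
    stop("at least one reference-class site per study required", call. = FALSE)
  }

  # --- abundance model ---
  resc <- standardise_and_rescale_abundance(abund, sites$effort, sites$study)
  dat <- data.frame(y = sqrt(resc$rescaled),
                    land_use = factor(sites$land_use, levels = classes),
                    study = factor(sites$study),
                    sqrt_npp = sqrt(sites$npp))
  fit_ab <- stats::lm(y ~ 0 + study + land_use + sqrt_npp, data = dat)
  cf <- stats::coef(fit_ab)
  # reference prediction: study intercepts at reference-site NPP levels
  base <- mean(cf[grep("^study", names(cf))]) +
    cf[["sqrt_npp"]] * mean(dat$sqrt_npp[dat$land_use == ref])
  ab_coef <- stats::setNames(rep(NA_real_, length(classes)), classes)
  ab_coef[ref] <- 1
  for (cl in setdiff(classes, ref)) {
    nm <- paste0("land_use", cl)
    if (nm %in% names(cf) && !is.na(cf[[nm]])) {
      ab_coef[cl] <- clamp(((base + cf[[nm]]) / base)^2, 0, 1)
    }
  }

  # --- compositional-similarity model ---
  env_vars <- intersect(c("temp", "precip"), names(sites))
  ranges <- vapply(env_vars, function(v) diff(range(sites[[v]])), numeric(1))
  rows <- list()
  for (st in unique(sites$study)) {
    idx <- which(sites$study == st)
    ref_idx <- idx[sites$land_use[idx] == ref]
    if (length(ref_idx) == 0L) next
    for (r in ref_idx) for (s in idx) {
      if (s == r) next
      sim <- bc_balanced_dissimilarity(abund[r, ], abund[s, ])$similarity
      gd <- sqrt((sites$x[r] - sites$x[s])^2 + (sites$y[r] - sites$y[s])^2)
      ed <- if (length(env_vars)) {
        gower_env_distance(
          stats::setNames(as.numeric(sites[r, env_vars]), env_vars),
          stats::setNames(as.numeric(sites[s, env_vars]), env_vars),
          ranges, cube_root = TRUE)
      } else 0
      rows[[length(rows) + 1L]] <- data.frame(
        ls = logit_adjusted(sim, adj), class2 = sites$land_use[s],
        study = st, log_gd = log1p(gd), cbrt_ed = ed,
        sqrt_npp = sqrt(sites$npp[s]))
    }
  }
  pd <- do.call(rbind, rows)
  pd$class2 <- factor(pd$class2, levels = classes)
  pd$study <- factor(pd$study)
  fit_cs <- stats::lm(
    ls ~ 0 + study + class2 + poly(log_gd, 3, raw = TRUE) +
      poly(cbrt_ed, 3, raw = TRUE) + sqrt_npp, data = pd)
  cfs <- stats::coef(fit_cs)
  cfs[is.na(cfs)] <- 0
  base_cs <- mean(cfs[grep("^study", names(cfs))]) +
    cfs[["sqrt_npp"]] * mean(pd$sqrt_npp[pd$class2 == ref])  # zero distance
  s_ref <- inv_logit_adjusted(base_cs, adj)
  cs_coef <- stats::setNames(rep(NA_real_, length(classes)), classes)
  cs_coef[ref] <- 1
  for (cl in setdiff(classes, ref)) {
    nm <- paste0("class2", cl)
    if (nm %in% names(cfs) && cl %in% pd$class2) {
      s_cl <- inv_logit_adjusted(base_cs + cfs[[nm]], adj)
      cs_coef[cl] <- clamp(s_cl / s_ref, 0, 1)
    }
  }

  bii_table(data.frame(class = classes,
                       ab_coef = as.numeric(ab_coef[classes]),
                       cs_coef = as.numeric(cs_coef[classes]),
                       bii = clamp(as.numeric(ab_coef[classes]) *
                                     as.numeric(cs_coef[classes]), 0, 1)))
}

#' Construct / validate a BII coefficient table
#'
#' One row per harmonised land-use class: abundance coefficient,
#' compositional-similarity coefficient, and combined `bii` in `[0, 1]`.
#' Dynamic classes (hyper-intensive land uses whose intensity keeps rising
#' in high-development futures) carry interpolation endpoints
#' `(year_start, bii_start, year_end, bii_end)` with
#' `bii_end <= bii_start`.
#'
#' @param df data.frame with at least `class` and `bii`; optional
#'   `ab_coef`, `cs_coef`, `dynamic`, `year_start`, `bii_start`,
#'   `year_end`, `bii_end`.
#' @return A `bii_table`.
#' @export
bii_table <- function(df) {
  stopifnot(is.data.frame(df), all(c("class", "bii") %in% names(df)))
  if (!"dynamic" %in% names(df)) df$dynamic <- FALSE
  ok <- !is.na(df$bii)
  if (any(df$bii[ok] < 0 | df$bii[ok] > 1)) {
    stop("`bii` must lie in [0, 1]", call. = FALSE)
  }
  dyn <- which(df$dynamic)
  if (length(dyn)) {
    need <- c("year_start", "bii_start", "year_end", "bii_end")
    stopifnot(all(need %in% names(df)))
    if (any(df$bii_end[dyn] > df$bii_start[dyn])) {
      stop("dynamic classes require bii_end <= bii_start", call. = FALSE)
    }
  }
  structure(df, class = c("bii_table", "data.frame"))
}

#' Adjust an urban BII for impervious cover
#'
#' The impermeable fraction of urban land supports no biodiversity, so the
#' urban coefficient is scaled by the permeable fraction:
#' `(1 - imperviousness) * b_urban`. Default imperviousness 0.30 (mean UK
#' urban imperviousness).
#'
#' @param b_urban unadjusted urban BII in `[0, 1]`.
#' @param imperviousness impervious fraction in `[0, 1]` (default 0.30).
#' @return adjusted BII.
#' @export
adjust_urban <- function(b_urban, imperviousness = 0.30) {
  stopifnot(b_urban >= 0, b_urban <= 1,
            imperviousness >= 0, imperviousness <= 1)
  (1 - imperviousness) * b_urban
}

#' Agroforestry BII as the mean of its component systems
#'
#' Agroforestry mixes woodland and low-intensity farming, so its BII is the
#' arithmetic mean of sustainable agriculture, extensive pastoral and
#' productive forestry.
#'
#' @param b_sustainable_ag,b_extensive_pastoral,b_productive_forestry BII
#'   values in `[0, 1]`.
#' @return mean BII.
#' @export
agroforestry_bii <- function(b_sustainable_ag, b_extensive_pastoral,
                             b_productive_forestry) {
  vals <- c(b_sustainable_ag, b_extensive_pastoral, b_productive_forestry)
  stopifnot(all(vals >= 0 & vals <= 1))
  mean(vals)
}

#' Time-varying BII of a hyper-intensive land-use class
#'
#' Before `year_start` the class behaves like its intensive counterpart
#' (`bii_start`); between the endpoints the BII declines linearly as
#' intensity rises beyond present-day levels; after `year_end` intensity
#' plateaus and the BII stays at `bii_end`. Default endpoints
#' `(2037, 0.63, 2070, 0.50)` follow the hyper-intensive pastoral
#' trajectory under a fossil-fuelled development pathway.
#'
#' @param year calendar year (vectorised).
#' @param endpoints numeric `c(year_start, bii_start, year_end, bii_end)`
#'   with `bii_end <= bii_start`.
#' @return BII at `year`.
#' @export
hyper_intensive_bii <- function(year, endpoints = c(2037, 0.63, 2070, 0.50)) {
  ys <- endpoints[1]; bs <- endpoints[2]; ye <- endpoints[3]; be <- endpoints[4]
  if (be > bs) stop("bii_end must not exceed bii_start", call. = FALSE)
  stopifnot(ye > ys)
  frac <- clamp((year - ys) / (ye - ys), 0, 1)
  bs + frac * (be - bs)
}

#' Default synthetic BII coefficient table
#'
#' Plausible per-class coefficients for the bundled synthetic land-use
#' classes (these are package defaults for synthetic scenarios, not
#' empirical estimates): the semi-natural reference at 1, declining
#' through extensive and sustainable systems to intensive agriculture,
#' with the urban class pre-adjusted for 30% impervious cover, the
#' agroforestry class the mean of its components, and dynamic
#' hyper-intensive classes declining linearly over 2037-2070 (about 21%
#' for pastoral, 11% for agriculture, relative to their intensive
#' counterparts' starting values).
#'
#' @return A [bii_table()].
#' @export
default_bii_table <- function() {
  b_ext_pas <- 0.90; b_sus_ag <- 0.80; b_for <- 0.77
  b_int_pas <- 0.63; b_int_ag <- 0.45; b_urban_raw <- 0.55
  df <- data.frame(
    class = c("seminatural", "extensive_pastoral", "sustainable_agriculture",
              "productive_forestry", "agroforestry", "intensive_pastoral",
              "intensive_agriculture", "urban",
              "hyper_intensive_pastoral", "hyper_intensive_agriculture"),
    ab_coef = NA_real_, cs_coef = NA_real_,
    bii = c(1, b_ext_pas, b_sus_ag, b_for,
            agroforestry_bii(b_sus_ag, b_ext_pas, b_for),
            b_int_pas, b_int_ag, adjust_urban(b_urban_raw),
            b_int_pas, b_int_ag),
    dynamic = c(rep(FALSE, 8), TRUE, TRUE),
    year_start = c(rep(NA, 8), 2037, 2037),
    bii_start = c(rep(NA, 8), 0.63, b_int_ag),
    year_end = c(rep(NA, 8), 2070, 2070),
    bii_end = c(rep(NA, 8), 0.50, round(b_int_ag * 0.89, 2))
  )
  bii_table(df)
}

# BII of one class at one (vector of) year(s), honouring dynamic classes.
bii_value <- function(table, class, year) {
  row <- which(table$class == class)
  if (length(row) != 1L) {
    stop("land-use class without a BII entry: ", class, call. = FALSE)
  }
  if (isTRUE(table$dynamic[row])) {
    hyper_intensive_bii(year, c(table$year_start[row], table$bii_start[row],
                                table$year_end[row], table$bii_end[row]))
  } else {
    rep(table$bii[row], length(year))
  }
}

#' Build per-cell habitat condition maps from land use and BII
#'
#' Habitat condition of a cell in a year is the BII of its land-use class
#' in that year (dynamic classes interpolate over time). The slice value is
#' the mean over the map years falling inside the slice window, so it is
#' always bounded by the yearly extremes.
#'
#' @param landuse character matrix cells x years (column names are years),
#'   as from [generate_landuse()].
#' @param table a [bii_table()] covering every class present.
#' @param slice optional `c(start, end)` years; when supplied the result
#'   also carries the per-slice mean.
#' @return A `habitat_condition_map`: `yearly` (cells x years numeric
#'   matrix in `[0, 1]`) and, if `slice` given, `slice_mean` (per cell)
#'   and `slice`.
#' @export
habitat_condition_map <- function(landuse, table, slice = NULL) {
  stopifnot(inherits(table, "bii_table"))
  years <- as.integer(colnames(landuse))
  classes <- unique(as.vector(landuse))
  missing_cls <- setdiff(classes, table$class)
  if (length(missing_cls)) {
    stop("land-use class without a BII entry: ",
         paste(missing_cls, collapse = ", "), call. = FALSE)
  }
  yearly <- matrix(NA_real_, nrow(landuse), length(years),
                   dimnames = list(NULL, years))
  for (cl in classes) {
    bv <- bii_value(table, cl, years)
    for (t in seq_along(years)) {
      idx <- landuse[, t] == cl
      yearly[idx, t] <- bv[t]
    }
  }
  out <- list(yearly = clamp(yearly, 0, 1), years = years)
  if (!is.null(slice)) {
    in_slice <- years >= slice[1] & years <= slice[2]
    if (!any(in_slice)) stop("no map years inside the slice", call. = FALSE)
    out$slice <- slice
    out$slice_mean <- rowMeans(yearly[, in_slice, drop = FALSE])
  }
  structure(out, class = "habitat_condition_map")
}
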