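#' Specification for a synthetic environmental landscape
#'
#' Defines the grid size, variable counts and soil-gap fraction for
#' [generate_landscape()]. Defaults mirror the study design this package
#' emulates: three static variables (terrain ruggedness, topographic
#' wetness, soil pH) and seven climate variables (temperature extremes,
#' diurnal range, precipitation totals and seasonality, dry-season
#' evapotranspiration, sunshine).
#'
#' @param grid_dims integer `c(rows, cols)`; cells are unit squares.
#' @param n_static_vars number of static variables (default 3).
#' @param n_climate_vars number of climate variables (default 7).
#' @param missing_fraction fraction of cells whose soil value is missing and
#'   must be interpolated (default 0.1, in `[0, 1)`).
#' @param seed integer seed; the same spec is bit-reproducible.
#' @return A `landscape_spec` list.
#' @export
landscape_spec <- function(grid_dims = c(20L, 20L), n_static_vars = 3L,
                           n_climate_vars = 7L, missing_fraction = 0.1,
                           seed = 1L) {
  grid_dims <- as.integer(grid_dims)
  if (length(grid_dims) != 2L || any(grid_dims <= 0L)) {
    stop("`grid_dims` must be two positive integers", call. = FALSE)
  }
  if (missing_fraction < 0 || missing_fraction >= 1) {
    stop("`missing_fraction` must be in [0, 1)", call. = FALSE)
  }
  stopifnot(n_static_vars >= 1L, n_climate_vars >= 1L)
  structure(list(grid_dims = grid_dims,
                 n_static_vars = as.integer(n_static_vars),
                 n_climate_vars = as.integer(n_climate_vars),
                 missing_fraction = missing_fraction,
                 seed = as.integer(seed)),
            class = "landscape_spec")
}

# Canonical variable names; extra variables beyond the named set get
# generic names so non-default counts still work.
landscape_var_names <- function(n_static, n_climate) {
  static <- c("tri", "twi", "soil_ph")
  climate <- c("tmin", "tmax", "diurnal_range", "annual_precip",
               "precip_seasonality", "peti_driest", "sunshine")
  pad <- function(base, n, prefix) {
    if (n <= length(base)) base[seq_len(n)]
    else c(base, paste0(prefix, seq_len(n - length(base))))
  }
  list(static = pad(static, n_static, "static_"),
       climate = pad(climate, n_climate, "climate_"))
}

# Smooth spatially autocorrelated field: superposed low-frequency random
# harmonics plus a little white noise, standardised to mean 0 / sd 1.
smooth_field <- function(nr, nc, n_harmonics = 4L, noise_sd = 0.15) {
  co <- expand.grid(col = seq_len(nc), row = seq_len(nr))
  x <- co$col / nc; y <- co$row / nr
  f <- numeric(nr * nc)
  for (h in seq_len(n_harmonics)) {
    fx <- stats::runif(1, 0.4, 2.2); fy <- stats::runif(1, 0.4, 2.2)
    ph <- stats::runif(1, 0, 2 * pi)
    amp <- 1 / h
    f <- f + amp * cos(2 * pi * (fx * x + fy * y) + ph)
  }
  f <- f + stats::rnorm(nr * nc, sd = noise_sd)
  as.numeric(scale(f))
}

#' Generate a synthetic environmental landscape
#'
#' Builds smooth, spatially autocorrelated fields (superposed low-frequency
#' harmonics plus noise) for each static and climate variable, rescaled to
#' field-realistic units. A `missing_fraction` of soil cells is masked
#' (`NA`), emulating gappy soil surveys, and can be filled with
#' [idw_fill()]. Deterministic under the spec's seed.
#'
#' @param spec a [landscape_spec()].
#' @return An [env_grid()] with epoch `"current"`.
#' @export
generate_landscape <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  nr <- spec$grid_dims[1]; nc <- spec$grid_dims[2]
  nm <- landscape_var_names(spec$n_static_vars, spec$n_climate_vars)
  vars <- c(nm$static, nm$climate)
  # centre / spread / floor per canonical variable (units as named)
  scale_tab <- list(
    tri = c(10, 6, 0), twi = c(7, 2, 0), soil_ph = c(5.5, 0.8, 3),
    tmin = c(2, 2.5, NA), tmax = c(18, 2.5, NA), diurnal_range = c(8, 1.5, 0),
    annual_precip = c(900, 250, 0), precip_seasonality = c(30, 9, 0),
    peti_driest = c(45, 12, 0), sunshine = c(130, 25, 0)
  )
  with_seed(spec$seed, {
    values <- sapply(vars, function(v) {
      f <- smooth_field(nr, nc)
      sc <- scale_tab[[v]]
      if (is.null(sc)) sc <- c(0, 1, NA)
      out <- sc[1] + sc[2] * f
      if (!is.na(sc[3])) out <- pmax(out, sc[3])
      out
    })
    colnames(values) <- vars
    n_missing <- round(spec$missing_fraction * nr * nc)
    if (n_missing > 0) {
      soil_var <- nm$static[min(3L, spec$n_static_vars)]
      gaps <- sample.int(nr * nc, n_missing)
      values[gaps, soil_var] <- NA_real_
    }
    env_grid(values, spec$grid_dims,
             c(rep("static", spec$n_static_vars),
               rep("climate", spec$n_climate_vars)))
  })
}

#' Derive climate summary variables from monthly series
#'
#' Computes, per cell: annual minimum temperature (minimum of monthly
#' minima), annual maximum temperature (maximum of monthly maxima), maximum
#' monthly diurnal range (largest monthly `tmax - tmin`), annual
#' precipitation (sum), and precipitation seasonality as the coefficient of
#' variation, `100 * sd / mean`, using the population standard deviation
#' (the bio15 convention). Cells with zero mean precipitation have an
#' undefined seasonality, flagged `NA`.
#'
#' @param monthly_tmin,monthly_tmax,monthly_precip numeric matrices,
#'   cells x 12 months.
#' @return data.frame with one row per cell and columns `tmin`, `tmax`,
#'   `diurnal_range`, `annual_precip`, `precip_seasonality`.
#' @export
derive_climate_variables <- function(monthly_tmin, monthly_tmax, monthly_precip) {
  monthly_tmin <- rbind(as.matrix(monthly_tmin))
  monthly_tmax <- rbind(as.matrix(monthly_tmax))
  monthly_precip <- rbind(as.matrix(monthly_precip))
  if (ncol(monthly_tmin) != 12L || ncol(monthly_tmax) != 12L ||
      ncol(monthly_precip) != 12L) {
    stop("12 monthly values per cell required", call. = FALSE)
  }
  pm <- rowMeans(monthly_precip)
  psd <- apply(monthly_precip, 1L, pop_sd)
  seasonality <- ifelse(pm > 0, 100 * psd / pm, NA_real_)
  data.frame(
    tmin = apply(monthly_tmin, 1L, min),
    tmax = apply(monthly_tmax, 1L, max),
    diurnal_range = apply(monthly_tmax - monthly_tmin, 1L, max),
    annual_precip = rowSums(monthly_precip),
    precip_seasonality = seasonality
  )
}

#' Terrain ruggedness index
#'
#' Per cell, the mean absolute elevation difference between the focal cell
#' and its up-to-8 neighbours. Edge cells use only their existing
#' neighbours (no padding), so the index is translation invariant.
#'
#' @param elevation numeric matrix (rows x cols), at least 3 x 3.
#' @return matrix of the same dimensions.
#' @export
ruggedness_index <- function(elevation) {
  elevation <- as.matrix(elevation)
  nr <- nrow(elevation); nc <- ncol(elevation)
  if (nr < 3L || nc < 3L) stop("elevation grid must be at least 3 x 3", call. = FALSE)
  sum_abs <- matrix(0, nr, nc)
  n_nb <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    rs <- seq_len(nr); cs <- seq_len(nc)
    rs_ok <- rs[rs + dr >= 1L & rs + dr <= nr]
    cs_ok <- cs[cs + dc >= 1L & cs + dc <= nc]
    nb <- elevation[rs_ok + dr, cs_ok + dc, drop = FALSE]
    sum_abs[rs_ok, cs_ok] <- sum_abs[rs_ok, cs_ok] +
      abs(elevation[rs_ok, cs_ok, drop = FALSE] - nb)
    n_nb[rs_ok, cs_ok] <- n_nb[rs_ok, cs_ok] + 1L
  }
  sum_abs / n_nb
}

#' Fill missing grid cells by inverse distance weighting
#'
#' Missing cells receive `sum(w_k v_k) / sum(w_k)` with `w_k = d_k^-power`
#' over the `max_neighbours` nearest observed cells (all observed cells by
#' default). Observed cells are returned unchanged. Distances are Euclidean
#' between cell centres of the unit grid.
#'
#' @param grid numeric matrix with `NA` for missing cells.
#' @param power IDW exponent (default 2).
#' @param max_neighbours number of nearest observed cells to use
#'   (default `Inf`, i.e. all).
#' @return matrix with missing cells filled.
#' @export
idw_fill <- function(grid, power = 2, max_neighbours = Inf) {
  grid <- as.matrix(grid)
  obs <- which(!is.na(grid), arr.ind = TRUE)
  mis <- which(is.na(grid), arr.ind = TRUE)
  if (nrow(obs) == 0L) stop("all cells missing: nothing to interpolate from", call. = FALSE)
  if (nrow(mis) == 0L) return(grid)
  vals <- grid[obs]
  for (k in seq_len(nrow(mis))) {
    d <- sqrt((obs[, 1] - mis[k, 1])^2 + (obs[, 2] - mis[k, 2])^2)
    use <- seq_along(d)
    if (is.finite(max_neighbours) && max_neighbours < length(d)) {
      use <- order(d)[seq_len(max_neighbours)]
    }
    w <- d[use]^(-power)
    grid[mis[k, 1], mis[k, 2]] <- sum(w * vals[use]) / sum(w)
  }
  grid
}

#' Fill a grid variable's soil gaps in place
#'
#' Convenience wrapper applying [idw_fill()] to one variable of an
#' [env_grid()].
#' @param env an [env_grid()].
#' @param variable column name to fill (default `"soil_ph"`).
#' @inheritParams idw_fill
#' @return the grid with the variable filled.
#' @export
fill_env_variable <- function(env, variable = "soil_ph", power = 2,
                              max_neighbours = Inf) {
  stopifnot(inherits(env, "env_grid"), variable %in% colnames(env$values))
  m <- matrix(env$values[, variable], env$dims[1], env$dims[2], byrow = TRUE)
  filled <- idw_fill(m, power = power, max_neighbours = max_neighbours)
  env$values[, variable] <- as.numeric(t(filled))
  env
}
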