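#' Sample ground-truth species niches for a landscape
#'
#' Each species responds to a random subset of environmental variables
#' through a product-Gaussian suitability surface: optimum and tolerance per
#' used variable, a maximum occurrence probability, and an annual detection
#' probability (imperfect multi-year detection). These niches are the
#' ground truth against which turnover models are scored.
#'
#' @param env an [env_grid()] providing variable ranges.
#' @param n_species number of species.
#' @param seed integer seed.
#' @param vars_per_species how many variables each species responds to.
#' @param tolerance_range tolerance as a fraction of the variable range,
#'   drawn uniformly from this interval.
#' @param max_occurrence_range range for the plateau occurrence probability.
#' @param detection_range range for the per-year detection probability.
#' @return A `species_niches` object: matrices `optimum` and `tolerance`
#'   (species x variables, `NA` for unused variables), vectors
#'   `max_occurrence_prob` and `detection_prob`.
#' @export
sample_species_niches <- function(env, n_species, seed = 1L,
                                  vars_per_species = 3L,
                                  tolerance_range = c(0.15, 0.4),
                                  max_occurrence_range = c(0.6, 1),
                                  detection_range = c(0.7, 1)) {
  stopifnot(inherits(env, "env_grid"), n_species >= 1L)
  vars <- colnames(env$values)
  rng <- apply(env$values, 2L, function(v) range(v, na.rm = TRUE))
  with_seed(seed, {
    optimum <- matrix(NA_real_, n_species, length(vars),
                      dimnames = list(NULL, vars))
    tolerance <- optimum
    for (s in seq_len(n_species)) {
      use <- sample(vars, min(vars_per_species, length(vars)))
      for (v in use) {
        optimum[s, v] <- stats::runif(1, rng[1, v], rng[2, v])
        span <- max(rng[2, v] - rng[1, v], 1e-9)
        tolerance[s, v] <- stats::runif(1, tolerance_range[1],
                                        tolerance_range[2]) * span
      }
    }
    structure(list(
      optimum = optimum, tolerance = tolerance,
      max_occurrence_prob = stats::runif(n_species, max_occurrence_range[1],
                                         max_occurrence_range[2]),
      detection_prob = stats::runif(n_species, detection_range[1],
                                    detection_range[2])
    ), class = "species_niches")
  })
}

# Occurrence probability of every species in every (valid) cell.
niche_suitability <- function(env, niches, cells) {
  vals <- env$values[cells, , drop = FALSE]
  n_sp <- nrow(niches$optimum)
  out <- matrix(0, length(cells), n_sp)
  for (s in seq_len(n_sp)) {
    use <- which(!is.na(niches$optimum[s, ]))
    z2 <- 0
    for (v in use) {
      z2 <- z2 + ((vals[, v] - niches$optimum[s, v]) / niches$tolerance[s, v])^2
    }
    out[, s] <- niches$max_occurrence_prob[s] * exp(-0.5 * z2)
  }
  out
}

#' Generate niche-structured community incidence records
#'
#' True presence of each species in each cell is a Bernoulli draw from its
#' product-Gaussian suitability; observed incidence in each year is the true
#' presence thinned by the species' annual detection probability. Community
#' turnover therefore increases with environmental separation, by
#' construction, with known ground truth attached.
#'
#' @param env an [env_grid()].
#' @param niches a [sample_species_niches()] object.
#' @param n_years number of survey years (detection repeats).
#' @param seed integer seed.
#' @param cells cell indices to survey (default: all valid cells).
#' @return A `community_table`: data.frame of detections
#'   (`site_id`, `species_id`, `year`, `present = 1`) with attributes
#'   `truth` (true presence matrix), `cells` and `n_years`.
#' @export
generate_communities <- function(env, niches, n_years = 3L, seed = 1L,
                                 cells = NULL) {
  stopifnot(inherits(env, "env_grid"), inherits(niches, "species_niches"),
            n_years >= 1L)
  if (is.null(cells)) cells <- which(valid_cells(env))
  suit <- niche_suitability(env, niches, cells)
  n_sp <- ncol(suit)
  with_seed(seed, {
    truth <- matrix(stats::rbinom(length(suit), 1L, as.numeric(suit)),
                    nrow(suit), n_sp)
    rec <- vector("list", n_years)
    for (y in seq_len(n_years)) {
      det <- truth * matrix(
        stats::rbinom(length(suit), 1L,
                      rep(niches$detection_prob, each = nrow(suit))),
        nrow(suit), n_sp)
      idx <- which(det == 1L, arr.ind = TRUE)
      rec[[y]] <- data.frame(site_id = cells[idx[, 1]],
                             species_id = paste0("sp", idx[, 2]),
                             year = y, present = 1L)
    }
    out <- do.call(rbind, rec)
    out <- out[order(out$site_id, out$species_id, out$year), ]
    rownames(out) <- NULL
    structure(out, truth = truth, cells = cells, n_years = n_years,
              class = c("community_table", "data.frame"))
  })
}

#' Write / read community incidence tables
#'
#' Plain CSV with columns `site_id,species_id,year,present` (present in
#' `{0,1}`; absences may be omitted).
#' @param records a community table (data.frame).
#' @param path CSV path.
#' @return `path` (writer) or a `community_table` (reader).
#' @export
write_community_table <- function(records, path) {
  utils::write.csv(as.data.frame(records)[, c("site_id", "species_id",
                                              "year", "present")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_community_table
#' @export
read_community_table <- function(path) {
  out <- utils::read.csv(path)
  need <- c("site_id", "species_id", "year", "present")
  if (!all(need %in% names(out))) {
    stop("community file must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  if (!all(out$present %in% c(0L, 1L))) {
    stop("`present` must be 0 or 1", call. = FALSE)
  }
  structure(out[out$present == 1L, need],
            class = c("community_table", "data.frame"))
}

#' Ground-truth niche-space distance between surveyed cells
#'
#' Environmental separation weighted by how strongly the species pool
#' responds to each variable (mean inverse tolerance), i.e. distance in the
#' space that actually drives the generated turnover. Used to score fitted
#' turnover models against the generator's truth.
#'
#' @param env an [env_grid()].
#' @param niches the [sample_species_niches()] truth.
#' @param cells cell indices.
#' @return a `dist`-like full matrix of pairwise distances.
#' @export
niche_space_distance <- function(env, niches, cells) {
  w <- colMeans(1 / niches$tolerance, na.rm = TRUE)
  w[is.na(w) | !is.finite(w)] <- 0
  vals <- sweep(env$values[cells, names(w), drop = FALSE], 2L, w, `*`)
  as.matrix(stats::dist(vals, method = "manhattan"))
}
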