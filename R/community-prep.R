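#' Pool incidence records for one site across years
#'
#' @param records a community table (`site_id`, `species_id`, `year`,
#'   `present`).
#' @param site site identifier.
#' @return list with `species` (union over years) and `year_frequency`
#'   (named vector: number of distinct years each species was detected).
#' @export
pool_incidence <- function(records, site) {
  records <- as.data.frame(records)
  sub <- records[records$site_id == site & records$present == 1L, ]
  if (nrow(sub) == 0L && !site %in% records$site_id) {
    stop("unknown site: ", site, call. = FALSE)
  }
  freq <- tapply(sub$year, sub$species_id, function(y) length(unique(y)))
  freq <- stats::setNames(as.integer(freq), names(freq))
  list(species = names(freq), year_frequency = freq)
}

#' Jaccard dissimilarity between two assemblages
#'
#' `1 - |A intersect B| / |A union B|` on species identity; symmetric.
#' Undefined (error) when both assemblages are empty.
#'
#' @param assemblage_a,assemblage_b character vectors of species.
#' @return dissimilarity in `[0, 1]`.
#' @export
jaccard_dissimilarity <- function(assemblage_a, assemblage_b) {
  a <- unique(assemblage_a); b <- unique(assemblage_b)
  if (length(a) == 0L && length(b) == 0L) {
    stop("Jaccard dissimilarity undefined for two empty assemblages",
         call. = FALSE)
  }
  1 - length(intersect(a, b)) / length(union(a, b))
}

#' Incidence-based sample coverage (Chao estimator)
#'
#' Estimated completeness of a multi-year incidence sample from its
#' singleton/doubleton frequencies:
#' `C_hat = 1 - (Q1/U) * (T-1)Q1 / ((T-1)Q1 + 2 Q2)`,
#' where `T` is the number of sampling years, `U` the total incidence count
#' (sum of year frequencies), `Q1`/`Q2` the species detected in exactly
#' one/two years. Sites with fewer than two sampled years cannot be
#' estimated and are excluded upstream; `Q1 = 0` gives coverage exactly 1.
#'
#' @param year_frequencies integer vector: years-detected per species.
#' @param T number of sampling years; default `max(year_frequencies)`
#'   (supply explicitly when species were not detected in all survey years).
#' @return A `coverage_stats` list: `T`, `U`, `Q1`, `Q2`, `C_hat`,
#'   `estimable`.
#' @export
incidence_sample_coverage <- function(year_frequencies,
                                      T = max(year_frequencies, 1L)) {
  if (T < 2L) {
    stop("sample coverage requires at least two sampled years (T >= 2)",
         call. = FALSE)
  }
  f <- as.integer(year_frequencies)
  U <- sum(f)
  Q1 <- sum(f == 1L)
  Q2 <- sum(f == 2L)
  if (U == 0L) {
    return(structure(list(T = T, U = 0L, Q1 = 0L, Q2 = 0L,
                          C_hat = NA_real_, estimable = FALSE),
                     class = "coverage_stats"))
  }
  C_hat <- if (Q1 == 0L) 1 else {
    1 - (Q1 / U) * ((T - 1) * Q1 / ((T - 1) * Q1 + 2 * Q2))
  }
  structure(list(T = T, U = U, Q1 = Q1, Q2 = Q2,
                 C_hat = clamp(C_hat, 0, 1), estimable = TRUE),
            class = "coverage_stats")
}

#' Build a weighted site-pair dissimilarity table
#'
#' All unordered site pairs (or a seeded uniform subset) with observed
#' Jaccard dissimilarity, a pair weight equal to the arithmetic mean of the
#' two sites' sample coverages, and both sites' predictor values. This is
#' the training table for [fit_gdm()].
#'
#' @param assemblages named list: species vector per site.
#' @param env_values matrix/data.frame of predictors, rows named by site
#'   (or in the order of `assemblages`).
#' @param coverages named numeric vector of per-site sample coverage
#'   weights (default 1 for all).
#' @param max_pairs optional cap; a seeded uniform subsample of pairs.
#' @param seed seed for the pair subsample.
#' @return A `site_pair_table` data.frame: `site_i`, `site_j`, `distance`,
#'   `weight`, `s1.<var>`, `s2.<var>` columns.
#' @export
build_site_pair_table <- function(assemblages, env_values, coverages = NULL,
                                  max_pairs = Inf, seed = 1L) {
  sites <- names(assemblages)
  if (length(sites) < 2L) stop("need at least 2 sites", call. = FALSE)
  env_values <- as.matrix(env_values)
  if (is.null(rownames(env_values))) rownames(env_values) <- sites
  if (!all(sites %in% rownames(env_values))) {
    stop("every site needs environment values", call. = FALSE)
  }
  if (is.null(coverages)) coverages <- stats::setNames(rep(1, length(sites)), sites)
  if (!all(sites %in% names(coverages))) {
    stop("every site needs a coverage weight", call. = FALSE)
  }
  pairs <- utils::combn(seq_along(sites), 2L)
  if (is.finite(max_pairs) && max_pairs < ncol(pairs)) {
    keep <- with_seed(seed, sample.int(ncol(pairs), max_pairs))
    pairs <- pairs[, sort(keep), drop = FALSE]
  }
  i <- pairs[1, ]; j <- pairs[2, ]
  d <- mapply(function(a, b) jaccard_dissimilarity(assemblages[[a]],
                                                   assemblages[[b]]),
              i, j)
  w <- (coverages[sites[i]] + coverages[sites[j]]) / 2
  vars <- colnames(env_values)
  out <- data.frame(site_i = sites[i], site_j = sites[j],
                    distance = as.numeric(d), weight = as.numeric(w))
  s1 <- env_values[sites[i], , drop = FALSE]
  s2 <- env_values[sites[j], , drop = FALSE]
  colnames(s1) <- paste0("s1.", vars)
  colnames(s2) <- paste0("s2.", vars)
  out <- cbind(out, as.data.frame(s1, row.names = NULL),
               as.data.frame(s2, row.names = NULL))
  structure(out, predictors = vars,
            class = c("site_pair_table", "data.frame"))
}

#' Pairwise Pearson collinearity screen of predictors
#'
#' Diagnostic only: reports all pairwise correlations and flags pairs with
#' `|r|` at or above the threshold. Flagged predictors are retained (the
#' model is robust to collinearity and correlated variables can represent
#' distinct ecological dimensions); zero-variance variables are flagged as
#' undefined.
#'
#' @param env_table matrix/data.frame of site x predictor values.
#' @param threshold absolute-correlation flag level (default 0.8).
#' @return list with `correlations` (matrix), `flagged` (data.frame of
#'   variable pairs with `|r| >= threshold`), `zero_variance` (names).
#' @export
collinearity_screen <- function(env_table, threshold = 0.8) {
  env_table <- as.matrix(env_table)
  if (ncol(env_table) < 2L || nrow(env_table) < 3L) {
    stop("need >= 2 variables and >= 3 sites", call. = FALSE)
  }
  sds <- apply(env_table, 2L, stats::sd)
  zero_var <- colnames(env_table)[sds == 0]
  cors <- suppressWarnings(stats::cor(env_table))
  flagged <- which(abs(cors) >= threshold & upper.tri(cors), arr.ind = TRUE)
  flagged <- data.frame(var_a = rownames(cors)[flagged[, 1]],
                        var_b = colnames(cors)[flagged[, 2]],
                        r = cors[flagged])
  list(correlations = cors, flagged = flagged, zero_variance = zero_var)
}

#' Prepare a community table into GDM inputs
#'
#' Pools incidence per site, estimates sample coverage, drops sites with
#' fewer than two sampled years or unestimable coverage (logged in the
#' result), and builds the weighted site-pair table against the site
#' environment.
#'
#' @param records a community table.
#' @param env_values site x predictor matrix with site rownames.
#' @param min_years minimum sampled years per site (default 2).
#' @inheritParams build_site_pair_table
#' @return list with `pairs` (the [build_site_pair_table()] result),
#'   `coverage` (per retained site), `dropped` (data.frame of site,
#'   reason).
#' @export
prepare_site_pairs <- function(records, env_values, min_years = 2L,
                               max_pairs = Inf, seed = 1L) {
  records <- as.data.frame(records)
  sites <- as.character(unique(records$site_id))
  assemblages <- list(); coverages <- c(); dropped <- list()
  for (s in sites) {
    sub <- records[records$site_id == s & records$present == 1L, ]
    n_yr <- length(unique(sub$year))
    if (n_yr < min_years) {
      dropped[[s]] <- "fewer than two sampled years"; next
    }
    pooled <- pool_incidence(records, s)
    cov <- incidence_sample_coverage(pooled$year_frequency, T = n_yr)
    if (!cov$estimable) {
      dropped[[s]] <- "coverage unestimable (no incidences)"; next
    }
    assemblages[[s]] <- pooled$species
    coverages[s] <- cov$C_hat
  }
  if (length(assemblages) < 2L) {
    stop("fewer than two usable sites after filtering", call. = FALSE)
  }
  env_values <- as.matrix(env_values)
  keep <- names(assemblages)
  pairs <- build_site_pair_table(assemblages,
                                 env_values[keep, , drop = FALSE],
                                 coverages, max_pairs = max_pairs,
                                 seed = seed)
  list(pairs = pairs, coverage = coverages,
       dropped = data.frame(site = names(dropped),
                            reason = unlist(dropped, use.names = FALSE)))
}

#' Write a site-pair table with stable column order
#' @param pairs a `site_pair_table`.
#' @param path CSV path.
#' @export
write_site_pair_table <- function(pairs, path) {
  utils::write.csv(as.data.frame(pairs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_site_pair_table
#' @export
read_site_pair_table <- function(path) {
  out <- utils::read.csv(path)
  vars <- sub("^s1\\.", "", grep("^s1\\.", names(out), value = TRUE))
  structure(out, predictors = vars,
            class = c("site_pair_table", "data.frame"))
}
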