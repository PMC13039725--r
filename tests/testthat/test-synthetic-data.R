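test_that("landscape generation is deterministic and respects the spec", {
  spec <- landscape_spec(grid_dims = c(10L, 10L), seed = 5L)
  a <- generate_landscape(spec)
  b <- generate_landscape(spec)
  expect_identical(a$values, b$values)

  no_gap <- generate_landscape(landscape_spec(grid_dims = c(10L, 10L),
                                              missing_fraction = 0, seed = 5L))
  expect_false(anyNA(no_gap$values))

  gap <- generate_landscape(landscape_spec(grid_dims = c(10L, 10L),
                                           missing_fraction = 0.2, seed = 5L))
  expect_equal(sum(is.na(gap$values[, "soil_ph"])), 20L)

  expect_error(landscape_spec(grid_dims = c(0L, 5L)), "positive")
  expect_error(landscape_spec(missing_fraction = 1), "missing_fraction")
})

test_that("generated fields are spatially autocorrelated", {
  env <- generate_landscape(landscape_spec(grid_dims = c(20L, 20L),
                                           missing_fraction = 0, seed = 3L))
  # lag-1 neighbour correlation (horizontal): positive for every variable
  for (v in colnames(env$values)) {
    m <- matrix(env$values[, v], 20, 20, byrow = TRUE)
    r <- cor(as.numeric(m[, -20]), as.numeric(m[, -1]))
    expect_gt(r, 0)
  }
})

test_that("derived climate variables follow their defining formulas", {
  tmin <- matrix(rep(5, 12), 1)
  tmax <- tmin + 8
  precip <- matrix(rep(50, 12), 1)
  out <- derive_climate_variables(tmin, tmax, precip)
  expect_equal(out$diurnal_range, 8)
  expect_equal(out$precip_seasonality, 0)
  expect_equal(out$annual_precip, 600)

  # one wet month: CV against the direct population-sd formula
  p <- matrix(c(100, rep(0, 11)), 1)
  m <- mean(p); s <- sqrt(mean((p - m)^2))
  out2 <- derive_climate_variables(tmin, tmax, p)
  expect_equal(out2$precip_seasonality, 100 * s / m)

  # zero mean precipitation: seasonality flagged missing
  out3 <- derive_climate_variables(tmin, tmax, matrix(0, 1, 12))
  expect_true(is.na(out3$precip_seasonality))

  expect_error(derive_climate_variables(tmin[, 1:11, drop = FALSE], tmax, precip),
               "12 monthly")
})

test_that("communities reflect niches, detection, and environmental turnover", {
  env <- fixture_landscape()
  cells <- which(valid_cells(env))[1:40]
  niches <- sample_species_niches(env, 50L, seed = 7L,
                                  detection_range = c(1, 1))
  comm <- generate_communities(env, niches, n_years = 1L, seed = 8L,
                               cells = cells)
  truth <- attr(comm, "truth")
  # perfect detection, one year: observed incidence equals true presence
  obs <- matrix(0L, length(cells), nrow(niches$optimum))
  for (k in seq_len(nrow(comm))) {
    i <- match(comm$site_id[k], cells)
    j <- as.integer(sub("sp", "", comm$species_id[k]))
    obs[i, j] <- 1L
  }
  expect_identical(obs, truth)

  # Jaccard dissimilarity rises with environmental separation
  comm2 <- generate_communities(env, sample_species_niches(env, 60L, seed = 9L),
                                n_years = 2L, seed = 10L, cells = cells)
  asm <- lapply(cells, function(s) unique(comm2$species_id[comm2$site_id == s]))
  keep <- which(lengths(asm) > 0)
  pairs <- combn(keep, 2)
  dd <- apply(pairs, 2, function(ij) {
    jaccard_dissimilarity(asm[[ij[1]]], asm[[ij[2]]])
  })
  envd <- as.matrix(dist(scale(env$values[cells, ])))
  ed <- envd[cbind(keep[pairs[1, ]] |> match(cells),
                   keep[pairs[2, ]] |> match(cells))]
  expect_gt(cor(dd, ed, method = "spearman"), 0)
})

test_that("future climates shift linearly with severity and time", {
  env <- fixture_landscape()
  P <- diag(2); dimnames(P) <- list(c("a", "b"), c("a", "b"))
  sc0 <- scenario_spec("null", c(tmax = 0), P, 2015:2080,
                       list(c(2060, 2080)))
  fut0 <- generate_future_climate(env, sc0, c(2060, 2080))
  expect_equal(fut0$values, env$values)

  sc <- scenario_spec("warm", c(tmax = 0.4, tmin = 0.2), P, 2015:2080,
                      list(c(2020, 2040), c(2040, 2060)))
  decades <- (mean(c(2040, 2060)) - 2015) / 10
  fut <- generate_future_climate(env, sc, c(2040, 2060))
  expect_equal(fut$values[, "tmax"], env$values[, "tmax"] + 0.4 * decades)
  expect_equal(fut$values[, "tri"], env$values[, "tri"])  # static untouched

  early <- generate_future_climate(env, sc, c(2020, 2040))
  expect_gt(mean(fut$values[, "tmax"]) - mean(env$values[, "tmax"]),
            mean(early$values[, "tmax"]) - mean(env$values[, "tmax"]))
  expect_error(generate_future_climate(env, sc, c(2070, 2090)), "outside")
})

test_that("land-use maps evolve as the specified Markov chain", {
  cls <- c("seminatural", "arable", "urban")
  ident <- diag(3); dimnames(ident) <- list(cls, cls)
  sc_id <- scenario_spec("static", c(), ident, 2015:2030, list(c(2020, 2030)))
  lu <- generate_landuse(sc_id, cls, 50L, seed = 2L)
  expect_true(all(lu == lu[, 1]))

  # absorbing urban class: urban area never decreases
  P <- matrix(c(0.9, 0.05, 0.05,
                0.05, 0.9, 0.05,
                0, 0, 1), 3, byrow = TRUE, dimnames = list(cls, cls))
  sc <- scenario_spec("sprawl", c(), P, 2015:2060, list(c(2020, 2040)))
  lu2 <- generate_landuse(sc, cls, 200L, seed = 3L)
  urban <- colSums(lu2 == "urban")
  expect_true(all(diff(urban) >= 0))

  # long-run frequencies approach the stationary distribution
  P2 <- matrix(c(0.8, 0.15, 0.05,
                 0.1, 0.85, 0.05,
                 0.05, 0.05, 0.9), 3, byrow = TRUE, dimnames = list(cls, cls))
  pi_star <- landuse_stationary_distribution(P2)
  expect_equal(as.numeric(pi_star %*% P2), as.numeric(pi_star), tolerance = 1e-12)
  sc2 <- scenario_spec("mix", c(), P2, 2000:2120, list(c(2100, 2120)))
  lu3 <- generate_landuse(sc2, cls, 3000L, seed = 4L)
  freq <- table(factor(lu3[, ncol(lu3)], levels = cls)) / 3000
  expect_lt(max(abs(as.numeric(freq) - pi_star[cls])), 0.05)

  bad <- matrix(c(0.5, 0.4, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE,
                dimnames = list(cls, cls))
  expect_error(scenario_spec("bad", c(), bad, 2015:2030, list()),
               "summing to 1")
})

test_that("ruggedness index matches its neighbourhood definition", {
  expect_true(all(ruggedness_index(matrix(4, 5, 5)) == 0))
  m <- matrix(3, 3, 3); m[2, 2] <- 5
  expect_equal(ruggedness_index(m)[2, 2], 2)
  # translation invariance
  e <- matrix(rnorm(36), 6, 6)
  expect_equal(ruggedness_index(e + 100), ruggedness_index(e))
  # edge cells average over existing neighbours only: corner of a ramp
  ramp <- matrix(rep(1:4, each = 4), 4, 4)
  expect_equal(ruggedness_index(ramp)[1, 1], mean(c(0, 1, 1)))
  expect_error(ruggedness_index(matrix(1, 2, 5)), "3 x 3")
})

test_that("inverse distance weighting fills gaps convexly", {
  g <- matrix(c(2, NA, 4), 1, 3)
  expect_equal(idw_fill(g)[1, 2], 3)  # equidistant between 2 and 4

  const <- matrix(7, 4, 4); const[2, 3] <- NA
  expect_equal(idw_fill(const)[2, 3], 7)

  set.seed(12)
  for (rep in 1:5) {
    m <- matrix(runif(49, 1, 9), 7, 7)
    m[sample(49, 10)] <- NA
    filled <- idw_fill(m)
    expect_true(all(filled >= min(m, na.rm = TRUE) - 1e-12 &
                      filled <= max(m, na.rm = TRUE) + 1e-12))
  }
  expect_error(idw_fill(matrix(NA_real_, 2, 2)), "all cells missing")
})

test_that("the multi-study abundance generator meets its contract", {
  cls <- c("reference", "cropland", "urban")
  pr <- generate_predicts_like(cls, n_studies = 5L, sites_per_study = 8L,
                               n_species = 20L, seed = 6L)
  # at least one reference site per study, effort varies
  ref_per_study <- tapply(pr$sites$land_use == "reference", pr$sites$study, sum)
  expect_true(all(ref_per_study >= 1))
  expect_gt(sd(pr$sites$effort), 0)
  # NPP is elevated on agricultural classes relative to reference
  pr2 <- generate_predicts_like(c("reference", "agriculture"), n_studies = 20L,
                                seed = 7L)
  expect_gt(mean(pr2$sites$npp[pr2$sites$land_use == "agriculture"]),
            mean(pr2$sites$npp[pr2$sites$land_use == "reference"]))
  # generator exposes its ground truth
  expect_named(pr$truth, c("ab", "cs"))
})
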