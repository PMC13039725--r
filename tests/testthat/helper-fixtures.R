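# Shared fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small filled landscape used across modules.
fixture_landscape <- function() {
  memo("landscape", {
    env <- generate_landscape(landscape_spec(grid_dims = c(12L, 12L), seed = 11L))
    fill_env_variable(env, "soil_ph")
  })
}

# Niches + communities + fitted turnover model on the fixture landscape.
fixture_model <- function() {
  memo("model", {
    env <- fixture_landscape()
    niches <- sample_species_niches(env, 60L, seed = 21L)
    cells <- which(valid_cells(env))
    comm <- generate_communities(env, niches, n_years = 3L, seed = 31L,
                                 cells = cells)
    site_env <- env$values[cells, , drop = FALSE]
    rownames(site_env) <- as.character(cells)
    prep <- prepare_site_pairs(comm, site_env, max_pairs = 1500L, seed = 41L)
    list(env = env, niches = niches, cells = cells, comm = comm,
         prep = prep, model = fit_gdm(prep$pairs))
  })
}

# Build a transformed_grid directly from a matrix of transformed values.
make_tg <- function(values, dims = NULL, epoch = "current",
                    valid = NULL, intercept = 0) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("v", seq_len(ncol(values)))
  }
  if (is.null(dims)) dims <- c(nrow(values), 1L)
  if (is.null(valid)) valid <- rep(TRUE, nrow(values))
  structure(list(values = values, dims = as.integer(dims), valid = valid,
                 epoch = epoch, scenario = NULL, slice = NULL,
                 f_max = apply(values, 2, max), intercept = intercept),
            class = "transformed_grid")
}

# Independent single-predictor site-pair generator: d = 1 - exp(-(a0 + b I2))
# plus Gaussian noise, for parameter-recovery checks.
make_synthetic_pairs <- function(n_pairs, a0 = 0, b = 1.2, noise_sd = 0.02,
                                 seed = 99L) {
  set.seed(seed)
  x1 <- runif(n_pairs); x2 <- runif(n_pairs)
  knots <- c(0, 0.5, 1)
  i1 <- ispline_basis(x1, knots)[, 2]
  i2 <- ispline_basis(x2, knots)[, 2]
  eta <- a0 + b * abs(i1 - i2)
  d <- pmin(pmax(1 - exp(-eta) + rnorm(n_pairs, sd = noise_sd), 0), 1)
  structure(data.frame(site_i = paste0("a", seq_len(n_pairs)),
                       site_j = paste0("b", seq_len(n_pairs)),
                       distance = d, weight = 1, s1.x = x1, s2.x = x2),
            predictors = "x", class = c("site_pair_table", "data.frame"))
}
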