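#' Quadratic I-spline basis on a three-knot sequence
#'
#' Monotone non-decreasing basis functions obtained by integrating
#' order-2 (piecewise-linear) M-splines on the knot sequence
#' `(t1, t1, t2, t3, t3)` with `t1 <= t2 <= t3` placed at the minimum,
#' median and maximum of the training values. Each basis is 0 at or below
#' `t1`, 1 at or above `t3`, and piecewise quadratic in between; values
#' outside `[t1, t3]` are clamped to the boundary. A degenerate knot
#' sequence (`t1 == t3`, constant predictor) yields an all-zero basis.
#'
#' @param x numeric vector of predictor values.
#' @param knots numeric `c(t1, t2, t3)`.
#' @return matrix `length(x)` x 3 of basis values in `[0, 1]`.
#' @export
ispline_basis <- function(x, knots) {
  stopifnot(length(knots) == 3L, !is.unsorted(knots))
  t1 <- knots[1]; t2 <- knots[2]; t3 <- knots[3]
  n <- length(x)
  out <- matrix(0, n, 3L)
  if (t3 - t1 <= .Machine$double.eps * max(1, abs(t3))) {
    return(out)  # inert predictor
  }
  x <- clamp(x, t1, t3)
  # basis 1: support [t1, t2] (boundary-knot multiplicity at t1)
  if (t2 > t1) {
    lo <- x < t2
    out[lo, 1] <- 1 - ((t2 - x[lo]) / (t2 - t1))^2
    out[!lo, 1] <- 1
  } else {
    out[x > t1, 1] <- 1
  }
  # basis 2: support [t1, t3], peak density at t2
  if (t2 > t1) {
    seg <- x <= t2
    out[seg, 2] <- (x[seg] - t1)^2 / ((t3 - t1) * (t2 - t1))
  } else seg <- rep(FALSE, n)
  if (t3 > t2) {
    out[!seg, 2] <- 1 - (t3 - x[!seg])^2 / ((t3 - t1) * (t3 - t2))
  } else out[!seg, 2] <- 1
  # basis 3: support [t2, t3] (boundary-knot multiplicity at t3)
  if (t3 > t2) {
    hi <- x > t2
    out[hi, 3] <- ((x[hi] - t2) / (t3 - t2))^2
  } else {
    out[x >= t3, 3] <- 1
  }
  out
}

# Knot positions (min, median, max) per predictor from a site-pair table.
pair_knots <- function(pairs, predictors) {
  lapply(stats::setNames(predictors, predictors), function(p) {
    v <- c(pairs[[paste0("s1.", p)]], pairs[[paste0("s2.", p)]])
    as.numeric(stats::quantile(v, c(0, 0.5, 1), names = FALSE))
  })
}

# Design matrix of |I(s1) - I(s2)| blocks, 3 columns per predictor.
pair_design <- function(pairs, knots) {
  preds <- names(knots)
  blocks <- lapply(preds, function(p) {
    b1 <- ispline_basis(pairs[[paste0("s1.", p)]], knots[[p]])
    b2 <- ispline_basis(pairs[[paste0("s2.", p)]], knots[[p]])
    abs(b1 - b2)
  })
  X <- do.call(cbind, blocks)
  colnames(X) <- as.vector(t(outer(preds, 1:3, paste, sep = ".k")))
  X
}

# Weighted binomial-form deviance with clamping away from {0, 1}.
binomial_deviance <- function(y, mu, w, eps = 1e-6) {
  y <- clamp(y, eps, 1 - eps)
  mu <- clamp(mu, eps, 1 - eps)
  sum(w * 2 * (y * log(y / mu) + (1 - y) * log((1 - y) / (1 - mu))))
}

gdm_objective <- function(theta, X1, d, w, objective) {
  mu <- 1 - exp(-as.numeric(X1 %*% theta))
  if (objective == "sse") sum(w * (d - mu)^2) else binomial_deviance(d, mu, w)
}

#' Fit a generalised dissimilarity model
#'
#' Relates observed pairwise compositional dissimilarity `d_ij` to
#' environmental separation through monotone I-spline transforms and a
#' negative exponential link:
#' `E(d_ij) = 1 - exp(-(a0 + sum_pk beta_pk |I_pk(x_pi) - I_pk(x_pj)|))`
#' with `a0, beta >= 0`. The default objective is the weighted squared
#' error on the response scale; a binomial-form deviance objective is
#' available via `objective = "binomial"`. Fitting iterates: linearise the
#' link at the current linear predictor, solve the non-negative least
#' squares subproblem, and damp the step until the objective decreases;
#' the solver is deterministic (no random initialisation).
#'
#' @param pairs a [build_site_pair_table()] table (`distance`, `weight`,
#'   `s1.*`/`s2.*` predictor columns).
#' @param objective `"sse"` (default) or `"binomial"`.
#' @param max_iter,tol iteration cap (200) and objective-change tolerance
#'   (1e-8).
#' @param knots optional named list of `c(min, median, max)` knots; by
#'   default placed at the training minimum, median and maximum.
#' @return A `gdm_model`: `intercept`, `coefficients` (3 x P matrix),
#'   `knots`, `predictors`, `objective`, `deviance` diagnostics
#'   (binomial-form `null`, `model`, `explained_pct`), `fitted`,
#'   `converged`, `iterations`.
#' @export
fit_gdm <- function(pairs, objective = c("sse", "binomial"),
                    max_iter = 200L, tol = 1e-8, knots = NULL) {
  objective <- match.arg(objective)
  predictors <- attr(pairs, "predictors")
  if (is.null(predictors)) {
    predictors <- sub("^s1\\.", "", grep("^s1\\.", names(pairs), value = TRUE))
  }
  d <- pairs$distance
  w <- pairs$weight
  stopifnot(all(d >= 0 & d <= 1), all(w >= 0), length(d) >= 1L)
  if (is.null(knots)) knots <- pair_knots(pairs, predictors)
  inert <- vapply(knots, function(k) k[3] - k[1] <=
                    .Machine$double.eps * max(1, abs(k[3])), logical(1))
  if (any(inert)) {
    warning("dropping constant predictor(s): ",
            paste(names(knots)[inert], collapse = ", "), call. = FALSE)
    knots <- knots[!inert]
  }
  P <- length(knots)
  X <- if (P > 0L) pair_design(pairs, knots) else
    matrix(numeric(0), nrow(pairs), 0L)
  if (P == 0L) {
    warning("no predictors with variation; fitting intercept-only model",
            call. = FALSE)
  }
  X1 <- cbind(`(Intercept)` = 1, X)
  sw <- sqrt(w)

  theta <- rep(0, ncol(X1))
  obj <- gdm_objective(theta, X1, d, w, objective)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- as.numeric(X1 %*% theta)
    mu <- 1 - exp(-eta)
    E <- exp(-eta)                      # d mu / d eta
    gw <- if (objective == "sse") w else {
      mu_c <- clamp(mu, 1e-6, 1 - 1e-6)
      w / (mu_c * (1 - mu_c))           # IRLS weight for binomial deviance
    }
    sgw <- sqrt(gw)
    A <- (sgw * E) * X1
    b <- sgw * ((d - mu) + E * eta)
    theta_star <- pracma::lsqnonneg(A, b)$x
    # damped step: halve until the true objective decreases
    improved <- FALSE
    alpha <- 1
    for (ls in 1:30) {
      cand <- theta + alpha * (theta_star - theta)
      obj_cand <- gdm_objective(cand, X1, d, w, objective)
      if (obj_cand <= obj) { improved <- TRUE; break }
      alpha <- alpha / 2
    }
    if (!improved) { converged <- TRUE; break }
    delta <- obj - obj_cand
    theta <- cand
    obj <- obj_cand
    if (delta < tol) { converged <- TRUE; break }
  }

  intercept <- theta[1]
  coefs <- if (P > 0L) {
    matrix(theta[-1], nrow = 3L,
           dimnames = list(paste0("k", 1:3), names(knots)))
  } else matrix(numeric(0), 3L, 0L)
  fitted <- 1 - exp(-as.numeric(X1 %*% theta))

  mu_null <- clamp(stats::weighted.mean(d, w), 1e-6, 1 - 1e-6)
  d_null <- binomial_deviance(d, rep(mu_null, length(d)), w)
  d_model <- binomial_deviance(d, fitted, w)
  expl <- if (d_null > 0) 100 * (1 - d_model / d_null) else 0

  structure(list(intercept = intercept, coefficients = coefs,
                 knots = knots, predictors = names(knots),
                 objective = objective,
                 deviance = list(null = d_null, model = d_model,
                                 explained_pct = expl),
                 fitted = fitted, objective_value = obj,
                 converged = converged, iterations = iter),
            class = "gdm_model")
}

#' @export
print.gdm_model <- function(x, ...) {
  cat(sprintf("gdm_model: %d predictor(s), intercept %.4f, %s objective\n",
              length(x$predictors), x$intercept, x$objective))
  if (length(x$predictors)) {
    cat("  sum of spline coefficients per predictor:\n")
    print(round(colSums(x$coefficients), 4))
  }
  cat(sprintf("  explained deviance (binomial form): %.1f%%\n",
              x$deviance$explained_pct))
  invisible(x)
}

#' Percentage of deviance explained by a fitted model
#'
#' `100 * (1 - D_model / D_null)` where the null model is intercept-only
#' (a constant equal to the weighted mean dissimilarity). The default uses
#' binomial-form deviance with observed and fitted values clamped to
#' `[1e-6, 1 - 1e-6]`; `type = "sse"` uses weighted squared error instead.
#' Defined as 0 when the null deviance is 0.
#'
#' @param model a fitted `gdm_model`.
#' @param pairs the pairs to evaluate on (typically the training table).
#' @param type `"binomial"` (default) or `"sse"`.
#' @return percentage (can be negative for a model worse than null).
#' @export
explained_deviance <- function(model, pairs, type = c("binomial", "sse")) {
  type <- match.arg(type)
  d <- pairs$distance; w <- pairs$weight
  mu <- predict_pairs(model, pairs)
  mu_null <- clamp(stats::weighted.mean(d, w), 1e-6, 1 - 1e-6)
  if (type == "binomial") {
    dn <- binomial_deviance(d, rep(mu_null, length(d)), w)
    dm <- binomial_deviance(d, mu, w)
  } else {
    dn <- sum(w * (d - mu_null)^2)
    dm <- sum(w * (d - mu)^2)
  }
  if (dn <= 0) 0 else 100 * (1 - dm / dn)
}

#' Predicted dissimilarity for each row of a site-pair table
#'
#' Rebuilds the I-spline design from the model's knots and applies the
#' fitted coefficients and intercept through the negative exponential
#' link.
#' @param model a `gdm_model`.
#' @param pairs a site-pair table with the model's predictors.
#' @return numeric vector of predicted dissimilarities in `[0, 1)`.
#' @export
predict_pairs <- function(model, pairs) {
  X1 <- cbind(1, pair_design(pairs, model$knots))
  theta <- c(model$intercept, as.numeric(model$coefficients))
  1 - exp(-as.numeric(X1 %*% theta))
}

#' Transform an environmental grid through a fitted model
#'
#' Applies the fitted monotone transform `f_p(x) = sum_k beta_pk I_pk(x)`
#' to every cell and model predictor, yielding the "bioclimate space" in
#' which Manhattan distance maps to predicted dissimilarity. Cells with
#' missing values stay missing.
#'
#' @param model a `gdm_model`.
#' @param env an [env_grid()] containing every model predictor.
#' @return A `transformed_grid`: `values` (cells x predictors), `dims`,
#'   `valid` (logical per cell), epoch/scenario/slice tags, and the per
#'   predictor coefficient totals `f_max`.
#' @export
gdm_transform <- function(model, env) {
  stopifnot(inherits(model, "gdm_model"), inherits(env, "env_grid"))
  missing_p <- setdiff(model$predictors, colnames(env$values))
  if (length(missing_p)) {
    stop("grid lacks model predictor(s): ", paste(missing_p, collapse = ", "),
         call. = FALSE)
  }
  ok <- valid_cells(env)
  values <- matrix(NA_real_, nrow(env$values), length(model$predictors),
                   dimnames = list(NULL, model$predictors))
  for (p in model$predictors) {
    basis <- ispline_basis(env$values[ok, p], model$knots[[p]])
    values[ok, p] <- as.numeric(basis %*% model$coefficients[, p])
  }
  structure(list(values = values, dims = env$dims, valid = ok,
                 epoch = env$epoch, scenario = env$scenario,
                 slice = env$slice,
                 f_max = colSums(model$coefficients),
                 intercept = model$intercept),
            class = "transformed_grid")
}

#' Predicted dissimilarity between two transformed vectors
#'
#' `d = 1 - exp(-(a0 * include_intercept + sum_p |f_a - f_b|))`. With the
#' intercept removed (the default for change-through-time predictions) two
#' identical environments predict exactly zero change.
#'
#' @param model the `gdm_model` the vectors came from.
#' @param f_a,f_b numeric vectors of transformed predictor values.
#' @param include_intercept logical (default `FALSE`).
#' @return dissimilarity in `[0, 1)`.
#' @export
predict_dissimilarity <- function(model, f_a, f_b, include_intercept = FALSE) {
  if (length(f_a) != length(f_b)) stop("length mismatch", call. = FALSE)
  eta <- sum(abs(f_a - f_b)) + if (include_intercept) model$intercept else 0
  1 - exp(-eta)
}

#' Serialise a fitted model to a plain-text file
#'
#' Keyed sections (predictors, knots, coefficients, intercept,
#' diagnostics) written with full double precision (`%.17g`) so that
#' `read_gdm(write_gdm(m))` round-trips bit-exactly.
#'
#' @param model a `gdm_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gdm <- function(model, path) {
  g <- function(x) sprintf("%.17g", x)
  lines <- c(
    "# gdm_model v1",
    paste0("objective: ", model$objective),
    paste0("intercept: ", g(model$intercept)),
    paste0("predictors: ", paste(model$predictors, collapse = ",")),
    unlist(lapply(model$predictors, function(p) {
      c(paste0("knots ", p, ": ", paste(g(model$knots[[p]]), collapse = ",")),
        paste0("coef ", p, ": ",
               paste(g(model$coefficients[, p]), collapse = ",")))
    })),
    paste0("deviance_null: ", g(model$deviance$null)),
    paste0("deviance_model: ", g(model$deviance$model)),
    paste0("explained_pct: ", g(model$deviance$explained_pct))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gdm
#' @export
read_gdm <- function(path) {
  lines <- readLines(path)
  val <- function(key) sub(paste0("^", key, ": "), "",
                           grep(paste0("^", key, ": "), lines, value = TRUE))
  preds <- strsplit(val("predictors"), ",")[[1]]
  if (length(preds) == 1L && preds == "") preds <- character(0)
  knots <- lapply(stats::setNames(preds, preds), function(p) {
    as.numeric(strsplit(val(paste0("knots ", p)), ",")[[1]])
  })
  coefs <- vapply(preds, function(p) {
    as.numeric(strsplit(val(paste0("coef ", p)), ",")[[1]])
  }, numeric(3))
  coefs <- matrix(coefs, nrow = 3L,
                  dimnames = list(paste0("k", 1:3), preds))
  structure(list(intercept = as.numeric(val("intercept")),
                 coefficients = coefs, knots = knots, predictors = preds,
                 objective = val("objective"),
                 deviance = list(null = as.numeric(val("deviance_null")),
                                 model = as.numeric(val("deviance_model")),
                                 explained_pct = as.numeric(val("explained_pct"))),
                 fitted = NULL, converged = NA, iterations = NA_integer_),
            class = "gdm_model")
}
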