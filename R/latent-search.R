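# Latent-space search: a Gaussian-process surrogate with squared-exponential
# kernel, the expected-improvement acquisition, the Bayesian-optimization
# loop (random initialization followed by sequential EI maximization), and
# the distance-binned similarity probe that quantifies how well the latent
# space preserves chemical similarity around a query molecule.

#' Expected improvement
#'
#' EI for maximization: `(mu - best) * pnorm(u) + sigma * dnorm(u)` with
#' `u = (mu - best) / sigma`; at `sigma = 0` it degenerates to
#' `max(mu - best, 0)`. Always nonnegative.
#'
#' @param mu Predictive mean(s).
#' @param sigma Predictive standard deviation(s), >= 0.
#' @param best Incumbent best observed value.
#' @return Expected improvement, vectorized over `mu`/`sigma`.
#' @export
expected_improvement <- function(mu, sigma, best) {
  stopifnot(all(sigma >= 0))
  out <- pmax(mu - best, 0)
  pos <- sigma > 0
  if (any(pos)) {
    u <- (mu[pos] - best) / sigma[pos]
    out[pos] <- (mu[pos] - best) * stats::pnorm(u) + sigma[pos] * stats::dnorm(u)
  }
  pmax(out, 0)
}

# --- Gaussian process regression -------------------------------------------

sq_dist <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d <- outer(an, bn, "+") - 2 * A %*% t(B)
  pmax(d, 0)
}

# Squared-exponential kernel GP with hyperparameters (lengthscale, signal
# variance, noise variance) fitted by marginal likelihood; jitter 1e-6.
gp_fit <- function(X, y, optimize = TRUE, jitter = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X)
  ym <- mean(y)
  yc <- y - ym
  d2 <- sq_dist(X, X)
  med <- stats::median(d2[upper.tri(d2)])
  if (!is.finite(med) || med <= 0) med <- 1
  sy <- stats::var(yc)
  if (!is.finite(sy) || sy <= 0) sy <- 1e-4

  nll <- function(theta) {
    ls2 <- exp(theta[1]); s2 <- exp(theta[2]); sn2 <- exp(theta[3])
    K <- s2 * exp(-0.5 * d2 / ls2)
    diag(K) <- diag(K) + sn2 + jitter
    L <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(L)) return(1e10)
    alpha <- backsolve(L, forwardsolve(t(L), yc))
    0.5 * sum(yc * alpha) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
  }

  theta0 <- c(log(med), log(sy), log(sy / 10 + 1e-6))
  theta <- theta0
  if (optimize && n >= 5) {
    op <- tryCatch(
      stats::optim(theta0, nll, method = "L-BFGS-B",
                   lower = theta0 - 8, upper = theta0 + 8,
                   control = list(maxit = 60)),
      error = function(e) NULL)
    if (!is.null(op) && is.finite(op$value)) theta <- op$par
  }

  ls2 <- exp(theta[1]); s2 <- exp(theta[2]); sn2 <- exp(theta[3])
  K <- s2 * exp(-0.5 * d2 / ls2)
  diag(K) <- diag(K) + sn2 + jitter
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), yc))
  structure(list(X = X, y = y, ymean = ym, L = L, alpha = alpha,
                 ls2 = ls2, s2 = s2, sn2 = sn2, jitter = jitter,
                 theta = theta),
            class = "latent_gp")
}

gp_predict <- function(gp, Xs) {
  Xs <- as.matrix(Xs)
  ks <- gp$s2 * exp(-0.5 * sq_dist(gp$X, Xs) / gp$ls2)
  mu <- drop(crossprod(ks, gp$alpha)) + gp$ymean
  v <- forwardsolve(t(gp$L), ks)
  s2 <- pmax(gp$s2 - colSums(v^2), 0)
  list(mean = mu, sd = sqrt(s2))
}

# maximize EI over the box by random multistart + Nelder-Mead refinement
maximize_ei <- function(gp, best, lower, upper, n_cand = 600L) {
  d <- length(lower)
  cand <- matrix(stats::runif(n_cand * d, rep(lower, each = n_cand),
                              rep(upper, each = n_cand)), n_cand, d)
  # include perturbations of the incumbent best point
  bi <- which.max(gp$y)
  near <- matrix(rep(gp$X[bi, ], 20), 20, d, byrow = TRUE) +
    matrix(stats::rnorm(20 * d, sd = 0.05 * (upper - lower)), 20, d)
  cand <- rbind(cand, sweep_clamp(near, lower, upper))
  pr <- gp_predict(gp, cand)
  ei <- expected_improvement(pr$mean, pr$sd, best)
  x0 <- cand[which.max(ei), ]
  neg_ei <- function(x) {
    x <- pmin(pmax(x, lower), upper)
    p <- gp_predict(gp, matrix(x, 1))
    -expected_improvement(p$mean, p$sd, best)
  }
  op <- tryCatch(stats::optim(x0, neg_ei, method = "Nelder-Mead",
                              control = list(maxit = 80)),
                 error = function(e) NULL)
  x <- if (!is.null(op) && -op$value >= max(ei)) op$par else x0
  pmin(pmax(x, lower), upper)
}

sweep_clamp <- function(X, lower, upper) {
  X <- sweep(X, 2, lower, pmax)
  sweep(X, 2, upper, pmin)
}

#' Bayesian optimization over a box
#'
#' Evaluates the objective at `n_init` uniform random points, then for
#' `n_iter` iterations fits the Gaussian-process surrogate to all
#' observations, maximizes expected improvement over the box, evaluates the
#' objective at the selected point and appends the observation. Objective
#' failures (errors) are recorded as score 0 and the search continues.
#'
#' @param objective Function taking a numeric vector (one point) and
#'   returning a scalar score.
#' @param lower,upper Numeric vectors: box bounds per coordinate.
#' @param n_init Random starting points (default 100).
#' @param n_iter Optimization iterations (default 500).
#' @param seed Integer seed.
#' @param refit_every Re-optimize GP hyperparameters every this many
#'   iterations (the surrogate itself is refitted to all data each
#'   iteration).
#' @return A `bo_result`: `trace` tibble (iteration, phase, score,
#'   best_score), observed points `X`, scores `y`, `best_point`,
#'   `best_score`.
#' @export
bo_search <- function(objective, lower, upper, n_init = 100L, n_iter = 500L,
                      seed = 1L, refit_every = 10L) {
  stopifnot(length(lower) == length(upper), all(lower < upper),
            n_init > 0, n_iter >= 0)
  d <- length(lower)
  safe_obj <- function(x) {
    v <- tryCatch(objective(x), error = function(e) 0)
    if (!is.finite(v)) 0 else v
  }
  with_seed(seed, {
    X <- matrix(stats::runif(n_init * d, rep(lower, each = n_init),
                             rep(upper, each = n_init)), n_init, d)
    y <- apply(X, 1, safe_obj)
    theta <- NULL
    gp <- NULL
    for (it in seq_len(n_iter)) {
      refit <- is.null(gp) || (it - 1L) %% refit_every == 0L
      gp <- if (refit) {
        gp_fit(X, y)
      } else {
        g <- gp_fit_fixed(X, y, gp)
        g
      }
      xn <- maximize_ei(gp, max(y), lower, upper)
      yn <- safe_obj(xn)
      X <- rbind(X, matrix(xn, 1))
      y <- c(y, yn)
    }
    trace <- tibble::tibble(
      iteration = seq_along(y),
      phase = rep(c("init", "bo"), c(n_init, n_iter)),
      score = y,
      best_score = cummax(y)
    )
    structure(list(trace = trace, X = X, y = y,
                   best_point = X[which.max(y), ],
                   best_score = max(y),
                   n_init = n_init, n_iter = n_iter),
              class = "bo_result")
  })
}

# refit the GP to new data keeping previous hyperparameters
gp_fit_fixed <- function(X, y, gp_old) {
  X <- as.matrix(X)
  ym <- mean(y)
  yc <- y - ym
  d2 <- sq_dist(X, X)
  K <- gp_old$s2 * exp(-0.5 * d2 / gp_old$ls2)
  diag(K) <- diag(K) + gp_old$sn2 + gp_old$jitter
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), yc))
  structure(list(X = X, y = y, ymean = ym, L = L, alpha = alpha,
                 ls2 = gp_old$ls2, s2 = gp_old$s2, sn2 = gp_old$sn2,
                 jitter = gp_old$jitter, theta = gp_old$theta),
            class = "latent_gp")
}

#' @export
print.bo_result <- function(x, ...) {
  cat("<bo_result>", x$n_init, "random +", x$n_iter, "BO iterations;",
      sprintf("best score %.4f\n", x$best_score))
  invisible(x)
}

#' @export
tidy.bo_result <- function(x, ...) x$trace

#' @export
glance.bo_result <- function(x, ...) {
  tibble::tibble(n_init = x$n_init, n_iter = x$n_iter,
                 best_score = x$best_score,
                 best_iteration = which.max(x$y))
}

#' Latent-point activity objective
#'
#' Builds the objective used when searching latent space against an activity
#' model: decode the latent point by repeated sampling, drop invalid strings
#' and macrocycles (rings larger than `max_ring`), predict P(active) for the
#' survivors and combine with the two-branch score rule.
#'
#' @param model A trained `molecular_autoencoder`.
#' @param activity An `activity_model`.
#' @param n_samples Decoding samples per latent point (default 500).
#' @param max_ring Macrocycle threshold (default 8).
#' @return A function: numeric latent vector -> scalar score in \[0, 1\].
#' @export
make_activity_objective <- function(model, activity, n_samples = 500L,
                                    max_ring = 8L) {
  function(z) {
    rep <- generate(model, z, n_samples = n_samples)
    activity_score(rep, activity, max_ring = max_ring)$score
  }
}

#' Default search box for a trained model
#'
#' Uniform-prior adversarial models are searched over the prior's support;
#' all other variants over \[-4, 4\] per coordinate, covering essentially all
#' the mass of a standard Gaussian latent distribution.
#'
#' @param model A trained `molecular_autoencoder`.
#' @return List with `lower` and `upper` vectors of length `latent_dim`.
#' @export
default_search_bounds <- function(model) {
  d <- model$config$latent_dim
  if (!is.null(model$prior) && model$prior$family == "uniform") {
    list(lower = rep(model$prior$lower, d), upper = rep(model$prior$upper, d))
  } else {
    list(lower = rep(-4, d), upper = rep(4, d))
  }
}

# --- similarity probe -------------------------------------------------------

#' Distance-binned similarity probe
#'
#' Maps the query molecule to its latent point, then for each distance d
#' draws `points_per_bin` points uniformly on the sphere of radius d around
#' it, decodes `samples_per_point` sequences from each, and records the
#' fraction of valid SMILES and the median ECFP6 Tanimoto similarity of all
#' valid structures to the query. Per bin there are
#' `points_per_bin * samples_per_point` reconstruction attempts.
#'
#' @param model A trained `molecular_autoencoder`.
#' @param query A single valid SMILES string.
#' @param distances Distance grid (default `seq(0, 8, by = 0.1)`).
#' @param points_per_bin Random points per distance (default 10).
#' @param samples_per_point Decoding samples per point (default 500).
#' @param seed Integer seed.
#' @param nbits Fingerprint length for the Tanimoto computation.
#' @return A `probe_curve` tibble: `distance`, `median_tanimoto` (`NA` where
#'   no valid structure was produced), `valid_fraction`, `n_attempts`. The
#'   raw per-sample log is attached as attribute `"samples"` (tibble:
#'   distance, point, sample, smiles, valid, tanimoto).
#' @export
similarity_probe <- function(model, query, distances = seq(0, 8, by = 0.1),
                             points_per_bin = 10L, samples_per_point = 500L,
                             seed = 1L, nbits = 2048L) {
  if (!is_valid_smiles(query)) stop("query is not a valid SMILES: ", query)
  query <- canonicalize_smiles(query)
  fq <- fingerprint_ecfp6(query, nbits = nbits)[1, ]
  z0 <- encode_posterior(model, query)$mean[1, ]
  d <- length(z0)

  with_seed(seed, {
    rows <- vector("list", length(distances))
    raw <- vector("list", length(distances))
    for (i in seq_along(distances)) {
      dist <- distances[i]
      u <- matrix(stats::rnorm(points_per_bin * d), points_per_bin, d)
      u <- u / sqrt(rowSums(u^2))
      pts <- sweep(u * dist, 2, z0, "+")
      zbig <- pts[rep(seq_len(points_per_bin), each = samples_per_point), ,
                  drop = FALSE]
      idx <- sample_sequences(model, zbig)
      strings <- apply(idx, 1, decode_indices, vocab = model$vocab)
      uniq <- unique(strings)
      vu <- is_valid_smiles(uniq)
      valid <- vu[match(strings, uniq)]
      tn <- rep(NA_real_, length(strings))
      vs <- uniq[vu & nzchar(uniq)]
      if (length(vs) > 0) {
        fps <- fingerprint_ecfp6(vs, nbits = nbits)
        tv <- vapply(seq_along(vs), function(k) tanimoto(fps[k, ], fq),
                     numeric(1))
        tn[valid] <- tv[match(strings[valid], vs)]
      }
      raw[[i]] <- tibble::tibble(
        distance = dist,
        point = rep(seq_len(points_per_bin), each = samples_per_point),
        sample = rep(seq_len(samples_per_point), points_per_bin),
        smiles = strings, valid = valid, tanimoto = tn
      )
      rows[[i]] <- tibble::tibble(
        distance = dist,
        median_tanimoto = if (any(valid)) stats::median(tn[valid]) else NA_real_,
        valid_fraction = mean(valid),
        n_attempts = points_per_bin * samples_per_point
      )
    }
    out <- dplyr::bind_rows(rows)
    attr(out, "samples") <- dplyr::bind_rows(raw)
    class(out) <- c("probe_curve", class(out))
    out
  })
}

#' Raw per-sample log of a similarity probe
#'
#' @param curve A `probe_curve` from [similarity_probe()].
#' @return Tibble with one row per reconstruction attempt.
#' @export
probe_samples <- function(curve) {
  s <- attr(curve, "samples")
  if (is.null(s)) stop("no raw sample log attached")
  s
}
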