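# Bayesian optimization of the CNN hyperparameters: Matern-5/2 Gaussian
# process surrogate on the unit cube, expected-improvement acquisition,
# random initialization followed by GP-guided proposals.

#' Encode hyperparameters onto the unit cube
#'
#' Each dimension maps linearly so the lower bound hits 0 and the upper
#' bound hits 1. Integer dimensions are relaxed to continuous values and
#' rounded on decoding.
#'
#' @param hp a [hyperparams()] object (must lie inside `space`).
#' @param space search space, default [hyperparam_space()].
#' @return numeric vector in `[0, 1]^d`.
#' @export
encode_hp <- function(hp, space = hyperparam_space()) {
  v <- vapply(space$name, function(nm) as.numeric(hp[[nm]]), numeric(1))
  if (any(v < space$lower - 1e-9) || any(v > space$upper + 1e-9))
    stop("hyperparameters outside the search space")
  stats::setNames((v - space$lower) / (space$upper - space$lower), space$name)
}

#' Decode a unit-cube vector into hyperparameters
#' @param u numeric vector in `[0, 1]^d`.
#' @param space search space, default [hyperparam_space()].
#' @return a [hyperparams()] object (integers rounded).
#' @export
decode_hp <- function(u, space = hyperparam_space()) {
  u <- pmin(1, pmax(0, as.numeric(u)))
  v <- space$lower + u * (space$upper - space$lower)
  v[space$integer] <- round(v[space$integer])
  do.call(hyperparams, as.list(stats::setNames(v, space$name)))
}

# Matern-5/2 kernel with per-dimension length scales; X, Y rows are points.
matern52 <- function(X, Y, lengthscales, sigma_f2) {
  Xs <- sweep(X, 2L, lengthscales, "/")
  Ys <- sweep(Y, 2L, lengthscales, "/")
  d2 <- outer(rowSums(Xs^2), rowSums(Ys^2), "+") - 2 * tcrossprod(Xs, Ys)
  r <- sqrt(pmax(d2, 0))
  s5 <- sqrt(5) * r
  sigma_f2 * (1 + s5 + 5 * d2 / 3) * exp(-s5)
}

#' Fit a Gaussian-process surrogate
#'
#' Zero-mean GP on standardized objective values with a Matern-5/2 ARD
#' kernel plus a noise term; kernel hyperparameters (length scales, signal
#' variance and — unless fixed — noise variance) are set by maximizing the
#' log marginal likelihood from a small multistart.
#'
#' @param X numeric matrix of encoded observations (rows in `[0,1]^d`).
#' @param y objective values (validation RMSE; finite).
#' @param noise `NULL` to fit the noise variance, or a fixed non-negative
#'   value (on the standardized scale) for noiseless interpolation.
#' @return an object of class `gp_surrogate`.
#' @export
gp_fit <- function(X, y, noise = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) < 2L) stop("gp_fit needs at least 2 observations")
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop("gp_fit requires finite inputs")
  if (nrow(unique(X)) < 2L)
    stop("conditioning error: all observation inputs identical")
  d <- ncol(X)
  ym <- mean(y)
  ys <- stats::sd(y)
  if (!is.finite(ys) || ys < 1e-12) ys <- 1
  yz <- (y - ym) / ys

  fit_noise <- is.null(noise)
  nll <- function(theta) {
    ls <- exp(theta[seq_len(d)])
    sf2 <- exp(theta[d + 1L])
    sn2 <- if (fit_noise) exp(theta[d + 2L]) else noise
    K <- matern52(X, X, ls, sf2)
    diag(K) <- diag(K) + sn2 + 1e-10
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    alpha <- backsolve(ch, forwardsolve(t(ch), yz))
    as.numeric(0.5 * sum(yz * alpha) + sum(log(diag(ch))) +
               0.5 * length(yz) * log(2 * pi))
  }
  starts <- list(c(rep(log(0.5), d), log(1), log(1e-2)),
                 c(rep(log(0.2), d), log(1), log(1e-4)),
                 c(rep(log(1.0), d), log(0.5), log(1e-1)))
  lower <- c(rep(log(0.03), d), log(1e-3), log(1e-8))
  upper <- c(rep(log(20), d), log(1e3), log(1))
  npar <- d + 1L + as.integer(fit_noise)
  best <- NULL
  for (s in starts) {
    o <- tryCatch(
      optim(s[seq_len(npar)], nll, method = "L-BFGS-B",
            lower = lower[seq_len(npar)], upper = upper[seq_len(npar)],
            control = list(maxit = 100)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("GP hyperparameter optimization failed")
  theta <- best$par
  ls <- exp(theta[seq_len(d)])
  sf2 <- exp(theta[d + 1L])
  sn2 <- if (fit_noise) exp(theta[d + 2L]) else noise
  K <- matern52(X, X, ls, sf2)
  diag(K) <- diag(K) + sn2 + 1e-10
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), yz))
  structure(list(X = X, y = y, y_mean = ym, y_sd = ys,
                 lengthscales = ls, sigma_f2 = sf2, sigma_n2 = sn2,
                 chol = ch, alpha = alpha, nll = best$value),
            class = "gp_surrogate")
}

#' GP posterior mean and standard deviation
#'
#' @param gp a [gp_fit()] surrogate.
#' @param Xnew matrix of query points (rows in `[0,1]^d`) or a single vector.
#' @return list with `mean` and `sd` on the original objective scale.
#' @export
gp_predict <- function(gp, Xnew) {
  stopifnot(inherits(gp, "gp_surrogate"))
  if (is.null(dim(Xnew))) Xnew <- matrix(Xnew, nrow = 1)
  Ks <- matern52(Xnew, gp$X, gp$lengthscales, gp$sigma_f2)
  mu <- as.numeric(Ks %*% gp$alpha)
  V <- forwardsolve(t(gp$chol), t(Ks))
  var <- pmax(gp$sigma_f2 - colSums(V^2), 0)
  list(mean = mu * gp$y_sd + gp$y_mean, sd = sqrt(var) * gp$y_sd)
}

#' Expected improvement from posterior moments
#'
#' Closed form for minimization:
#' `EI = (f* - mu - xi) * Phi(z) + sd * phi(z)`, `z = (f* - mu - xi) / sd`,
#' degenerating to `max(f* - mu - xi, 0)` as `sd -> 0`. Always >= 0.
#'
#' @param mu,sd posterior mean(s) and standard deviation(s) (`sd >= 0`).
#' @param best_so_far incumbent best (minimum) objective `f*`.
#' @param xi exploration margin (default 0.01).
#' @return EI value(s).
#' @export
ei_moments <- function(mu, sd, best_so_far, xi = 0.01) {
  if (any(sd < 0)) stop("invariant violation: sd must be >= 0")
  imp <- best_so_far - mu - xi
  ei <- ifelse(sd > 0,
               imp * pnorm(imp / pmax(sd, 1e-300)) +
                 sd * dnorm(imp / pmax(sd, 1e-300)),
               pmax(imp, 0))
  pmax(ei, 0)
}

#' Expected improvement at a point under a surrogate
#'
#' @param gp a [gp_fit()] surrogate.
#' @param point encoded point(s) in `[0,1]^d` (vector or matrix rows).
#' @param best_so_far incumbent best objective.
#' @param xi exploration margin.
#' @return EI value(s).
#' @export
expected_improvement <- function(gp, point, best_so_far, xi = 0.01) {
  p <- gp_predict(gp, point)
  ei_moments(p$mean, p$sd, best_so_far, xi)
}

#' Propose the next hyperparameters by maximizing EI
#'
#' Random-candidate search over the unit cube followed by a local polish
#' (L-BFGS-B) from the best few candidates. A proposal whose integer-decoded
#' point collides with an already-evaluated one is perturbed until new.
#'
#' @param gp a [gp_fit()] surrogate.
#' @param space search space.
#' @param best_so_far incumbent best objective.
#' @param xi exploration margin.
#' @param n_candidates random candidates (default 2000).
#' @param n_polish candidates polished locally (default 5).
#' @param evaluated optional matrix of already-evaluated encoded points.
#' @return list with `hp` (a [hyperparams()]), `u` (encoded point) and `ei`.
#' @export
propose_next <- function(gp, space = hyperparam_space(), best_so_far,
                         xi = 0.01, n_candidates = 2000L, n_polish = 5L,
                         evaluated = NULL) {
  d <- nrow(space)
  U <- matrix(runif(n_candidates * d), ncol = d)
  ei <- expected_improvement(gp, U, best_so_far, xi)
  ord <- order(ei, decreasing = TRUE)
  best_u <- U[ord[1L], ]
  best_ei <- ei[ord[1L]]
  for (i in seq_len(min(n_polish, n_candidates))) {
    o <- tryCatch(
      optim(U[ord[i], ],
            function(u) -expected_improvement(gp, pmin(1, pmax(0, u)),
                                              best_so_far, xi),
            method = "L-BFGS-B", lower = 0, upper = 1,
            control = list(maxit = 30)),
      error = function(e) NULL)
    if (!is.null(o) && -o$value > best_ei) {
      best_ei <- -o$value
      best_u <- pmin(1, pmax(0, o$par))
    }
  }
  if (!is.null(evaluated) && nrow(evaluated) > 0) {
    key <- function(u) paste(encode_hp(decode_hp(u, space), space),
                             collapse = "|")
    seen <- apply(evaluated, 1L, key)
    tries <- 0L
    while (key(best_u) %in% seen && tries < 100L) {
      best_u <- pmin(1, pmax(0, best_u + rnorm(d, sd = 0.05)))
      tries <- tries + 1L
    }
  }
  list(hp = decode_hp(best_u, space), u = best_u, ei = best_ei)
}

#' Bayesian optimization with a GP surrogate and EI acquisition
#'
#' `n_random` random evaluations initialize the trace, followed by up to
#' `n_gp_iter` GP-guided evaluations. Failed or non-finite evaluations are
#' recorded with a large finite penalty and excluded from surrogate fitting.
#'
#' @param objective_fn function taking a [hyperparams()] object and
#'   returning a finite objective value (validation RMSE) or `NA`/`Inf` on
#'   failure.
#' @param space search space, default [hyperparam_space()].
#' @param n_random random initial evaluations (default 20).
#' @param n_gp_iter GP-guided iterations (default 200).
#' @param seed RNG seed (deterministic trace for a deterministic objective).
#' @param xi EI exploration margin.
#' @param n_candidates acquisition candidates per proposal.
#' @return an object of class `tune_result`: `best_hp`, `best_objective`,
#'   and the full `trace` data.frame (iteration, phase, hp fields,
#'   objective).
#' @export
bogp_optimize <- function(objective_fn, space = hyperparam_space(),
                          n_random = 20L, n_gp_iter = 200L, seed = 1L,
                          xi = 0.01, n_candidates = 2000L) {
  local_seed(seed)
  d <- nrow(space)
  U <- matrix(NA_real_, 0, d)
  objs <- numeric(0)
  phases <- character(0)
  hps <- list()

  eval_point <- function(u, phase) {
    hp <- decode_hp(u, space)
    val <- tryCatch(objective_fn(hp), error = function(e) NA_real_)
    val <- if (!is.numeric(val) || length(val) != 1L || !is.finite(val))
      NA_real_ else as.numeric(unname(val))
    U <<- rbind(U, encode_hp(hp, space))
    objs <<- c(objs, val)
    phases <<- c(phases, phase)
    hps[[length(hps) + 1L]] <<- hp
    invisible(val)
  }

  for (i in seq_len(n_random)) eval_point(runif(d), "random")

  penalty <- function() {
    valid <- objs[is.finite(objs)]
    if (!length(valid)) Inf else max(valid) * 10 + 1
  }

  for (i in seq_len(n_gp_iter)) {
    valid <- which(is.finite(objs))
    if (length(valid) < 2L) { eval_point(runif(d), "gp"); next }
    gp <- tryCatch(gp_fit(U[valid, , drop = FALSE], objs[valid]),
                   error = function(e) NULL)
    if (is.null(gp)) { eval_point(runif(d), "gp"); next }
    prop <- propose_next(gp, space, best_so_far = min(objs[valid]), xi = xi,
                         n_candidates = n_candidates, evaluated = U)
    eval_point(prop$u, "gp")
  }

  if (!any(is.finite(objs)))
    stop("optimization error: all evaluations failed")
  reported <- ifelse(is.finite(objs), objs, penalty())
  best_i <- which.min(reported)
  trace <- cbind(
    data.frame(iteration = seq_along(objs), phase = phases,
               stringsAsFactors = FALSE),
    do.call(rbind, lapply(hps, function(h) as.data.frame(unclass(h)))),
    data.frame(objective = reported, failed = !is.finite(objs)))
  structure(list(best_hp = hps[[best_i]], best_objective = reported[best_i],
                 trace = trace, seed = as.integer(seed)),
            class = "tune_result")
}

#' @export
print.tune_result <- function(x, ...) {
  cat("<tune_result> ", nrow(x$trace), " evaluations, best objective ",
      format(x$best_objective, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Persist a tuning trace as CSV
#' @param result a `tune_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tune_trace <- function(result, path) {
  stopifnot(inherits(result, "tune_result"))
  write.csv(result$trace, path, row.names = FALSE)
  invisible(path)
}
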