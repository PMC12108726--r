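# Gaussian mixture model fitted by expectation-maximization, written from
# scratch: responsibilities, weighted parameter updates, log-likelihood
# convergence and hard assignment.  All densities are evaluated in log
# space through a Cholesky factorization of the regularized covariance;
# the literal responsibility ratio under- and overflows at dimension 16
# with the near-singular covariances this data produces.

#' Multivariate normal log-density
#'
#' Log of `N(x | mu, sigma + reg_eps * I)`, evaluated through the Cholesky
#' factor of the regularized covariance for numerical stability.
#'
#' @param x Numeric vector, or an `N x d` matrix of row vectors.
#' @param mu Mean vector of length `d`.
#' @param sigma `d x d` symmetric covariance matrix.
#' @param reg_eps Nonnegative ridge added to the diagonal before
#'   factorization.
#' @return Log densities, one per row of `x`.
#' @export
component_logpdf <- function(x, mu, sigma, reg_eps = 0) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  d <- length(mu)
  sig <- sigma + diag(reg_eps, d)
  R <- tryCatch(chol(sig), error = function(e) {
    stop("covariance not positive definite after regularization: ",
         conditionMessage(e), call. = FALSE)
  })
  # quad form through triangular solve: z = R^-T (x - mu)'
  z <- backsolve(R, t(x) - mu, transpose = TRUE)
  -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(R))) + colSums(z^2))
}

# K-column matrix of log(pi_k) + log N(x_i | mu_k, sigma_k)
.weighted_logdens <- function(params, X) {
  K <- params$K
  out <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    out[, k] <- log(params$weights[k]) +
      component_logpdf(X, params$means[k, ], params$covariances[, , k],
                       params$reg_eps)
  }
  out
}

.logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Initialize mixture parameters
#'
#' Component weights start uniform at `1/K`, covariances start as identity
#' matrices (isotropic), and means are drawn at random: uniformly over
#' `[0, 1]^dim` (`"random_uniform"`, the default, matching the all-index
#' vectors' value range) or as `K` distinct rows of the data
#' (`"random_datapoint"`).
#'
#' @param K Number of components.
#' @param dim Data dimension.
#' @param scheme Mean initialization scheme.
#' @param X Data matrix; required for `"random_datapoint"`.
#' @param reg_eps Diagonal regularization carried by the parameters.
#' @return A list of class `"gmm_params"` with `weights` (length `K`),
#'   `means` (`K x dim`), `covariances` (`dim x dim x K`), `K`, `dim`,
#'   `reg_eps`.
#' @export
init_params <- function(K, dim, scheme = c("random_uniform",
                                           "random_datapoint"),
                        X = NULL, reg_eps = 1e-6) {
  scheme <- match.arg(scheme)
  stopifnot(K >= 1, dim >= 1)
  means <- switch(scheme,
    random_uniform = matrix(stats::runif(K * dim), K, dim),
    random_datapoint = {
      if (is.null(X)) stop("random_datapoint init needs data", call. = FALSE)
      X[sample.int(nrow(X), K), , drop = FALSE]
    })
  covariances <- array(0, c(dim, dim, K))
  for (k in seq_len(K)) covariances[, , k] <- diag(dim)
  structure(list(weights = rep(1 / K, K), means = means,
                 covariances = covariances, K = K, dim = dim,
                 reg_eps = reg_eps),
            class = "gmm_params")
}

#' E-step: posterior responsibilities
#'
#' The responsibility of component `k` for point `i` is
#' `pi_k N(x_i | mu_k, Sigma_k)` normalized over components, computed in
#' log space with the log-sum-exp trick.
#'
#' @param params A `"gmm_params"` list (see [init_params()]).
#' @param X `N x dim` data matrix.
#' @return A list with `R` (`N x K` responsibility matrix, rows summing to
#'   1), `Nk` (effective component counts, the column sums) and `loglik`
#'   (the data log-likelihood under `params`).
#' @export
e_step <- function(params, X) {
  if (!is.matrix(X)) X <- as.matrix(X)
  wl <- .weighted_logdens(params, X)
  lse <- .logsumexp_rows(wl)
  if (any(!is.finite(lse))) {
    stop("zero total density for some point: numerical failure",
         call. = FALSE)
  }
  R <- exp(wl - lse)
  list(R = R, Nk = colSums(R), loglik = sum(lse))
}

#' M-step: weighted parameter updates
#'
#' Means become responsibility-weighted averages of the data, covariances
#' responsibility-weighted outer products about the new means plus
#' `reg_eps` on the diagonal, and weights the effective counts over `N`.
#' A component whose effective count collapses below `1e-10` is reseeded
#' to a random data point with identity covariance (reported via
#' [message()]) rather than aborting the fit.
#'
#' @param X `N x dim` data matrix.
#' @param R `N x K` responsibility matrix.
#' @param reg_eps Diagonal regularization.
#' @return A `"gmm_params"` list.
#' @export
m_step <- function(X, R, reg_eps = 1e-6) {
  if (!is.matrix(X)) X <- as.matrix(X)
  N <- nrow(X); d <- ncol(X); K <- ncol(R)
  Nk <- colSums(R)
  means <- matrix(0, K, d)
  covariances <- array(0, c(d, d, K))
  for (k in seq_len(K)) {
    if (Nk[k] < 1e-10) {
      message("component ", k, " collapsed (N_k = ", format(Nk[k]),
              "); reseeding to a random data point")
      means[k, ] <- X[sample.int(N, 1L), ]
      covariances[, , k] <- diag(d)
      Nk[k] <- 1
      next
    }
    mk <- colSums(R[, k] * X) / Nk[k]
    Xc <- sweep(X, 2L, mk)
    covariances[, , k] <- crossprod(Xc * sqrt(R[, k])) / Nk[k] +
      diag(reg_eps, d)
    means[k, ] <- mk
  }
  structure(list(weights = Nk / sum(Nk), means = means,
                 covariances = covariances, K = K, dim = d,
                 reg_eps = reg_eps),
            class = "gmm_params")
}

#' Mixture log-likelihood
#'
#' `sum_i log sum_k pi_k N(x_i | mu_k, Sigma_k)`, evaluated with
#' log-sum-exp.
#'
#' @inheritParams e_step
#' @return A single number.
#' @export
log_likelihood <- function(params, X) {
  if (!is.matrix(X)) X <- as.matrix(X)
  sum(.logsumexp_rows(.weighted_logdens(params, X)))
}

# one full EM run to convergence from given parameters
.run_em <- function(params, X, max_iter, tol, reg_eps) {
  N <- nrow(X)
  trace <- numeric(0)
  prev_ll <- -Inf
  n_iter <- 0L
  converged <- FALSE
  repeat {
    es <- e_step(params, X)
    trace <- c(trace, es$loglik)
    if (abs(es$loglik - prev_ll) / N < tol) {
      converged <- TRUE
      break
    }
    if (n_iter >= max_iter) break
    params <- m_step(X, es$R, reg_eps)
    prev_ll <- es$loglik
    n_iter <- n_iter + 1L
  }
  list(params = params, loglik = trace[length(trace)], trace = trace,
       n_iter = n_iter, converged = converged)
}

# Split-and-merge refinement of a converged EM run (after Ueda et al.):
# merge the component pair with the most similar responsibility profiles,
# split the component with the largest covariance volume (one Gaussian
# straddling several clusters), rerun EM, and keep the move only if the
# log-likelihood improves.  Escapes the label-degenerate local optima that
# purely random mean initialization frequently produces.
.refine_split_merge <- function(fit, X, max_iter, tol, reg_eps,
                                n_refine) {
  N <- nrow(X); K <- fit$params$K
  if (K < 3L || n_refine < 1L) return(fit)
  total_iter <- fit$n_iter
  for (attempt in seq_len(n_refine)) {
    R <- e_step(fit$params, X)$R
    nrm <- sqrt(colSums(R^2)); nrm[nrm == 0] <- 1
    sim <- crossprod(sweep(R, 2L, nrm, "/"))
    diag(sim) <- -Inf
    jk <- which(sim == max(sim), arr.ind = TRUE)[1L, ]
    j <- jk[1L]; k <- jk[2L]
    logdet <- vapply(seq_len(K), function(l) {
      as.numeric(determinant(fit$params$covariances[, , l])$modulus)
    }, 0)
    logdet[c(j, k)] <- -Inf
    l <- which.max(logdet)
    p2 <- fit$params
    wj <- p2$weights[j]; wk <- p2$weights[k]
    p2$means[j, ] <- (wj * p2$means[j, ] + wk * p2$means[k, ]) / (wj + wk)
    p2$covariances[, , j] <-
      (wj * p2$covariances[, , j] + wk * p2$covariances[, , k]) / (wj + wk)
    p2$weights[j] <- wj + wk
    pr <- R[, l]
    if (sum(pr) < 1e-12) pr <- rep(1, N)
    seeds <- sample.int(N, 2L, prob = pr)
    p2$means[k, ] <- X[seeds[1L], ]
    p2$means[l, ] <- X[seeds[2L], ]
    p2$covariances[, , k] <- p2$covariances[, , l]
    p2$weights[k] <- p2$weights[l] / 2
    p2$weights[l] <- p2$weights[l] / 2
    cand <- .run_em(p2, X, max_iter, tol, reg_eps)
    if (cand$loglik > fit$loglik + tol * N) {
      total_iter <- total_iter + cand$n_iter
      fit <- cand
    } else {
      break
    }
  }
  fit$n_iter <- total_iter
  fit
}

#' Fit a Gaussian mixture by expectation-maximization
#'
#' Alternates [e_step()] and [m_step()] from a random initialization until
#' the mean per-point log-likelihood change drops below `tol` or `max_iter`
#' updates have run.  The log-likelihood is evaluated at each E-step, and
#' convergence is declared before the next M-step, so `n_iter` counts
#' parameter-update passes actually performed.  `n_init` independent
#' restarts are run from distinct sub-seeds and the restart with the
#' highest final log-likelihood is returned: purely random means can land
#' in label-degenerate local optima, and best-of-restarts makes the global
#' structure reliable.
#'
#' After each restart converges, up to `n_refine` split-and-merge moves
#' are attempted (merge the two components with the most similar
#' responsibility profiles, split the component with the largest
#' covariance volume, rerun EM) and kept only when they raise the
#' log-likelihood.  This standard refinement reliably escapes optima in
#' which one Gaussian straddles two clusters while two share a third; set
#' `n_refine = 0` for plain EM.
#'
#' @param X `N x dim` data matrix (`N >= K`).
#' @param K Number of components (default 8, one per motion direction).
#' @param seed Optional integer seed controlling all randomness of the fit.
#' @param max_iter Maximum EM updates per restart (default 100).
#' @param tol Convergence tolerance on the mean per-point log-likelihood
#'   change (default `1e-3`).
#' @param n_init Number of random restarts (default 10).
#' @param reg_eps Diagonal covariance regularization (default `1e-6`).
#'   Required here: within one direction cluster 14 of the 16 dimensions
#'   are identically zero, so the unregularized covariance update is
#'   singular.
#' @param init Mean initialization scheme, see [init_params()].
#' @param n_refine Maximum split-and-merge refinement moves per restart
#'   (default 8).
#' @return An object of class `"gmm_em"`: the fitted `weights`, `means`,
#'   `covariances` and `reg_eps`, plus `loglik` (final), `loglik_trace`
#'   (E-step values of the winning restart's final EM run), `n_iter`
#'   (parameter updates across accepted stages), `converged`, `K`, `dim`,
#'   `n_obs` and `seed`.
#' @examples
#' set.seed(1)
#' X <- rbind(matrix(rnorm(100, 0), ncol = 2),
#'            matrix(rnorm(100, 5), ncol = 2))
#' fit <- gmm_em(X, K = 2, seed = 42, n_init = 3)
#' fit
#' table(predict(fit, X))
#' @export
gmm_em <- function(X, K = 8, seed = NULL, max_iter = 100, tol = 1e-3,
                   n_init = 10, reg_eps = 1e-6,
                   init = c("random_uniform", "random_datapoint"),
                   n_refine = 8) {
  init <- match.arg(init)
  if (!is.matrix(X)) X <- as.matrix(X)
  N <- nrow(X); d <- ncol(X)
  if (N < K) stop("need at least K data points", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sub_seeds <- sample.int(2147483646L, n_init)
  best <- NULL
  for (r in seq_len(n_init)) {
    set.seed(sub_seeds[r])
    params <- init_params(K, d, scheme = init, X = X, reg_eps = reg_eps)
    run <- .run_em(params, X, max_iter, tol, reg_eps)
    run <- .refine_split_merge(run, X, max_iter, tol, reg_eps, n_refine)
    if (is.null(best) || run$loglik > best$loglik) {
      best <- list(params = run$params, loglik = run$loglik,
                   trace = run$trace, n_iter = run$n_iter,
                   converged = run$converged,
                   restart = r, sub_seed = sub_seeds[r])
    }
  }
  structure(list(weights = best$params$weights, means = best$params$means,
                 covariances = best$params$covariances, reg_eps = reg_eps,
                 K = K, dim = d, n_obs = N,
                 loglik = best$loglik, loglik_trace = best$trace,
                 n_iter = best$n_iter, converged = best$converged,
                 n_init = n_init, restart = best$restart,
                 seed = seed, call = match.call()),
            class = "gmm_em")
}

#' Hard assignment and responsibilities of new data
#'
#' `type = "class"` assigns every point to the component with the highest
#' responsibility (ties broken toward the lowest component index);
#' `type = "responsibility"` returns the full `N x K` posterior matrix.
#'
#' @param object A fitted [gmm_em()] model.
#' @param newdata `N x dim` data matrix.
#' @param type `"class"` or `"responsibility"`.
#' @param ... Unused.
#' @return Integer labels in `0..K-1`, or a responsibility matrix.
#' @export
predict.gmm_em <- function(object, newdata,
                           type = c("class", "responsibility"), ...) {
  type <- match.arg(type)
  R <- e_step(object, newdata)$R
  if (type == "responsibility") return(R)
  max.col(R, ties.method = "first") - 1L
}

#' @export
print.gmm_em <- function(x, ...) {
  cat(sprintf("Gaussian mixture (EM): K = %d, dim = %d, N = %d\n",
              x$K, x$dim, x$n_obs))
  cat(sprintf("log-likelihood %.4f after %d update(s)%s; best of %d restart(s)\n",
              x$loglik, x$n_iter,
              if (x$converged) " (converged)" else " (max_iter reached)",
              x$n_init))
  cat("mixing weights:", format(x$weights, digits = 4), "\n")
  invisible(x)
}

#' @export
logLik.gmm_em <- function(object, ...) {
  p <- object$K - 1 + object$K * object$dim +
    object$K * object$dim * (object$dim + 1) / 2
  structure(object$loglik, df = p, nobs = object$n_obs, class = "logLik")
}

#' @export
coef.gmm_em <- function(object, ...) {
  list(weights = object$weights, means = object$means,
       covariances = object$covariances)
}
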