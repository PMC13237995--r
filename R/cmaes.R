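#' Covariance matrix adaptation evolution strategy (CMA-ES)
#'
#' Derivative-free minimizer used for the femoral pose search. Standard
#' (mu/mu_w, lambda) formulation: rank-based recombination weights,
#' cumulative step-size adaptation and rank-one / rank-mu covariance
#' updates. Box bounds are handled by resampling-free projection penalty:
#' candidates are evaluated as given; callers wanting hard bounds should
#' penalize inside `fn` (see [optimize_gb()]) or pass `lower`/`upper`, in
#' which case candidates are clamped to the box before evaluation and the
#' clamping distance is added as a quadratic penalty.
#'
#' @param fn objective function taking a numeric vector, returning a scalar.
#' @param x0 start point (also the distribution mean m_0).
#' @param sigma0 initial global step size.
#' @param lower,upper optional box bounds (recycled to length(x0)).
#' @param max_evals evaluation budget.
#' @param lambda population size (default 4 + floor(3 log n)).
#' @param stop_fitness stop when the best value falls at or below this.
#' @param tol_sigma stop when sigma drops below `tol_sigma * sigma0`.
#' @param seed RNG seed.
#' @return list with `par`, `value`, `evals`, `iterations`, `converged`.
#' @references Hansen, N. The CMA evolution strategy: a tutorial.
#' @export
cma_es <- function(fn, x0, sigma0 = 1, lower = NULL, upper = NULL,
                   max_evals = 2000, lambda = NULL,
                   stop_fitness = -Inf, tol_sigma = 1e-8, seed = 1L) {
  n <- length(x0)
  stopifnot(n >= 1, sigma0 > 0, max_evals >= 1)
  if (!is.null(lower)) lower <- rep_len(lower, n)
  if (!is.null(upper)) upper <- rep_len(upper, n)
  if (is.null(lambda)) lambda <- 4L + floor(3 * log(n))
  lambda <- max(4L, as.integer(lambda))
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mu_eff <- 1 / sum(w^2)

  c_sigma <- (mu_eff + 2) / (n + mu_eff + 5)
  d_sigma <- 1 + 2 * max(0, sqrt((mu_eff - 1) / (n + 1)) - 1) + c_sigma
  c_c <- (4 + mu_eff / n) / (n + 4 + 2 * mu_eff / n)
  c_1 <- 2 / ((n + 1.3)^2 + mu_eff)
  c_mu <- min(1 - c_1, 2 * (mu_eff - 2 + 1 / mu_eff) / ((n + 2)^2 + mu_eff))
  chi_n <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  wrap <- function(x) {
    pen <- 0
    if (!is.null(lower) || !is.null(upper)) {
      xc <- x
      if (!is.null(lower)) xc <- pmax(xc, lower)
      if (!is.null(upper)) xc <- pmin(xc, upper)
      pen <- 1e4 * sum((x - xc)^2)
      x <- xc
    }
    list(x = x, f = fn(x) + pen)
  }

  with_seed(seed, {
    m <- as.numeric(x0)
    sigma <- sigma0
    C <- diag(n)
    p_sigma <- numeric(n)
    p_c <- numeric(n)
    best_x <- m
    best_f <- Inf
    evals <- 0L
    iter <- 0L
    converged <- FALSE

    while (evals + lambda <= max_evals) {
      iter <- iter + 1L
      eig <- eigen(C, symmetric = TRUE)
      D <- sqrt(pmax(eig$values, 1e-20))
      B <- eig$vectors
      BD <- B %*% diag(D, n)
      invsqrtC <- B %*% diag(1 / D, n) %*% t(B)

      Z <- matrix(stats::rnorm(n * lambda), n, lambda)
      Y <- BD %*% Z
      X <- m + sigma * Y
      fs <- numeric(lambda)
      Xe <- matrix(0, n, lambda)
      for (k in seq_len(lambda)) {
        r <- wrap(X[, k])
        fs[k] <- r$f
        Xe[, k] <- r$x
      }
      evals <- evals + lambda
      o <- order(fs)
      if (fs[o[1]] < best_f) {
        best_f <- fs[o[1]]
        best_x <- Xe[, o[1]]
      }

      y_w <- drop(Y[, o[seq_len(mu)], drop = FALSE] %*% w)
      m <- m + sigma * y_w

      p_sigma <- (1 - c_sigma) * p_sigma +
        sqrt(c_sigma * (2 - c_sigma) * mu_eff) * drop(invsqrtC %*% y_w)
      h_sigma <- as.numeric(
        sqrt(sum(p_sigma^2)) / sqrt(1 - (1 - c_sigma)^(2 * iter)) / chi_n <
          1.4 + 2 / (n + 1))
      p_c <- (1 - c_c) * p_c +
        h_sigma * sqrt(c_c * (2 - c_c) * mu_eff) * y_w

      Ymu <- Y[, o[seq_len(mu)], drop = FALSE]
      rank_mu <- Ymu %*% diag(w, mu) %*% t(Ymu)
      C <- (1 - c_1 - c_mu) * C +
        c_1 * (tcrossprod(p_c) + (1 - h_sigma) * c_c * (2 - c_c) * C) +
        c_mu * rank_mu
      C <- (C + t(C)) / 2
      sigma <- sigma * exp((c_sigma / d_sigma) *
                             (sqrt(sum(p_sigma^2)) / chi_n - 1))

      if (best_f <= stop_fitness || sigma < tol_sigma * sigma0) {
        converged <- TRUE
        break
      }
    }
    list(par = best_x, value = best_f, evals = evals,
         iterations = iter, converged = converged)
  })
}
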