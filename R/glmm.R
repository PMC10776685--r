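# Statistical core: the negative binomial random-intercept mixed model for
# within-cell-line viability ranks, fitted by maximising the marginal
# likelihood with a Laplace (n_quad = 1) or adaptive Gauss-Hermite
# approximation of each cell line's random-intercept integral.
#
# Model: R_ik ~ NB(mu_ik, theta), mu_ik = exp(beta0 + beta * X_ik + u_k),
# u_k ~ N(0, sigma^2) independent across cell lines (Sigma = sigma^2 I), so
# the marginal likelihood factorises over cell lines:
#   l = sum_k log INT prod_i f(R_ik; mu_ik, theta) phi(u; 0, sigma^2) du.
# X is the gene's binary alteration status and is constant within a cell
# line, so each cluster's integrand depends on the data only through the
# rank sum S_k and the cluster size n_k (plus theta-dependent lgamma terms);
# the per-cluster mode is found by a damped Newton iteration on a globally
# concave objective, vectorised over clusters.

#' Negative binomial probability mass function (mean/shape form)
#'
#' `f(r) = Gamma(r+theta) / (Gamma(theta) r!) * (theta/(mu+theta))^theta *
#' (mu/(mu+theta))^r`, the NB2 parameterisation with mean `mu` and variance
#' `mu + mu^2/theta`, evaluated in log space.
#'
#' @param r non-negative integer count(s).
#' @param mu positive mean.
#' @param theta positive shape.
#' @param log return the log pmf.
#' @return probability (or log probability).
#' @export
nb_pmf <- function(r, mu, theta, log = FALSE) {
  if (any(!is.finite(r)) || any(r < 0) || any(r != round(r)))
    stop("r must be a non-negative integer")
  if (any(!is.finite(mu)) || any(mu <= 0)) stop("mu must be positive")
  if (any(!is.finite(theta)) || any(theta <= 0)) stop("theta must be positive")
  stats::dnbinom(r, size = theta, mu = mu, log = log)
}

#' Assemble observations for the rank mixed model
#'
#' @param rank positive integer viability ranks R_ik (one per observation,
#'   i.e. per retained shRNA x cell line with an observed rank).
#' @param mutant 0/1 alteration status X_ik; must be constant within a cell
#'   line (it is a property of the cell line for the tested gene).
#' @param cell_line cell-line identifier per observation.
#' @return object of class `nbdep_glmm_obs` carrying the observation vectors
#'   and per-cluster sufficient statistics.
#' @export
glmm_observations <- function(rank, mutant, cell_line) {
  rank <- as.numeric(rank)
  mutant <- as.numeric(mutant)
  cell_line <- as.character(cell_line)
  stopifnot(length(rank) == length(mutant), length(rank) == length(cell_line))
  if (length(rank) == 0L) stop("no observations")
  if (anyNA(rank) || any(rank < 0) || any(rank != round(rank)))
    stop("ranks must be non-negative integers with no missing values")
  if (anyNA(mutant) || !all(mutant %in% c(0, 1)))
    stop("mutant indicator must be 0/1")
  cl <- factor(cell_line)
  k <- as.integer(cl)
  xk <- tapply(mutant, k, function(v) unique(v))
  if (any(lengths(xk) != 1L))
    stop("mutant status must be constant within a cell line")
  xk <- as.numeric(unlist(xk))
  structure(list(
    r = rank, x = mutant, cell = cell_line, k = k,
    n = length(rank), l = nlevels(cl), cell_levels = levels(cl),
    x_k = xk,
    Sr = as.vector(rowsum(rank, k)),
    n_k = tabulate(k, nbins = nlevels(cl)),
    lg1_k = as.vector(rowsum(lgamma(rank + 1), k)),
    lg1 = sum(lgamma(rank + 1))
  ), class = "nbdep_glmm_obs")
}

.gh_nodes <- function(n) {
  key <- as.character(n)
  if (is.null(.nbdep_cache$gh[[key]])) {
    gh <- pracma::gaussHermite(n)
    if (is.null(.nbdep_cache$gh)) .nbdep_cache$gh <- list()
    .nbdep_cache$gh[[key]] <- list(x = gh$x, logw = log(gh$w))
  }
  .nbdep_cache$gh[[key]]
}

# Core marginal log-likelihood. sig2 = 0 is the analytic degenerate case
# (u identically 0). Returns -Inf-safe finite value or NaN on failure.
# The theta-dependent lgamma terms are needed per cluster only for
# quadrature; the Laplace and sigma = 0 paths use their total.
.nb_glmm_loglik_core <- function(b0, b, theta, sig2, obs, n_quad = 1L) {
  eta <- b0 + b * obs$x_k
  A <- obs$Sr + obs$n_k * theta
  if (sig2 <= 0) {
    Ctot <- sum(lgamma(obs$r + theta)) - obs$n * lgamma(theta) - obs$lg1 +
      obs$n * theta * log(theta)
    mu <- exp(eta)
    return(Ctot + sum(obs$Sr * eta - A * log(mu + theta)))
  }
  # per-cluster posterior mode by damped Newton (objective globally concave)
  u <- log(pmax(obs$Sr, 0.5) / obs$n_k) - eta
  u <- u * sig2 * obs$n_k / (sig2 * obs$n_k + 1)   # shrink start toward prior
  for (it in 1:100) {
    mu <- exp(eta + u)
    g <- obs$Sr - A * mu / (mu + theta) - u / sig2
    H <- A * theta * mu / (mu + theta)^2 + 1 / sig2
    step <- pmax(pmin(g / H, 4), -4)
    u <- u + step
    if (max(abs(step)) < 1e-12) break
  }
  mu <- exp(eta + u)
  H <- A * theta * mu / (mu + theta)^2 + 1 / sig2
  if (n_quad <= 1L) {
    Ctot <- sum(lgamma(obs$r + theta)) - obs$n * lgamma(theta) - obs$lg1 +
      obs$n * theta * log(theta)
    h_no_C <- obs$Sr * (eta + u) - A * log(mu + theta) -
      u^2 / (2 * sig2) - 0.5 * log(sig2)
    return(Ctot + sum(h_no_C - 0.5 * log(H)))
  }
  C_k <- as.vector(rowsum(lgamma(obs$r + theta), obs$k)) -
    obs$n_k * lgamma(theta) - obs$lg1_k
  base_k <- C_k + obs$n_k * theta * log(theta)
  gh <- .gh_nodes(n_quad)
  s <- 1 / sqrt(H)
  U <- u + sqrt(2) * outer(s, gh$x)                       # l x q
  MU <- exp(eta + U)
  Hm <- base_k + obs$Sr * (eta + U) - A * log(MU + theta) -
    U^2 / (2 * sig2) - 0.5 * log(2 * pi * sig2)
  W <- Hm + matrix(gh$x^2 + gh$logw, nrow = obs$l, ncol = n_quad, byrow = TRUE)
  m <- apply(W, 1, max)
  sum(log(rowSums(exp(W - m))) + m + 0.5 * log(2) + log(s))
}

#' Marginal log-likelihood of the NB random-intercept model
#'
#' Each cell line's integral over its random intercept is evaluated by
#' adaptive Gauss-Hermite quadrature centred at the per-cluster posterior
#' mode with curvature scaling; `n_quad = 1` reproduces the Laplace
#' approximation. The `sigma -> 0` limit is handled analytically (u = 0).
#'
#' @param params numeric vector `(beta0, beta, log theta, log sigma)`;
#'   `log sigma = -Inf` selects the degenerate sigma = 0 model.
#' @param obs [glmm_observations()] object.
#' @param n_quad number of quadrature nodes (default 1 = Laplace).
#' @return the marginal log-likelihood (finite for valid parameters).
#' @export
nb_glmm_marginal_loglik <- function(params, obs, n_quad = 1L) {
  stopifnot(inherits(obs, "nbdep_glmm_obs"), length(params) == 4L)
  if (any(!is.finite(params[1:3])) || is.na(params[4]) || params[4] == Inf)
    stop("non-finite parameters")
  sig <- exp(params[4])
  val <- .nb_glmm_loglik_core(params[1], params[2], exp(params[3]), sig^2,
                              obs, n_quad = n_quad)
  if (!is.finite(val)) warning("marginal log-likelihood is non-finite at these parameters")
  val
}

.num_grad <- function(f, x, h = 1e-5 * (1 + abs(x))) {
  vapply(seq_along(x), function(i) {
    e <- replace(numeric(length(x)), i, h[i])
    (f(x + e) - f(x - e)) / (2 * h[i])
  }, numeric(1))
}

.num_hessian <- function(f, x, h = 1e-4 * (1 + abs(x))) {
  p <- length(x)
  H <- matrix(NA_real_, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    ei <- replace(numeric(p), i, h[i])
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i < p) for (j in (i + 1):p) {
      ej <- replace(numeric(p), j, h[j])
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

#' Fit the NB random-intercept mixed model by maximum likelihood
#'
#' Quasi-Newton (BFGS) maximisation of the marginal log-likelihood over
#' `(beta0, beta, log theta, log sigma)` from a deterministic moment-based
#' start. The sigma = 0 boundary is handled by also fitting the
#' three-parameter sigma = 0 profile and keeping whichever attains the
#' higher likelihood. The standard error of `beta` comes from the inverse of
#' a central-difference observed-information matrix at the optimum.
#'
#' @param obs [glmm_observations()] with both mutant and wild-type cell lines.
#' @param n_quad quadrature nodes (1 = Laplace, the default).
#' @param sigma_zero constrain sigma^2 = 0 (independent NB regression).
#' @param max_iter BFGS iteration cap.
#' @param tol relative gradient-norm tolerance for the convergence flag:
#'   converged requires `max |grad l| <= tol * (1 + |l|)` at the optimum.
#' @return object of class `nbdep_glmm_fit` with elements `beta0`, `beta`,
#'   `theta`, `sigma2`, `se_beta`, `loglik`, `converged`, `n_quad`,
#'   `n_obs`, `n_cell_lines`.
#' @export
fit_nb_glmm <- function(obs, n_quad = 1L, sigma_zero = FALSE,
                        max_iter = 200L, tol = 1e-6) {
  stopifnot(inherits(obs, "nbdep_glmm_obs"))
  if (length(unique(obs$x_k)) < 2L)
    stop("observations must include both mutant (X=1) and wild-type (X=0) cell lines")
  if (stats::var(obs$r) == 0) stop("degenerate observations: all ranks are equal")

  m0 <- mean(obs$r[obs$x == 0]); m1 <- mean(obs$r[obs$x == 1])
  b0_0 <- log(max(m0, 0.5))
  b_0 <- log(max(m1, 0.5)) - log(max(m0, 0.5))
  rbar <- mean(obs$r); v <- stats::var(obs$r)
  th0 <- min(max(rbar^2 / max(v - rbar, rbar / 10), 0.05), 1e4)
  cm <- obs$Sr / obs$n_k
  s0 <- min(max(stats::sd(log(pmax(cm, 0.5)) - (b0_0 + b_0 * obs$x_k)), 0.05), 3)
  start <- c(b0_0, b_0, log(th0), log(s0))

  neg4 <- function(p) {
    val <- .nb_glmm_loglik_core(p[1], p[2], exp(p[3]), exp(p[4])^2, obs, n_quad)
    if (!is.finite(val)) 1e10 else -val
  }
  neg3 <- function(p) {
    val <- .nb_glmm_loglik_core(p[1], p[2], exp(p[3]), 0, obs, n_quad)
    if (!is.finite(val)) 1e10 else -val
  }
  # box-constrained quasi-Newton; the log-sigma floor avoids grinding along
  # the flat ridge sigma -> 0 (that boundary is covered by the 3-parameter
  # sigma = 0 profile fit below)
  ctrl <- function(p) list(maxit = max_iter, factr = 1e5, ndeps = rep(1e-6, p))
  lo4 <- c(-50, -50, -30, log(1e-3)); hi4 <- c(50, 50, 30, 10)
  start[4] <- min(max(start[4], lo4[4]), hi4[4])
  polish <- function(opt, fn) {
    # rare abnormal L-BFGS-B terminations: restart with a simplex search
    if (opt$convergence == 0L) return(opt)
    nm <- stats::optim(opt$par, fn, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-12))
    if (nm$value <= opt$value) nm else opt
  }
  opt3 <- polish(stats::optim(start[1:3], neg3, method = "L-BFGS-B",
                              lower = lo4[1:3], upper = hi4[1:3],
                              control = ctrl(3L)), neg3)
  opt4 <- if (sigma_zero) NULL else
    polish(stats::optim(start, neg4, method = "L-BFGS-B",
                        lower = lo4, upper = hi4, control = ctrl(4L)), neg4)

  use0 <- sigma_zero || opt3$value <= opt4$value + 1e-6
  if (use0) {
    par <- opt3$par; negf <- neg3; loglik <- -opt3$value
    sigma2 <- 0; conv_code <- opt3$convergence
  } else {
    par <- opt4$par; negf <- neg4; loglik <- -opt4$value
    sigma2 <- exp(par[4])^2; conv_code <- opt4$convergence
  }

  H <- .num_hessian(negf, par)
  se_beta <- NA_real_
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (!is.null(V) && is.finite(V[2, 2]) && V[2, 2] > 0)
    se_beta <- sqrt(V[2, 2])
  grad <- .num_grad(negf, par)
  converged <- conv_code == 0L && is.finite(se_beta) &&
    max(abs(grad)) <= max(1e-4, tol * (1 + abs(loglik)))
  if (!converged && conv_code != 0L)
    warning("NB mixed model did not converge within max_iter; estimates returned")

  structure(list(beta0 = par[1], beta = par[2], theta = exp(par[3]),
                 sigma2 = sigma2, se_beta = se_beta, loglik = loglik,
                 converged = converged, n_quad = n_quad,
                 n_obs = obs$n, n_cell_lines = obs$l),
            class = "nbdep_glmm_fit")
}

#' @export
print.nbdep_glmm_fit <- function(x, ...) {
  cat("NB random-intercept fit:", x$n_obs, "obs in", x$n_cell_lines, "cell lines\n")
  cat(sprintf("  beta0 = %.4f  beta = %.4f (se %.4f)  theta = %.4g  sigma2 = %.4g\n",
              x$beta0, x$beta, x$se_beta, x$theta, x$sigma2))
  cat(sprintf("  loglik = %.4f  converged = %s  (quadrature nodes: %d)\n",
              x$loglik, x$converged, x$n_quad))
  invisible(x)
}

#' One-sided Wald p-value for depletion
#'
#' Tests H0: beta = 0 against H1: beta < 0 (altered lines have lower ranks,
#' i.e. stronger depletion): `p = Phi(beta_hat / se)`, the lower tail of the
#' standard normal.
#'
#' @param beta_hat estimated mutant effect.
#' @param se positive standard error.
#' @return p-value.
#' @export
wald_one_sided_p <- function(beta_hat, se) {
  if (any(!is.finite(se)) || any(se <= 0)) stop("se must be positive")
  stats::pnorm(beta_hat / se)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment `q_(i) = min_(j>=i) p_(j) n / j`, capped at 1 and
#' returned in input order (delegates to [stats::p.adjust]).
#'
#' @param pvalues numeric p-values in `[0, 1]`.
#' @return adjusted q-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Upper-tail hypergeometric overlap p-value
#'
#' `P(X >= k)` for X ~ Hypergeometric(N, K, n): the probability that a
#' random size-`n` hit list from a universe of `N` genes shares at least `k`
#' members with a size-`K` reference set (e.g. a curated driver-gene
#' catalogue).
#'
#' @param k observed overlap.
#' @param K reference-set size.
#' @param n hit-list size.
#' @param N universe size.
#' @return enrichment p-value.
#' @export
hypergeom_overlap_p <- function(k, K, n, N) {
  vals <- c(k = k, K = K, n = n, N = N)
  if (any(vals != round(vals)) || any(vals < 0)) stop("counts must be non-negative integers")
  if (k > min(n, K) || K > N || n > N)
    stop("inconsistent counts: need 0 <= k <= min(n, K) <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}
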