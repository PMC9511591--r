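# stage2_heritability: variance-component estimation under
#   y ~ N(X beta, G sigma_g2 + I sigma_e2)
# by ReML (eigen-rotation + 1-D profile in lambda = sigma_g2/sigma_e2),
# Gibbs sampling and Hamiltonian Monte Carlo on the marginalised posterior.
# All three work in the eigenbasis of G, where the covariance is diagonal.

#' Standardize a vector to mean 0, sample variance 1
#' @param v numeric vector without missing values.
#' @return standardized vector.
#' @export
standardize <- function(v) {
  if (anyNA(v)) stop("standardize: missing values present")
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) stop("standardize: constant vector")
  (v - mean(v)) / s
}

#' Heritability from variance components
#' @param sigma_g2 genetic variance (>= 0).
#' @param sigma_e2 error variance (>= 0).
#' @return `sigma_g2 / (sigma_g2 + sigma_e2)`.
#' @export
h2_from_components <- function(sigma_g2, sigma_e2) {
  if (any(sigma_g2 < 0) || any(sigma_e2 < 0)) {
    stop("variance components must be non-negative")
  }
  tot <- sigma_g2 + sigma_e2
  if (any(tot == 0)) stop("h2 undefined: both components zero")
  sigma_g2 / tot
}

#' Prior specification for the Bayesian samplers
#'
#' Fixed effects `beta_j ~ N(0, beta_sd^2)` (default SD 1000, effectively
#' flat on standardized data); both variance components
#' `~ InvGamma(s1, s2)` with `s1 = s2 = 0.001` as a conventional
#' non-informative default.
#'
#' @param beta_sd prior SD of each fixed effect.
#' @param s1,s2 inverse-gamma shape and scale for both variances.
#' @return list of class `h2_priors`.
#' @export
h2_priors <- function(beta_sd = 1000, s1 = 0.001, s2 = 0.001) {
  stopifnot(beta_sd > 0, s1 > 0, s2 > 0)
  structure(list(beta_sd = beta_sd, s1 = s1, s2 = s2), class = "h2_priors")
}

# ---- restricted log-likelihood in the eigenbasis --------------------------

# yt = U'y, Xt = U'X, d = eigenvalues of G.  Profiled GLS at given
# components; returns the REML log-likelihood
#   -1/2 [ sum log v + log|X'V^-1 X| + r'V^-1 r + (n-p) log 2pi ]
reml_ll_components <- function(sg2, se2, yt, Xt, d) {
  n <- length(yt); p <- ncol(Xt)
  v <- sg2 * d + se2
  if (any(v <= 0)) return(-Inf)
  w <- 1 / v
  A <- crossprod(Xt, Xt * w)
  bet <- tryCatch(solve(A, crossprod(Xt, w * yt)), error = function(e) NULL)
  if (is.null(bet)) return(-Inf)
  r <- yt - Xt %*% bet
  quad <- sum(w * r^2)
  ldA <- as.numeric(determinant(A, logarithm = TRUE)$modulus)
  -0.5 * (sum(log(v)) + ldA + quad + (n - p) * log(2 * pi))
}

# Profile over lambda = sg2/se2 with se2 maximised analytically.
reml_ll_lambda <- function(lam, yt, Xt, d) {
  n <- length(yt); p <- ncol(Xt)
  w <- 1 / (lam * d + 1)
  A <- crossprod(Xt, Xt * w)
  bet <- solve(A, crossprod(Xt, w * yt))
  r <- yt - Xt %*% bet
  rss <- sum(w * r^2)
  se2 <- rss / (n - p)
  ll <- -0.5 * ((n - p) * log(se2) - sum(log(w)) +
                  as.numeric(determinant(A, logarithm = TRUE)$modulus) +
                  (n - p) * (1 + log(2 * pi)))
  list(ll = ll, se2 = se2, beta = bet, A = A)
}

#' Restricted maximum likelihood fit of the polygenic mixed model
#'
#' Maximises the restricted log-likelihood of
#' `y ~ N(X beta, G sigma_g2 + I sigma_e2)` over non-negative variance
#' components, using the eigendecomposition of `G` and a 1-D profile in
#' `lambda = sigma_g2 / sigma_e2` (coarse log-grid bracket then golden
#' section).  Boundary estimates (`sigma_g2 = 0`) are permitted; there the
#' observed information is singular and SDs are reported as `NA`.
#' Standard deviations elsewhere come from the inverse observed
#' information (central-difference Hessian), with the h2 SD by the delta
#' method.
#'
#' @param y numeric response (typically standardized).
#' @param X fixed-effects design matrix (with intercept column).
#' @param G genetic relatedness matrix aligned with `y`.
#' @param ed optional precomputed `eigen(G, symmetric = TRUE)`.
#' @return list with components `sigma_g2`, `sigma_e2`, `h2`, their SDs,
#'   `beta` (GLS estimates with SDs), `loglik`, `loglik_null` (restricted
#'   log-likelihood at `sigma_g2 = 0`), `lambda`, `boundary`.
#' @export
reml_fit <- function(y, X, G, ed = NULL) {
  X <- as.matrix(X)
  n <- length(y); p <- ncol(X)
  if (n <= p) stop("need more observations than fixed effects")
  if (is.null(ed)) ed <- eigen(G, symmetric = TRUE)
  if (min(ed$values) < -1e-8) stop("G is not positive semi-definite")
  d <- pmax(ed$values, 1e-12)
  yt <- drop(crossprod(ed$vectors, y))
  Xt <- crossprod(ed$vectors, X)
  if (qr(Xt)$rank < p) stop("singular fixed-effects design")

  loglam <- seq(-18, 18, length.out = 73)
  lls <- vapply(loglam, function(ll) reml_ll_lambda(exp(ll), yt, Xt, d)$ll,
                numeric(1))
  k <- which.max(lls)
  lo <- loglam[max(1, k - 1)]; hi <- loglam[min(length(loglam), k + 1)]
  opt <- stats::optimize(function(ll) reml_ll_lambda(exp(ll), yt, Xt, d)$ll,
                         c(lo, hi), maximum = TRUE, tol = 1e-9)
  null <- reml_ll_lambda(0, yt, Xt, d)
  boundary <- null$ll >= opt$objective - 1e-9 || exp(opt$maximum) < 1e-7
  if (boundary) {
    lam <- 0; prof <- null; ll_hat <- null$ll
  } else {
    lam <- exp(opt$maximum); prof <- reml_ll_lambda(lam, yt, Xt, d)
    ll_hat <- prof$ll
  }
  se2 <- prof$se2
  sg2 <- lam * se2
  h2 <- h2_from_components(sg2, se2)

  # fixed effects and their GLS covariance at the optimum
  beta_cov <- solve(prof$A) * se2
  beta <- drop(prof$beta)
  beta_sd <- sqrt(diag(beta_cov))
  names(beta) <- names(beta_sd) <- colnames(X)

  sds <- c(sg2 = NA_real_, se2 = NA_real_, sp2 = NA_real_, h2 = NA_real_)
  if (!boundary) {
    f <- function(a, b) reml_ll_components(a, b, yt, Xt, d)
    h1 <- 1e-5 + 1e-4 * sg2
    h2s <- 1e-5 + 1e-4 * se2
    H <- matrix(NA_real_, 2, 2)
    H[1, 1] <- (f(sg2 + h1, se2) - 2 * ll_hat + f(sg2 - h1, se2)) / h1^2
    H[2, 2] <- (f(sg2, se2 + h2s) - 2 * ll_hat + f(sg2, se2 - h2s)) / h2s^2
    H[1, 2] <- H[2, 1] <-
      (f(sg2 + h1, se2 + h2s) - f(sg2 + h1, se2 - h2s) -
         f(sg2 - h1, se2 + h2s) + f(sg2 - h1, se2 - h2s)) / (4 * h1 * h2s)
    V <- tryCatch(solve(-H), error = function(e) NULL)
    if (!is.null(V) && all(diag(V) > 0)) {
      tot <- sg2 + se2
      gh <- c(se2, -sg2) / tot^2
      sds <- c(sg2 = sqrt(V[1, 1]), se2 = sqrt(V[2, 2]),
               sp2 = sqrt(sum(V)), h2 = sqrt(drop(t(gh) %*% V %*% gh)))
    }
  }
  list(sigma_g2 = sg2, sigma_e2 = se2, h2 = h2,
       sigma_g2_sd = sds[["sg2"]], sigma_e2_sd = sds[["se2"]],
       sigma_p2 = sg2 + se2, sigma_p2_sd = sds[["sp2"]],
       h2_sd = sds[["h2"]],
       beta = beta, beta_sd = beta_sd, beta_cov = beta_cov,
       loglik = ll_hat, loglik_null = null$ll,
       lambda = lam, boundary = boundary)
}

# ---- Gibbs sampler --------------------------------------------------------

rinvgamma1 <- function(shape, scale) 1 / stats::rgamma(1L, shape, rate = scale)

#' Gibbs sampler for the Bayesian polygenic model
#'
#' Systematic-scan Gibbs sampling of `beta | .` (Gaussian), the polygenic
#' effect `g | .` (Gaussian; sampled in the eigenbasis of `G`, where its
#' full-conditional precision `I/sigma_e2 + G^-1/sigma_g2` is diagonal),
#' `sigma_g2 | g ~ InvGamma(s1 + n/2, s2 + g'G^-1 g / 2)` and
#' `sigma_e2 | resid ~ InvGamma(s1 + n/2, s2 + e'e / 2)`.  The first
#' `burnin` draws are discarded; per-draw `h2 = sigma_g2 /
#' (sigma_g2 + sigma_e2)` is recorded.
#'
#' @param y,X,G,ed as in [reml_fit()].
#' @param priors an [h2_priors()] object.
#' @param niter total iterations (the study design uses 100000).
#' @param burnin discarded iterations (study design 10000).
#' @param seed RNG seed; fixed seed reproduces the chain exactly.
#' @return list with `draws` (data.frame of kept draws: fixed effects,
#'   `sigma_g2`, `sigma_e2`, `h2`), `n_total`, `n_kept`, and `diagnostics`
#'   (effective sample size and split-Rhat for `h2`).
#' @export
gibbs_fit <- function(y, X, G, priors = h2_priors(), niter = 100000,
                      burnin = 10000, seed = NULL, ed = NULL) {
  stopifnot(niter > burnin, burnin >= 0)
  X <- as.matrix(X)
  n <- length(y); p <- ncol(X)
  if (is.null(ed)) ed <- eigen(G, symmetric = TRUE)
  d <- ed$values
  if (min(d) < 1e-10) {
    stop("G must be positive definite for the Gibbs sampler")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  yt <- drop(crossprod(ed$vectors, y))
  Xt <- crossprod(ed$vectors, X)
  XtX <- crossprod(Xt)            # == X'X (U orthogonal)
  Xty <- drop(crossprod(Xt, yt))  # == X'y
  s1 <- priors$s1; s2 <- priors$s2
  prior_prec_b <- diag(1 / priors$beta_sd^2, p)

  beta <- rep(0, p)
  v0 <- stats::var(y)
  sg2 <- se2 <- max(v0 / 2, 1e-3)
  h <- rep(0, n)                  # polygenic effect in eigen coordinates

  keep <- niter - burnin
  draws <- matrix(NA_real_, keep, p + 3)
  colnames(draws) <- c(colnames(X), "sigma_g2", "sigma_e2", "h2")
  shape <- s1 + n / 2
  for (it in seq_len(niter)) {
    # h | . : diagonal Gaussian in the eigenbasis
    rt <- yt - drop(Xt %*% beta)
    prec <- 1 / se2 + 1 / (sg2 * d)
    h <- rt / (se2 * prec) + stats::rnorm(n) / sqrt(prec)
    # beta | .
    Pb <- XtX / se2 + prior_prec_b
    Lb <- chol(Pb)
    mb <- backsolve(Lb, forwardsolve(t(Lb), (Xty - drop(crossprod(Xt, h))) / se2))
    beta <- mb + backsolve(Lb, stats::rnorm(p))
    # variance components
    sg2 <- rinvgamma1(shape, s2 + sum(h^2 / d) / 2)
    e <- yt - drop(Xt %*% beta) - h
    se2 <- rinvgamma1(shape, s2 + sum(e^2) / 2)
    if (!is.finite(sg2) || !is.finite(se2)) {
      stop("divergent chain at iteration ", it)
    }
    if (it > burnin) {
      draws[it - burnin, ] <- c(beta, sg2, se2, sg2 / (sg2 + se2))
    }
  }
  draws <- as.data.frame(draws)
  list(draws = draws, n_total = niter, n_kept = keep,
       diagnostics = chain_diagnostics(draws$h2))
}

# ---- Hamiltonian Monte Carlo ---------------------------------------------

# Marginalised log-posterior over theta = (beta, log sg2, log se2): the
# polygenic effect is integrated out analytically via the eigenbasis, the
# log-variance parameterisation carries its Jacobian, and the gradient is
# analytic.
hmc_logpost_grad <- function(theta, yt, Xt, d, priors) {
  p <- ncol(Xt)
  beta <- theta[seq_len(p)]
  sg2 <- exp(theta[p + 1]); se2 <- exp(theta[p + 2])
  v <- sg2 * d + se2
  r <- yt - drop(Xt %*% beta)
  s1 <- priors$s1; s2 <- priors$s2
  lp <- -0.5 * sum(log(v) + r^2 / v) -
    0.5 * sum(beta^2) / priors$beta_sd^2 -
    s1 * theta[p + 1] - s2 / sg2 -
    s1 * theta[p + 2] - s2 / se2
  q <- -0.5 * (1 / v - r^2 / v^2)
  grad <- c(drop(crossprod(Xt, r / v)) - beta / priors$beta_sd^2,
            sum(q * d) * sg2 - s1 + s2 / sg2,
            sum(q) * se2 - s1 + s2 / se2)
  list(lp = lp, grad = grad)
}

leapfrog <- function(theta, mom, eps, n_steps, yt, Xt, d, priors) {
  lg <- hmc_logpost_grad(theta, yt, Xt, d, priors)
  mom <- mom + 0.5 * eps * lg$grad
  for (s in seq_len(n_steps)) {
    theta <- theta + eps * mom
    lg <- hmc_logpost_grad(theta, yt, Xt, d, priors)
    if (!all(is.finite(lg$grad))) return(list(theta = theta, lp = -Inf, mom = mom))
    mom <- mom + (if (s < n_steps) eps else 0.5 * eps) * lg$grad
  }
  list(theta = theta, lp = lg$lp, mom = mom)
}

#' Hamiltonian Monte Carlo for the Bayesian polygenic model
#'
#' HMC with leapfrog integration on the marginalised posterior of
#' `(beta, log sigma_g2, log sigma_e2)` — the polygenic effect is
#' integrated out analytically in the eigenbasis of `G`, and the
#' log-variance parameters carry the Jacobian correction.  The step size
#' is tuned by dual averaging (target acceptance 0.8) during burn-in and
#' then frozen; the trajectory length is fixed.  Persistent divergences
#' after warm-up (> 5% of iterations) raise an error.
#'
#' @inheritParams gibbs_fit
#' @param n_leapfrog leapfrog steps per trajectory.
#' @return list as in [gibbs_fit()] plus `step_size`, `accept_rate`,
#'   `divergences`.
#' @export
hmc_fit <- function(y, X, G, priors = h2_priors(), niter = 100000,
                    burnin = 10000, seed = NULL, n_leapfrog = 25,
                    ed = NULL) {
  stopifnot(niter > burnin, burnin >= 1)
  X <- as.matrix(X)
  n <- length(y); p <- ncol(X)
  if (is.null(ed)) ed <- eigen(G, symmetric = TRUE)
  d <- ed$values
  if (min(d) < 1e-10) stop("G must be positive definite for HMC")
  if (!is.null(seed)) set.seed(as.integer(seed))
  yt <- drop(crossprod(ed$vectors, y))
  Xt <- crossprod(ed$vectors, X)

  v0 <- stats::var(y)
  theta <- c(rep(0, p), log(v0 / 2), log(v0 / 2))
  npar <- p + 2
  cur <- hmc_logpost_grad(theta, yt, Xt, d, priors)

  # dual averaging (target acceptance 0.8)
  eps <- 0.1; mu <- log(10 * eps)
  hbar <- 0; log_eps_bar <- log(eps)
  gamma <- 0.05; t0 <- 10; kappa <- 0.75; delta <- 0.8

  keep <- niter - burnin
  draws <- matrix(NA_real_, keep, p + 3)
  colnames(draws) <- c(colnames(X), "sigma_g2", "sigma_e2", "h2")
  acc_sum <- 0; n_div <- 0L
  for (it in seq_len(niter)) {
    mom0 <- stats::rnorm(npar)
    H0 <- cur$lp - 0.5 * sum(mom0^2)
    prop <- leapfrog(theta, mom0, eps, n_leapfrog, yt, Xt, d, priors)
    H1 <- prop$lp - 0.5 * sum(prop$mom^2)
    dH <- H1 - H0
    divergent <- !is.finite(dH) || dH < -1000
    a <- if (divergent) 0 else min(1, exp(dH))
    if (!divergent && stats::runif(1) < a) {
      theta <- prop$theta
      cur <- hmc_logpost_grad(theta, yt, Xt, d, priors)
    }
    if (it <= burnin) {
      m <- it
      hbar <- (1 - 1 / (m + t0)) * hbar + (delta - a) / (m + t0)
      log_eps <- mu - sqrt(m) / gamma * hbar
      w <- m^(-kappa)
      log_eps_bar <- w * log_eps + (1 - w) * log_eps_bar
      eps <- exp(log_eps)
      if (it == burnin) eps <- exp(log_eps_bar)
    } else {
      acc_sum <- acc_sum + a
      n_div <- n_div + divergent
      sg2 <- exp(theta[p + 1]); se2 <- exp(theta[p + 2])
      draws[it - burnin, ] <- c(theta[seq_len(p)], sg2, se2,
                                sg2 / (sg2 + se2))
    }
  }
  if (n_div / keep > 0.05) {
    stop("HMC: ", n_div, " divergences in ", keep,
         " post-warmup iterations (> 5%)")
  }
  draws <- as.data.frame(draws)
  list(draws = draws, n_total = niter, n_kept = keep,
       step_size = eps, accept_rate = acc_sum / keep, divergences = n_div,
       diagnostics = chain_diagnostics(draws$h2))
}

# ---- chain diagnostics ----------------------------------------------------

# Effective sample size via Geyer's initial positive sequence.
ess <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(NA_real_)
  lag_max <- min(n - 1L, 1000L)
  rho <- drop(stats::acf(x, lag.max = lag_max, plot = FALSE)$acf)[-1]
  npair <- floor(length(rho) / 2)
  if (npair == 0) return(n)
  g <- rho[2 * seq_len(npair) - 1] + rho[2 * seq_len(npair)]
  m <- which(g <= 0)[1]
  s <- if (is.na(m)) sum(g) else if (m > 1) sum(g[seq_len(m - 1)]) else 0
  min(n, n / (1 + 2 * s))
}

# Split-Rhat: compare the two halves of a single chain.
split_rhat <- function(x) {
  n <- 2 * (length(x) %/% 2)
  if (n < 4) return(NA_real_)
  half <- matrix(x[seq_len(n)], ncol = 2)
  m <- ncol(half); len <- nrow(half)
  means <- colMeans(half)
  vars <- apply(half, 2, stats::var)
  B <- len * stats::var(means)
  W <- mean(vars)
  if (W == 0) return(NA_real_)
  sqrt(((len - 1) / len * W + B / len) / W)
}

chain_diagnostics <- function(x) {
  list(ess = ess(x), split_rhat = split_rhat(x))
}

# ---- user-facing fitting function ----------------------------------------

#' Fit the polygenic mixed model and estimate heritability
#'
#' The Stage-2 fitting function.  The left-hand side of `formula` names
#' the trait, the right-hand side the fixed covariates (default age
#' only).  The trait and all numeric covariates are standardized to mean
#' 0, variance 1 before estimation; rows with a missing trait or
#' covariate are dropped and `G` is subset to the remaining individuals.
#' Method `"reml"` maximises the restricted likelihood; `"gibbs"` and
#' `"hmc"` sample the Bayesian model with priors from [h2_priors()],
#' keeping the last `niter - burnin` draws and summarising `h2` as the
#' posterior mean (SD) of the per-draw ratio.
#'
#' @param formula e.g. `cimt_left ~ age`.
#' @param data phenotype data.frame with `individual_id`.
#' @param pedigree a [build_pedigree()] object covering the individuals
#'   (or a precomputed GRM with dimnames).
#' @param method `"reml"`, `"gibbs"` or `"hmc"`.
#' @param niter,burnin sampler lengths (ignored for ReML).
#' @param priors an [h2_priors()] object.
#' @param seed RNG seed for the samplers.
#' @param scale standardize trait and numeric covariates (default TRUE).
#' @param ... passed to the low-level fitters.
#' @return object of class `heritability`.
#' @examples
#' sim <- generate_dataset(synthetic_config(n_families = 40, seed = 7))
#' fit <- heritability(cimt_left ~ age, sim$data, sim$pedigree)
#' fit
#' @export
heritability <- function(formula, data, pedigree,
                         method = c("reml", "gibbs", "hmc"),
                         niter = 100000, burnin = 10000,
                         priors = h2_priors(), seed = NULL,
                         scale = TRUE, ...) {
  method <- match.arg(method)
  cl <- match.call()
  if (!"individual_id" %in% names(data)) {
    stop("data must carry individual_id to align with the pedigree")
  }
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  keep <- stats::complete.cases(mf)
  if (sum(keep) < 5) stop("insufficient complete observations")
  mf <- mf[keep, , drop = FALSE]
  ids <- data$individual_id[keep]
  y <- mf[[1L]]
  trait <- deparse(formula[[2L]])
  covs <- attr(stats::terms(formula), "term.labels")
  X <- matrix(1, nrow(mf), 1, dimnames = list(NULL, "(Intercept)"))
  for (cv in covs) {
    v <- mf[[cv]]
    if (is.character(v) || is.factor(v)) {
      v <- as.numeric(as.factor(v)) - 1
    } else if (scale) {
      v <- standardize(v)
    }
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- cv
  }
  if (scale) y <- standardize(y)

  Gfull <- if (inherits(pedigree, "pedigree")) grm(pedigree) else pedigree
  miss <- setdiff(ids, rownames(Gfull))
  if (length(miss)) {
    stop("pedigree does not cover individuals: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  G <- Gfull[ids, ids]
  ed <- eigen(G, symmetric = TRUE)

  fit <- switch(method,
    reml = reml_fit(y, X, G, ed = ed),
    gibbs = gibbs_fit(y, X, G, priors, niter, burnin, seed, ed = ed),
    hmc = hmc_fit(y, X, G, priors, niter, burnin, seed, ed = ed, ...))

  obj <- list(call = cl, method = method, trait = trait, n = length(y),
              ids = ids, y = y, X = X, G = G, ed = ed,
              niter = if (method == "reml") NA_integer_ else niter,
              burnin = if (method == "reml") NA_integer_ else burnin,
              priors = priors, seed = seed)
  if (method == "reml") {
    obj <- c(obj, fit[c("sigma_g2", "sigma_e2", "h2", "sigma_g2_sd",
                        "sigma_e2_sd", "sigma_p2", "sigma_p2_sd", "h2_sd",
                        "beta", "beta_sd", "beta_cov", "loglik",
                        "loglik_null", "lambda", "boundary")])
    obj$samples <- NULL
    obj$diagnostics <- NULL
  } else {
    dr <- fit$draws
    p <- ncol(obj$X)
    obj$sigma_g2 <- mean(dr$sigma_g2); obj$sigma_g2_sd <- stats::sd(dr$sigma_g2)
    obj$sigma_e2 <- mean(dr$sigma_e2); obj$sigma_e2_sd <- stats::sd(dr$sigma_e2)
    sp <- dr$sigma_g2 + dr$sigma_e2
    obj$sigma_p2 <- mean(sp); obj$sigma_p2_sd <- stats::sd(sp)
    obj$h2 <- mean(dr$h2); obj$h2_sd <- stats::sd(dr$h2)
    obj$beta <- colMeans(dr[seq_len(p)])
    obj$beta_sd <- vapply(dr[seq_len(p)], stats::sd, numeric(1))
    names(obj$beta) <- names(obj$beta_sd) <- colnames(obj$X)
    obj$boundary <- FALSE
    obj$samples <- dr
    obj$n_kept <- fit$n_kept
    obj$diagnostics <- fit$diagnostics
    if (method == "hmc") {
      obj$step_size <- fit$step_size
      obj$accept_rate <- fit$accept_rate
      obj$divergences <- fit$divergences
    }
  }
  class(obj) <- "heritability"
  obj
}

#' @export
print.heritability <- function(x, ...) {
  cat(sprintf("Polygenic mixed model (%s), trait '%s', n = %d\n",
              toupper(x$method), x$trait, x$n))
  cat("  genetic variance   :", fmt_est_sd(x$sigma_g2, x$sigma_g2_sd), "\n")
  cat("  error variance     :", fmt_est_sd(x$sigma_e2, x$sigma_e2_sd), "\n")
  cat("  phenotypic variance:", fmt_est_sd(x$sigma_p2, x$sigma_p2_sd), "\n")
  cat("  heritability h2    :", fmt_est_sd(x$h2, x$h2_sd), "\n")
  if (isTRUE(x$boundary)) {
    cat("  note: sigma_g2 on the boundary (0); SDs unavailable\n")
  }
  invisible(x)
}

#' @export
summary.heritability <- function(object, ...) {
  out <- list(fit = object)
  class(out) <- "summary.heritability"
  out
}

#' @export
print.summary.heritability <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("  fixed effects:\n")
  tab <- cbind(estimate = f$beta, sd = f$beta_sd)
  print(round(tab, 4))
  if (!is.null(f$diagnostics)) {
    cat(sprintf("  kept draws: %d   ESS(h2): %.0f   split-Rhat(h2): %.3f\n",
                f$n_kept, f$diagnostics$ess, f$diagnostics$split_rhat))
  }
  if (!is.null(f$loglik)) {
    cat(sprintf("  restricted log-likelihood: %.4f\n", f$loglik))
  }
  invisible(x)
}

#' @export
coef.heritability <- function(object, ...) object$beta

#' @export
vcov.heritability <- function(object, ...) {
  if (object$method == "reml") return(object$beta_cov)
  p <- ncol(object$X)
  stats::cov(object$samples[seq_len(p)])
}

#' @export
logLik.heritability <- function(object, ...) {
  if (object$method != "reml") {
    stop("log-likelihood only available for the ReML fit")
  }
  structure(object$loglik, df = ncol(object$X) + 2, class = "logLik")
}

# BLUP of the polygenic effect at the point estimates, in the eigenbasis.
blup_g <- function(object) {
  r <- object$y - drop(object$X %*% object$beta)
  d <- object$ed$values
  shrink <- object$sigma_g2 * d / (object$sigma_g2 * d + object$sigma_e2)
  drop(object$ed$vectors %*% (shrink * drop(crossprod(object$ed$vectors, r))))
}

#' @export
fitted.heritability <- function(object, ...) {
  drop(object$X %*% object$beta) + blup_g(object)
}

#' @export
residuals.heritability <- function(object, ...) {
  object$y - fitted(object)
}

#' @export
simulate.heritability <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n
  d <- pmax(object$ed$values, 0)
  mu <- drop(object$X %*% object$beta)
  out <- replicate(nsim, {
    g <- drop(object$ed$vectors %*% (sqrt(object$sigma_g2 * d) * stats::rnorm(n)))
    mu + g + stats::rnorm(n, sd = sqrt(object$sigma_e2))
  })
  as.data.frame(out)
}

#' @export
plot.heritability <- function(x, ...) {
  if (x$method == "reml") {
    h2g <- seq(0.001, 0.95, length.out = 120)
    yt <- drop(crossprod(x$ed$vectors, x$y))
    Xt <- crossprod(x$ed$vectors, x$X)
    ll <- vapply(h2g, function(h) {
      reml_ll_lambda(h / (1 - h), yt, Xt, pmax(x$ed$values, 1e-12))$ll
    }, numeric(1))
    plot(h2g, ll, type = "l", xlab = expression(h^2),
         ylab = "restricted log-likelihood",
         main = paste("Profile likelihood:", x$trait), ...)
    abline(v = x$h2, col = "firebrick", lwd = 2)
  } else {
    op <- par(mfrow = c(1, 2)); on.exit(par(op))
    plot(x$samples$h2, type = "l", xlab = "kept iteration",
         ylab = expression(h^2), main = paste("Trace:", x$trait))
    plot(stats::density(x$samples$h2), xlab = expression(h^2),
         main = "Posterior density")
    abline(v = x$h2, col = "firebrick", lwd = 2)
  }
  invisible(x)
}

#' Likelihood-ratio test for a genetic variance component
#'
#' `2 * (loglik_full - loglik_null)` referred to the boundary null, a
#' 50:50 mixture of a point mass at 0 and chi-squared with 1 df.
#'
#' @param fit a `heritability` object fitted with `method = "reml"`.
#' @return list with `statistic` and `p`.
#' @export
lrt_h2 <- function(fit) {
  if (!inherits(fit, "heritability") || fit$method != "reml") {
    stop("lrt_h2 requires a ReML heritability fit")
  }
  stat <- max(0, 2 * (fit$loglik - fit$loglik_null))
  p <- if (stat <= 0) 1 else 0.5 * stats::pchisq(stat, df = 1,
                                                 lower.tail = FALSE)
  list(statistic = stat, p = p)
}

#' Simulation-based power for detecting heritability
#'
#' Simulates maternal-line trio cohorts with a trait of true heritability
#' `h2_true` (unit phenotypic variance), fits the polygenic model by ReML
#' and applies the boundary likelihood-ratio test at level `alpha`.  The
#' rejection fraction estimates power, with a binomial Monte-Carlo SE.
#' This is a simulation analogue of an analytic design calculation, not a
#' replication of any particular closed form.
#'
#' @param n_families trio count of the design.
#' @param h2_true true heritability in `[0, 1)`.
#' @param alpha test level.
#' @param n_reps simulation replicates (>= 100 recommended).
#' @param seed RNG seed.
#' @return object of class `power_estimate`: `power`, `se`, `n_reps`, ...
#' @export
estimate_power <- function(n_families = 65, h2_true, alpha = 0.05,
                           n_reps = 500, seed = NULL) {
  stopifnot(h2_true >= 0, h2_true < 1, n_reps >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  f <- n_families
  n <- 3L * f
  # fixed trio GRM eigensystem (block-diagonal, identical blocks)
  ped <- generate_pedigree(f, seed = NULL, p_female_child = 0.5)
  G <- grm(ped, check_psd = FALSE)
  ed <- eigen(G, symmetric = TRUE)
  sg2 <- h2_true; se2 <- 1 - h2_true
  mi <- match(ped$mother_id, ped$individual_id)  # topological order
  rej <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    g <- numeric(n)
    if (sg2 > 0) {
      for (i in seq_len(n)) {
        g[i] <- if (is.na(mi[i])) stats::rnorm(1, sd = sqrt(sg2))
        else 0.5 * g[mi[i]] + stats::rnorm(1, sd = sqrt(0.75 * sg2))
      }
    }
    y <- g + stats::rnorm(n, sd = sqrt(se2))
    X <- cbind(`(Intercept)` = rep(1, n))
    fit <- reml_fit(y, X, G, ed = ed)
    stat <- max(0, 2 * (fit$loglik - fit$loglik_null))
    p <- if (stat <= 0) 1 else 0.5 * stats::pchisq(stat, 1, lower.tail = FALSE)
    rej[r] <- p < alpha
  }
  pw <- mean(rej)
  structure(list(power = pw, se = sqrt(pw * (1 - pw) / n_reps),
                 n_reps = n_reps, h2_true = h2_true, alpha = alpha,
                 n_families = n_families),
            class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf(
    "Simulated power: %.3f (MC-SE %.3f) for h2 = %.2f, %d families, alpha = %.2f (%d reps)\n",
    x$power, x$se, x$h2_true, x$n_families, x$alpha, x$n_reps))
  invisible(x)
}
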