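# Independent oracles, kept deliberately naive: dense linear algebra and
# direct formulas, no shared code with the package internals.

# Restricted log-likelihood of y ~ N(X b, sg2*G + se2*I) by dense solves:
#   -1/2 [ log|V| + log|X'V^-1 X| + r'V^-1 r + (n-p) log 2pi ]
oracle_reml_ll <- function(sg2, se2, y, X, G) {
  n <- length(y); p <- ncol(X)
  V <- sg2 * G + se2 * diag(n)
  Vi <- solve(V)
  A <- t(X) %*% Vi %*% X
  beta <- solve(A, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  ldV <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  ldA <- as.numeric(determinant(A, logarithm = TRUE)$modulus)
  -0.5 * (ldV + ldA + drop(t(r) %*% Vi %*% r) + (n - p) * log(2 * pi))
}

# OLS coefficients straight from the normal equations.
oracle_ols <- function(X, y) drop(solve(t(X) %*% X, t(X) %*% y))
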