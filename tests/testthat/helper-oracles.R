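# Independent oracles used to cross-check the package's linear algebra.

# naive double-loop evaluation of diag(y)(r + A y)
rhs_oracle <- function(y, r, A) {
  n <- length(y)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- r[i]
    for (j in seq_len(n)) s <- s + A[i, j] * y[j]
    out[i] <- y[i] * s
  }
  out
}

# characteristic polynomial coefficients by the Faddeev-LeVerrier
# recursion; spectral abscissa from polyroot() — no eigendecomposition
spectral_abscissa_oracle <- function(J) {
  n <- nrow(J)
  coefs <- numeric(n + 1)  # c0 x^n + c1 x^(n-1) + ... + cn
  coefs[1] <- 1
  M <- diag(1, n)
  for (k in seq_len(n)) {
    M <- J %*% M
    ck <- -sum(diag(M)) / k
    coefs[k + 1] <- ck
    M <- M + diag(ck, n)
  }
  roots <- polyroot(rev(coefs))
  max(Re(roots))
}

random_model <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(stats::rnorm(n * n, 0, 0.5), n, n)
  diag(A) <- -abs(stats::rnorm(n, 1, 0.3))
  y_bar <- stats::runif(n, 0.05, 1)
  r <- as.numeric(-A %*% y_bar)
  community_model(paste0("t", seq_len(n)), r, A)
}

# a tiny stable 2-taxon model used across tests
toy_model <- function() {
  community_model(c("x", "y"), r = c(1, 0.5),
                  A = matrix(c(-1, 0.5, 0, -0.5), 2, byrow = FALSE))
}
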