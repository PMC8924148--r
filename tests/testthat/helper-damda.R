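## Shared fixtures and independent oracles used across the test files.
## Oracles deliberately avoid the code paths they check (dense formulas,
## explicit enumeration) so that agreement is informative.

## random SPD matrix via A'A + eps I (independent of the package generator)
rspd <- function(d, scale = 1) {
  A <- matrix(rnorm(d * d), d, d)
  scale * (crossprod(A) / d + diag(0.5, d))
}

## dense-formula Gaussian log-density (solve + determinant, no Cholesky)
oracle_ldmvnorm <- function(x, mu, sigma) {
  d <- length(mu)
  ld <- as.numeric(determinant(sigma, logarithm = TRUE)$modulus)
  q <- as.numeric(t(x - mu) %*% solve(sigma) %*% (x - mu))
  -0.5 * (d * log(2 * pi) + ld + q)
}

## weighted moments by explicit accumulation
oracle_weighted_moments <- function(y, w) {
  n <- sum(w)
  mu <- rep(0, ncol(y))
  for (i in seq_len(nrow(y))) mu <- mu + w[i] * y[i, ]
  mu <- mu / n
  S <- matrix(0, ncol(y), ncol(y))
  for (i in seq_len(nrow(y))) S <- S + w[i] * tcrossprod(y[i, ] - mu)
  list(mean = mu, sigma = S / n, scatter = S, n = n)
}

## all permutations of 1:n (small n), for exhaustive assignment oracles
perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in perms(n - 1L)) for (k in seq_len(n))
    out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  out
}

## exhaustive minimum-total-cost injection of columns into rows
oracle_min_assignment <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  best <- Inf; best_map <- NULL
  for (rows in utils::combn(nr, nc, simplify = FALSE)) {
    for (p in perms(nc)) {
      v <- sum(cost[cbind(rows[p], seq_len(nc))])
      if (v < best) { best <- v; best_map <- rows[p] }
    }
  }
  list(value = best, map = best_map)
}

## adjusted Rand index from explicit pair counting over all N(N-1)/2 pairs
oracle_ari_pairs <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) s11 <- s11 + 1
    else if (!sa && !sb) s00 <- s00 + 1
    else if (sa) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  tot <- choose(n, 2)
  exp_idx <- (s11 + s10) * (s11 + s01) / tot
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  (s11 - exp_idx) / (max_idx - exp_idx)
}

## construct an edda classifier object directly from given parameters
make_edda <- function(means, sigmas, props,
                      var_names = paste0("v", seq_len(nrow(means))),
                      class_names = paste0("class", seq_len(ncol(means)))) {
  rownames(means) <- var_names
  damda:::new_edda(means = means, sigmas = sigmas, props = props,
                   family = "VVV", var_names = var_names,
                   class_names = class_names)
}

## draw a test set from a mixture: K known classes on P learned variables
## augmented to R variables, plus H hidden classes; returns the test matrix
## (learned variables first) and the generating parameters
draw_augmented <- function(N, K, H, P, Q, sep = 4) {
  R <- P + Q; C <- K + H
  means <- matrix(rnorm(R * C, sd = sep / 2), R, C)
  sigmas <- array(0, c(R, R, C))
  for (c in seq_len(C)) sigmas[, , c] <- rspd(R)
  tau <- rep(1 / C, C)
  z <- sample.int(C, N, replace = TRUE, prob = tau)
  y <- matrix(0, N, R)
  for (c in seq_len(C)) {
    idx <- z == c
    if (!any(idx)) next
    y[idx, ] <- matrix(rnorm(sum(idx) * R), ncol = R) %*% chol(sigmas[, , c]) +
      matrix(means[, c], sum(idx), R, byrow = TRUE)
  }
  colnames(y) <- paste0("v", seq_len(R))
  learned <- make_edda(means[seq_len(P), seq_len(K), drop = FALSE],
                       array(sigmas[seq_len(P), seq_len(P), seq_len(K)],
                             c(P, P, K)),
                       props = rep(1 / K, K))
  list(y = y, z = z, learned = learned, means = means, sigmas = sigmas)
}

## expected complete log-likelihood term for the extra-variable block of one
## known class (the objective the inductive conditional estimates maximise),
## evaluated directly from its definition
eq8_objective <- function(yP, yQ, w, mu_bar, sigma_bar, C_k, E_k, mu_Q) {
  Sinv <- solve(sigma_bar)
  ldE <- as.numeric(determinant(as.matrix(E_k), logarithm = TRUE)$modulus)
  Einv <- solve(E_k)
  q <- ncol(as.matrix(yQ))
  total <- 0
  for (i in seq_along(w)) {
    m_ik <- mu_Q + as.numeric(t(C_k) %*% Sinv %*% (yP[i, ] - mu_bar))
    r <- yQ[i, ] - m_ik
    total <- total + w[i] *
      (-0.5 * (q * log(2 * pi) + ldE + as.numeric(t(r) %*% Einv %*% r)))
  }
  total
}
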