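## Synthetic-data generator for the class-generative / correlated / noise
## variable designs used to validate adaptive classification, plus the
## partition-agreement metrics (adjusted Rand index and matched
## classification error).
##
## Three variable types:
##   Gen - class-generative: a mixture of C multivariate Gaussians whose
##         means sit at the vertices of a scaled simplex;
##   Cor - redundant: each is a noisy linear combination of 2 randomly
##         chosen Gen variables (informative about the classes only
##         through Gen, i.e. conditionally independent of the labels);
##   Noi - independent Gaussian noise.
## A random subset of classes and of variables is hidden from the training
## set; the test set carries all classes and all variables.

#' Specification of a synthetic adaptive-classification design
#'
#' @param n_gen,n_cor,n_noi Numbers of class-generative, correlated and
#'   noise variables.
#' @param C Number of classes in the population.
#' @param K_obs Number of classes observed in the training set.
#' @param n_obs Number of variables observed in the training set.
#' @param policy Which variables the training set observes:
#'   `"all-gen"` (as many Gen variables as fit in `n_obs`, then random
#'   Cor/Noi), `"half-gen"` (half of the Gen variables), or `"few-gen"`
#'   (about a fifth, at least 2).
#' @param M,N Training and test sample sizes.
#' @param separation Pairwise distance between class means on the Gen
#'   block, in units of the average within-class standard deviation
#'   (default 3).
#' @param cor_links Number of Gen variables each Cor variable is linked to.
#' @param cor_target Target correlation between a Cor variable and its
#'   generating Gen combination (default 0.6; sets the noise variance).
#' @param noi_sd Standard deviation of the Noi variables.
#' @param cond_max Maximum condition number of the random within-class
#'   covariances on the Gen block.
#' @return A list of class `damda_sim_spec`.
#' @export
sim_spec <- function(n_gen = 10, n_cor = 30, n_noi = 60, C = 4, K_obs = 2,
                     n_obs = 20, policy = c("all-gen", "half-gen", "few-gen"),
                     M = 400, N = 400, separation = 3, cor_links = 2,
                     cor_target = 0.6, noi_sd = 1, cond_max = 10) {
  policy <- match.arg(policy)
  stopifnot(n_gen >= 1, n_cor >= 0, n_noi >= 0, C >= 1, K_obs >= 1,
            K_obs <= C, n_obs >= 1, n_obs <= n_gen + n_cor + n_noi,
            M >= 2, N >= 2, separation > 0, cor_links >= 1)
  structure(list(n_gen = n_gen, n_cor = n_cor, n_noi = n_noi, C = C,
                 K_obs = K_obs, n_obs = n_obs, policy = policy, M = M, N = N,
                 separation = separation, cor_links = cor_links,
                 cor_target = cor_target, noi_sd = noi_sd,
                 cond_max = cond_max),
            class = "damda_sim_spec")
}

## Random SPD matrix with condition number <= cond_max and eigenvalues in
## [1/cond_max, 1]: the largest within-class standard deviation is 1, so
## the separation parameter of the design reads directly in SD units.
random_spd <- function(d, cond_max) {
  if (d == 1L) return(matrix(1, 1, 1))
  lv <- sort(runif(d, -log(cond_max), 0), decreasing = TRUE)
  lv[1L] <- 0                          # anchor the largest eigenvalue at 1
  Q <- qr.Q(qr(matrix(rnorm(d * d), d, d)))
  Q %*% (exp(lv) * t(Q))
}

## C class means at the vertices of a regular simplex on the Gen block,
## scaled to the requested pairwise separation and put in general position
## by a random rotation, so that every Gen coordinate carries class-mean
## signal. When the Gen dimension is too small to host a simplex with C
## vertices, random directions with the same circumradius are used.
simplex_means <- function(n_gen, C, separation) {
  mu <- matrix(0, n_gen, C)
  if (n_gen >= C - 1 && C > 1) {
    V <- diag(C) - 1 / C               # C points, pairwise distance sqrt(2)
    B <- qr.Q(qr(V[, seq_len(C - 1), drop = FALSE]))  # orthonormal basis
    pts <- t(V %*% B)                  # (C-1) x C
    pts <- pts / sqrt(sum((pts[, 1] - pts[, 2])^2)) * separation
    mu[seq_len(C - 1), ] <- pts
    rot <- qr.Q(qr(matrix(rnorm(n_gen * n_gen), n_gen, n_gen)))
    mu <- rot %*% mu                   # distances preserved
  } else if (C > 1) {
    r <- separation / sqrt(2)
    for (c in seq_len(C)) {
      v <- rnorm(n_gen)
      mu[, c] <- v / sqrt(sum(v^2)) * r
    }
  }
  mu
}

draw_classes <- function(n, means, chols, labels, tau) {
  d <- nrow(means)
  z <- sample(seq_along(tau), n, replace = TRUE, prob = tau)
  x <- matrix(rnorm(n * d), n, d)
  for (c in seq_along(tau)) {
    idx <- z == c
    if (!any(idx)) next
    x[idx, ] <- x[idx, , drop = FALSE] %*% chols[[c]] +
      matrix(means[, c], sum(idx), d, byrow = TRUE)
  }
  list(x = x, class = labels[z])
}

#' Generate a synthetic adaptive-classification data set
#'
#' Draws training and test sets under a [sim_spec()] design: the training
#' set contains only the observed classes and observed variables; the test
#' set contains all classes and all variables, with ground-truth labels.
#'
#' @param spec A [sim_spec()] design.
#' @param seed Optional integer seed (the generator is fully reproducible
#'   given `spec` and `seed`).
#' @return A list with `train` (M x n_obs matrix), `train_class` (factor),
#'   `test` (N x R matrix), `truth` (factor), `observed_vars`,
#'   `observed_classes`, `hidden_classes`, and `params` (the population
#'   parameters: class means/covariances on Gen, Cor links and weights,
#'   noise scales).
#' @export
simulate_damda <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "damda_sim_spec"))
  if (!is.null(seed)) set.seed(seed)
  G <- spec$n_gen
  class_names <- paste0("class", seq_len(spec$C))
  var_names <- c(if (G) paste0("gen", seq_len(G)),
                 if (spec$n_cor) paste0("cor", seq_len(spec$n_cor)),
                 if (spec$n_noi) paste0("noi", seq_len(spec$n_noi)))
  tau <- rep(1 / spec$C, spec$C)
  means <- simplex_means(G, spec$C, spec$separation)
  covs <- lapply(seq_len(spec$C), function(c) random_spd(G, spec$cond_max))
  chols <- lapply(covs, chol)
  ## population moments of the Gen block under the mixture (for Cor noise)
  m_mix <- as.numeric(means %*% tau)
  Exx <- matrix(0, G, G)
  for (c in seq_len(spec$C))
    Exx <- Exx + tau[c] * (covs[[c]] + tcrossprod(means[, c]))
  cov_mix <- Exx - tcrossprod(m_mix)
  links <- weights <- vector("list", spec$n_cor)
  cor_sd <- numeric(spec$n_cor)
  for (j in seq_len(spec$n_cor)) {
    links[[j]] <- sample.int(G, min(spec$cor_links, G))
    w <- runif(length(links[[j]]), 0.5, 1.5) *
      sample(c(-1, 1), length(links[[j]]), replace = TRUE)
    weights[[j]] <- w
    s2 <- as.numeric(crossprod(w, cov_mix[links[[j]], links[[j]]] %*% w))
    cor_sd[j] <- sqrt(max(s2, 1e-12) * (1 / spec$cor_target^2 - 1))
  }
  observed_classes <- sort(sample.int(spec$C, spec$K_obs))
  n_gen_obs <- switch(spec$policy,
                      "all-gen" = G,
                      "half-gen" = max(1L, floor(G / 2)),
                      "few-gen" = max(2L, round(G / 5)))
  n_gen_obs <- min(n_gen_obs, spec$n_obs, G)
  gen_obs <- sort(sample.int(G, n_gen_obs))
  other_pool <- setdiff(var_names, paste0("gen", seq_len(G)))
  n_other <- spec$n_obs - n_gen_obs
  if (n_other > length(other_pool))
    stop("n_obs too large for the requested policy", call. = FALSE)
  observed_vars <- c(paste0("gen", gen_obs),
                     if (n_other > 0) sort(sample(other_pool, n_other)))
  observed_vars <- var_names[var_names %in% observed_vars]  # natural order

  fill <- function(n, draw) {
    x <- matrix(0, n, length(var_names), dimnames = list(NULL, var_names))
    if (G) x[, seq_len(G)] <- draw$x
    for (j in seq_len(spec$n_cor))
      x[, G + j] <- draw$x[, links[[j]], drop = FALSE] %*% weights[[j]] +
        rnorm(n, sd = cor_sd[j])
    if (spec$n_noi)
      x[, G + spec$n_cor + seq_len(spec$n_noi)] <-
        matrix(rnorm(n * spec$n_noi, sd = spec$noi_sd), n)
    x
  }
  tau_obs <- tau[observed_classes] / sum(tau[observed_classes])
  dtr <- draw_classes(spec$M, means[, observed_classes, drop = FALSE],
                      chols[observed_classes],
                      class_names[observed_classes], tau_obs)
  train <- fill(spec$M, dtr)[, observed_vars, drop = FALSE]
  dte <- draw_classes(spec$N, means, chols, class_names, tau)
  test <- fill(spec$N, dte)
  list(train = train,
       train_class = factor(dtr$class, levels = class_names[observed_classes]),
       test = test,
       truth = factor(dte$class, levels = class_names),
       observed_vars = observed_vars,
       observed_classes = class_names[observed_classes],
       hidden_classes = setdiff(class_names, class_names[observed_classes]),
       params = list(tau = tau, means = means, covs = covs,
                     cor_links = links, cor_weights = weights,
                     cor_sd = cor_sd),
       spec = spec)
}

#' Adjusted Rand index
#'
#' Hubert-Arabie chance-corrected agreement between two partitions;
#' invariant to label permutations, equal to 1 for identical partitions.
#'
#' @param a,b Two label vectors (factors, characters or integers) of the
#'   same length.
#' @return Scalar ARI.
#' @export
ari <- function(a, b) {
  if (length(a) != length(b)) stop("partitions differ in length", call. = FALSE)
  mclust::adjustedRandIndex(a, b)
}

#' Classification error on optimally matched classes
#'
#' Misclassification rate after matching predicted classes one-to-one to
#' true classes so that total agreement is maximal (exact assignment on
#' the confusion matrix); a relabelling of a perfect prediction therefore
#' has error 0.
#'
#' @param truth,pred Label vectors of the same length.
#' @return Misclassification rate in `[0, 1]`.
#' @export
matched_error <- function(truth, pred) {
  if (length(truth) != length(pred))
    stop("partitions differ in length", call. = FALSE)
  A <- as.matrix(table(truth, pred))
  if (ncol(A) > nrow(A)) A <- t(A)
  agree <- best_assignment(A)$value
  1 - agree / length(truth)
}
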