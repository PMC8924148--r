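## Initialization of the discovery EM. A hierarchical partition of the test
## data provides C = K + H candidate clusters; clusters are matched
## one-to-one to the known classes by a Gaussian Kullback-Leibler ranking
## (exact assignment), and the remaining clusters seed the hidden classes.

#' Hierarchical partition of the test data
#'
#' Deterministic Ward-linkage agglomeration on standardised columns, cut at
#' `C` clusters. Used to initialise the discovery EM.
#'
#' @param y Numeric matrix.
#' @param C Number of clusters (`C <= nrow(y)`).
#' @return Integer vector of cluster labels in `1:C`.
#' @export
hierarchical_partition <- function(y, C) {
  y <- as.matrix(y)
  if (C > nrow(y)) stop("more clusters requested than observations", call. = FALSE)
  if (C < 1L) stop("C must be >= 1", call. = FALSE)
  cutree(hclust_tree(y), k = C)
}

## Ward tree on standardised columns; shared across cuts at different C.
hclust_tree <- function(y) {
  sds <- apply(y, 2, stats::sd)
  sds[sds <= 0 | !is.finite(sds)] <- 1
  ys <- sweep(sweep(y, 2, colMeans(y)), 2, sds, "/")
  hclust(dist(ys), method = "ward.D2")
}

#' Gaussian Kullback-Leibler divergence score for cluster matching
#'
#' The matching score between a cluster (moments \eqn{\tilde\mu,
#' \tilde\Sigma}) and a known class (\eqn{\bar\mu, \bar\Sigma}):
#' \deqn{\mathrm{tr}(\tilde\Sigma^{-1}\bar\Sigma) + (\tilde\mu -
#'   \bar\mu)'\tilde\Sigma^{-1}(\tilde\mu - \bar\mu) +
#'   \log(\det\tilde\Sigma / \det\bar\Sigma).}
#' The score equals twice the KL divergence plus the dimension and is used
#' only for ranking; its minimum over matched moments is the dimension P.
#'
#' @param mu_g,sigma_g Cluster mean and covariance (SPD).
#' @param mu_k,sigma_k Known-class mean and covariance (SPD).
#' @return Scalar divergence score.
#' @export
kl_divergence <- function(mu_g, sigma_g, mu_k, sigma_k) {
  Lg <- tryCatch(chol(sigma_g), error = function(e) NULL)
  if (is.null(Lg)) stop("singular cluster covariance in KL matching", call. = FALSE)
  Sg_inv <- chol2inv(Lg)
  d <- mu_g - mu_k
  ld_g <- 2 * sum(log(diag(Lg)))
  ld_k <- as.numeric(determinant(as.matrix(sigma_k), logarithm = TRUE)$modulus)
  sum(Sg_inv * sigma_k) + as.numeric(crossprod(d, Sg_inv %*% d)) + ld_g - ld_k
}

## Exhaustive search for the injective column -> row assignment of a score
## matrix that maximises the total score. Returns the row picked for each
## column. Feasible because the number of classes is small.
best_assignment <- function(score) {
  nr <- nrow(score); nc <- ncol(score)
  stopifnot(nc <= nr)
  best <- list(value = -Inf, map = integer(nc))
  recurse <- function(j, used, acc, map) {
    if (j > nc) {
      if (acc > best$value) best <<- list(value = acc, map = map)
      return(invisible())
    }
    for (r in seq_len(nr)) {
      if (used[r]) next
      used[r] <- TRUE
      map[j] <- r
      recurse(j + 1L, used, acc + score[r, j], map)
      used[r] <- FALSE
    }
  }
  recurse(1L, logical(nr), 0, integer(nc))
  best
}

#' Match clusters to known classes by minimum total divergence
#'
#' Solves the exact assignment problem: the `K` known classes are mapped
#' one-to-one to `K` distinct clusters so that the total divergence is
#' minimal; the remaining clusters become hidden-class seeds. Exact
#' assignment (rather than greedy sequential matching) makes the result
#' independent of class ordering when one cluster is closest to several
#' classes.
#'
#' @param div C x K matrix of divergence scores (rows = clusters,
#'   columns = known classes).
#' @return List with `map` (cluster index assigned to each class) and
#'   `hidden` (the unmatched cluster indices).
#' @export
match_clusters <- function(div) {
  div <- as.matrix(div)
  if (nrow(div) < ncol(div))
    stop("need at least as many clusters as known classes", call. = FALSE)
  res <- best_assignment(-div)
  list(map = res$map, hidden = setdiff(seq_len(nrow(div)), res$map))
}

## Per-cluster moments on all R variables. Clusters with fewer than R + 2
## members have their covariance shrunk toward the pooled within-cluster
## covariance, with weight proportional to the deficiency; all covariances
## get an eigenvalue floor so they are usable as EM starting values.
cluster_moments <- function(y, part, C) {
  R <- ncol(y); N <- nrow(y)
  sizes <- tabulate(part, nbins = C)
  means <- matrix(0, R, C)
  raw <- vector("list", C)
  pooled <- matrix(0, R, R)
  for (g in seq_len(C)) {
    idx <- part == g
    yg <- y[idx, , drop = FALSE]
    means[, g] <- colMeans(yg)
    Sg <- if (sizes[g] > 1L)
      crossprod(sweep(yg, 2, means[, g])) / sizes[g] else matrix(0, R, R)
    raw[[g]] <- Sg
    pooled <- pooled + sizes[g] * Sg
  }
  pooled <- pooled / N
  if (!any(diag(pooled) > 0)) pooled <- diag(1e-8, R)
  covs <- vector("list", C)
  for (g in seq_len(C)) {
    w <- min(1, max(0, (sizes[g] - 1) / (R + 1)))
    S <- w * raw[[g]] + (1 - w) * pooled
    covs[[g]] <- pd_floor(S)
  }
  list(sizes = sizes, means = means, covs = covs)
}

## Eigenvalue floor at 1e-8 * trace / R: repairs near-singular moment
## estimates without visibly distorting well-conditioned ones.
pd_floor <- function(S) {
  S <- (S + t(S)) / 2
  R <- nrow(S)
  eg <- eigen(S, symmetric = TRUE)
  floor_val <- max(1e-8 * sum(diag(S)) / R, 1e-12)
  vals <- pmax(eg$values, floor_val)
  eg$vectors %*% (vals * t(eg$vectors))
}

## Build an initial augmented model from a hard partition of the test data.
init_from_partition <- function(y, learned, H, part) {
  K <- length(learned$class_names)
  P <- length(learned$var_names)
  R <- ncol(y); Q <- R - P; C <- K + H
  mom <- cluster_moments(y, part, C)
  ip <- seq_len(P)
  div <- matrix(0, C, K)
  for (g in seq_len(C)) for (k in seq_len(K))
    div[g, k] <- kl_divergence(mom$means[ip, g], mom$covs[[g]][ip, ip, drop = FALSE],
                               learned$means[, k], learned$sigmas[, , k])
  mc <- match_clusters(div)
  var_names <- colnames(y)
  class_names <- c(learned$class_names,
                   if (H > 0) paste0("hidden", seq_len(H)) else character(0))
  means <- matrix(0, R, C, dimnames = list(var_names, class_names))
  sigmas <- array(0, c(R, R, C))
  props <- numeric(C)
  for (k in seq_len(K)) {
    g <- mc$map[k]
    props[k] <- mom$sizes[g]
    if (Q > 0) {
      Ct <- mom$covs[[g]][ip, -ip, drop = FALSE]
      Sq <- mom$covs[[g]][-ip, -ip, drop = FALSE]
      ## scale the cross block down until the Schur complement is PD
      ak <- NULL
      for (j in 0:30) {
        ak <- tryCatch(
          assemble_known(learned$means[, k], learned$sigmas[, , k],
                         mom$means[-ip, g], Ct * 0.7^j, Sq),
          damda_assembly = function(c) NULL)
        if (!is.null(ak)) break
      }
      if (is.null(ak))
        ak <- assemble_known(learned$means[, k], learned$sigmas[, , k],
                             mom$means[-ip, g], matrix(0, P, Q), pd_floor(Sq))
      means[, k] <- ak$mean
      sigmas[, , k] <- ak$sigma
    } else {
      means[, k] <- learned$means[, k]
      sigmas[, , k] <- learned$sigmas[, , k]
    }
  }
  for (h in seq_len(H)) {
    g <- mc$hidden[h]
    props[K + h] <- mom$sizes[g]
    means[, K + h] <- mom$means[, g]
    sigmas[, , K + h] <- mom$covs[[g]]
  }
  new_damda_model(means = means, sigmas = sigmas, props = props / sum(props),
                  var_names = var_names, class_names = class_names,
                  K = K, H = H, p = P, learned = learned)
}

#' Initial augmented model for the discovery EM
#'
#' Hierarchically partitions the test data into `K + H` clusters, matches
#' `K` of them to the known classes by [kl_divergence()] (exact
#' assignment), and initialises: matched clusters take the learned
#' parameters on the learned-variable block and their own moments on the
#' extra block; unmatched clusters seed the hidden classes with their full
#' moments; mixing proportions start at the cluster shares.
#'
#' @param test Test matrix (learned variables first; see [damda_em()]).
#' @param learned A fitted `edda` classifier.
#' @param H Number of hidden classes.
#' @param control A [damda_control()] list (unused fields ignored).
#' @return An initial `damda` model satisfying all model invariants.
#' @export
damda_init <- function(test, learned, H, control = damda_control()) {
  y <- match_columns(test, c(learned$var_names,
                             setdiff(colnames(test), learned$var_names)),
                     "test data")
  part <- hierarchical_partition(y, length(learned$class_names) + H)
  init_from_partition(y, learned, H, part)
}

## Random restart: a uniform random partition with all clusters non-empty.
random_damda_init <- function(y, learned, H, control) {
  C <- length(learned$class_names) + H
  N <- nrow(y)
  for (i in 1:100) {
    part <- sample.int(C, N, replace = TRUE)
    if (length(unique(part)) == C && min(tabulate(part, C)) >= 2) break
  }
  init_from_partition(y, learned, H, part)
}
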