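## Discovery phase. Given the (frozen) learning-phase EDDA parameters and an
## unlabelled test matrix on a superset of the training variables, an EM
## algorithm detects H hidden classes and completes the known-class
## parameters on the enlarged variable space. Known-class updates use the
## inductive conditional estimation closed forms: the marginal distribution
## of the learned variables is held fixed and only the conditional
## distribution of the extra variables given the learned ones is estimated,
## which keeps every assembled covariance positive definite (Schur
## complement of a fixed positive definite marginal block).

damda_condition <- function(class, message) {
  structure(class = c(class, "error", "condition"),
            list(message = message, call = NULL))
}

#' EM control parameters for the discovery phase
#'
#' @param tol Relative log-likelihood change below which the EM stops:
#'   `|L(t) - L(t-1)| / (1 + |L(t)|) < tol`.
#' @param max_iter Maximum number of EM iterations.
#' @param restarts Number of random re-initialisations attempted when a
#'   class empties or a covariance degenerates mid-run.
#' @param regularize Logical; add an inverse-Wishart-style prior scatter to
#'   each class scattering matrix (needed when effective class sizes can
#'   fall below the number of variables).
#' @param nu Prior weight of the regularisation (default `R + 2`, the
#'   weakest proper choice).
#' @param psi Prior scatter matrix (default: diagonal of pooled test-data
#'   variances).
#' @param renormalize Logical; if `TRUE`, keep the learned class balance
#'   and only renormalise the known-class proportions around the hidden
#'   mass instead of re-estimating all proportions on the test data
#'   (off by default: proportions are re-estimated).
#' @param cond_limit Relative condition number of the within-class scatter
#'   beyond which the run demands regularisation instead of silently
#'   pseudo-inverting.
#' @return A list of class `damda_control`.
#' @export
damda_control <- function(tol = 1e-5, max_iter = 500L, restarts = 5L,
                          regularize = FALSE, nu = NULL, psi = NULL,
                          renormalize = FALSE, cond_limit = 1e12) {
  if (!is.numeric(tol) || tol <= 0) stop("tol must be > 0", call. = FALSE)
  if (!is.null(nu) && nu < 0) stop("regularisation weight nu must be >= 0",
                                   call. = FALSE)
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 restarts = as.integer(restarts), regularize = regularize,
                 nu = nu, psi = psi, renormalize = renormalize,
                 cond_limit = cond_limit),
            class = "damda_control")
}

#' Number of free parameters in the discovery phase
#'
#' Counts the parameters estimated on the test data when K known classes
#' (on P learned variables) are augmented to R = P + Q variables and H
#' hidden classes are added: mixing proportions (H + K - 1), hidden-class
#' means and covariances, and the known-class extra-variable means,
#' cross-covariances and marginal covariances:
#' \deqn{\eta_H = (H + K - 1) + 2HR + H\binom{R}{2} + 2KQ + KPQ + K\binom{Q}{2}.}
#'
#' @param K,H,P,Q Non-negative integers (K >= 1).
#' @return Integer parameter count.
#' @export
count_params <- function(K, H, P, Q) {
  stopifnot(K >= 1, H >= 0, P >= 0, Q >= 0)
  R <- P + Q
  as.integer((H + K - 1) + 2 * H * R + H * choose(R, 2) +
               2 * K * Q + K * P * Q + K * choose(Q, 2))
}

#' Weighted within-class scattering matrix, partitioned by variable block
#'
#' Computes \eqn{O_k = \sum_i t_{ik} (y_i - \bar y_k)(y_i - \bar y_k)'}
#' about the weighted class mean \eqn{\bar y_k}, split into the block `W`
#' of the `p` learned variables, the cross block `V`, and the block `U` of
#' the extra variables.
#'
#' @param y Test matrix (learned variables first).
#' @param w Non-negative weight vector (one responsibility column).
#' @param p Number of learned variables (the first `p` columns).
#' @return A list with `W` (p x p), `V` (p x q), `U` (q x q), `n` (the
#'   effective class size, `sum(w)` plus any prior weight), and `ybar`
#'   (the raw weighted mean).
#' @export
scatter_partition <- function(y, w, p) {
  y <- as.matrix(y)
  n <- sum(w)
  ybar <- if (n > 0) as.numeric(crossprod(w, y)) / n else colMeans(y)
  O <- .weighted_scatter(y, as.numeric(w), ybar)
  ip <- seq_len(p)
  list(W = O[ip, ip, drop = FALSE],
       V = O[ip, -ip, drop = FALSE],
       U = O[-ip, -ip, drop = FALSE],
       n = n, ybar = ybar)
}

#' Bayesian regularisation of a scattering partition
#'
#' Adds a prior scatter `nu * psi` to the partitioned scattering matrix and
#' `nu` to the effective class size used in downstream covariance
#' divisions, so that the regularised scatter is positive definite for any
#' `nu > 0` and positive definite `psi`. As `nu` grows, the resulting
#' covariance estimates shrink toward `psi`.
#'
#' @param sp A partition from [scatter_partition()].
#' @param nu Prior weight (>= 0); 0 is the identity transform.
#' @param psi Prior scatter matrix (R x R, learned variables first).
#' @return The regularised partition.
#' @export
regularize_scatter <- function(sp, nu, psi) {
  if (nu < 0) stop("regularisation weight nu must be >= 0", call. = FALSE)
  if (nu == 0) return(sp)
  p <- nrow(sp$W)
  psi <- as.matrix(psi)
  ip <- seq_len(p)
  sp$W <- sp$W + nu * psi[ip, ip, drop = FALSE]
  sp$V <- sp$V + nu * psi[ip, -ip, drop = FALSE]
  sp$U <- sp$U + nu * psi[-ip, -ip, drop = FALSE]
  sp$n <- sp$n + nu
  sp
}

#' Closed-form conditional estimates for the extra-variable block
#'
#' Given the scattering partition of one known class and its fixed learned
#' covariance block, returns the estimates of the regression block
#' \eqn{C_k} (cross-covariance between learned and extra variables) and the
#' conditional covariance \eqn{E_k} that maximise the expected complete
#' log-likelihood with the marginal of the learned variables held fixed:
#' \deqn{\hat C_k = (\bar\Sigma^{-1} W \bar\Sigma^{-1})^{-1}(\bar\Sigma^{-1} V),}
#' \deqn{\hat E_k = \frac{1}{N_k}\left[\hat C' \bar\Sigma^{-1} W \bar\Sigma^{-1}
#'   \hat C - 2 V' \bar\Sigma^{-1} \hat C + U\right].}
#'
#' @param sp Scattering partition (possibly regularised).
#' @param sigma_bar Fixed learned covariance block (p x p, SPD).
#' @param cond_limit Condition-number threshold for `W` beyond which an
#'   error asks for the regularisation flag.
#' @return List with `C` (p x q) and `E` (q x q, symmetric PSD).
#' @export
conditional_estimates <- function(sp, sigma_bar, cond_limit = 1e12) {
  W <- sp$W
  ev <- eigen(W, symmetric = TRUE, only.values = TRUE)$values
  if (ev[length(ev)] <= 0 || ev[1L] / ev[length(ev)] > cond_limit)
    stop(damda_condition("damda_singular_scatter",
      "within-class scattering matrix is singular or ill-conditioned; enable regularisation (control = damda_control(regularize = TRUE))"))
  Sinv <- chol2inv(chol(sigma_bar))
  A <- Sinv %*% W %*% Sinv
  Ck <- solve(A, Sinv %*% sp$V)
  Ek <- (crossprod(Ck, A %*% Ck) - 2 * crossprod(sp$V, Sinv %*% Ck) + sp$U) / sp$n
  Ek <- (Ek + t(Ek)) / 2
  list(C = Ck, E = Ek)
}

#' Marginal mean and covariance of the extra variables for a known class
#'
#' Completes the inductive conditional estimation:
#' \deqn{\hat\mu_Q = \bar y^Q_k - \hat C' \bar\Sigma^{-1} (\bar y^P_k -
#'   \bar\mu_k), \qquad \hat\Sigma_Q = \hat E + \hat C' \bar\Sigma^{-1}
#'   \hat C.}
#'
#' @param sp Scattering partition of the class.
#' @param sigma_bar,mu_bar Fixed learned covariance block and mean.
#' @param C_k,E_k Output of [conditional_estimates()].
#' @return List with `mu_Q` (length q) and `Sigma_Q` (q x q).
#' @export
marginal_extras <- function(sp, sigma_bar, mu_bar, C_k, E_k) {
  p <- length(mu_bar)
  Sinv <- chol2inv(chol(sigma_bar))
  ybarP <- sp$ybar[seq_len(p)]
  ybarQ <- sp$ybar[-seq_len(p)]
  mu_Q <- as.numeric(ybarQ - crossprod(C_k, Sinv %*% (ybarP - mu_bar)))
  Sigma_Q <- E_k + crossprod(C_k, Sinv %*% C_k)
  list(mu_Q = mu_Q, Sigma_Q = (Sigma_Q + t(Sigma_Q)) / 2)
}

#' Assemble an augmented known-class Gaussian
#'
#' Builds \eqn{\mu^* = (\bar\mu, \hat\mu_Q)'} and the block covariance
#' \eqn{\Sigma^* = [[\bar\Sigma, \hat C], [\hat C', \hat\Sigma_Q]]},
#' verifying positive definiteness via the Schur complement
#' \eqn{\hat\Sigma_Q - \hat C'\bar\Sigma^{-1}\hat C \succ 0}. The learned
#' block is inserted unchanged (bit-identical to the learning-phase value).
#'
#' @param mu_bar,sigma_bar Fixed learned mean and covariance block.
#' @param mu_Q,C_k,Sigma_Q Extra-variable estimates.
#' @return List with `mean` (length R) and `sigma` (R x R).
#' @export
assemble_known <- function(mu_bar, sigma_bar, mu_Q, C_k, Sigma_Q) {
  p <- length(mu_bar); q <- length(mu_Q)
  if (q == 0L) return(list(mean = as.numeric(mu_bar), sigma = sigma_bar))
  if (!all(dim(C_k) == c(p, q)) || !all(dim(Sigma_Q) == c(q, q)))
    stop("inconsistent block dimensions in augmented covariance", call. = FALSE)
  Sinv <- chol2inv(chol(sigma_bar))
  schur <- Sigma_Q - crossprod(C_k, Sinv %*% C_k)
  ev <- eigen((schur + t(schur)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (ev[length(ev)] <= 1e-12 * max(ev[1L], 1))
    stop(damda_condition("damda_assembly",
      "Schur complement of the augmented covariance is not positive definite"))
  sigma <- matrix(0, p + q, p + q)
  sigma[seq_len(p), seq_len(p)] <- sigma_bar
  sigma[seq_len(p), p + seq_len(q)] <- C_k
  sigma[p + seq_len(q), seq_len(p)] <- t(C_k)
  sigma[p + seq_len(q), p + seq_len(q)] <- Sigma_Q
  list(mean = c(as.numeric(mu_bar), mu_Q), sigma = sigma)
}

#' E step: posterior class membership probabilities
#'
#' @param model A `damda` (or `edda`) model.
#' @param test Test matrix; columns matched to the model variables by name.
#' @return List with `t` (N x C responsibility matrix, rows sum to 1) and
#'   `loglik`, the observed-data mixture log-likelihood.
#' @export
e_step <- function(model, test) {
  y <- match_columns(test, model$var_names, "test data")
  lw <- log_component_matrix(y, model$means, model$sigmas, model$props)
  post <- posterior_from_log(lw)
  colnames(post$probs) <- model$class_names
  list(t = post$probs, loglik = post$loglik)
}

#' Hidden-class M-step update
#'
#' Weighted mean and maximum-likelihood covariance of one hidden class:
#' \eqn{\hat\mu_h = N_h^{-1}\sum_i t_{ih} y_i}, with the weighted scatter
#' about \eqn{\hat\mu_h} divided by \eqn{N_h = \sum_i t_{ih}}.
#'
#' @param y Test matrix.
#' @param t Responsibility matrix.
#' @param h Column index of the hidden class in `t`.
#' @param nu,psi Optional regularisation (prior weight and scatter).
#' @return List with `mean` and `sigma`.
#' @export
update_hidden <- function(y, t, h, nu = 0, psi = NULL) {
  w <- t[, h]
  n <- sum(w)
  if (n < 1e-8)
    stop(damda_condition("damda_empty_class",
                         sprintf("class %d has vanishing responsibility mass", h)))
  mu <- as.numeric(crossprod(w, y)) / n
  S <- .weighted_scatter(as.matrix(y), as.numeric(w), mu)
  sigma <- if (nu > 0) (S + nu * psi) / (n + nu) else S / n
  list(mean = mu, sigma = (sigma + t(sigma)) / 2)
}

#' Mixing proportion update
#'
#' @param t Responsibility matrix.
#' @return `colMeans(t)`: each class's effective share of the test data.
#' @export
update_props <- function(t) colMeans(t)

## ---- EM driver -----------------------------------------------------------

## One complete EM run from a given initial model. Signals restartable
## conditions (empty class, degenerate covariance) as errors; the caller
## decides whether to re-initialise.
damda_em_once <- function(y, learned, H, ctrl, model) {
  K <- length(learned$class_names)
  P <- length(learned$var_names)
  R <- ncol(y); Q <- R - P; C <- K + H
  nu <- 0; psi <- NULL
  if (isTRUE(ctrl$regularize)) {
    nu <- if (is.null(ctrl$nu)) R + 2 else ctrl$nu
    psi <- if (is.null(ctrl$psi)) diag(apply(y, 2, function(v) {
      s <- mean((v - mean(v))^2); if (s <= 0) 1e-8 else s
    }), R) else as.matrix(ctrl$psi)
  }
  trace <- numeric(0)
  ll_prev <- -Inf
  t <- NULL
  for (iter in seq_len(ctrl$max_iter)) {
    lw <- log_component_matrix(y, model$means, model$sigmas, model$props)
    post <- posterior_from_log(lw)
    t <- post$probs
    trace <- c(trace, post$loglik)
    if (iter > 1L &&
        abs(post$loglik - ll_prev) / (1 + abs(post$loglik)) < ctrl$tol)
      break
    ll_prev <- post$loglik
    ## M step ----------------------------------------------------------
    Nc <- colSums(t)
    if (any(Nc < 1e-8))
      stop(damda_condition("damda_empty_class",
                           sprintf("class %d has vanishing responsibility mass",
                                   which(Nc < 1e-8)[1L])))
    if (isTRUE(ctrl$renormalize)) {
      tau_h <- Nc[seq_len(H) + K] / nrow(y)
      model$props <- c(learned$props * (1 - sum(tau_h)), tau_h)
    } else {
      model$props <- Nc / nrow(y)
    }
    for (k in seq_len(K)) {
      if (Q == 0L) next
      sp <- scatter_partition(y, t[, k], P)
      if (nu > 0) sp <- regularize_scatter(sp, nu, psi)
      ce <- conditional_estimates(sp, learned$sigmas[, , k],
                                  cond_limit = ctrl$cond_limit)
      me <- marginal_extras(sp, learned$sigmas[, , k], learned$means[, k],
                            ce$C, ce$E)
      ak <- assemble_known(learned$means[, k], learned$sigmas[, , k],
                           me$mu_Q, ce$C, me$Sigma_Q)
      model$means[, k] <- ak$mean
      model$sigmas[, , k] <- ak$sigma
    }
    for (h in seq_len(H)) {
      up <- update_hidden(y, t, K + h, nu = nu, psi = psi)
      model$means[, K + h] <- up$mean
      model$sigmas[, , K + h] <- up$sigma
    }
  }
  model$z <- t
  model$trace <- trace
  model$loglik <- trace[length(trace)]
  model$iter <- length(trace)
  model$converged <- length(trace) < ctrl$max_iter ||
    (length(trace) >= 2L &&
       abs(trace[length(trace)] - trace[length(trace) - 1L]) /
         (1 + abs(trace[length(trace)])) < ctrl$tol)
  model
}

#' Discovery-phase EM for a fixed number of hidden classes
#'
#' Runs the discovery EM on the unlabelled test data: E-step posteriors
#' under the current augmented mixture, hidden-class weighted updates,
#' mixing-proportion re-estimation, and the inductive conditional
#' estimation of each known class's extra-variable parameters. The
#' learning-phase blocks \eqn{(\bar\mu_k, \bar\Sigma_k)} are never
#' re-estimated: they are inserted unchanged at every iteration.
#'
#' @param test Test matrix whose columns include all learned variables (by
#'   name) plus `Q >= 0` extra variables.
#' @param learned A fitted `edda` classifier.
#' @param H Number of hidden classes (>= 0).
#' @param control A [damda_control()] list.
#' @param init Optional initial `damda` model (default: hierarchical
#'   partition with Kullback-Leibler matching, see [damda_init()]).
#' @return A `damda` model with responsibilities `z`, hard
#'   `classification`, the log-likelihood `trace`, `loglik`, `bic`,
#'   and the frozen `learned` classifier attached.
#' @export
damda_em <- function(test, learned, H, control = damda_control(), init = NULL) {
  stopifnot(inherits(learned, "edda"), H >= 0)
  y0 <- check_data_matrix(test, "test data")
  P <- length(learned$var_names)
  extras <- setdiff(colnames(y0), learned$var_names)
  y <- match_columns(y0, c(learned$var_names, extras), "test data")
  K <- length(learned$class_names)
  model <- if (is.null(init)) damda_init(y, learned, H, control) else init
  attempt <- 0L
  repeat {
    res <- tryCatch(damda_em_once(y, learned, H, control, model),
                    damda_singular_scatter = function(c) stop(c),
                    error = function(c) c)
    if (!inherits(res, "condition")) break
    attempt <- attempt + 1L
    if (attempt > control$restarts)
      stop(sprintf("discovery EM failed after %d restart(s): %s",
                   control$restarts, conditionMessage(res)), call. = FALSE)
    model <- random_damda_init(y, learned, H, control)
  }
  res$classification <- res$class_names[max.col(res$z, ties.method = "first")]
  colnames(res$z) <- res$class_names
  N <- nrow(y); Q <- ncol(y) - P
  res$df <- count_params(K, H, P, Q)
  res$bic <- 2 * res$loglik - res$df * log(N)
  res
}

#' Fit D-AMDA with BIC selection of the number of hidden classes
#'
#' Runs the discovery EM for each candidate number of hidden classes and
#' selects the one maximising
#' \eqn{\mathrm{BIC}_H = 2 L(Y; \hat\Theta) - \eta_H \log N}, where
#' \eqn{\eta_H} is the discovery-phase parameter count ([count_params()]).
#'
#' @inheritParams damda_em
#' @param h Integer vector of candidate hidden-class counts (default 0:5).
#' @return The best `damda` model, with the BIC table in `$bic_table`.
#' @export
damda_fit <- function(test, learned, h = 0:5, control = damda_control()) {
  if (!length(h)) stop("empty range of hidden-class counts", call. = FALSE)
  h <- sort(unique(as.integer(h)))
  ## one hierarchical tree serves the initialisation of every candidate H
  y0 <- check_data_matrix(test, "test data")
  y <- match_columns(y0, c(learned$var_names,
                           setdiff(colnames(y0), learned$var_names)),
                     "test data")
  K <- length(learned$class_names)
  tree <- hclust_tree(y)
  fits <- vector("list", length(h))
  errs <- character(0)
  for (i in seq_along(h)) {
    fits[[i]] <- tryCatch({
      init <- init_from_partition(y, learned, h[i], cutree(tree, k = K + h[i]))
      damda_em(y, learned, h[i], control, init = init)
    }, error = function(e) conditionMessage(e))
    if (is.character(fits[[i]]))
      errs <- c(errs, sprintf("H=%d: %s", h[i], fits[[i]]))
  }
  ok <- vapply(fits, inherits, TRUE, what = "damda")
  if (!any(ok))
    stop(paste(c("discovery failed for every candidate H:", errs),
               collapse = "\n  "), call. = FALSE)
  bics <- rep(NA_real_, length(h))
  bics[ok] <- vapply(fits[ok], function(f) f$bic, 0)
  best <- fits[[which.max(bics)]]      # ties: smaller H (first index)
  best$bic_table <- data.frame(H = h, bic = bics)
  best
}
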