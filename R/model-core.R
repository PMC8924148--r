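## Shared domain types and basic operations: Gaussian log-densities,
## MAP classification, posterior responsibilities, input validation.
##
## Data matrices are plain numeric matrices with unique column names;
## labels are factors (or one-hot indicator matrices, see `as_indicator`).

#' Multivariate Gaussian log-density
#'
#' Evaluates \eqn{\log \phi(x; \mu, \Sigma)} through the Cholesky factor of
#' \eqn{\Sigma}, so that computation stays in log scale and remains stable in
#' high dimension.
#'
#' @param x Numeric vector, or matrix with one row per observation.
#' @param mean Mean vector.
#' @param sigma Symmetric positive definite covariance matrix.
#' @param label Optional label used in error messages (e.g. a class name).
#' @return Numeric vector of log-density values, one per row of `x`.
#' @examples
#' mvn_log_density(c(0, 0), mean = c(0, 0), sigma = diag(2))  # log(1/(2*pi))
#' @export
mvn_log_density <- function(x, mean, sigma, label = NULL) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  mean <- as.numeric(mean)
  sigma <- as.matrix(sigma)
  d <- length(mean)
  if (ncol(x) != d || !all(dim(sigma) == d))
    stop("dimension mismatch between point, mean and covariance", call. = FALSE)
  L <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(L) || any(diag(L) < .Machine$double.eps))
    stop(sprintf("singular covariance matrix%s",
                 if (is.null(label)) "" else paste0(" for class '", label, "'")),
         call. = FALSE)
  z <- backsolve(L, t(x) - mean, transpose = TRUE)
  q <- colSums(z^2)
  as.numeric(-0.5 * d * log(2 * pi) - sum(log(diag(L))) - 0.5 * q)
}

## N x C matrix of log tau_c + log phi(y_i; mu_c, Sigma_c).
## means: R x C matrix; sigmas: R x R x C array; props: length C.
log_component_matrix <- function(y, means, sigmas, props) {
  ld <- tryCatch(
    .mvn_logdens_all(y, means, sigmas),
    error = function(e) stop(conditionMessage(e), call. = FALSE)
  )
  sweep(ld, 2L, log(props), "+")
}

## Normalise a matrix of log-weights row-wise; returns list(probs, loglik).
## The per-row log-sum-exp values sum to the observed-data log-likelihood.
posterior_from_log <- function(lw) {
  lse <- as.numeric(.row_logsumexp(lw))
  if (any(!is.finite(lse))) {
    bad <- which(!is.finite(lse))[1L]
    stop(sprintf("non-finite mixture density for observation %d", bad),
         call. = FALSE)
  }
  probs <- exp(lw - lse)
  list(probs = probs, loglik = sum(lse))
}

## Convert a factor / character label vector into a one-hot indicator matrix.
as_indicator <- function(labels, levels = NULL) {
  if (is.matrix(labels)) {
    if (any(rowSums(labels) != 1))
      stop("label indicator rows must each sum to 1", call. = FALSE)
    return(labels)
  }
  f <- if (is.null(levels)) factor(labels) else factor(labels, levels = levels)
  if (anyNA(f)) stop("labels contain values outside the class set", call. = FALSE)
  z <- matrix(0, length(f), nlevels(f), dimnames = list(NULL, levels(f)))
  z[cbind(seq_along(f), as.integer(f))] <- 1
  z
}

## Check a data matrix: numeric, no NA, unique non-empty column names.
check_data_matrix <- function(x, what = "data") {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop(sprintf("%s must be numeric", what), call. = FALSE)
  if (anyNA(x)) stop(sprintf("%s contains missing values", what), call. = FALSE)
  cn <- colnames(x)
  if (is.null(cn) || any(cn == "") || anyDuplicated(cn))
    stop(sprintf("%s must have unique, non-empty column names", what), call. = FALSE)
  x
}

## Reorder the columns of `x` to `wanted` (matched by name), with an
## informative error listing missing / extra columns.
match_columns <- function(x, wanted, what = "data") {
  x <- check_data_matrix(x, what)
  missing <- setdiff(wanted, colnames(x))
  if (length(missing))
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  x[, wanted, drop = FALSE]
}

## Scale-free positive-definiteness check: smallest eigenvalue must exceed
## tol times the largest.
is_spd <- function(sigma, tol = 1e-10) {
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  ev[length(ev)] > tol * max(ev[1L], .Machine$double.xmin)
}

#' MAP classification under a Gaussian mixture classifier
#'
#' Assigns each observation to the class with the highest posterior
#' probability, \eqn{\Pr(\ell_{ic} = 1 \mid y_i) \propto \tau_c \phi(y_i;
#' \mu_c, \Sigma_c)}. Columns of `newdata` are matched to the model's
#' variables by name, so their order in the file or matrix is irrelevant.
#'
#' @param model An object of class `edda` (see [fit_edda()]) or
#'   `damda` (see [damda_em()], [damda_fit()]).
#' @param newdata Numeric matrix or data frame whose columns include all
#'   model variables.
#' @return A list with `classification` (character vector of class names),
#'   and `z`, the matrix of posterior class probabilities (rows sum to 1).
#' @export
map_classify <- function(model, newdata) {
  y <- match_columns(newdata, model$var_names, what = "newdata")
  lw <- log_component_matrix(y, model$means, model$sigmas, model$props)
  post <- posterior_from_log(lw)
  cls <- model$class_names[max.col(post$probs, ties.method = "first")]
  colnames(post$probs) <- model$class_names
  list(classification = cls, z = post$probs, loglik = post$loglik)
}

#' @export
predict.edda <- function(object, newdata, ...) map_classify(object, newdata)

#' @export
predict.damda <- function(object, newdata, ...) map_classify(object, newdata)

## Internal constructor for the augmented model produced in the discovery
## phase. `p` learned variables come first in var_names; the first K classes
## are the known classes whose P-blocks are carried over (never re-estimated)
## from the learning phase.
new_damda_model <- function(means, sigmas, props, var_names, class_names,
                            K, H, p, learned) {
  structure(list(
    means = means, sigmas = sigmas, props = props,
    var_names = var_names, class_names = class_names,
    K = K, H = H, p = p, q = length(var_names) - p,
    learned = learned
  ), class = "damda")
}

#' @export
print.damda <- function(x, ...) {
  cat("Dimension-adaptive mixture discriminant model\n")
  cat(sprintf("  known classes: %d   hidden classes: %d\n", x$K, x$H))
  cat(sprintf("  learned variables: %d   extra variables: %d\n", x$p, x$q))
  if (!is.null(x$bic)) cat(sprintf("  BIC: %.3f\n", x$bic))
  invisible(x)
}
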