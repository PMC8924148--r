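## Learning phase: eigenvalue decomposition discriminant analysis (EDDA).
## Class covariances are constrained through the eigen-decomposition
## Sigma_k = lambda_k D_k A_k D_k', giving a family of parsimonious models
## (volume / shape / orientation equal or varying across classes). The data
## are complete and labelled, so fitting reduces to per-family constrained
## covariance estimation; the family is then chosen by BIC.

#' Supported EDDA covariance families
#'
#' The default set comprises the single-decomposition families with
#' closed-form estimators (EII, VII, EEI, VEI, EVI, VVI) plus the equal
#' (EEE) and unconstrained (VVV) full-covariance models. Iterative
#' families (VEE, EVE, VVE, EEV, VEV, EVV) can be requested explicitly in
#' [fit_edda()].
#'
#' @return Character vector of family codes.
#' @export
edda_families <- function() c("EII", "VII", "EEI", "VEI", "EVI", "VVI", "EEE", "VVV")

edda_families_iterative <- function() c("VEE", "EVE", "VVE", "EEV", "VEV", "EVV")

new_edda <- function(means, sigmas, props, family, var_names, class_names,
                     bic = NA_real_, loglik = NA_real_, df = NA_real_) {
  structure(list(means = means, sigmas = sigmas, props = props,
                 family = family, var_names = var_names,
                 class_names = class_names, bic = bic, loglik = loglik,
                 df = df),
            class = "edda")
}

#' @export
print.edda <- function(x, ...) {
  cat(sprintf("EDDA classifier (%s): %d classes, %d variables, BIC %.3f\n",
              x$family, length(x$class_names), length(x$var_names), x$bic))
  invisible(x)
}

## Labelled log-likelihood sum_s sum_k l_sk log(tau_k phi(x_s; mu_k, Sigma_k)).
edda_loglik <- function(x, z, means, sigmas, props) {
  lw <- log_component_matrix(x, means, sigmas, props)
  sum(z * lw)
}

## Univariate closed forms: families collapse to equal ("E"-like) or
## class-specific ("V"-like) variances.
edda_univariate_sigma <- function(x, z, family) {
  varying <- substr(family, 1L, 1L) == "V"
  nk <- colSums(z)
  mu <- colSums(z * as.numeric(x)) / nk
  if (varying) {
    s2 <- vapply(seq_along(nk),
                 function(k) sum(z[, k] * (x - mu[k])^2) / nk[k], 0)
  } else {
    s2 <- rep(sum(vapply(seq_along(nk),
                         function(k) sum(z[, k] * (x - mu[k])^2), 0)) / sum(nk),
              length(nk))
  }
  list(sigma = array(s2, c(1L, 1L, length(nk))),
       nvar = if (varying) length(nk) else 1L)
}

#' Fit one EDDA covariance family
#'
#' Estimates class means, proportions and covariance matrices under the
#' structural constraint of a single family, and records its BIC
#' \eqn{2 L(X, \ell) - \eta \log M} where \eqn{\eta} counts the class
#' means, the free mixing proportions, and the family-specific covariance
#' parameters.
#'
#' @param x Numeric training matrix (rows = observations) with column names.
#' @param class Factor (or character) of class labels, or a one-hot matrix.
#' @param family A covariance family code, see [edda_families()].
#' @return An object of class `edda`.
#' @export
fit_edda_family <- function(x, class, family) {
  x <- check_data_matrix(x, "training data")
  z <- as_indicator(class)
  if (is.null(colnames(z))) colnames(z) <- paste0("class", seq_len(ncol(z)))
  class_names <- colnames(z)
  counts <- colSums(z)
  if (any(counts < 2))
    stop(sprintf("class '%s' has fewer than 2 observations",
                 class_names[which(counts < 2)[1L]]), call. = FALSE)
  M <- nrow(x); P <- ncol(x); K <- ncol(z)
  props <- counts / M
  means <- t(z) %*% x / counts          # K x P
  means <- t(means)                     # P x K
  if (P == 1L) {
    uni <- edda_univariate_sigma(x, z, family)
    sigmas <- uni$sigma
    nvar <- uni$nvar
  } else {
    mstep_fun <- tryCatch(getExportedValue("mclust", paste0("mstep", family)),
                          error = function(e)
                            stop(sprintf("unsupported covariance family '%s'",
                                         family), call. = FALSE))
    ms <- mstep_fun(data = x, z = z)
    sigmas <- ms$parameters$variance$sigma
    if (is.null(sigmas) || any(!is.finite(sigmas)))
      stop(sprintf("constrained covariance estimation did not converge for family '%s'",
                   family), call. = FALSE)
    means <- ms$parameters$mean
    nvar <- mclust::nVarParams(family, d = P, G = K)
  }
  ## degenerate (zero-variance) directions: ridge and warn
  for (k in seq_len(K)) {
    if (!is_spd(sigmas[, , k])) {
      ridge <- 1e-8 * mean(diag(sigmas[, , k, drop = TRUE]))
      if (!is.finite(ridge) || ridge <= 0) ridge <- 1e-8
      sigmas[, , k] <- sigmas[, , k] + diag(ridge, P)
      warning(sprintf("degenerate covariance for class '%s' (family %s): ridge added",
                      class_names[k], family), call. = FALSE)
      if (!is_spd(sigmas[, , k]))
        stop(sprintf("constrained covariance estimation did not converge for family '%s'",
                     family), call. = FALSE)
    }
  }
  dimnames(sigmas) <- NULL
  rownames(means) <- colnames(x)
  ll <- edda_loglik(x, z, means, sigmas, props)
  df <- K * P + (K - 1) + nvar
  new_edda(means = means, sigmas = sigmas, props = props, family = family,
           var_names = colnames(x), class_names = class_names,
           bic = 2 * ll - df * log(M), loglik = ll, df = df)
}

#' Fit an EDDA classifier with BIC family selection
#'
#' Fits every candidate covariance family on the complete labelled training
#' data and returns the fit maximising the BIC; ties are broken toward the
#' family with fewer parameters.
#'
#' @inheritParams fit_edda_family
#' @param families Character vector of candidate family codes.
#' @return An `edda` object for the selected family, with the full BIC
#'   table attached as attribute `"bic_table"`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("v1", "v2")))
#' cl <- rep(c("a", "b"), each = 50)
#' x[cl == "b", ] <- x[cl == "b", ] + 2
#' fit <- fit_edda(x, cl)
#' @export
fit_edda <- function(x, class, families = edda_families()) {
  if (!length(families)) stop("no candidate families supplied", call. = FALSE)
  fits <- vector("list", length(families))
  errs <- character(0)
  for (i in seq_along(families)) {
    fits[[i]] <- tryCatch(fit_edda_family(x, class, families[i]),
                          error = function(e) conditionMessage(e))
    if (is.character(fits[[i]]))
      errs <- c(errs, sprintf("%s: %s", families[i], fits[[i]]))
  }
  ok <- vapply(fits, inherits, TRUE, what = "edda")
  if (!any(ok))
    stop(paste(c("all EDDA families failed:", errs), collapse = "\n  "),
         call. = FALSE)
  fits <- fits[ok]
  dfs <- vapply(fits, function(f) f$df, 0)
  bics <- vapply(fits, function(f) f$bic, 0)
  ord <- order(dfs)                     # ties go to fewer parameters
  best <- fits[[ord[which.max(bics[ord])]]]
  tab <- data.frame(family = vapply(fits, function(f) f$family, ""),
                    df = dfs, loglik = vapply(fits, function(f) f$loglik, 0),
                    bic = bics)
  attr(best, "bic_table") <- tab[order(-tab$bic), ]
  best
}
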