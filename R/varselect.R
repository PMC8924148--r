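## Inductive stepwise variable selection. At each step the classification
## model M1 (the proposal variable carries class information, jointly with
## the current relevant set) is compared by BIC against M2 (the proposal is
## conditionally independent of the classes given a regression subset of
## the relevant variables). Learned-variable parameters are only ever
## sliced from the learning-phase estimates, never refit, so steps are fast
## and the search suits high-dimensional test data.

#' Ranked starting subset for the variable-selection search
#'
#' Scores every variable by the gain of a univariate Gaussian mixture over
#' a single Gaussian: `max` over `g in 2:G` of `BIC(g-component mixture) -
#' BIC(single Gaussian)`. Variables with multimodal marginals (hence
#' likely class information) score high; the top `S` names, in decreasing
#' score order, form the starting subset.
#'
#' @param y Test matrix restricted to the variables observed in training.
#' @param G Largest number of mixture components tried (must exceed the
#'   number of known classes to leave room for hidden ones).
#' @param S Size of the returned subset.
#' @return Character vector of `min(S, ncol(y))` column names, with the
#'   scores attached as attribute `"scores"`.
#' @export
rank_start_set <- function(y, G, S) {
  y <- check_data_matrix(y, "test data")
  n <- nrow(y)
  scores <- vapply(seq_len(ncol(y)), function(j) {
    x <- y[, j]
    s2 <- mean((x - mean(x))^2)
    ll1 <- sum(dnorm(x, mean(x), sqrt(s2), log = TRUE))
    bic1 <- 2 * ll1 - 2 * log(n)
    bics <- vapply(2:G, function(g) {
      fit <- tryCatch(
        mclust::Mclust(x, G = g, modelNames = "V", verbose = FALSE),
        error = function(e) NULL)
      if (is.null(fit) || is.null(fit$bic) || !is.finite(fit$bic))
        -Inf else as.numeric(fit$bic)
    }, 0)
    max(bics) - bic1
  }, 0)
  names(scores) <- colnames(y)
  ord <- order(scores, decreasing = TRUE)
  out <- colnames(y)[ord][seq_len(min(S, ncol(y)))]
  attr(out, "scores") <- scores[ord]
  out
}

#' Slice a learned classifier to a subset of its variables
#'
#' Returns the classifier whose means and covariances are the row/column
#' slices of the learning-phase estimates for the requested variables; no
#' re-estimation takes place (the family is recorded as `"sliced"` since
#' the blocks are fixed numeric values, not refit under a constraint).
#'
#' @param learned A fitted `edda` classifier.
#' @param names Subset of `learned$var_names`, in the desired order.
#' @return An `edda` object on the selected variables.
#' @export
subset_classifier <- function(learned, names) {
  unknown <- setdiff(names, learned$var_names)
  if (length(unknown))
    stop(sprintf("unknown variable(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  idx <- match(names, learned$var_names)
  K <- length(learned$class_names)
  sig <- array(0, c(length(idx), length(idx), K))
  for (k in seq_len(K)) sig[, , k] <- learned$sigmas[idx, idx, k]
  new_edda(means = learned$means[idx, , drop = FALSE], sigmas = sig,
           props = learned$props, family = "sliced",
           var_names = learned$var_names[idx],
           class_names = learned$class_names)
}

## Gaussian regression BIC (2*loglik - df*log(n), df = #coef + intercept +
## error variance) from a residual sum of squares.
reg_bic <- function(rss, n, p) {
  ll <- -n / 2 * (log(2 * pi * rss / n) + 1)
  2 * ll - (p + 2) * log(n)
}

#' Stepwise regression BIC of a proposal variable on the relevant set
#'
#' Bidirectional stepwise Gaussian linear regression (BIC-scored, intercept
#' always included, intercept-only model a candidate) of the proposal on
#' the columns of the current relevant set. Encodes the possibility that
#' the proposal is redundant given already-selected variables.
#'
#' @param y_prop Numeric response vector (the proposal variable).
#' @param y_class Matrix of candidate predictors (may have zero columns).
#' @return List with `bic` of the best model and `predictors`, the chosen
#'   subset of column names.
#' @export
bic_reg <- function(y_prop, y_class) {
  n <- length(y_prop)
  y_class <- as.matrix(y_class)
  pool <- colnames(y_class)
  rss0 <- sum((y_prop - mean(y_prop))^2)
  current <- character(0)
  best_bic <- reg_bic(rss0, n, 0)
  repeat {
    moves <- character(0); bics <- numeric(0); kinds <- character(0)
    for (v in setdiff(pool, current)) {
      X <- cbind(1, y_class[, c(current, v), drop = FALSE])
      rss <- sum(stats::lm.fit(X, y_prop)$residuals^2)
      moves <- c(moves, v); kinds <- c(kinds, "add")
      bics <- c(bics, reg_bic(rss, n, length(current) + 1L))
    }
    for (v in current) {
      keep <- setdiff(current, v)
      X <- cbind(1, y_class[, keep, drop = FALSE])
      rss <- sum(stats::lm.fit(X, y_prop)$residuals^2)
      moves <- c(moves, v); kinds <- c(kinds, "drop")
      bics <- c(bics, reg_bic(rss, n, length(keep)))
    }
    if (!length(bics) || max(bics) <= best_bic + 1e-8) break
    i <- which.max(bics)
    best_bic <- bics[i]
    current <- if (kinds[i] == "add") c(current, moves[i])
               else setdiff(current, moves[i])
  }
  list(bic = best_bic, predictors = current)
}

## Cached evaluation of the classification BIC of a variable set:
## slices the learned classifier to the learned variables in the set,
## fits D-AMDA maximised over the hidden-class range, and returns the best
## BIC together with the fit. Keyed by the unordered variable set.
make_bic_class <- function(test, learned, h, control) {
  cache <- new.env(parent = emptyenv())
  function(varset) {
    key <- paste(sort(varset), collapse = "\r")
    if (!is.null(cache[[key]])) return(cache[[key]])
    res <- tryCatch({
      lnames <- learned$var_names[learned$var_names %in% varset]
      if (!length(lnames))
        stop("candidate set contains no learned variables", call. = FALSE)
      lsub <- subset_classifier(learned, lnames)
      fit <- damda_fit(test[, varset, drop = FALSE], lsub, h = h,
                       control = control)
      list(bic = fit$bic, H = fit$H, fit = fit)
    }, error = function(e) list(bic = -Inf, H = NA_integer_, fit = NULL,
                                error = conditionMessage(e)))
    cache[[key]] <- res
    res
  }
}

#' Evaluate one stepwise proposal and update the selection state
#'
#' Applies the printed decision rule: for an addition, the proposal joins
#' the relevant set when `BIC1 - BIC2 > 0` with
#' `BIC1 = BIC_class(relevant + proposal)` and `BIC2 =
#' BIC_class(relevant) + BIC_reg(proposal | relevant)`; for a removal the
#' same comparison is applied with the roles of the two sets reversed.
#' Both classification BICs are maximised over the hidden-class range.
#'
#' @param state A selection state as created by [damda_select()] (list
#'   with `relevant` and `history`).
#' @param proposal A variable name (not in `relevant` for `"add"`, in
#'   `relevant` for `"remove"`).
#' @param direction `"add"` or `"remove"`.
#' @param test,learned,h,control As in [damda_select()].
#' @param bic_class Optional evaluator from an ongoing search (so its
#'   cache is reused); built on the fly if missing.
#' @return The updated state, with the decision appended to `history`.
#' @export
step_decision <- function(state, proposal, direction = c("add", "remove"),
                          test, learned, h = 0:3,
                          control = damda_control(), bic_class = NULL) {
  direction <- match.arg(direction)
  if (is.null(bic_class)) bic_class <- make_bic_class(test, learned, h, control)
  rel <- state$relevant
  if (direction == "add") {
    stopifnot(!(proposal %in% rel))
    with_p <- bic_class(c(rel, proposal))
    without <- bic_class(rel)
    reg <- bic_reg(test[, proposal], test[, rel, drop = FALSE])
    bic1 <- with_p$bic
    bic2 <- without$bic + reg$bic
    accepted <- is.finite(bic1) && bic1 - bic2 > 0
    if (accepted) state$relevant <- c(rel, proposal)
  } else {
    stopifnot(proposal %in% rel)
    keep <- setdiff(rel, proposal)
    with_p <- bic_class(rel)
    without <- bic_class(keep)
    reg <- bic_reg(test[, proposal], test[, keep, drop = FALSE])
    bic1 <- with_p$bic
    bic2 <- without$bic + reg$bic
    accepted <- is.finite(bic2) && bic2 - bic1 > 0
    if (accepted) state$relevant <- keep
  }
  state$history <- rbind(state$history,
                         data.frame(step = nrow(state$history) + 1L,
                                    proposal = proposal, direction = direction,
                                    bic1 = bic1, bic2 = bic2,
                                    accepted = accepted))
  state
}

#' Inductive stepwise variable selection for D-AMDA
#'
#' Greedy forward/backward search over the test variables: each cycle makes
#' one best-addition pass (all candidates scored, the best positive BIC
#' difference accepted) and one best-removal pass, stopping when a full
#' cycle changes nothing. Candidate evaluations within a pass are
#' independent, so the accepted proposal does not depend on enumeration
#' order. The learned-variable parameters used at every step are slices of
#' the learning-phase estimates; the number of hidden classes is
#' re-selected over `h` at every evaluation (cached per variable set).
#'
#' @param train Training matrix (or `NULL` if `learned` is supplied).
#' @param class Training labels (ignored when `learned` is supplied).
#' @param test Test matrix (superset of the training variables, by name).
#' @param h Candidate numbers of hidden classes.
#' @param S Size of the ranked starting subset (when `start = "rank"`).
#' @param G Largest univariate mixture size for the ranking (default
#'   `K + 3`).
#' @param start `"rank"` for the ranked subset, `"observed"` to start from
#'   all training variables present in the test data.
#' @param control A [damda_control()] list.
#' @param learned Optionally, an already fitted `edda` classifier.
#' @param max_cycles Safety cap on add/remove cycles.
#' @return A list of class `damda_select`: `relevant` (selected variable
#'   names), `h_star`, `model` (the final D-AMDA fit on the selected
#'   variables), `history` (the BIC ledger), and `learned`.
#' @export
damda_select <- function(train, class, test, h = 0:3, S = 10, G = NULL,
                         start = c("rank", "observed"),
                         control = damda_control(), learned = NULL,
                         max_cycles = 50L) {
  start <- match.arg(start)
  if (is.null(learned)) learned <- fit_edda(train, class)
  test <- check_data_matrix(test, "test data")
  K <- length(learned$class_names)
  obs <- intersect(learned$var_names, colnames(test))
  if (!length(obs))
    stop("test data share no variables with the learned classifier",
         call. = FALSE)
  relevant <- if (start == "observed") obs else {
    if (is.null(G)) G <- K + 3
    as.character(rank_start_set(test[, obs, drop = FALSE], G = G,
                                S = min(S, length(obs))))
  }
  bic_class <- make_bic_class(test, learned, h, control)
  state <- list(relevant = relevant,
                history = data.frame(step = integer(0), proposal = character(0),
                                     direction = character(0), bic1 = numeric(0),
                                     bic2 = numeric(0), accepted = logical(0)))
  for (cycle in seq_len(max_cycles)) {
    changed <- FALSE
    ## best-addition pass
    cand <- setdiff(colnames(test), state$relevant)
    if (length(cand)) {
      base <- bic_class(state$relevant)$bic
      diffs <- vapply(cand, function(v) {
        b1 <- bic_class(c(state$relevant, v))$bic
        if (!is.finite(b1)) return(-Inf)
        b1 - (base + bic_reg(test[, v], test[, state$relevant, drop = FALSE])$bic)
      }, 0)
      best <- cand[which.max(diffs)]
      state <- step_decision(state, best, "add", test, learned, h, control,
                             bic_class)
      if (state$history$accepted[nrow(state$history)]) changed <- TRUE
    }
    ## best-removal pass (never empty the relevant set)
    if (length(state$relevant) > 1L) {
      base <- bic_class(state$relevant)$bic
      cand <- state$relevant
      diffs <- vapply(cand, function(v) {
        keep <- setdiff(state$relevant, v)
        b2 <- bic_class(keep)$bic
        if (!is.finite(b2)) return(-Inf)
        (b2 + bic_reg(test[, v], test[, keep, drop = FALSE])$bic) - base
      }, 0)
      best <- cand[which.max(diffs)]
      state <- step_decision(state, best, "remove", test, learned, h, control,
                             bic_class)
      if (state$history$accepted[nrow(state$history)]) changed <- TRUE
    } else if (length(state$relevant) == 1L) {
      warning("relevant set reduced to a single variable; stopping removals",
              call. = FALSE)
    }
    if (!changed) break
  }
  final <- bic_class(state$relevant)
  structure(list(relevant = state$relevant, h_star = final$H,
                 bic = final$bic, model = final$fit, history = state$history,
                 learned = learned),
            class = "damda_select")
}

#' @export
print.damda_select <- function(x, ...) {
  cat(sprintf("Inductive variable selection: %d variable(s), H* = %s, BIC %.3f\n",
              length(x$relevant), x$h_star, x$bic))
  cat("  selected:", paste(x$relevant, collapse = ", "), "\n")
  invisible(x)
}
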