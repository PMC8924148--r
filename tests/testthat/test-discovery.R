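test_that("E step reproduces direct Bayes-rule posteriors", {
  set.seed(1)
  # single component: all responsibility on it
  m1 <- make_edda(cbind(c(0, 0)), array(diag(2), c(2, 2, 1)), 1)
  y <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("v1", "v2")))
  r1 <- e_step(m1, y)
  expect_equal(unname(r1$t), matrix(1, 5, 1))

  # two symmetric classes, point at the midpoint
  m2 <- make_edda(cbind(c(-2, 0), c(2, 0)),
                  array(rep(diag(2), 2), c(2, 2, 2)), c(0.5, 0.5))
  r2 <- e_step(m2, matrix(c(0, 1.3), 1, 2, dimnames = list(NULL, c("v1", "v2"))))
  expect_equal(unname(r2$t[1, ]), c(0.5, 0.5))

  # 1-D three-component hand computation
  mu <- c(-2, 0, 3); tau <- c(0.2, 0.5, 0.3); s <- c(1, 0.5, 2)
  m3 <- make_edda(matrix(mu, 1), array(s^2, c(1, 1, 3)), tau, var_names = "x")
  pt <- 0.7
  r3 <- e_step(m3, matrix(pt, 1, 1, dimnames = list(NULL, "x")))
  w <- tau * dnorm(pt, mu, s)
  expect_equal(unname(r3$t[1, ]), w / sum(w), tolerance = 1e-12)
  expect_equal(r3$loglik, log(sum(w)))
})

test_that("hidden-class updates equal direct weighted-moment computation", {
  set.seed(2)
  y <- matrix(rnorm(90), 30, 3)
  # hard 0/1 weights: ordinary per-group MLE
  t_hard <- cbind(rep(c(1, 0), c(12, 18)), rep(c(0, 1), c(12, 18)))
  up <- update_hidden(y, t_hard, 2)
  grp <- y[13:30, ]
  expect_equal(up$mean, colMeans(grp))
  expect_equal(up$sigma, unname(crossprod(sweep(grp, 2, colMeans(grp))) / 18))
  # equal weights: global moments
  t_eq <- matrix(0.5, 30, 2)
  up2 <- update_hidden(y, t_eq, 1)
  expect_equal(up2$mean, colMeans(y))
  expect_equal(up2$sigma, unname(crossprod(sweep(y, 2, colMeans(y))) / 30))
  # random soft weights against the explicit accumulation oracle
  w <- runif(30)
  orc <- oracle_weighted_moments(y, w)
  up3 <- update_hidden(y, cbind(w, 1 - w), 1)
  expect_equal(up3$mean, orc$mean, tolerance = 1e-12)
  expect_equal(up3$sigma, orc$sigma, tolerance = 1e-12)
  # vanishing mass signals an empty class
  expect_error(update_hidden(y, cbind(rep(0, 30), 1), 1), "vanishing")

  # proportions: hard counts and random responsibilities
  expect_equal(update_props(t_hard), c(12, 18) / 30)
  tr <- matrix(runif(60), 30, 2); tr <- tr / rowSums(tr)
  expect_equal(update_props(tr), colMeans(tr))
})

test_that("scatter partition equals dense outer-product accumulation", {
  set.seed(3)
  y <- matrix(rnorm(80), 20, 4)
  w <- runif(20)
  sp <- scatter_partition(y, w, 2)
  orc <- oracle_weighted_moments(y, w)
  O <- rbind(cbind(sp$W, sp$V), cbind(t(sp$V), sp$U))
  expect_equal(O, orc$scatter, tolerance = 1e-10)
  expect_equal(sp$ybar, orc$mean)
  expect_equal(sp$n, sum(w))
  expect_equal(O, t(O))
  # single active point: zero scatter
  w1 <- c(1, rep(0, 19))
  sp1 <- scatter_partition(y, w1, 2)
  expect_equal(rbind(cbind(sp1$W, sp1$V), cbind(t(sp1$V), sp1$U)),
               matrix(0, 4, 4), tolerance = 1e-12)
  # no extra variables: W is the full scatter
  sp0 <- scatter_partition(y, w, 4)
  expect_equal(sp0$W, orc$scatter, tolerance = 1e-10)
  expect_equal(dim(sp0$V), c(4L, 0L))
})

test_that("conditional estimates obey their closed-form identities", {
  set.seed(4)
  for (i in 1:10) {
    P <- sample(1:3, 1); Q <- sample(1:3, 1)
    y <- matrix(rnorm(40 * (P + Q)), 40, P + Q)
    w <- runif(40)
    sp <- scatter_partition(y, w, P)
    n <- sp$n
    # sigma_bar = W / N_k: C = V / N_k and E = (U - V'W^-1 V) / N_k
    ce <- conditional_estimates(sp, sp$W / n)
    expect_equal(ce$C, sp$V / n, tolerance = 1e-8)
    expect_equal(ce$E, (sp$U - t(sp$V) %*% solve(sp$W) %*% sp$V) / n,
                 tolerance = 1e-8)
    # and the assembled covariance is the full weighted MLE O / N_k
    me <- marginal_extras(sp, sp$W / n, sp$ybar[1:P], ce$C, ce$E)
    ak <- assemble_known(sp$ybar[1:P], sp$W / n, me$mu_Q, ce$C, me$Sigma_Q)
    O <- rbind(cbind(sp$W, sp$V), cbind(t(sp$V), sp$U))
    expect_equal(ak$sigma, O / n, tolerance = 1e-10)
    expect_equal(ak$mean, sp$ybar, tolerance = 1e-10)

    # uncorrelated blocks: V = 0 gives C = 0, E = U / N_k
    sp0 <- sp; sp0$V <- matrix(0, P, Q)
    sb <- rspd(P)
    ce0 <- conditional_estimates(sp0, sb)
    expect_equal(ce0$C, matrix(0, P, Q), tolerance = 1e-10)
    expect_equal(ce0$E, sp$U / n, tolerance = 1e-10)
    me0 <- marginal_extras(sp0, sb, sp$ybar[1:P], ce0$C, ce0$E)
    expect_equal(me0$mu_Q, sp$ybar[-(1:P)])
    expect_equal(me0$Sigma_Q, ce0$E)
  }
})

test_that("closed-form estimates maximise the conditional objective (brute force)", {
  set.seed(5)
  for (i in 1:3) {
    N <- 12
    y <- matrix(rnorm(N * 2), N, 2)
    w <- runif(N)
    mu_bar <- rnorm(1); sigma_bar <- matrix(runif(1, 0.5, 2), 1, 1)
    sp <- scatter_partition(y, w, 1)
    ce <- conditional_estimates(sp, sigma_bar)
    me <- marginal_extras(sp, sigma_bar, mu_bar, ce$C, ce$E)
    obj_closed <- eq8_objective(y[, 1, drop = FALSE], y[, 2, drop = FALSE], w,
                                mu_bar, sigma_bar, ce$C, ce$E, me$mu_Q)
    # independent numerical maximisation over (C, log E, mu_Q)
    f <- function(par) -eq8_objective(y[, 1, drop = FALSE], y[, 2, drop = FALSE],
                                      w, mu_bar, sigma_bar,
                                      matrix(par[1], 1, 1),
                                      matrix(exp(par[2]), 1, 1), par[3])
    best <- Inf
    for (start in list(c(0, 0, 0), c(0.5, log(0.5), mean(y[, 2])))) {
      o <- optim(start, f, method = "BFGS", control = list(maxit = 500))
      best <- min(best, o$value)
    }
    expect_equal(obj_closed, -best, tolerance = 1e-4)
  }
})

test_that("assembly reduces exactly when there are no extra variables", {
  S <- rspd(3); mu <- rnorm(3)
  ak <- assemble_known(mu, S, numeric(0), matrix(0, 3, 0), matrix(0, 0, 0))
  expect_identical(ak$sigma, S)
  expect_identical(ak$mean, mu)
  # assembled covariances are positive definite whenever the Schur condition holds
  set.seed(6)
  Ck <- matrix(0.1 * rnorm(6), 3, 2)
  Sq <- rspd(2) + diag(2)
  a2 <- assemble_known(rnorm(3), S, rnorm(2), Ck, Sq)
  expect_true(all(eigen(a2$sigma, symmetric = TRUE)$values > 0))
  # violated Schur condition: error
  expect_error(assemble_known(rnorm(3), S, rnorm(2), 10 * Ck, 0.001 * diag(2)),
               "Schur")
})

test_that("regularisation is the identity at nu = 0 and shrinks toward the prior", {
  set.seed(7)
  y <- matrix(rnorm(30 * 6), 30, 6)
  w <- runif(30)
  sp <- scatter_partition(y, w, 3)
  expect_identical(regularize_scatter(sp, 0, diag(6)), sp)
  expect_error(regularize_scatter(sp, -1, diag(6)), "nu")

  # singular scatter (few effective points), prior makes estimates usable
  w_small <- c(runif(4), rep(0, 26))
  sps <- scatter_partition(y, w_small, 3)
  psi <- diag(apply(y, 2, var))
  spr <- regularize_scatter(sps, 8, psi)
  ce <- conditional_estimates(spr, rspd(3))
  expect_true(all(eigen(ce$E, symmetric = TRUE)$values > -1e-10))

  # nu -> infinity: with a diagonal prior the cross block vanishes and the
  # extra-block covariance approaches the prior block
  sb <- rspd(3)
  spl <- regularize_scatter(sp, 1e6, psi)
  cel <- conditional_estimates(spl, sb)
  mel <- marginal_extras(spl, sb, sp$ybar[1:3], cel$C, cel$E)
  expect_equal(max(abs(cel$C)), 0, tolerance = 1e-3)
  expect_equal(mel$Sigma_Q, psi[4:6, 4:6], tolerance = 1e-3)
})

test_that("discovery-phase parameter count follows the printed formula", {
  expect_identical(count_params(2, 1, 2, 1), 19L)
  expect_identical(count_params(1, 1, 1, 0), 3L)
  expect_identical(count_params(3, 0, 4, 0), 2L)  # K - 1 when H = Q = 0
})

test_that("EM with no hidden classes and no extra variables only updates proportions", {
  set.seed(8)
  d <- draw_augmented(N = 200, K = 2, H = 0, P = 3, Q = 0)
  fit <- damda_em(d$y, d$learned, H = 0)
  expect_identical(fit$sigmas[, , 1], d$learned$sigmas[, , 1])
  expect_identical(fit$sigmas[, , 2], d$learned$sigmas[, , 2])
  expect_identical(unname(fit$means), unname(d$learned$means))
  expect_false(isTRUE(all.equal(fit$props, d$learned$props)))
  expect_true(all(diff(fit$trace) >= -1e-8))
  expect_gte(length(fit$trace), 1L)
})

test_that("EM traces are monotone and learned blocks stay bit-identical", {
  set.seed(9)
  for (i in 1:10) {
    K <- sample(1:2, 1); H <- sample(0:2, 1)
    P <- sample(1:3, 1); Q <- sample(0:2, 1)
    d <- draw_augmented(N = 150, K = K, H = H, P = P, Q = Q)
    fit <- damda_em(d$y, d$learned, H = H)
    expect_true(all(diff(fit$trace) >= -1e-8))
    for (k in seq_len(K)) {
      expect_identical(fit$sigmas[seq_len(P), seq_len(P), k],
                       d$learned$sigmas[, , k])
      expect_identical(unname(fit$means[seq_len(P), k]),
                       unname(d$learned$means[, k]))
    }
    expect_equal(rowSums(fit$z), rep(1, 150), tolerance = 1e-10)
  }
})

test_that("BIC over the hidden-class range selects sensibly", {
  set.seed(10)
  d <- draw_augmented(N = 500, K = 2, H = 1, P = 3, Q = 1, sep = 6)
  sel <- damda_fit(d$y, d$learned, h = 0:2)
  expect_identical(sel$H, 1L)
  expect_equal(nrow(sel$bic_table), 3L)
  expect_true(all(sel$bic >= sel$bic_table$bic, na.rm = TRUE))
  # singleton range: returned regardless of the data
  s2 <- damda_fit(d$y, d$learned, h = 2)
  expect_identical(s2$H, 2L)
})
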