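test_that("univariate mixture ranking puts multimodal variables first", {
  set.seed(1)
  wins <- 0; noise_neg <- 0
  for (s in 1:10) {
    bim <- c(rnorm(150, -4), rnorm(150, 4))
    noi <- rnorm(300)
    y <- cbind(bimodal = sample(bim), noise = noi)
    r <- rank_start_set(y, G = 4, S = 2)
    sc <- attr(r, "scores")
    if (r[1] == "bimodal") wins <- wins + 1
    if (sc["noise"] < 0) noise_neg <- noise_neg + 1
  }
  expect_gte(wins, 9)       # separated mixture outranks pure noise
  expect_gte(noise_neg, 9)  # a single Gaussian scores negative
  # S = P returns every variable, ordered by score
  y <- cbind(a = rnorm(100), b = c(rnorm(50, -3), rnorm(50, 3)))
  r2 <- rank_start_set(y, G = 3, S = 2)
  expect_setequal(as.character(r2), c("a", "b"))
  expect_identical(r2[1], "b")
})

test_that("classifier slicing is exact and structure-preserving", {
  set.seed(2)
  x <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("u", "v", "w")))
  cl <- rep(c("a", "b"), each = 50)
  x[cl == "b", ] <- x[cl == "b", ] + 2
  fit <- fit_edda(x, cl, families = "EEE")
  full <- subset_classifier(fit, c("u", "v", "w"))
  expect_identical(unname(full$means), unname(fit$means))
  expect_identical(full$sigmas, fit$sigmas)
  # drop then re-add: bit-for-bit identical restricted model
  s1 <- subset_classifier(fit, c("u", "w"))
  s2 <- subset_classifier(fit, c("u", "v", "w"))
  s3 <- subset_classifier(s2, c("u", "w"))
  expect_identical(s1$sigmas, s3$sigmas)
  expect_identical(s1$means, s3$means)
  # an EEE slice still has equal covariances across classes
  expect_identical(s1$sigmas[, , 1], s1$sigmas[, , 2])
  expect_identical(s1$family, "sliced")
  expect_error(subset_classifier(fit, c("u", "zz")), "unknown variable.*zz")
})

test_that("regression BIC detects predictors and rejects noise", {
  set.seed(3)
  # intercept-only closed form when the relevant set is empty
  yp <- rnorm(100)
  b0 <- bic_reg(yp, matrix(nrow = 100, ncol = 0))
  rss <- sum((yp - mean(yp))^2)
  ll <- -100 / 2 * (log(2 * pi * rss / 100) + 1)
  expect_equal(b0$bic, 2 * ll - 2 * log(100))
  expect_identical(b0$predictors, character(0))

  hit_strong <- 0; empty_noise <- 0
  for (s in 1:10) {
    X <- matrix(rnorm(300 * 3), 300, 3, dimnames = list(NULL, c("y1", "y2", "y3")))
    strong <- bic_reg(2 * X[, "y1"] + rnorm(300, sd = 0.1), X)
    if (identical(strong$predictors, "y1")) hit_strong <- hit_strong + 1
    pure <- bic_reg(rnorm(300), X)
    if (length(pure$predictors) == 0) empty_noise <- empty_noise + 1
  }
  expect_gte(hit_strong, 9)
  expect_gte(empty_noise, 8)
})

test_that("step decisions apply the BIC comparison rule inductively", {
  set.seed(4)
  sim <- simulate_damda(sim_spec(n_gen = 4, n_cor = 0, n_noi = 3, C = 3,
                                 K_obs = 2, n_obs = 5, M = 300, N = 300,
                                 separation = 4), seed = 4)
  learned <- fit_edda(sim$train, sim$train_class)
  state <- list(relevant = paste0("gen", 1:4),
                history = data.frame(step = integer(0), proposal = character(0),
                                     direction = character(0), bic1 = numeric(0),
                                     bic2 = numeric(0), accepted = logical(0)))
  # adding a pure-noise variable is rejected
  st1 <- step_decision(state, "noi1", "add", sim$test, learned, h = 0:1)
  expect_false(st1$history$accepted[1])
  expect_identical(st1$relevant, state$relevant)
  # removing a generative variable is rejected
  st2 <- step_decision(state, "gen2", "remove", sim$test, learned, h = 0:1)
  expect_false(st2$history$accepted[1])
  expect_true(all(c("bic1", "bic2") %in% names(st2$history)))
  # history is append-only
  st3 <- step_decision(st1, "noi2", "add", sim$test, learned, h = 0:1)
  expect_identical(nrow(st3$history), 2L)
  expect_identical(st3$history$proposal, c("noi1", "noi2"))
})

test_that("greedy search is deterministic and respects the inductive contract", {
  sim <- simulate_damda(sim_spec(n_gen = 4, n_cor = 2, n_noi = 4, C = 3,
                                 K_obs = 2, n_obs = 6, M = 300, N = 300,
                                 separation = 4), seed = 5)
  set.seed(99)
  s1 <- damda_select(sim$train, sim$train_class, sim$test, h = 0:1,
                     start = "observed")
  set.seed(99)
  s2 <- damda_select(sim$train, sim$train_class, sim$test, h = 0:1,
                     start = "observed")
  expect_identical(s1$history, s2$history)
  expect_identical(s1$relevant, s2$relevant)
  # learned-variable parameters in the final model are slices, never refits
  learned <- s1$learned
  fit <- s1$model
  lnames <- intersect(learned$var_names, s1$relevant)
  idx <- match(lnames, learned$var_names)
  P <- length(idx)
  for (k in seq_along(learned$class_names)) {
    expect_identical(fit$sigmas[seq_len(P), seq_len(P), k],
                     learned$sigmas[idx, idx, k])
    expect_identical(unname(fit$means[seq_len(P), k]),
                     unname(learned$means[idx, k]))
  }
  # generative variables survive the search on separated data
  expect_gte(sum(grepl("^gen", s1$relevant)), 3)
})
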