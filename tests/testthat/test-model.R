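# Model core: linear predictors, the independent-Bernoulli choice
# likelihood, ZIB parameters and density, priors, and the consistency of
# the vectorised sampling targets with the scalar definitions.

test_that("linear predictor equals the term-wise sum", {
  cs <- zero_coef()
  expect_equal(linear_predictor(cs, "happiness", c(0, 0, 0)), 0)

  cs$alpha["anger"] <- 1
  cs$beta["anger", ] <- c(1, 2, 3)
  expect_equal(linear_predictor(cs, "anger", c(0.5, 0, 0)), 1.5)

  set.seed(1)
  for (i in 1:10) {
    alpha <- setNames(rnorm(6), expression_labels())
    beta <- matrix(rnorm(18), 6, 3,
                   dimnames = list(expression_labels(), area_labels()))
    r_s <- matrix(rnorm(4 * 6), 4, 6,
                  dimnames = list(paste0("p", 1:4), expression_labels()))
    r_v <- matrix(rnorm(2 * 6), 2, 6,
                  dimnames = list(paste0("v", 1:2), expression_labels()))
    cs <- coefficient_set(alpha, beta, r_s, r_v)
    g <- runif(3)
    k <- sample(expression_labels(), 1)
    expected <- alpha[[k]] + g[1] * beta[k, 1] + g[2] * beta[k, 2] +
      g[3] * beta[k, 3] + r_s["p2", k] + r_v["v1", k]
    expect_equal(linear_predictor(cs, k, g, "p2", "v1"), expected)
  }

  expect_error(linear_predictor(cs, "anger", runif(3), subj_id = "nope"),
               "unknown id")
  expect_error(linear_predictor(zero_coef(), "anger", runif(5)), "length")
})

test_that("choice log-likelihood is the six-term Bernoulli sum", {
  cs <- zero_coef()
  expect_equal(choice_loglik(cs, "anger", c(0, 0, 0)), 6 * log(0.5))

  sat <- zero_coef()
  sat$alpha[] <- -50
  sat$alpha["fear"] <- 50
  expect_equal(choice_loglik(sat, "fear", c(0, 0, 0)), 0, tolerance = 1e-10)

  # mu = (1, -1, 0, 0, 0, 0), chosen = first label
  cs <- zero_coef()
  cs$alpha[1:2] <- c(1, -1)
  expected <- log(1 / (1 + exp(-1))) + log(1 - 1 / (1 + exp(1))) +
    4 * log(0.5)
  expect_equal(choice_loglik(cs, "happiness", c(0, 0, 0)), expected)

  # decomposition: equals the sum of six scalar Bernoulli log-likelihoods
  set.seed(2)
  for (i in 1:10) {
    cs <- zero_coef()
    cs$alpha[] <- rnorm(6)
    cs$beta[] <- rnorm(18)
    g <- runif(3)
    chosen <- sample(expression_labels(), 1)
    by_hand <- sum(vapply(expression_labels(), function(k) {
      mu <- linear_predictor(cs, k, g)
      p <- 1 / (1 + exp(-mu))
      if (k == chosen) log(p) else log(1 - p)
    }, numeric(1)))
    expect_equal(choice_loglik(cs, chosen, g), by_hand)
  }

  expect_error(choice_loglik(zero_coef(), "smile", c(0, 0, 0)), "labels")
})

test_that("zib_params maps traits to (q, a, b) with a + b = phi", {
  z <- zero_zib(phi = 10)
  p <- zib_params(z, "upper", rep(0, 5))
  expect_equal(p$q, 0.5)
  expect_equal(p$a, 5)
  expect_equal(p$b, 5)

  z$beta_part$alpha["middle"] <- qlogis(0.3)
  p <- zib_params(z, "middle", rep(0, 5))
  expect_equal(c(p$a, p$b), c(3, 7))

  set.seed(3)
  for (i in 1:10) {
    z2 <- zero_zib(phi = runif(1, 0.5, 30))
    z2$zero$beta[] <- rnorm(15)
    z2$beta_part$beta[] <- rnorm(15, 0, 0.3)
    p <- zib_params(z2, sample(area_labels(), 1), runif(5, 1, 7))
    expect_equal(p$a + p$b, z2$phi)
    expect_equal(p$a / (p$a + p$b), p$mu)   # Beta mean equals mu
    expect_true(p$q > 0 && p$q < 1)
  }

  expect_error(zib_coefficient_set(z$zero, z$beta_part, phi = -1), "positive")
})

test_that("the ZIB density matches closed forms and integrates to one", {
  expect_equal(zib_loglik(0.5, 2, 2, 0), log(0.5))
  expect_equal(zib_loglik(1 - 1e-12, 1, 1, 0.5), 0, tolerance = 1e-9)
  # Beta(2, 2) density at 0.25 is 6 * 0.25 * 0.75
  expect_equal(zib_loglik(0.8, 2, 2, 0.25), log(0.8 * 6 * 0.25 * 0.75))
  expect_equal(zib_loglik(0.8, 2, 2, 0.25), log(0.9), tolerance = 1e-12)

  # point mass + q * integral of the Beta part = 1 to 1e-8
  for (q in c(0.1, 0.5, 0.9)) {
    for (ab in list(c(1, 1), c(2, 5), c(0.7, 3), c(8, 8))) {
      cont <- stats::integrate(function(g) exp(zib_loglik(q, ab[1], ab[2], g)),
                               0, 1, rel.tol = 1e-10)$value
      expect_lt(abs((1 - q) + cont - 1), 1e-8)
    }
  }

  expect_error(zib_loglik(0.5, 2, 2, 1), "clamp")
  expect_error(zib_loglik(0.5, 2, 2, -0.1), "upstream")
  expect_error(zib_loglik(1.2, 2, 2, 0.5), "q")
})

test_that("log prior matches closed-form densities and peaks at the gamma mode", {
  base <- zero_coef()
  bumped <- zero_coef()
  bumped$beta["happiness", "upper"] <- 1
  # moving one fixed effect from 0 to 1 changes the prior by the normal
  # log-density difference
  expect_equal(log_prior(bumped) - log_prior(base),
               dnorm(1, 0, 10, log = TRUE) - dnorm(0, 0, 10, log = TRUE))
  # a fixed effect at the mode contributes -log(10 sqrt(2 pi))
  expect_equal(dnorm(0, 0, 10, log = TRUE), -log(10 * sqrt(2 * pi)))

  # gamma(10, 10) prior on scales is maximised at the mode 0.9
  lp_at_scale <- vapply(seq(0.1, 3, by = 0.01), function(s) {
    cs <- zero_coef()
    cs$sd_subj <- s
    log_prior(cs)
  }, numeric(1))
  expect_equal(seq(0.1, 3, by = 0.01)[which.max(lp_at_scale)], 0.9)

  cs <- zero_coef(); cs$sd_subj <- -1
  expect_equal(log_prior(cs), -Inf)
})

test_that("sampling targets agree with the scalar model definitions", {
  st <- sim_study(4, seed = 21, parts = 2, n_actors = 2)
  trials <- st$trials
  m <- choice_model(trials, st$weights, "happiness", "A")
  set.seed(1)
  theta <- m$init()
  rep_par <- m$transform(theta)
  # rebuild the constrained coefficient set from the reported draws
  cond_trials <- dplyr::filter(trials, presented == "happiness")
  subj <- sort(unique(cond_trials$participant_id))
  stim <- sort(unique(cond_trials$stimulus_id))
  cs <- coefficient_set(
    alpha = setNames(rep_par[paste0("alpha[", expression_labels(), "]")],
                     expression_labels()),
    beta = matrix(rep_par[grep("^beta\\[", names(rep_par))], 6, 3,
                  dimnames = list(expression_labels(), area_labels())),
    r_subj = matrix(rep_par[grep("^r_subj\\[", names(rep_par))],
                    length(subj), 6,
                    dimnames = list(subj, expression_labels())),
    r_stim = matrix(rep_par[grep("^r_stim\\[", names(rep_par))],
                    length(stim), 6,
                    dimnames = list(stim, expression_labels())),
    sd_subj = rep_par[["sd_subj"]], sd_stim = rep_par[["sd_stim"]]
  )
  cond <- dplyr::inner_join(
    dplyr::filter(trials, presented == "happiness"),
    st$weights[, c("session_id", "w_upper", "w_middle", "w_low")],
    by = "session_id")
  ll <- sum(vapply(seq_len(nrow(cond)), function(i) {
    choice_loglik(cs, cond$chosen[i],
                  as.numeric(cond[i, c("w_upper", "w_middle", "w_low")]),
                  cond$participant_id[i], cond$stimulus_id[i])
  }, numeric(1)))
  # non-centred parameterisation: the unconstrained target adds the
  # jacobians log(sd) per random effect and log(sd) per sampled scale
  n_s <- length(subj) * 6; n_v <- length(stim) * 6
  expected <- ll + log_prior(cs) +
    n_s * log(cs$sd_subj) + n_v * log(cs$sd_stim) +
    log(cs$sd_subj) + log(cs$sd_stim)
  expect_equal(m$lp_grad(theta)$lp, expected)
})

test_that("analytic gradients match finite differences", {
  st <- sim_study(3, seed = 8, parts = 2, n_actors = 2)
  mA <- choice_model(st$trials, st$weights, "sadness", "A")
  mB <- choice_model(st$trials, st$participants, "sadness", "B")
  mC <- zib_model(st$weights, st$participants, st$trials, "sadness")
  set.seed(2)
  for (m in list(mA, mB, mC)) {
    theta <- m$init()
    g <- m$lp_grad(theta)$grad
    gn <- fd_grad(function(x) m$lp_grad(x)$lp, theta)
    expect_lt(max(abs(g - gn)), 1e-4)
  }
})
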