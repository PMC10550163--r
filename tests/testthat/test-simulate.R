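# Synthetic-data generators: trait profiles, landmark stimuli, ZIB
# observation weights, choices and cursor trajectories.

test_that("participant profiles are reproducible, truncated and validated", {
  p1 <- sim_participants(3, seed = 1)
  p2 <- sim_participants(3, seed = 1)
  expect_identical(p1, p2)
  expect_false(identical(p1, sim_participants(3, seed = 2)))

  big <- sim_participants(1000, seed = 2)
  scores <- as.matrix(big[, trait_labels()])
  expect_true(all(scores >= 1 & scores <= 7))

  point <- sim_participants(1000, seed = 3, trait_sd = 0)
  expect_true(all(as.matrix(point[, trait_labels()]) == 4))

  expect_error(sim_participants(0), "n")
})

test_that("stimulus generator emits actors x expressions videos of 68 points", {
  stim <- sim_stimuli(8, seed = 1)
  expect_equal(nrow(stim), 48)
  expect_true(all(vapply(stim$frames, function(f) dim(f)[2], numeric(1)) == 68))
  # 2500 ms at the default frame interval
  expect_true(all(vapply(stim$frames, function(f) dim(f)[1], numeric(1)) *
                    stim$frame_interval_ms == 2500))
  # all points inside the canvas; face box roughly 200 x 250 px
  f <- stim$frames[[1]]
  expect_true(all(f[, , 1] >= 0 & f[, , 1] < 600))
  expect_true(all(f[, , 2] >= 0 & f[, , 2] < 800))
  wdt <- max(f[1, , 1]) - min(f[1, , 1])
  hgt <- max(f[1, , 2]) - min(f[1, , 2])
  expect_gt(wdt, 150); expect_lt(wdt, 260)
  expect_gt(hgt, 200); expect_lt(hgt, 320)

  s1 <- sim_stimuli(1, "happiness", seed = 5)
  s2 <- sim_stimuli(1, "happiness", seed = 5)
  expect_identical(s1$frames[[1]], s2$frames[[1]])

  expect_error(sim_stimuli(8, character(0)), "non-empty")
})

test_that("observation-weight draws follow the zero-inflated beta law", {
  # zero-part intercepts pushed to -infinity: no region is ever observed
  off <- zero_zib()
  off$zero$alpha[] <- -40
  set.seed(1)
  expect_equal(unname(sample_observation_weights(off, rep(4, 5))), c(0, 0, 0))

  # all coefficients zero, phi = 2: nonzero draws are Beta(1, 1), mean 1/2,
  # and the nonzero fraction is logit^-1(0) = 1/2
  z <- zero_zib(phi = 2)
  set.seed(2)
  draws <- replicate(10000, sample_observation_weights(z, rep(0, 5))[["upper"]])
  nonzero <- draws[draws > 0]
  se_mean <- sqrt(1 / 12) / sqrt(length(nonzero))
  expect_lt(abs(mean(nonzero) - 0.5), 3 * se_mean)
  se_frac <- sqrt(0.25 / 10000)
  expect_lt(abs(mean(draws > 0) - 0.5), 3 * se_frac)

  # trait-dependent (q, a, b): match the analytic zero probability and
  # conditional Beta moments within 3 Monte-Carlo standard errors
  tr <- c(5, 3, 4, 2, 6)
  zc <- zero_zib(phi = 10)
  zc$zero$beta[1, ] <- c(0.2, 0, -0.1, 0, 0.05)
  zc$beta_part$beta[1, ] <- c(-0.1, 0.05, 0, 0.1, 0)
  pars <- zib_params(zc, "upper", tr)
  set.seed(3)
  draws <- replicate(10000, sample_observation_weights(zc, tr)[["upper"]])
  nz <- draws[draws > 0]
  mu <- pars$a / (pars$a + pars$b)
  v <- pars$a * pars$b / ((pars$a + pars$b)^2 * (pars$a + pars$b + 1))
  expect_lt(abs(mean(draws > 0) - pars$q),
            3 * sqrt(pars$q * (1 - pars$q) / 10000))
  expect_lt(abs(mean(nz) - mu), 3 * sqrt(v / length(nz)))
  m4 <- mean((nz - mean(nz))^4)
  expect_lt(abs(var(nz) - v),
            3 * sqrt((m4 - var(nz)^2) / length(nz)))
})

test_that("choice draws respect the normalised-Bernoulli probabilities", {
  cs <- zero_coef()
  set.seed(1)
  ch <- sample_choices(cs, c(0, 0, 0), "A", n = 12000)
  freq <- table(factor(ch, levels = expression_labels())) / 12000
  expect_true(all(abs(freq - 1 / 6) < 3 * sqrt((1 / 6) * (5 / 6) / 12000)))

  sat <- zero_coef()
  sat$alpha["happiness"] <- 20
  set.seed(2)
  ch <- sample_choices(sat, c(0, 0, 0), "A", n = 2000)
  expect_gt(mean(ch == "happiness"), 0.99)

  set.seed(7); a <- sample_choices(cs, c(0.2, 0.3, 0.1), "A", n = 50)
  set.seed(7); b <- sample_choices(cs, c(0.2, 0.3, 0.1), "A", n = 50)
  expect_identical(a, b)

  expect_error(sample_choices(cs, rep(0, 5), "A"), "variant")
  expect_error(sample_choices(zero_coef(trait_labels()), rep(0, 3), "A"),
               "variant")
})

test_that("simulated trajectories round-trip through preprocessing", {
  stim <- sim_stimuli(1, "happiness", seed = 2)
  cfg <- screen_config()
  check_roundtrip <- function(w) {
    tr <- sim_trajectory(w, stim[1, ], config = cfg)
    expect_true(all(diff(tr$t_ms) > 0))
    tr$session_id <- "s1"; tr$participant_id <- "p1"
    tr$stimulus_id <- stim$stimulus_id[1]
    got <- preprocess_trajectories(tr, stim, cfg)
    sum(abs(c(got$w_upper, got$w_middle, got$w_low) - w))
  }
  set.seed(11)
  expect_lt(check_roundtrip(c(1, 0, 0)), 0.05)
  expect_lt(check_roundtrip(c(0.34, 0.33, 0.33)), 0.05)
  for (i in 1:5) {
    w <- runif(3); w <- w / sum(w) * runif(1)
    expect_lt(check_roundtrip(w), 0.05)
  }
  expect_error(sim_trajectory(c(1, 0, 0), stim[1, ],
                              trajectory_policy(duration_ms = 0)),
               "positive")
  empty <- stim$frames[[1]][0, , , drop = FALSE]
  expect_error(sim_trajectory(c(1, 0, 0), empty), "frames")
})

test_that("the study wrapper produces a consistent dataset", {
  st <- sim_study(3, seed = 5, parts = c(1, 2), n_actors = 2)
  expect_equal(nrow(st$trials), 3 * 12 * 2)   # participants x videos x parts
  expect_equal(nrow(st$weights), 3 * 12)      # part 2 only
  expect_true(all(st$trials$chosen %in% expression_labels()))
  expect_true(all(st$trials$confidence %in% 1:7))
  w <- as.matrix(st$weights[, c("w_upper", "w_middle", "w_low")])
  expect_true(all(w >= 0 & w < 1))
  st2 <- sim_study(3, seed = 5, parts = c(1, 2), n_actors = 2)
  expect_identical(st$trials, st2$trials)
})
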