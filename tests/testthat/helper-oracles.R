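# Independent oracles and small fixtures shared across test files.

# central finite differences of a scalar function
fd_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# exhaustive-search HDI: scan every window of ceiling(mass * n) sorted
# values and keep the narrowest (first on ties)
hdi_bruteforce <- function(samples, mass = 0.95) {
  s <- sort(samples)
  n <- length(s)
  m <- min(n, ceiling(mass * n))
  best <- c(-Inf, Inf)
  for (i in seq_len(n - m + 1)) {
    if (s[i + m - 1] - s[i] < best[2] - best[1]) {
      best <- c(s[i], s[i + m - 1])
    }
  }
  best
}

# split-chain potential scale reduction, transcribed term by term from the
# textbook definition (chains split in half; between/within variances)
rhat_reference <- function(mat) {
  half <- floor(nrow(mat) / 2)
  chains <- list()
  for (c in seq_len(ncol(mat))) {
    chains[[length(chains) + 1]] <- mat[1:half, c]
    chains[[length(chains) + 1]] <- mat[(nrow(mat) - half + 1):nrow(mat), c]
  }
  m <- length(chains)
  n <- half
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, var, numeric(1))
  B <- n / (m - 1) * sum((means - mean(means))^2)
  W <- mean(vars)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# flat zero coefficient set for the six responses
zero_coef <- function(p_names = area_labels()) {
  coefficient_set(
    alpha = setNames(rep(0, 6), expression_labels()),
    beta = matrix(0, 6, length(p_names),
                  dimnames = list(expression_labels(), p_names))
  )
}

zero_zib <- function(phi = 10) {
  blk <- list(alpha = setNames(rep(0, 3), area_labels()),
              beta = matrix(0, 3, 5,
                            dimnames = list(area_labels(), trait_labels())))
  zib_coefficient_set(zero = blk, beta_part = blk, phi = phi)
}

# hand-built ft_fit around given pooled samples for the fixed effects, for
# testing summaries without running MCMC. `samples` is a named list of
# numeric vectors keyed by parameter name (equal lengths, multiple of 2).
fake_choice_fit <- function(samples, variant = "B", condition = "happiness") {
  pn <- names(samples)
  nd <- length(samples[[1]])
  arr <- array(NA_real_, dim = c(2, nd / 2, length(pn)),
               dimnames = list(NULL, NULL, pn))
  for (p in pn) arr[, , p] <- matrix(samples[[p]], nrow = 2, byrow = TRUE)
  preds <- if (variant == "A") area_labels() else trait_labels()
  K <- 6
  beta_names <- as.vector(outer(expression_labels(), preds,
                                function(k, p) paste0("beta[", k, ",", p, "]")))
  beta_terms <- tibble::tibble(
    parameter = beta_names,
    response = rep(expression_labels(), times = length(preds)),
    predictor = rep(preds, each = K)
  )
  beta_terms <- beta_terms[beta_terms$parameter %in% pn, ]
  draws <- structure(
    list(draws = arr, schedule = mcmc_schedule(2, 1, nd / 2 + 1),
         seed = 1L, divergent = c(0L, 0L), treedepth = c(1L, 1L),
         step_size = c(1, 1),
         info = list(family = "choice", variant = variant,
                     condition = condition, responses = expression_labels(),
                     predictors = preds, beta_terms = beta_terms)),
    class = "ft_draws")
  facetrait:::new_ft_fit(draws)
}

# draws object holding constant per-chain values, for rhat edge cases
constant_chains <- function(values, n = 100) {
  vapply(values, function(v) rep(v, n), numeric(n))
}

# standard independent-normal target for sampler checks
gaussian_target <- function(mu, s) {
  mcmc_model(
    lp_grad = function(th) list(lp = -sum((th - mu)^2 / (2 * s^2)),
                                grad = -(th - mu) / s^2),
    n_params = length(mu),
    param_names = paste0("x", seq_along(mu))
  )
}
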