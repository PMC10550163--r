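#' MCMC schedule
#'
#' The default schedule is four chains of 2000 iterations each, the first
#' 1000 of which are warmup, so 4 x 1000 = 4000 draws are retained.
#'
#' @param chains Number of chains (default 4).
#' @param warmup Warmup (adaptation) iterations per chain (default 1000).
#' @param iterations Total iterations per chain including warmup (default
#'   2000).
#' @return A list of class `ft_schedule`.
#' @export
mcmc_schedule <- function(chains = 4, warmup = 1000, iterations = 2000) {
  stopifnot(chains >= 1, warmup >= 1, iterations > warmup)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 iterations = as.integer(iterations)),
            class = "ft_schedule")
}

#' Generic differentiable target for [run_mcmc()]
#'
#' Wraps a log-density and its gradient as a sampleable model. The model
#' builders [choice_model()] and [zib_model()] produce these internally;
#' `mcmc_model()` lets you sample any custom target with the same engine.
#'
#' @param lp_grad Function of the unconstrained parameter vector returning
#'   `list(lp = <number>, grad = <numeric vector>)`.
#' @param n_params Dimension of the unconstrained parameter vector.
#' @param param_names Names of the reported (constrained) parameters.
#' @param transform Function mapping the unconstrained vector to the named
#'   reported vector; default identity.
#' @param init Function of no arguments returning an initial unconstrained
#'   vector; default `rnorm(n_params, 0, 0.1)`.
#' @param info Optional metadata list carried into the draws object.
#' @return A list of class `ft_model`.
#' @export
#' @examples
#' m <- mcmc_model(
#'   lp_grad = function(th) list(lp = -sum(th^2) / 2, grad = -th),
#'   n_params = 2, param_names = c("x", "y")
#' )
#' d <- run_mcmc(m, mcmc_schedule(chains = 2, warmup = 100, iterations = 200),
#'               seed = 1)
#' dim(d$draws)
mcmc_model <- function(lp_grad, n_params, param_names = NULL,
                       transform = NULL, init = NULL, info = list()) {
  param_names <- param_names %||% paste0("theta[", seq_len(n_params), "]")
  transform <- transform %||% function(theta) setNames(theta, param_names)
  init <- init %||% function() rnorm(n_params, 0, 0.1)
  structure(list(lp_grad = lp_grad, n_params = as.integer(n_params),
                 param_names = param_names, transform = transform,
                 init = init, info = info),
            class = "ft_model")
}

# ---- No-U-Turn sampler -----------------------------------------------------

# One leapfrog step under a diagonal metric m (momentum covariance).
leapfrog <- function(theta, p, grad, eps, inv_m, lp_grad) {
  p <- p + 0.5 * eps * grad
  theta <- theta + eps * inv_m * p
  lg <- lp_grad(theta)
  p <- p + 0.5 * eps * lg$grad
  list(theta = theta, p = p, lp = lg$lp, grad = lg$grad)
}

joint_lp <- function(lp, p, inv_m) lp - 0.5 * sum(p^2 * inv_m)

find_epsilon <- function(theta, lp_grad, inv_m, m_diag) {
  eps <- 1
  lg <- lp_grad(theta)
  p <- rnorm(length(theta), 0, sqrt(m_diag))
  h0 <- joint_lp(lg$lp, p, inv_m)
  st <- leapfrog(theta, p, lg$grad, eps, inv_m, lp_grad)
  h1 <- joint_lp(st$lp, st$p, inv_m)
  if (!is.finite(h1)) h1 <- -Inf
  a <- if (h1 - h0 > log(0.5)) 1 else -1
  for (i in 1:50) {
    eps <- eps * 2^a
    st <- leapfrog(theta, p, lg$grad, eps, inv_m, lp_grad)
    h1 <- joint_lp(st$lp, st$p, inv_m)
    if (!is.finite(h1)) h1 <- -Inf
    if (a * (h1 - h0) <= -a * log(2)) break
  }
  eps
}

build_tree <- function(st, logu, v, j, eps, h0, inv_m, lp_grad) {
  if (j == 0) {
    st1 <- leapfrog(st$theta, st$p, st$grad, v * eps, inv_m, lp_grad)
    h1 <- joint_lp(st1$lp, st1$p, inv_m)
    if (!is.finite(h1)) h1 <- -Inf
    n1 <- as.integer(logu <= h1)
    s1 <- as.integer(logu < h1 + 1000)
    list(minus = st1, plus = st1, prop = st1, n = n1, s = s1,
         alpha = min(1, exp(h1 - h0)), n_alpha = 1L,
         divergent = s1 == 0L)
  } else {
    t1 <- build_tree(st, logu, v, j - 1L, eps, h0, inv_m, lp_grad)
    if (t1$s == 1L) {
      if (v == -1) {
        t2 <- build_tree(t1$minus, logu, v, j - 1L, eps, h0, inv_m, lp_grad)
        t1$minus <- t2$minus
      } else {
        t2 <- build_tree(t1$plus, logu, v, j - 1L, eps, h0, inv_m, lp_grad)
        t1$plus <- t2$plus
      }
      if (t2$n > 0L && runif(1) < t2$n / (t1$n + t2$n)) t1$prop <- t2$prop
      d <- t1$plus$theta - t1$minus$theta
      t1$s <- t2$s *
        as.integer(sum(d * inv_m * t1$minus$p) >= 0) *
        as.integer(sum(d * inv_m * t1$plus$p) >= 0)
      t1$n <- t1$n + t2$n
      t1$alpha <- t1$alpha + t2$alpha
      t1$n_alpha <- t1$n_alpha + t2$n_alpha
      t1$divergent <- t1$divergent || t2$divergent
    }
    t1
  }
}

nuts_transition <- function(theta, lp, grad, eps, inv_m, m_diag, lp_grad,
                            max_treedepth) {
  d <- length(theta)
  p0 <- rnorm(d, 0, sqrt(m_diag))
  h0 <- joint_lp(lp, p0, inv_m)
  logu <- h0 - stats::rexp(1)
  st <- list(theta = theta, p = p0, lp = lp, grad = grad)
  minus <- st; plus <- st; prop <- st
  j <- 0L; n <- 1L; s <- 1L
  alpha <- 0; n_alpha <- 0L; divergent <- FALSE
  while (s == 1L && j < max_treedepth) {
    v <- sample(c(-1, 1), 1)
    if (v == -1) {
      t1 <- build_tree(minus, logu, v, j, eps, h0, inv_m, lp_grad)
      minus <- t1$minus
    } else {
      t1 <- build_tree(plus, logu, v, j, eps, h0, inv_m, lp_grad)
      plus <- t1$plus
    }
    if (t1$s == 1L && t1$n > 0L && runif(1) < t1$n / n) prop <- t1$prop
    n <- n + t1$n
    dth <- plus$theta - minus$theta
    s <- t1$s *
      as.integer(sum(dth * inv_m * minus$p) >= 0) *
      as.integer(sum(dth * inv_m * plus$p) >= 0)
    alpha <- t1$alpha; n_alpha <- t1$n_alpha
    divergent <- divergent || t1$divergent
    j <- j + 1L
  }
  list(theta = prop$theta, lp = prop$lp, grad = prop$grad,
       accept_stat = if (n_alpha > 0) alpha / n_alpha else 0,
       treedepth = j, divergent = divergent)
}

# Stan-style warmup phases: step-size-only buffers at both ends, doubling
# metric-estimation windows in between. Returns iterations at which the
# metric is updated.
metric_update_points <- function(warmup, init_buffer = 75, term_buffer = 50,
                                 base_window = 25) {
  if (warmup < init_buffer + term_buffer + base_window) {
    return(integer(0))
  }
  pts <- integer(0)
  pos <- init_buffer
  win <- base_window
  while (TRUE) {
    nxt <- pos + win
    if (nxt + 2 * win + term_buffer > warmup) {
      nxt <- warmup - term_buffer
      pts <- c(pts, nxt)
      break
    }
    pts <- c(pts, nxt)
    pos <- nxt
    win <- 2 * win
  }
  pts
}

nuts_chain <- function(model, schedule, control) {
  d <- model$n_params
  lp_grad <- model$lp_grad
  # re-initialise until the log-posterior is finite
  for (try in 1:20) {
    theta <- model$init()
    lg <- lp_grad(theta)
    if (is.finite(lg$lp)) break
    if (try == 20) stop("could not find a finite initial log-posterior",
                        call. = FALSE)
  }
  warmup <- schedule$warmup
  n_keep <- schedule$iterations - warmup
  m_diag <- rep(1, d); inv_m <- 1 / m_diag
  eps <- find_epsilon(theta, lp_grad, inv_m, m_diag)
  # dual averaging (target acceptance control$adapt_delta)
  da_mu <- log(10 * eps); da_h <- 0; da_logeps_bar <- 0; da_count <- 0
  gamma <- 0.05; t0 <- 10; kappa <- 0.75
  upd <- metric_update_points(warmup)
  welford_n <- 0; welford_m <- numeric(d); welford_s <- numeric(d)
  rep_draw <- model$transform(theta)
  draws <- matrix(NA_real_, n_keep, length(rep_draw),
                  dimnames = list(NULL, names(rep_draw)))
  treedepth <- integer(n_keep); divergent <- logical(n_keep)
  accept <- numeric(n_keep)
  for (it in seq_len(schedule$iterations)) {
    tr <- nuts_transition(theta, lg$lp, lg$grad, eps, inv_m, m_diag,
                          lp_grad, control$max_treedepth)
    theta <- tr$theta; lg <- list(lp = tr$lp, grad = tr$grad)
    if (it <= warmup) {
      da_count <- da_count + 1
      da_h <- (1 - 1 / (da_count + t0)) * da_h +
        (control$adapt_delta - tr$accept_stat) / (da_count + t0)
      logeps <- da_mu - sqrt(da_count) / gamma * da_h
      w <- da_count^(-kappa)
      da_logeps_bar <- w * logeps + (1 - w) * da_logeps_bar
      eps <- exp(logeps)
      if (length(upd) > 0 && it > 75) {
        welford_n <- welford_n + 1
        dlt <- theta - welford_m
        welford_m <- welford_m + dlt / welford_n
        welford_s <- welford_s + dlt * (theta - welford_m)
      }
      if (it %in% upd && welford_n > 4) {
        v <- welford_s / (welford_n - 1)
        v <- welford_n / (welford_n + 5) * v + 1e-3 * 5 / (welford_n + 5)
        m_diag <- 1 / v; inv_m <- v
        welford_n <- 0; welford_m[] <- 0; welford_s[] <- 0
        eps <- find_epsilon(theta, lp_grad, inv_m, m_diag)
        da_mu <- log(10 * eps); da_h <- 0; da_logeps_bar <- 0; da_count <- 0
      }
      if (it == warmup) eps <- exp(da_logeps_bar)
    } else {
      k <- it - warmup
      draws[k, ] <- model$transform(theta)
      treedepth[k] <- tr$treedepth
      divergent[k] <- tr$divergent
      accept[k] <- tr$accept_stat
    }
  }
  list(draws = draws, treedepth = treedepth, divergent = divergent,
       accept = accept, step_size = eps)
}

#' Run MCMC on a model
#'
#' Samples the posterior with a No-U-Turn sampler (multiplicative step-size
#' adaptation by dual averaging, diagonal mass-matrix estimation in
#' doubling windows during warmup). The default schedule retains 4 chains
#' x 1000 post-warmup draws = 4000 samples.
#'
#' @param model An `ft_model` from [choice_model()], [zib_model()] or
#'   [mcmc_model()].
#' @param schedule An [mcmc_schedule()].
#' @param seed Integer seed; the full run is reproducible given the seed.
#' @param control List with `max_treedepth` (default 10) and `adapt_delta`
#'   (target acceptance, default 0.8).
#' @return An object of class `ft_draws`: a list with `draws`, an array of
#'   dimension (chains, draws, parameters) with parameter dimnames;
#'   `schedule`; sampler diagnostics (`divergent`, `treedepth`,
#'   `step_size`); and the model `info` metadata.
#' @export
run_mcmc <- function(model, schedule = mcmc_schedule(), seed = 1,
                     control = list()) {
  stopifnot(inherits(model, "ft_model"), inherits(schedule, "ft_schedule"))
  control <- modifyList(list(max_treedepth = 10, adapt_delta = 0.8), control)
  set.seed(as.integer(seed))
  chains <- lapply(seq_len(schedule$chains), function(ch) {
    nuts_chain(model, schedule, control)
  })
  n_keep <- schedule$iterations - schedule$warmup
  pnames <- colnames(chains[[1]]$draws)
  arr <- array(NA_real_, dim = c(schedule$chains, n_keep, length(pnames)),
               dimnames = list(NULL, NULL, pnames))
  for (ch in seq_along(chains)) arr[ch, , ] <- chains[[ch]]$draws
  structure(
    list(draws = arr, schedule = schedule, seed = as.integer(seed),
         divergent = vapply(chains, function(x) sum(x$divergent), integer(1)),
         treedepth = vapply(chains, function(x) max(x$treedepth), integer(1)),
         step_size = vapply(chains, function(x) x$step_size, numeric(1)),
         info = model$info),
    class = "ft_draws"
  )
}

#' @export
print.ft_draws <- function(x, ...) {
  cat("<ft_draws> ", dim(x$draws)[1], " chains x ", dim(x$draws)[2],
      " draws x ", dim(x$draws)[3], " parameters\n", sep = "")
  cat("divergences per chain:", paste(x$divergent, collapse = " "), "\n")
  invisible(x)
}

# ---- diagnostics -----------------------------------------------------------

#' Split-chain potential scale reduction factor (Rhat)
#'
#' Each chain is split in half and the classical potential scale reduction
#' factor is computed on the split chains: `sqrt(((n - 1)/n * W + B/n) / W)`
#' with `W` the mean within-chain variance and `B` the between-chain
#' variance of the split-chain means. Values near 1 indicate convergence;
#' 1.1 is the conventional cut-off.
#'
#' @param x A draws matrix (iterations x chains), or an `ft_draws` object.
#' @param coefficient For `ft_draws` input, the parameter name.
#' @return The split-Rhat value (>= 1 up to floating point; `Inf` when
#'   chains have zero within-chain variance but disagree).
#' @export
rhat <- function(x, coefficient = NULL) {
  if (inherits(x, "ft_draws")) {
    if (is.null(coefficient)) stop("supply a `coefficient` name", call. = FALSE)
    x <- t(x$draws[, , coefficient])   # iterations x chains
  }
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("rhat requires at least 2 chains", call. = FALSE)
  if (nrow(x) < 4) stop("rhat requires at least 4 draws per chain", call. = FALSE)
  half <- floor(nrow(x) / 2)
  splits <- cbind(x[seq_len(half), , drop = FALSE],
                  x[nrow(x) - half + seq_len(half), , drop = FALSE])
  n <- nrow(splits)
  w <- mean(apply(splits, 2, var))
  b <- n * var(colMeans(splits))
  if (w == 0) return(if (b == 0) 1 else Inf)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Rhat for every parameter of a draws object
#'
#' @param draws An `ft_draws` object.
#' @return A tibble with columns `parameter` and `rhat`.
#' @export
rhat_all <- function(draws) {
  stopifnot(inherits(draws, "ft_draws"))
  pn <- dimnames(draws$draws)[[3]]
  tibble::tibble(
    parameter = pn,
    rhat = vapply(pn, function(p) rhat(t(draws$draws[, , p])), numeric(1))
  )
}

#' Highest-density interval
#'
#' The shortest contiguous interval containing at least `mass` of the
#' sample: among all windows of `ceiling(mass * n)` consecutive order
#' statistics, the narrowest (ties broken toward the lowest lower bound).
#'
#' @param samples Numeric vector of at least 2 draws.
#' @param mass Probability mass of the interval (default 0.95).
#' @return Named numeric vector `c(lower, upper)` with attribute `mass`.
#' @export
#' @examples
#' hdi(rnorm(1e4))
hdi <- function(samples, mass = 0.95) {
  if (length(samples) < 2) stop("hdi requires at least 2 samples", call. = FALSE)
  if (mass <= 0 || mass >= 1) stop("`mass` must be in (0, 1)", call. = FALSE)
  s <- sort(samples)
  n <- length(s)
  m <- min(n, ceiling(mass * n))
  widths <- s[m:n] - s[seq_len(n - m + 1)]
  i <- which.min(widths)   # first minimum = lowest lower bound on ties
  structure(c(lower = s[i], upper = s[i + m - 1]), mass = mass)
}
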