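#' Coefficient set for a choice model
#'
#' Bundles the parameters of one independent-Bernoulli choice model: one
#' intercept per response expression, a fixed-effect matrix over the
#' predictors (three area weights for the behaviour variant "A", five trait
#' scores for the trait variant "B"), and per-participant / per-stimulus
#' random effects with their scales.
#'
#' @param alpha Named numeric vector of per-response intercepts; names must
#'   be the six expression labels.
#' @param beta Numeric matrix of fixed effects, rows named by response
#'   expression, columns by predictor (areas for variant "A", traits for
#'   variant "B").
#' @param r_subj,r_stim Optional random-effect matrices (rows named by
#'   participant / stimulus id, columns by response). `NULL` means all zero.
#' @param sd_subj,sd_stim Positive random-effect scales.
#' @return An object of class `ft_coef` (a list).
#' @export
#' @examples
#' cs <- coefficient_set(
#'   alpha = setNames(rep(0, 6), expression_labels()),
#'   beta = matrix(0, 6, 3, dimnames = list(expression_labels(), area_labels()))
#' )
#' linear_predictor(cs, "happiness", c(upper = 0.5, middle = 0.3, low = 0.1))
coefficient_set <- function(alpha, beta, r_subj = NULL, r_stim = NULL,
                            sd_subj = 1, sd_stim = 1) {
  stopifnot(is.numeric(alpha), is.matrix(beta), nrow(beta) == length(alpha))
  if (sd_subj <= 0 || sd_stim <= 0) {
    stop("random-effect scales must be positive", call. = FALSE)
  }
  structure(
    list(alpha = alpha, beta = beta, r_subj = r_subj, r_stim = r_stim,
         sd_subj = sd_subj, sd_stim = sd_stim),
    class = "ft_coef"
  )
}

#' Coefficient set for the zero-inflated beta behaviour model
#'
#' Parameters of the zero-inflated beta (ZIB) regression of observation
#' weights on traits: a zero block (logit model for whether a region was
#' observed at all) and a beta block (logit model for the conditional mean
#' dwell), each with per-area intercepts, an area-by-trait fixed-effect
#' matrix and participant/stimulus random effects, plus a shared precision
#' `phi` (Beta shapes are `a = phi * mu`, `b = phi * (1 - mu)`).
#'
#' @param zero,beta_part Lists with elements `alpha` (length-3 named vector
#'   over areas), `beta` (3 x 5 matrix, areas x traits), optional `r_subj`,
#'   `r_stim` matrices (rows ids, columns areas), and scales `sd_subj`,
#'   `sd_stim`.
#' @param phi Positive precision of the Beta part.
#' @return An object of class `ft_zib_coef`.
#' @export
zib_coefficient_set <- function(zero, beta_part, phi) {
  if (!is.numeric(phi) || length(phi) != 1L || phi <= 0) {
    stop("`phi` must be a single positive number", call. = FALSE)
  }
  blk <- function(b) {
    stopifnot(length(b$alpha) == 3L, is.matrix(b$beta),
              nrow(b$beta) == 3L, ncol(b$beta) == 5L)
    b$sd_subj <- b$sd_subj %||% 1
    b$sd_stim <- b$sd_stim %||% 1
    b
  }
  structure(list(zero = blk(zero), beta_part = blk(beta_part), phi = phi),
            class = "ft_zib_coef")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

lookup_ranef <- function(r, id, col) {
  if (is.null(r)) return(0)
  if (is.null(id)) return(0)
  if (!id %in% rownames(r)) {
    stop("unknown id '", id, "' in random-effect table", call. = FALSE)
  }
  r[id, col]
}

#' Linear predictor of a choice model
#'
#' Computes `alpha_k + sum_g predictors_g * beta_kg + r_subj + r_stim` for
#' one response expression `k`: the logit-scale mean of the Bernoulli
#' indicator that response `k` is chosen.
#'
#' @param coeffs A [coefficient_set()].
#' @param expression_k Response expression label.
#' @param predictors Numeric vector of predictor values, same length and
#'   order as the columns of `coeffs$beta`.
#' @param subj_id,stim_id Optional ids indexing the random-effect tables;
#'   `NULL` sets the corresponding effect to zero (population level).
#' @return A single number on the logit scale.
#' @export
linear_predictor <- function(coeffs, expression_k, predictors,
                             subj_id = NULL, stim_id = NULL) {
  stopifnot(inherits(coeffs, "ft_coef"))
  if (length(predictors) != ncol(coeffs$beta)) {
    stop("predictor length (", length(predictors),
         ") does not match coefficient columns (", ncol(coeffs$beta), ")",
         call. = FALSE)
  }
  if (!expression_k %in% names(coeffs$alpha)) {
    stop("unknown response expression '", expression_k, "'", call. = FALSE)
  }
  coeffs$alpha[[expression_k]] +
    sum(predictors * coeffs$beta[expression_k, ]) +
    lookup_ranef(coeffs$r_subj, subj_id, expression_k) +
    lookup_ranef(coeffs$r_stim, stim_id, expression_k)
}

#' Choice log-likelihood of one trial
#'
#' The likelihood treats the six possible responses as six independent
#' Bernoulli indicators: `y_k = 1` iff the participant chose expression `k`,
#' with `P(y_k = 1) = logit^-1(mu_k)`. The total log-likelihood is the sum
#' of the six Bernoulli terms (not a softmax; the six probabilities need
#' not sum to one). A categorical (softmax over the same linear predictors)
#' variant is available for sensitivity analysis via `categorical = TRUE`.
#'
#' @inheritParams linear_predictor
#' @param chosen The chosen expression label.
#' @param categorical If `TRUE`, evaluate a categorical likelihood with
#'   probabilities `exp(mu_k) / sum(exp(mu))` instead of the default
#'   independent-Bernoulli product.
#' @return The log-likelihood (a single number).
#' @export
#' @examples
#' cs <- coefficient_set(
#'   alpha = setNames(rep(0, 6), expression_labels()),
#'   beta = matrix(0, 6, 3, dimnames = list(expression_labels(), area_labels()))
#' )
#' choice_loglik(cs, chosen = "anger", predictors = rep(0, 3)) # 6 * log(0.5)
choice_loglik <- function(coeffs, chosen, predictors,
                          subj_id = NULL, stim_id = NULL,
                          categorical = FALSE) {
  responses <- names(coeffs$alpha)
  if (!chosen %in% responses) {
    stop("`chosen` must be one of the response labels", call. = FALSE)
  }
  mu <- vapply(responses, function(k) {
    linear_predictor(coeffs, k, predictors, subj_id, stim_id)
  }, numeric(1))
  if (any(!is.finite(mu))) return(-Inf)
  y <- as.numeric(responses == chosen)
  if (categorical) {
    m <- max(mu)
    return(mu[which(y == 1)] - m - log(sum(exp(mu - m))))
  }
  sum(y * mu - log1pexp(mu))
}

#' Zero-inflated beta parameters for one observation
#'
#' Maps ZIB regression coefficients and a participant's trait scores to the
#' distribution parameters of one region's observation weight: `q`, the
#' probability that the region was observed at all (the nonzero branch),
#' and the Beta shapes `a = phi * mu`, `b = phi * (1 - mu)` where `mu` is
#' the conditional mean dwell. Both `q` and `mu` are inverse-logit
#' transforms of trait-linear predictors with participant and stimulus
#' random effects.
#'
#' @param coeffs A [zib_coefficient_set()].
#' @param area_k Area label (`"upper"`, `"middle"` or `"low"`).
#' @param traits Numeric vector of the five trait scores (order of
#'   [trait_labels()]).
#' @param subj_id,stim_id Optional random-effect ids (see
#'   [linear_predictor()]).
#' @return A list with elements `q`, `a`, `b` (and `mu`); `a + b == phi`.
#' @export
#' @examples
#' zc <- zib_coefficient_set(
#'   zero = list(alpha = setNames(rep(0, 3), area_labels()),
#'               beta = matrix(0, 3, 5)),
#'   beta_part = list(alpha = setNames(rep(0, 3), area_labels()),
#'                    beta = matrix(0, 3, 5)),
#'   phi = 10
#' )
#' zib_params(zc, "upper", rep(0, 5)) # q = 0.5, a = b = 5
zib_params <- function(coeffs, area_k, traits, subj_id = NULL,
                       stim_id = NULL) {
  stopifnot(inherits(coeffs, "ft_zib_coef"), length(traits) == 5L)
  if (coeffs$phi <= 0) stop("`phi` must be positive", call. = FALSE)
  if (!area_k %in% names(coeffs$zero$alpha)) {
    stop("unknown area '", area_k, "'", call. = FALSE)
  }
  eta <- function(b) {
    b$alpha[[area_k]] + sum(traits * b$beta[area_k, ]) +
      lookup_ranef(b$r_subj, subj_id, area_k) +
      lookup_ranef(b$r_stim, stim_id, area_k)
  }
  q <- plogis(eta(coeffs$zero))
  mu <- plogis(eta(coeffs$beta_part))
  list(q = q, a = coeffs$phi * mu, b = coeffs$phi * (1 - mu), mu = mu)
}

#' Zero-inflated beta log-density
#'
#' Density of the ZIB mixture for an observation weight `g` in `[0, 1)`:
#' `log(1 - q)` when `g == 0`, and `log(q) + log Beta(g; a, b)` when
#' `g > 0`. Here `q` is the probability of a *nonzero* observation.
#'
#' @param q Probability of a nonzero observation, strictly in (0, 1).
#' @param a,b Positive Beta shape parameters.
#' @param g Observation weight(s) in `[0, 1)`; vectorised over `g`.
#' @return Log-density, same length as `g`.
#' @export
#' @examples
#' zib_loglik(q = 0.8, a = 2, b = 2, g = 0.25) # log(0.9)
zib_loglik <- function(q, a, b, g) {
  if (any(q <= 0) || any(q >= 1)) stop("`q` must be in (0, 1)", call. = FALSE)
  if (any(a <= 0) || any(b <= 0)) stop("Beta shapes must be positive", call. = FALSE)
  if (any(g < 0) || any(g >= 1)) {
    stop("`g` must be in [0, 1); clamp weights upstream", call. = FALSE)
  }
  out <- numeric(length(g))
  z <- g == 0
  out[z] <- log1p(-q)
  out[!z] <- log(q) + dbeta(g[!z], a, b, log = TRUE)
  out
}

#' Prior configuration
#'
#' Weakly informative priors used by every model: normal(0, `fixed_sd`) on
#' intercepts and fixed effects (sd 10, i.e. variance 100), gamma(`10`,
#' `10`) on random-effect scales, normal(0, scale) on the random effects
#' themselves, and gamma(`phi_shape`, `phi_rate`) on the ZIB precision.
#'
#' @param fixed_sd Prior sd of fixed effects (default 10).
#' @param scale_shape,scale_rate Gamma prior on random-effect scales
#'   (default shape 10, rate 10, mode 0.9).
#' @param phi_shape,phi_rate Gamma prior on the ZIB precision (default
#'   shape 2, rate 0.1: weakly informative on positive support).
#' @return A list of class `ft_priors`.
#' @export
prior_config <- function(fixed_sd = 10, scale_shape = 10, scale_rate = 10,
                         phi_shape = 2, phi_rate = 0.1) {
  stopifnot(fixed_sd > 0, scale_shape > 0, scale_rate > 0,
            phi_shape > 0, phi_rate > 0)
  structure(list(fixed_sd = fixed_sd, scale_shape = scale_shape,
                 scale_rate = scale_rate, phi_shape = phi_shape,
                 phi_rate = phi_rate),
            class = "ft_priors")
}

block_log_prior <- function(alpha, beta, r_subj, r_stim, sd_subj, sd_stim,
                            config) {
  if (sd_subj <= 0 || sd_stim <= 0) return(-Inf)
  lp <- sum(dnorm(c(alpha, beta), 0, config$fixed_sd, log = TRUE)) +
    dgamma(sd_subj, config$scale_shape, rate = config$scale_rate, log = TRUE) +
    dgamma(sd_stim, config$scale_shape, rate = config$scale_rate, log = TRUE)
  if (!is.null(r_subj)) lp <- lp + sum(dnorm(r_subj, 0, sd_subj, log = TRUE))
  if (!is.null(r_stim)) lp <- lp + sum(dnorm(r_stim, 0, sd_stim, log = TRUE))
  lp
}

#' Log prior density of a coefficient set
#'
#' Sums the log prior densities of [prior_config()] over every parameter in
#' a [coefficient_set()] or [zib_coefficient_set()].
#'
#' @param coeffs A coefficient set.
#' @param config A [prior_config()].
#' @return The log prior density; `-Inf` for non-positive scales.
#' @export
log_prior <- function(coeffs, config = prior_config()) {
  stopifnot(inherits(config, "ft_priors"))
  if (inherits(coeffs, "ft_coef")) {
    return(block_log_prior(coeffs$alpha, coeffs$beta, coeffs$r_subj,
                           coeffs$r_stim, coeffs$sd_subj, coeffs$sd_stim,
                           config))
  }
  if (inherits(coeffs, "ft_zib_coef")) {
    if (coeffs$phi <= 0) return(-Inf)
    lp <- 0
    for (b in list(coeffs$zero, coeffs$beta_part)) {
      lp <- lp + block_log_prior(b$alpha, b$beta, b$r_subj, b$r_stim,
                                 b$sd_subj, b$sd_stim, config)
    }
    return(lp + dgamma(coeffs$phi, config$phi_shape, rate = config$phi_rate,
                       log = TRUE))
  }
  stop("`coeffs` must be a coefficient_set() or zib_coefficient_set()",
       call. = FALSE)
}
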