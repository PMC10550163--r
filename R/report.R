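# Posterior-predictive summaries: per-response selection probabilities
# against the 1/6 chance level, and trait sweeps over the 1-7 scale.

choice_draw_matrices <- function(fit) {
  stopifnot(inherits(fit, "ft_fit"))
  if (fit$info$family != "choice") {
    stop("posterior-predictive reports require a choice-model fit",
         call. = FALSE)
  }
  responses <- fit$info$responses
  preds <- fit$info$predictors
  d <- fit$draws$draws
  pool <- function(p) as.vector(d[, , p])
  A <- vapply(paste0("alpha[", responses, "]"), pool,
              numeric(dim(d)[1] * dim(d)[2]))
  B <- lapply(responses, function(k) {
    vapply(paste0("beta[", k, ",", preds, "]"), pool, numeric(nrow(A)))
  })
  names(B) <- responses
  list(alpha = A, beta = B, responses = responses, preds = preds)
}

# per-draw, per-profile normalised selection probabilities;
# returns list(norm = draws x responses (profile-averaged),
#              raw = same for the unnormalised Bernoulli means)
predictive_probs <- function(fit, profiles) {
  m <- choice_draw_matrices(fit)
  X <- as.matrix(profiles)
  if (ncol(X) != length(m$preds)) {
    stop("profiles must have ", length(m$preds), " predictor columns (",
         paste(m$preds, collapse = ", "), ")", call. = FALSE)
  }
  nd <- nrow(m$alpha); np <- nrow(X); nk <- length(m$responses)
  MU <- array(0, dim = c(nd, np, nk))
  for (k in seq_len(nk)) {
    MU[, , k] <- m$alpha[, k] + m$beta[[k]] %*% t(X)
  }
  # softmax across responses (the generator's forced-choice convention)
  E <- exp(MU - as.vector(apply(MU, c(1, 2), max)))
  Pn <- E / as.vector(apply(E, c(1, 2), sum))
  list(norm = apply(Pn, c(1, 3), mean),
       raw = apply(plogis(MU), c(1, 3), mean),
       responses = m$responses)
}

#' Posterior-predictive selection probabilities
#'
#' For every retained draw, computes the six per-response selection
#' probabilities at population level (random effects 0), normalised across
#' responses, averaged over the supplied predictor profiles, and
#' summarises them with the posterior mean and 95% HDI. The chance level
#' for six alternatives is 1/6.
#'
#' @param fit A choice-model `ft_fit`.
#' @param profiles Tibble/matrix of predictor profiles to average over:
#'   columns `w_upper`, `w_middle`, `w_low` (variant A) or the five trait
#'   columns (variant B). A single reference profile is a one-row input.
#' @param condition Optional check: errors if it does not match the fit's
#'   condition.
#' @param mass HDI mass (default 0.95).
#' @return A tibble of class `ft_selection`: `condition`, `response`,
#'   `mean`, `hdi_low`, `hdi_high`, `mean_bernoulli` (unnormalised) and
#'   `chance_level`.
#' @export
selection_probabilities <- function(fit, profiles, condition = NULL,
                                    mass = 0.95) {
  if (!is.null(condition) && condition != fit$info$condition) {
    stop("fit is for condition '", fit$info$condition, "', not '",
         condition, "'", call. = FALSE)
  }
  cols <- if (fit$info$variant == "A") {
    c("w_upper", "w_middle", "w_low")
  } else {
    trait_labels()
  }
  if (is.data.frame(profiles)) profiles <- profiles[, cols, drop = FALSE]
  pp <- predictive_probs(fit, profiles)
  out <- dplyr::bind_rows(lapply(seq_along(pp$responses), function(k) {
    h <- hdi(pp$norm[, k], mass)
    tibble::tibble(
      condition = fit$info$condition, response = pp$responses[k],
      mean = mean(pp$norm[, k]), hdi_low = h[["lower"]],
      hdi_high = h[["upper"]], mean_bernoulli = mean(pp$raw[, k]),
      chance_level = 1 / 6
    )
  }))
  class(out) <- c("ft_selection", class(out))
  out
}

#' Posterior-predictive trait sweep
#'
#' Varies one trait over the integer grid 1-7 while fixing the other four
#' traits at 0, and computes the normalised selection probability of every
#' response at each grid value (population level, random effects 0) with
#' its 95% HDI.
#'
#' @param fit A variant-B (trait) choice-model `ft_fit`.
#' @param trait One of [trait_labels()].
#' @param mass HDI mass (default 0.95).
#' @return A tibble of class `ft_sweep`: `condition`, `trait`, `value`
#'   (1-7), `response`, `mean`, `hdi_low`, `hdi_high`.
#' @export
trait_sweep <- function(fit, trait, mass = 0.95) {
  if (fit$info$variant != "B") {
    stop("trait sweeps require a variant-B (trait-predictor) fit",
         call. = FALSE)
  }
  if (!trait %in% trait_labels()) {
    stop("unknown trait '", trait, "'", call. = FALSE)
  }
  rows <- lapply(1:7, function(v) {
    prof <- matrix(0, 1, 5, dimnames = list(NULL, trait_labels()))
    prof[1, trait] <- v
    sp <- selection_probabilities(fit, prof, mass = mass)
    dplyr::mutate(sp[, c("condition", "response", "mean", "hdi_low",
                         "hdi_high")],
                  trait = trait, value = v, .after = "condition")
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ft_sweep", class(out))
  out
}

#' Plot posterior-predictive selection probabilities
#'
#' @param object An `ft_selection` tibble.
#' @param ... Unused.
#' @return A ggplot object: per-response posterior mean and HDI with the
#'   1/6 chance level dashed.
#' @export
autoplot.ft_selection <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$response, y = .data$mean)) +
    ggplot2::geom_hline(yintercept = 1 / 6, linetype = "dashed") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$hdi_low,
                                          ymax = .data$hdi_high)) +
    ggplot2::labs(x = "response", y = "selection probability",
                  title = paste0("Presented: ", object$condition[1])) +
    ggplot2::theme_minimal()
}

#' Plot a trait sweep
#'
#' @param object An `ft_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot object: selection-probability curves over the 1-7
#'   trait grid, one panel per response, with HDI ribbons.
#' @export
autoplot.ft_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value, y = .data$mean)) +
    ggplot2::geom_hline(yintercept = 1 / 6, linetype = "dashed") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$hdi_low,
                                      ymax = .data$hdi_high), alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~response) +
    ggplot2::labs(x = paste0(object$trait[1], " (1-7)"),
                  y = "selection probability",
                  title = paste0("Presented: ", object$condition[1])) +
    ggplot2::theme_minimal()
}
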