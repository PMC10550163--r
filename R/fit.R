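# Vectorised log-posterior/gradient builders for the two model families,
# and the user-facing fit drivers. Random effects use the non-centred
# parameterisation r = sd * z with z ~ N(0, 1); scales and the ZIB
# precision are sampled on the log scale with the Jacobian included.

# scatter-sum rows of M by integer group idx into an n x ncol(M) matrix
agg_rows <- function(M, idx, n) {
  out <- matrix(0, n, ncol(M))
  o <- rowsum(M, idx)
  out[as.integer(rownames(o)), ] <- o
  out
}

one_hot <- function(labels, levels) {
  Y <- matrix(0, length(labels), length(levels),
              dimnames = list(NULL, levels))
  Y[cbind(seq_along(labels), match(labels, levels))] <- 1
  Y
}

#' Build a choice model ready for sampling
#'
#' Assembles the hierarchical independent-Bernoulli choice model for one
#' presented-expression condition. Variant `"A"` regresses the six response
#' indicators on the session's three observation weights; variant `"B"` on
#' the participant's five trait scores. Each response has its own intercept
#' and fixed effects; participant and stimulus random effects (one per
#' response) have gamma-prior scales.
#'
#' @param trials Trial tibble with columns `session_id`, `participant_id`,
#'   `stimulus_id`, `presented`, `chosen`.
#' @param predictors For variant `"A"`, a weights tibble with `session_id`,
#'   `w_upper`, `w_middle`, `w_low`; for variant `"B"`, a participants
#'   tibble with `participant_id` and the five trait columns.
#' @param condition Presented-expression label to fit.
#' @param variant `"A"` (observation weights) or `"B"` (traits).
#' @param priors A [prior_config()].
#' @return An `ft_model` for [run_mcmc()].
#' @export
choice_model <- function(trials, predictors, condition,
                         variant = c("A", "B"), priors = prior_config()) {
  variant <- match.arg(variant)
  responses <- expression_labels()
  tr <- dplyr::filter(trials, .data$presented == condition)
  if (nrow(tr) == 0) stop("no trials with presented == '", condition, "'",
                          call. = FALSE)
  if (variant == "A") {
    pred_names <- area_labels()
    tr <- dplyr::inner_join(
      tr, predictors[, c("session_id", "w_upper", "w_middle", "w_low")],
      by = "session_id")
    X <- as.matrix(tr[, c("w_upper", "w_middle", "w_low")])
  } else {
    pred_names <- trait_labels()
    tr <- dplyr::inner_join(
      tr, predictors[, c("participant_id", pred_names)],
      by = "participant_id")
    X <- as.matrix(tr[, pred_names])
  }
  colnames(X) <- pred_names
  subj_ids <- sort(unique(tr$participant_id))
  stim_ids <- sort(unique(tr$stimulus_id))
  si <- match(tr$participant_id, subj_ids)
  vi <- match(tr$stimulus_id, stim_ids)
  Y <- one_hot(tr$chosen, responses)
  N <- nrow(tr); S <- length(subj_ids); V <- length(stim_ids)
  K <- 6L; P <- ncol(X)

  ia <- 1:K
  ib <- K + seq_len(K * P)                       # beta, K x P column-major
  izs <- K + K * P + seq_len(S * K)              # z_subj, S x K
  izv <- K + K * P + S * K + seq_len(V * K)      # z_stim, V x K
  ils <- K + K * P + S * K + V * K + 1L
  ilv <- ils + 1L
  D <- ilv
  fs2 <- priors$fixed_sd^2
  sh <- priors$scale_shape; rt <- priors$scale_rate

  lp_grad <- function(theta) {
    alpha <- theta[ia]
    B <- matrix(theta[ib], K, P)
    Zs <- matrix(theta[izs], S, K)
    Zv <- matrix(theta[izv], V, K)
    ls <- theta[ils]; lv <- theta[ilv]
    ss <- exp(ls); sv <- exp(lv)
    MU <- matrix(alpha, N, K, byrow = TRUE) + X %*% t(B) +
      ss * Zs[si, , drop = FALSE] + sv * Zv[vi, , drop = FALSE]
    lp <- sum(Y * MU - log1pexp(MU)) +
      sum(dnorm(alpha, 0, priors$fixed_sd, log = TRUE)) +
      sum(dnorm(B, 0, priors$fixed_sd, log = TRUE)) +
      sum(dnorm(Zs, log = TRUE)) + sum(dnorm(Zv, log = TRUE)) +
      dgamma(ss, sh, rate = rt, log = TRUE) + ls +
      dgamma(sv, sh, rate = rt, log = TRUE) + lv
    R <- Y - plogis(MU)
    g <- numeric(D)
    g[ia] <- colSums(R) - alpha / fs2
    g[ib] <- crossprod(R, X) - B / fs2
    g[izs] <- ss * agg_rows(R, si, S) - Zs
    g[izv] <- sv * agg_rows(R, vi, V) - Zv
    g[ils] <- ss * sum(R * Zs[si, , drop = FALSE]) + sh - rt * ss
    g[ilv] <- sv * sum(R * Zv[vi, , drop = FALSE]) + sh - rt * sv
    list(lp = lp, grad = g)
  }

  beta_names <- as.vector(outer(responses, pred_names,
                                function(k, p) paste0("beta[", k, ",", p, "]")))
  nm <- c(paste0("alpha[", responses, "]"), beta_names,
          "sd_subj", "sd_stim",
          as.vector(outer(subj_ids, responses,
                          function(i, k) paste0("r_subj[", i, ",", k, "]"))),
          as.vector(outer(stim_ids, responses,
                          function(j, k) paste0("r_stim[", j, ",", k, "]"))))
  transform <- function(theta) {
    ss <- exp(theta[ils]); sv <- exp(theta[ilv])
    setNames(c(theta[ia], theta[ib], ss, sv,
               ss * theta[izs], sv * theta[izv]), nm)
  }
  init <- function() {
    th <- rnorm(D, 0, 0.1)
    th[c(ils, ilv)] <- log(0.9) + rnorm(2, 0, 0.1)
    th
  }
  beta_terms <- tibble::tibble(
    parameter = beta_names,
    response = rep(responses, times = P),
    predictor = rep(pred_names, each = K)
  )
  mcmc_model(lp_grad, D, param_names = nm, transform = transform, init = init,
             info = list(family = "choice", variant = variant,
                         condition = condition, responses = responses,
                         predictors = pred_names, beta_terms = beta_terms,
                         n_trials = N, n_subj = S, n_stim = V))
}

#' Build the zero-inflated beta behaviour model for sampling
#'
#' Assembles the hierarchical ZIB regression of the three region
#' observation weights on the five trait scores for one
#' presented-expression condition. The zero part is a logit model for
#' whether a region received any dwell; the beta part models the
#' conditional mean dwell with shared precision `phi`. Both parts carry
#' per-area intercepts, area-by-trait fixed effects and participant /
#' stimulus random effects.
#'
#' @param weights Weights tibble (`session_id`, `participant_id`,
#'   `stimulus_id`, `w_upper`, `w_middle`, `w_low`).
#' @param participants Participants tibble with the five trait columns.
#' @param trials Trial tibble used to select the sessions of `condition`.
#' @param condition Presented-expression label.
#' @param priors A [prior_config()].
#' @param shared_phi If `FALSE`, use one precision per area instead of a
#'   shared one.
#' @return An `ft_model` for [run_mcmc()].
#' @export
zib_model <- function(weights, participants, trials, condition,
                      priors = prior_config(), shared_phi = TRUE) {
  areas <- area_labels(); traits <- trait_labels()
  sess <- dplyr::filter(trials, .data$presented == condition)$session_id
  w <- dplyr::filter(weights, .data$session_id %in% sess)
  if (nrow(w) == 0) stop("no weight rows for condition '", condition, "'",
                         call. = FALSE)
  long <- tidyr::pivot_longer(
    w[, c("session_id", "participant_id", "stimulus_id",
          "w_upper", "w_middle", "w_low")],
    cols = c("w_upper", "w_middle", "w_low"),
    names_to = "area", values_to = "g", names_prefix = "w_"
  )
  long <- dplyr::inner_join(long, participants, by = "participant_id")
  g <- pmin(pmax(long$g, 0), 1 - 1e-8)
  g[long$g > 0 & g < 1e-8] <- 1e-8
  subj_ids <- sort(unique(long$participant_id))
  stim_ids <- sort(unique(long$stimulus_id))
  si <- match(long$participant_id, subj_ids)
  vi <- match(long$stimulus_id, stim_ids)
  ai <- match(long$area, areas)
  Tm <- as.matrix(long[, traits])
  N <- nrow(long); S <- length(subj_ids); V <- length(stim_ids)
  A <- 3L; L <- 5L
  nz <- g > 0
  z_ind <- as.numeric(nz)
  lg_g <- ifelse(nz, log(g), 0)
  lg_1mg <- ifelse(nz, log1p(-g), 0)
  n_phi <- if (shared_phi) 1L else A
  phi_idx <- if (shared_phi) rep(1L, length(ai)) else ai

  # unconstrained layout: two identical blocks (zero, beta) then log-phi
  blk_len <- A + A * L + S * A + V * A + 2L
  off_b <- blk_len
  i_lphi <- 2L * blk_len + seq_len(n_phi)
  D <- 2L * blk_len + n_phi
  fs2 <- priors$fixed_sd^2
  sh <- priors$scale_shape; rt <- priors$scale_rate

  unpack <- function(theta, off) {
    list(alpha = theta[off + 1:A],
         B = matrix(theta[off + A + seq_len(A * L)], A, L),
         Zs = matrix(theta[off + A + A * L + seq_len(S * A)], S, A),
         Zv = matrix(theta[off + A + A * L + S * A + seq_len(V * A)], V, A),
         ls = theta[off + blk_len - 1L], lv = theta[off + blk_len])
  }
  eta_of <- function(b) {
    b$alpha[ai] + rowSums(Tm * b$B[ai, , drop = FALSE]) +
      exp(b$ls) * b$Zs[cbind(si, ai)] + exp(b$lv) * b$Zv[cbind(vi, ai)]
  }
  # priors shared by both blocks (on the unconstrained block slice)
  block_prior <- function(b) {
    ss <- exp(b$ls); sv <- exp(b$lv)
    sum(dnorm(b$alpha, 0, priors$fixed_sd, log = TRUE)) +
      sum(dnorm(b$B, 0, priors$fixed_sd, log = TRUE)) +
      sum(dnorm(b$Zs, log = TRUE)) + sum(dnorm(b$Zv, log = TRUE)) +
      dgamma(ss, sh, rate = rt, log = TRUE) + b$ls +
      dgamma(sv, sh, rate = rt, log = TRUE) + b$lv
  }
  # gradient of one block given d(loglik)/d(eta) per row
  block_grad <- function(b, deta) {
    ss <- exp(b$ls); sv <- exp(b$lv)
    ga <- numeric(A)
    o <- rowsum(deta, ai)
    ga[as.integer(rownames(o))] <- o
    gB <- matrix(0, A, L)
    oB <- rowsum(deta * Tm, ai)
    gB[as.integer(rownames(oB)), ] <- oB
    gZs <- matrix(0, S, A); gZv <- matrix(0, V, A)
    # scatter-add deta into (si, ai) and (vi, ai) cells
    gZs_vec <- rowsum(deta, (ai - 1L) * S + si)
    gZs[as.integer(rownames(gZs_vec))] <- gZs_vec
    gZv_vec <- rowsum(deta, (ai - 1L) * V + vi)
    gZv[as.integer(rownames(gZv_vec))] <- gZv_vec
    c(ga - b$alpha / fs2,
      as.vector(gB) - as.vector(b$B) / fs2,
      as.vector(ss * gZs - b$Zs),
      as.vector(sv * gZv - b$Zv),
      ss * sum(deta * b$Zs[cbind(si, ai)]) + sh - rt * ss,
      sv * sum(deta * b$Zv[cbind(vi, ai)]) + sh - rt * sv)
  }

  lp_grad <- function(theta) {
    bz <- unpack(theta, 0L)
    bb <- unpack(theta, off_b)
    lphi <- theta[i_lphi]; phi <- exp(lphi)
    phin <- phi[phi_idx]
    etaZ <- eta_of(bz)
    etaB <- eta_of(bb)
    mu <- plogis(etaB)
    a <- phin * mu; b <- phin * (1 - mu)
    ll_zero <- sum(z_ind * etaZ - log1pexp(etaZ))
    ll_beta <- sum((lgamma(phin) - lgamma(a) - lgamma(b) +
                      (a - 1) * lg_g + (b - 1) * lg_1mg)[nz])
    lp <- ll_zero + ll_beta + block_prior(bz) + block_prior(bb) +
      sum(dgamma(phi, priors$phi_shape, rate = priors$phi_rate, log = TRUE) +
            lphi)
    detaZ <- z_ind - plogis(etaZ)
    dmu <- numeric(N)
    dg_a <- digamma(a); dg_b <- digamma(b)
    dmu[nz] <- (phin * (-dg_a + dg_b + lg_g - lg_1mg))[nz]
    detaB <- dmu * mu * (1 - mu)
    dphi_row <- numeric(N)
    dphi_row[nz] <- (digamma(phin) - mu * dg_a - (1 - mu) * dg_b +
                       mu * lg_g + (1 - mu) * lg_1mg)[nz]
    g_lphi <- numeric(n_phi)
    for (k in seq_len(n_phi)) {
      rows <- phi_idx == k
      g_lphi[k] <- phi[k] * sum(dphi_row[rows]) +
        priors$phi_shape - priors$phi_rate * phi[k]
    }
    list(lp = lp,
         grad = c(block_grad(bz, detaZ), block_grad(bb, detaB), g_lphi))
  }

  blk_names <- function(tag) {
    c(paste0("alpha_", tag, "[", areas, "]"),
      as.vector(outer(areas, traits,
                      function(k, l) paste0("beta_", tag, "[", k, ",", l, "]"))),
      paste0("sd_subj_", tag), paste0("sd_stim_", tag),
      as.vector(outer(subj_ids, areas,
                      function(i, k) paste0("r_subj_", tag, "[", i, ",", k, "]"))),
      as.vector(outer(stim_ids, areas,
                      function(j, k) paste0("r_stim_", tag, "[", j, ",", k, "]"))))
  }
  phi_names <- if (shared_phi) "phi" else paste0("phi[", areas, "]")
  nm <- c(blk_names("z"), blk_names("b"), phi_names)
  transform_block <- function(theta, off) {
    b <- unpack(theta, off)
    ss <- exp(b$ls); sv <- exp(b$lv)
    c(b$alpha, as.vector(b$B), ss, sv, ss * as.vector(b$Zs),
      sv * as.vector(b$Zv))
  }
  transform <- function(theta) {
    setNames(c(transform_block(theta, 0L), transform_block(theta, off_b),
               exp(theta[i_lphi])), nm)
  }
  init <- function() {
    th <- rnorm(D, 0, 0.1)
    th[c(A + A * L + S * A + V * A + c(1, 2),
         off_b + A + A * L + S * A + V * A + c(1, 2))] <-
      log(0.9) + rnorm(4, 0, 0.1)
    th[i_lphi] <- log(5) + rnorm(n_phi, 0, 0.1)
    th
  }
  beta_terms <- dplyr::bind_rows(
    tibble::tibble(parameter = blk_names("z")[A + seq_len(A * L)],
                   part = "Bernoulli",
                   area = rep(areas, times = L),
                   predictor = rep(traits, each = A)),
    tibble::tibble(parameter = blk_names("b")[A + seq_len(A * L)],
                   part = "Beta",
                   area = rep(areas, times = L),
                   predictor = rep(traits, each = A))
  )
  mcmc_model(lp_grad, D, param_names = nm, transform = transform, init = init,
             info = list(family = "zib", variant = "C", condition = condition,
                         areas = areas, predictors = traits,
                         beta_terms = beta_terms, n_obs = N,
                         n_subj = S, n_stim = V))
}

# ---- fit drivers -----------------------------------------------------------

new_ft_fit <- function(draws) {
  structure(list(draws = draws, info = draws$info), class = "ft_fit")
}

#' Fit a choice model by MCMC
#'
#' Builds the [choice_model()] for one presented-expression condition and
#' samples it with [run_mcmc()].
#'
#' @inheritParams choice_model
#' @param schedule An [mcmc_schedule()].
#' @param seed Integer seed.
#' @param control Sampler control list, see [run_mcmc()].
#' @return An `ft_fit` object; see [tidy.ft_fit()], [glance.ft_fit()],
#'   [significance_table()].
#' @export
fit_choice_model <- function(trials, predictors, condition,
                             variant = c("A", "B"),
                             schedule = mcmc_schedule(),
                             priors = prior_config(), seed = 1,
                             control = list()) {
  m <- choice_model(trials, predictors, condition, variant, priors)
  new_ft_fit(run_mcmc(m, schedule, seed, control))
}

#' Fit the zero-inflated beta behaviour model by MCMC
#'
#' @inheritParams zib_model
#' @inheritParams fit_choice_model
#' @return An `ft_fit` object.
#' @export
fit_zib_model <- function(weights, participants, trials, condition,
                          schedule = mcmc_schedule(),
                          priors = prior_config(), seed = 1,
                          control = list(), shared_phi = TRUE) {
  m <- zib_model(weights, participants, trials, condition, priors, shared_phi)
  new_ft_fit(run_mcmc(m, schedule, seed, control))
}

#' Fit one model per presented-expression condition
#'
#' Loops the requested fit over the six conditions (or a subset), matching
#' the blocked structure of the analysis: one independent fit per presented
#' expression.
#'
#' @param fit_fun One of [fit_choice_model()] or [fit_zib_model()].
#' @param conditions Conditions to fit (default all six expressions).
#' @param ... Arguments passed on to `fit_fun` (everything but `condition`).
#' @return A named list of `ft_fit` objects.
#' @export
fit_conditions <- function(fit_fun, conditions = expression_labels(), ...) {
  setNames(lapply(conditions, function(cond) fit_fun(condition = cond, ...)),
           conditions)
}

pooled_draws <- function(fit, parameter) {
  as.vector(fit$draws$draws[, , parameter])
}

#' @export
print.ft_fit <- function(x, ...) {
  cat("<ft_fit> ", x$info$family, " model, variant ", x$info$variant,
      ", condition '", x$info$condition, "'\n", sep = "")
  print(x$draws)
  invisible(x)
}

#' Tidy a fitted model
#'
#' One row per monitored parameter with the posterior mean, sd, 95% HDI
#' bounds and split-Rhat, in the style of broom.
#'
#' @param x An `ft_fit`.
#' @param mass HDI mass (default 0.95).
#' @param fixed_only If `TRUE`, keep only intercepts, fixed effects, scales
#'   and `phi` (drop random-effect draws).
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `rhat`.
#' @export
tidy.ft_fit <- function(x, mass = 0.95, fixed_only = FALSE, ...) {
  pn <- dimnames(x$draws$draws)[[3]]
  if (fixed_only) pn <- pn[!grepl("^r_subj|^r_stim", pn)]
  rows <- lapply(pn, function(p) {
    s <- pooled_draws(x, p)
    h <- hdi(s, mass)
    tibble::tibble(term = p, estimate = mean(s), std.error = stats::sd(s),
                   conf.low = h[["lower"]], conf.high = h[["upper"]],
                   rhat = rhat(t(x$draws$draws[, , p])))
  })
  dplyr::bind_rows(rows)
}

#' Glance at a fitted model
#'
#' @param x An `ft_fit`.
#' @param ... Unused.
#' @return A one-row tibble: variant, condition, chains, retained draws,
#'   maximum split-Rhat over all monitored parameters, divergence count.
#' @export
glance.ft_fit <- function(x, ...) {
  rh <- rhat_all(x$draws)
  tibble::tibble(
    variant = x$info$variant, condition = x$info$condition,
    chains = dim(x$draws$draws)[1],
    draws = dim(x$draws$draws)[1] * dim(x$draws$draws)[2],
    max_rhat = max(rh$rhat), divergences = sum(x$draws$divergent)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Significance table of fixed effects
#'
#' Summarises every fixed-effect coefficient of a fit (or list of fits) in
#' the layout of the headline tables: presented expression, response (or
#' model part and area for the ZIB model), predictor, posterior mean and
#' 95% HDI. A coefficient is flagged significant when 0 lies strictly
#' outside its HDI (0 on the boundary counts as included). Fits whose
#' maximum split-Rhat exceeds 1.1 trigger a warning but are still reported.
#'
#' @param fits An `ft_fit` or a list of them.
#' @param mass HDI mass (default 0.95).
#' @return A tibble with columns `expression`, `response` (choice models)
#'   or `part` + `area` (ZIB), `predictor`, `mean`, `hdi_low`, `hdi_high`,
#'   `significant`, sorted by expression then response/area.
#' @export
significance_table <- function(fits, mass = 0.95) {
  if (inherits(fits, "ft_fit")) fits <- list(fits)
  dplyr::bind_rows(lapply(fits, significance_table_one, mass = mass))
}

significance_table_one <- function(fit, mass) {
  stopifnot(inherits(fit, "ft_fit"))
  rh <- rhat_all(fit$draws)
  if (max(rh$rhat) > 1.1) {
    warning("maximum split-Rhat ", round(max(rh$rhat), 3),
            " exceeds 1.1 for condition '", fit$info$condition,
            "'; estimates may not have converged", call. = FALSE)
  }
  bt <- fit$info$beta_terms
  sums <- lapply(bt$parameter, function(p) {
    s <- pooled_draws(fit, p)
    h <- hdi(s, mass)
    tibble::tibble(mean = mean(s), hdi_low = h[["lower"]],
                   hdi_high = h[["upper"]],
                   significant = h[["lower"]] > 0 | h[["upper"]] < 0)
  })
  out <- dplyr::bind_cols(
    tibble::tibble(expression = fit$info$condition),
    bt[, setdiff(names(bt), "parameter")],
    dplyr::bind_rows(sums)
  )
  key2 <- if ("response" %in% names(out)) "response" else "area"
  dplyr::arrange(out, .data$expression, .data[[key2]], .data$predictor)
}

#' Plot fixed-effect posteriors of a fit
#'
#' Interval plot (posterior mean and 95% HDI) of every fixed-effect
#' coefficient, coloured by whether its HDI excludes 0.
#'
#' @param object An `ft_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ft_fit <- function(object, ...) {
  tab <- significance_table(object)
  key2 <- if ("response" %in% names(tab)) "response" else "area"
  tab$term <- paste(tab[[key2]], tab$predictor, sep = " : ")
  if ("part" %in% names(tab)) tab$term <- paste(tab$part, tab$term, sep = " / ")
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$mean, y = .data$term,
                                    colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$hdi_low,
                                         xmax = .data$hdi_high),
                            height = 0.2) +
    ggplot2::labs(x = "posterior mean and 95% HDI", y = NULL,
                  title = paste0("Fixed effects, condition '",
                                 object$info$condition, "'")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
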