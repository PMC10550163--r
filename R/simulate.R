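# Synthetic-data generators: participants, 68-point landmark stimuli,
# ZIB observation weights, choices, cursor trajectories, and the full
# study wrapper with known ground-truth coefficients.

#' Simulate participant trait profiles
#'
#' Big-Five trait scores are drawn independently per trait from a normal
#' distribution truncated to the 1-7 TIPI scale (default mean 4, sd 1.2).
#' `trait_sd = 0` gives a point mass at `trait_mean`.
#'
#' @param n Number of participants.
#' @param seed Integer seed.
#' @param trait_mean,trait_sd Mean and sd of the (pre-truncation) normal.
#' @return A tibble: `participant_id` plus one column per trait, every
#'   score in `[1, 7]`.
#' @export
#' @examples
#' sim_participants(3, seed = 1)
sim_participants <- function(n, seed = 1, trait_mean = 4, trait_sd = 1.2) {
  stopifnot_scalar_count(n)
  if (trait_sd < 0) stop("`trait_sd` must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))
  draw_trunc <- function(m) {
    if (trait_sd == 0) return(rep(m, n))
    x <- rnorm(n, m, trait_sd)
    while (any(bad <- x < 1 | x > 7)) {
      x[bad] <- rnorm(sum(bad), m, trait_sd)
    }
    x
  }
  out <- tibble::tibble(participant_id = sprintf("p%03d", seq_len(n)))
  for (tr in trait_labels()) out[[tr]] <- draw_trunc(trait_mean)
  out
}

# 68-point neutral face template, centred at 0, ~200 x 250 px.
# Standard layout: 17 jaw, 10 brow, 9 nose, 12 eye, 20 mouth points.
face_template <- function() {
  ellipse <- function(cx, cy, rx, ry, k, from = 0, to = 2 * pi) {
    th <- seq(from, to, length.out = k + 1)[seq_len(k)]
    cbind(cx + rx * cos(th), cy + ry * sin(th))
  }
  jaw_t <- seq(0, pi, length.out = 17)
  jaw <- cbind(-100 * cos(jaw_t), -10 + 135 * sin(jaw_t))
  brow <- function(sgn) cbind(sgn * seq(80, 30, length.out = 5),
                              -70 - c(0, 4, 6, 4, 0))
  nose <- rbind(cbind(0, seq(-55, 10, length.out = 4)),
                cbind(seq(-20, 20, length.out = 5), 25))
  eye <- function(sgn) ellipse(sgn * 55, -45, 18, 8, 6)
  mouth <- rbind(ellipse(0, 75, 45, 18, 12), ellipse(0, 75, 35, 8, 8))
  pts <- rbind(jaw, brow(-1), brow(1), nose, eye(-1), eye(1), mouth)
  pts[, 2] <- pts[, 2] * 1.25   # face box ~200 x 250 px
  colnames(pts) <- c("x", "y")
  pts
}

# per-expression displacement field (68 x 2) applied with a sinusoidal
# time envelope; mouth-opening movements for happiness/surprise/fear
expression_displacement <- function(expression) {
  d <- matrix(0, 68, 2)
  brows <- 18:27; nose <- 28:36; eyes <- 37:48
  mouth_out <- 49:60; mouth_in <- 61:68
  mouth <- c(mouth_out, mouth_in)
  mouth_cy <- 75 * 1.25   # mouth-centre y in the template
  open_mouth <- function(amount) {
    lower <- mouth[face_template()[mouth, 2] > mouth_cy]
    d[lower, 2] <<- d[lower, 2] + amount
  }
  switch(expression,
    happiness = {
      open_mouth(14)
      corners <- c(49, 55)          # outer mouth corners
      d[corners, 2] <- -8
      d[corners, 1] <- c(-6, 6)
    },
    surprise = {
      open_mouth(22)
      d[brows, 2] <- -10
      d[eyes, 2] <- c(rep(-3, 6), rep(-3, 6))
    },
    fear = {
      open_mouth(16)
      d[brows, 2] <- -7
      d[brows[c(4, 5, 6, 7)], 2] <- -11   # inner brows raised
    },
    sadness = {
      corners <- c(49, 55)
      d[corners, 2] <- 8
      d[brows[c(4, 5, 6, 7)], 2] <- -6
    },
    anger = {
      d[brows, 2] <- 6
      d[brows[c(4, 5, 6, 7)], 2] <- 10    # inner brows lowered
      d[mouth, 2] <- (face_template()[mouth, 2] - mouth_cy) * -0.2
    },
    disgust = {
      d[nose, 2] <- -5
      d[mouth_out[1:6], 2] <- -6          # upper lip raised
      d[brows, 2] <- 3
    },
    stop("unknown expression '", expression, "'", call. = FALSE)
  )
  d
}

#' Simulate landmark-animation stimuli
#'
#' Generates point-light face stimuli: a fixed 68-point template (jaw,
#' brows, nose, eyes, mouth) occupying roughly 200 x 250 px at the centre
#' of a 600 x 800 canvas, animated by an expression-specific displacement
#' field with a sinusoidal time envelope. Actor identity is a small random
#' rigid shift and scale of the template. Default timing: 2500 ms at 50 ms
#' per frame.
#'
#' @param n_actors Number of actors.
#' @param expressions Expression labels (default all six).
#' @param seed Integer seed.
#' @param canvas Canvas `c(width, height)` in pixels.
#' @param frame_interval_ms Frame interval (default 50).
#' @param duration_ms Total duration (default 2500).
#' @return A tibble with one row per video (`n_actors * length(expressions)`
#'   rows): `stimulus_id`, `actor_id`, `expression`, `canvas_w`,
#'   `canvas_h`, `frame_interval_ms` and a `frames` list-column of
#'   `(n_frames, 68, 2)` arrays.
#' @export
#' @examples
#' stim <- sim_stimuli(2, c("happiness", "fear"), seed = 1)
#' dim(stim$frames[[1]])
sim_stimuli <- function(n_actors, expressions = expression_labels(),
                        seed = 1, canvas = c(600, 800),
                        frame_interval_ms = 50, duration_ms = 2500) {
  stopifnot_scalar_count(n_actors, "n_actors")
  if (length(expressions) == 0) {
    stop("`expressions` must be non-empty", call. = FALSE)
  }
  set.seed(as.integer(seed))
  n_frames <- round(duration_ms / frame_interval_ms)
  centre <- canvas / 2
  template <- face_template()
  envelope <- sin(pi * (seq_len(n_frames) - 1) / (n_frames - 1))
  rows <- list()
  for (a in seq_len(n_actors)) {
    shift <- rnorm(2, 0, 5)
    scale <- runif(1, 0.95, 1.05)
    base <- sweep(template * scale, 2, centre + shift, `+`)
    for (ex in expressions) {
      disp <- expression_displacement(ex) * scale
      frames <- array(0, dim = c(n_frames, 68, 2))
      for (f in seq_len(n_frames)) {
        frames[f, , ] <- base + envelope[f] * disp
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        stimulus_id = sprintf("a%02d_%s", a, ex),
        actor_id = a, expression = ex,
        canvas_w = canvas[1], canvas_h = canvas[2],
        frame_interval_ms = frame_interval_ms,
        frames = list(frames)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Draw one session's observation weights from the ZIB model
#'
#' For each of the three face areas, the weight is 0 with probability
#' `1 - q` and otherwise a Beta(`a`, `b`) draw, with (`q`, `a`, `b`)
#' computed from the participant's traits via [zib_params()]. Exact draws
#' of 0 or 1 from the Beta are resampled and nonzero weights clamped to
#' `[1e-6, 1 - 1e-6]` (open-interval Beta support).
#'
#' @param coeffs A [zib_coefficient_set()] (ground truth).
#' @param traits Numeric vector of the participant's five trait scores.
#' @param subj_id,stim_id Optional random-effect ids.
#' @return Named numeric `c(upper, middle, low)`.
#' @export
sample_observation_weights <- function(coeffs, traits, subj_id = NULL,
                                       stim_id = NULL) {
  eps <- 1e-6
  vapply(area_labels(), function(k) {
    pr <- zib_params(coeffs, k, traits, subj_id, stim_id)
    if (rbinom(1, 1, pr$q) == 0) return(0)
    g <- rbeta(1, pr$a, pr$b)
    while (g <= 0 || g >= 1) g <- rbeta(1, pr$a, pr$b)
    min(max(g, eps), 1 - eps)
  }, numeric(1))
}

#' Draw choices from a choice model
#'
#' Computes the six per-response linear predictors and samples `n` chosen
#' labels from the multinomial-logit (softmax) distribution over them,
#' reconciling the independent-Bernoulli likelihood with the forced single
#' choice: equal predictors give 1/6 each, and a saturated predictor for
#' one response makes it all but certain.
#'
#' @param coeffs A [coefficient_set()] (ground truth).
#' @param predictors Observation-weight triple (variant `"A"`) or trait
#'   5-vector (variant `"B"`).
#' @param variant `"A"` or `"B"`; checked against the coefficient
#'   dimensions.
#' @param n Number of draws.
#' @param subj_id,stim_id Optional random-effect ids.
#' @return Character vector of chosen expression labels.
#' @export
sample_choices <- function(coeffs, predictors, variant = c("A", "B"),
                           n = 1, subj_id = NULL, stim_id = NULL) {
  variant <- match.arg(variant)
  need <- if (variant == "A") 3L else 5L
  if (length(predictors) != need || ncol(coeffs$beta) != need) {
    stop("variant ", variant, " requires ", need, " predictors and matching ",
         "coefficient columns", call. = FALSE)
  }
  responses <- names(coeffs$alpha)
  mu <- vapply(responses, function(k) {
    linear_predictor(coeffs, k, predictors, subj_id, stim_id)
  }, numeric(1))
  p <- exp(mu - max(mu))
  p <- p / sum(p)
  responses[sample.int(length(responses), n, replace = TRUE, prob = p)]
}

#' Cursor trajectory generation policy
#'
#' @param duration_ms Trajectory duration (default 2500, one stimulus).
#' @param sample_interval_ms Time between cursor samples (default 20).
#' @param jitter_sd Pixel sd of the jitter around each dwell point
#'   (default 4).
#' @return A list of class `ft_policy`.
#' @export
trajectory_policy <- function(duration_ms = 2500, sample_interval_ms = 20,
                              jitter_sd = 4) {
  if (!is.numeric(duration_ms) || duration_ms <= 0) {
    stop("`duration_ms` must be positive", call. = FALSE)
  }
  stopifnot(sample_interval_ms > 0, jitter_sd >= 0)
  structure(list(duration_ms = duration_ms,
                 sample_interval_ms = sample_interval_ms,
                 jitter_sd = jitter_sd),
            class = "ft_policy")
}

#' Simulate a cursor trajectory realising given observation weights
#'
#' The inverse of preprocessing: produces a cursor trace (in screen
#' coordinates) whose preprocessed weight triple approximates `weights`.
#' Samples are allocated to the three bands in proportion to the weights
#' and placed, with small jitter, at each band's centre; any remaining
#' fraction dwells at a far off-face corner of the canvas. With the
#' default policy the preprocessed triple matches within L1 0.05.
#'
#' @param weights Target `c(upper, middle, low)` triple, sum at most 1.
#' @param stimulus One row of a [sim_stimuli()] tibble (or frames array).
#' @param policy A [trajectory_policy()].
#' @param config A [screen_config()].
#' @return A tibble `t_ms`, `x_px`, `y_px` with strictly increasing
#'   timestamps.
#' @export
sim_trajectory <- function(weights, stimulus, policy = trajectory_policy(),
                           config = screen_config()) {
  stopifnot(inherits(policy, "ft_policy"), length(weights) == 3)
  if (any(weights < 0) || sum(weights) > 1 + 1e-9) {
    stop("`weights` must be non-negative with sum <= 1", call. = FALSE)
  }
  part <- partition_face(stimulus)
  b <- part$bbox; cuts <- part$cuts
  n <- max(1L, round(policy$duration_ms / policy$sample_interval_ms))
  counts <- round(weights * n)
  while (sum(counts) > n) counts[which.max(counts)] <- counts[which.max(counts)] - 1L
  n_off <- n - sum(counts)
  cx <- (b[["left"]] + b[["right"]]) / 2
  centres <- rbind(
    c(cx, (b[["top"]] + cuts[1]) / 2),
    c(cx, (cuts[1] + cuts[2]) / 2),
    c(cx, (cuts[2] + b[["bottom"]]) / 2),
    c(45, 45)                      # off-face dwell, far from the bbox
  )
  pts <- do.call(rbind, lapply(seq_len(4), function(i) {
    k <- if (i <= 3) counts[i] else n_off
    if (k == 0) return(NULL)
    cbind(centres[i, 1] + rnorm(k, 0, policy$jitter_sd),
          centres[i, 2] + rnorm(k, 0, policy$jitter_sd))
  }))
  tibble::tibble(
    t_ms = policy$sample_interval_ms * seq_len(n),
    x_px = pts[, 1] + config$origin[1],
    y_px = pts[, 2] + config$origin[2]
  )
}

#' Ground-truth coefficients for the generative study
#'
#' Bundles one choice [coefficient_set()] per condition and variant with a
#' [zib_coefficient_set()] for the behaviour model.
#'
#' @param choice_A,choice_B Named lists (by condition) of
#'   [coefficient_set()] objects for variants A and B.
#' @param zib A [zib_coefficient_set()].
#' @param seed Seed recorded with the truth.
#' @return A list of class `ft_truth`.
#' @export
ground_truth <- function(choice_A, choice_B, zib, seed = 1) {
  structure(list(choice_A = choice_A, choice_B = choice_B, zib = zib,
                 seed = as.integer(seed)),
            class = "ft_truth")
}

#' Default ground truth of the synthetic study
#'
#' Moderate, fixed coefficients: in each presented-expression condition the
#' matching response intercept is `alpha_match` and the others
#' `alpha_other` (so the presented expression is usually chosen); variant A
#' carries a `behaviour_effect` of the middle-face weight on the matching
#' response and `-0.8 * behaviour_effect` of the upper weight on the next
#' response; variant B carries a `trait_effect` of agreeableness on
#' choosing happiness (in the happiness condition) and of extraversion on
#' choosing surprise (surprise condition). The ZIB truth gives mean region
#' dwell near (0.38, 0.33, 0.25) with most regions observed
#' (`q` around 0.73-0.80) and precision `phi = 10`. Random-effect scales
#' default to 0.3.
#'
#' @param alpha_match,alpha_other Matching / non-matching intercepts.
#' @param behaviour_effect Variant-A fixed-effect size (default 1.0).
#' @param trait_effect Variant-B fixed-effect size (default 0.8).
#' @param sd_ranef True random-effect scale (default 0.3).
#' @param phi ZIB precision (default 10).
#' @param zero If `TRUE`, all fixed effects (intercepts and slopes) are 0
#'   (calibration truth); scales and `phi` keep their values.
#' @return An `ft_truth` object.
#' @export
default_ground_truth <- function(alpha_match = 1.2, alpha_other = -1.2,
                                 behaviour_effect = 1.0, trait_effect = 0.8,
                                 sd_ranef = 0.3, phi = 10, zero = FALSE) {
  responses <- expression_labels()
  if (zero) {
    alpha_match <- 0; alpha_other <- 0
    behaviour_effect <- 0; trait_effect <- 0
  }
  mk_choice <- function(cond, pred_names, beta_fill) {
    alpha <- setNames(rep(alpha_other, 6), responses)
    alpha[cond] <- alpha_match
    beta <- matrix(0, 6, length(pred_names),
                   dimnames = list(responses, pred_names))
    beta <- beta_fill(beta, cond)
    coefficient_set(alpha, beta, sd_subj = sd_ranef, sd_stim = sd_ranef)
  }
  fill_A <- function(beta, cond) {
    nxt <- responses[(match(cond, responses)) %% 6 + 1]
    beta[cond, "middle"] <- behaviour_effect
    beta[nxt, "upper"] <- -0.8 * behaviour_effect
    beta
  }
  fill_B <- function(beta, cond) {
    if (cond == "happiness") beta["happiness", "agreeableness"] <- trait_effect
    if (cond == "surprise") beta["surprise", "extraversion"] <- trait_effect
    beta
  }
  choice_A <- setNames(lapply(responses, mk_choice, area_labels(), fill_A),
                       responses)
  choice_B <- setNames(lapply(responses, mk_choice, trait_labels(), fill_B),
                       responses)
  areas <- area_labels()
  zib <- zib_coefficient_set(
    zero = list(alpha = setNames(c(1.4, 1.4, 1.0), areas),
                beta = matrix(0, 3, 5,
                              dimnames = list(areas, trait_labels())),
                sd_subj = sd_ranef, sd_stim = sd_ranef),
    beta_part = list(alpha = setNames(qlogis(c(0.38, 0.33, 0.25)), areas),
                     beta = matrix(0, 3, 5,
                                   dimnames = list(areas, trait_labels())),
                     sd_subj = sd_ranef, sd_stim = sd_ranef),
    phi = phi
  )
  ground_truth(choice_A, choice_B, zib)
}

draw_ranef <- function(ids, cols, sd) {
  matrix(rnorm(length(ids) * length(cols), 0, sd), length(ids), length(cols),
         dimnames = list(ids, cols))
}

#' Simulate a full study with known ground truth
#'
#' Generates everything the pipeline consumes: participants, the
#' `n_actors x 6` stimulus set, per-session observation weights drawn from
#' the ZIB truth, choices drawn from the choice truths (variant B for the
#' unrestricted Part 1, variant A — driven by the session's weights — for
#' the aperture-viewing Part 2), and optionally cursor trajectories whose
#' preprocessing reproduces the weights. Participant- and stimulus-level
#' random effects are drawn once per study from the truth's scales.
#'
#' @param n_participants Number of participants.
#' @param truth An `ft_truth` (default [default_ground_truth()]).
#' @param n_actors Number of actors (default 8: 48 stimuli).
#' @param seed Integer seed; the whole study is reproducible.
#' @param parts Which experiment parts to simulate (default `c(1, 2)`).
#' @param trajectories If `TRUE`, also generate Part-2 cursor trajectories
#'   (slower; weights are returned either way).
#' @param config A [screen_config()] used for trajectories.
#' @return A list with tibbles `participants`, `stimuli`, `trials`,
#'   `weights` (Part 2), optionally `trajectories`, and `truth` augmented
#'   with the drawn random effects.
#' @export
sim_study <- function(n_participants, truth = default_ground_truth(),
                      n_actors = 8, seed = 1, parts = c(1, 2),
                      trajectories = FALSE, config = screen_config()) {
  stopifnot(inherits(truth, "ft_truth"))
  set.seed(as.integer(seed))
  participants <- sim_participants(n_participants, seed = seed)
  stimuli <- sim_stimuli(n_actors, seed = seed)
  set.seed(as.integer(seed) + 1L)
  subj <- participants$participant_id
  stim <- stimuli$stimulus_id
  responses <- expression_labels()
  areas <- area_labels()
  # one random-effect draw per study, shared across conditions
  re <- function(cols, sd_s, sd_v) {
    list(subj = draw_ranef(subj, cols, sd_s), stim = draw_ranef(stim, cols, sd_v))
  }
  reA <- re(responses, truth$choice_A[[1]]$sd_subj, truth$choice_A[[1]]$sd_stim)
  reB <- re(responses, truth$choice_B[[1]]$sd_subj, truth$choice_B[[1]]$sd_stim)
  reZq <- re(areas, truth$zib$zero$sd_subj, truth$zib$zero$sd_stim)
  reZm <- re(areas, truth$zib$beta_part$sd_subj, truth$zib$beta_part$sd_stim)
  truth$zib$zero$r_subj <- reZq$subj; truth$zib$zero$r_stim <- reZq$stim
  truth$zib$beta_part$r_subj <- reZm$subj; truth$zib$beta_part$r_stim <- reZm$stim
  for (cond in responses) {
    truth$choice_A[[cond]]$r_subj <- reA$subj
    truth$choice_A[[cond]]$r_stim <- reA$stim
    truth$choice_B[[cond]]$r_subj <- reB$subj
    truth$choice_B[[cond]]$r_stim <- reB$stim
  }
  trials <- list(); weights <- list(); trajs <- list()
  for (part in parts) {
    for (i in subj) {
      tri <- as.numeric(participants[participants$participant_id == i,
                                     trait_labels()])
      for (j in stim) {
        cond <- stimuli$expression[stimuli$stimulus_id == j]
        sid <- sprintf("s_part%d_%s_%s", part, i, j)
        if (part == 2) {
          w <- sample_observation_weights(truth$zib, tri, i, j)
          weights[[sid]] <- tibble::tibble(
            session_id = sid, participant_id = i, stimulus_id = j,
            w_upper = w[[1]], w_middle = w[[2]], w_low = w[[3]]
          )
          chosen <- sample_choices(truth$choice_A[[cond]], w, "A",
                                   subj_id = i, stim_id = j)
          if (trajectories) {
            # trajectories can only realise triples with sum <= 1
            wn <- if (sum(w) > 1) w / sum(w) else w
            tr <- sim_trajectory(wn, stimuli[stimuli$stimulus_id == j, ],
                                 config = config)
            trajs[[sid]] <- dplyr::mutate(tr, session_id = sid,
                                          participant_id = i, stimulus_id = j,
                                          .before = 1)
          }
        } else {
          chosen <- sample_choices(truth$choice_B[[cond]], tri, "B",
                                   subj_id = i, stim_id = j)
        }
        trials[[sid]] <- tibble::tibble(
          session_id = sid, participant_id = i, stimulus_id = j,
          presented = cond, chosen = chosen,
          confidence = sample.int(7, 1), part = part
        )
      }
    }
  }
  out <- list(participants = participants, stimuli = stimuli,
              trials = dplyr::bind_rows(trials),
              weights = dplyr::bind_rows(weights),
              truth = truth)
  if (trajectories) out$trajectories <- dplyr::bind_rows(trajs)
  out
}
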