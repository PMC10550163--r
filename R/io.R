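# Readers and writers for the pipeline's file interchange formats:
# CSV tables, one JSON per stimulus, a ground-truth JSON and draws CSV.

#' Write a simulated study to disk
#'
#' Writes `participants.csv`, `trials.csv`, `weights.csv`, optionally
#' `trajectories.csv`, a `stimuli/` directory with one JSON per video, and
#' `truth.json` holding the ground-truth coefficients and seed.
#'
#' @param study A [sim_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(study$participants, file.path(dir, "participants.csv"))
  readr::write_csv(study$trials, file.path(dir, "trials.csv"))
  readr::write_csv(study$weights, file.path(dir, "weights.csv"))
  if (!is.null(study$trajectories)) {
    readr::write_csv(study$trajectories, file.path(dir, "trajectories.csv"))
  }
  sdir <- file.path(dir, "stimuli")
  dir.create(sdir, showWarnings = FALSE)
  for (i in seq_len(nrow(study$stimuli))) {
    s <- study$stimuli[i, ]
    fr <- s$frames[[1]]
    frames <- lapply(seq_len(dim(fr)[1]), function(f) unname(fr[f, , ]))
    jsonlite::write_json(
      list(stimulus_id = s$stimulus_id, actor_id = s$actor_id,
           expression = s$expression, canvas = c(s$canvas_w, s$canvas_h),
           frame_interval_ms = s$frame_interval_ms, frames = frames),
      file.path(sdir, paste0(s$stimulus_id, ".json")),
      auto_unbox = TRUE, digits = NA
    )
  }
  write_truth(study$truth, file.path(dir, "truth.json"))
  invisible(dir)
}

#' Read a stimuli directory written by [write_study()]
#'
#' @param dir The `stimuli/` directory.
#' @return A stimulus tibble in the [sim_stimuli()] layout.
#' @export
read_stimuli <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  rows <- lapply(files, function(f) {
    s <- jsonlite::read_json(f, simplifyVector = TRUE)
    fr <- array(0, dim = c(length(s$frames), 68, 2))
    for (i in seq_along(s$frames)) fr[i, , ] <- s$frames[[i]]
    tibble::tibble(stimulus_id = s$stimulus_id, actor_id = s$actor_id,
                   expression = s$expression, canvas_w = s$canvas[1],
                   canvas_h = s$canvas[2],
                   frame_interval_ms = s$frame_interval_ms,
                   frames = list(fr))
  })
  dplyr::bind_rows(rows)
}

coef_to_list <- function(cs) {
  list(alpha = as.list(cs$alpha), beta = cs$beta,
       beta_rows = rownames(cs$beta), beta_cols = colnames(cs$beta),
       r_subj = cs$r_subj, r_subj_ids = rownames(cs$r_subj),
       r_stim = cs$r_stim, r_stim_ids = rownames(cs$r_stim),
       sd_subj = cs$sd_subj, sd_stim = cs$sd_stim)
}

coef_from_list <- function(l) {
  beta <- as.matrix(l$beta)
  dimnames(beta) <- list(l$beta_rows, l$beta_cols)
  mk_r <- function(r, ids) {
    if (is.null(r)) return(NULL)
    r <- as.matrix(r); dimnames(r) <- list(ids, l$beta_rows); r
  }
  coefficient_set(unlist(l$alpha), beta,
                  r_subj = mk_r(l$r_subj, l$r_subj_ids),
                  r_stim = mk_r(l$r_stim, l$r_stim_ids),
                  sd_subj = l$sd_subj, sd_stim = l$sd_stim)
}

#' Write / read ground truth as JSON
#'
#' @param truth An `ft_truth`.
#' @param path File path.
#' @return `write_truth` returns `path` invisibly; `read_truth` an
#'   `ft_truth`.
#' @export
write_truth <- function(truth, path) {
  blk <- function(b) {
    list(alpha = as.list(b$alpha), beta = b$beta,
         areas = names(b$alpha), traits = colnames(b$beta),
         r_subj = b$r_subj, r_subj_ids = rownames(b$r_subj),
         r_stim = b$r_stim, r_stim_ids = rownames(b$r_stim),
         sd_subj = b$sd_subj, sd_stim = b$sd_stim)
  }
  jsonlite::write_json(
    list(choice_A = lapply(truth$choice_A, coef_to_list),
         choice_B = lapply(truth$choice_B, coef_to_list),
         zib = list(zero = blk(truth$zib$zero),
                    beta_part = blk(truth$zib$beta_part),
                    phi = truth$zib$phi),
         seed = truth$seed),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  blk <- function(b) {
    beta <- as.matrix(b$beta); dimnames(beta) <- list(b$areas, b$traits)
    mk_r <- function(r, ids) {
      if (is.null(r)) return(NULL)
      r <- as.matrix(r); dimnames(r) <- list(ids, b$areas); r
    }
    list(alpha = unlist(b$alpha), beta = beta,
         r_subj = mk_r(b$r_subj, b$r_subj_ids),
         r_stim = mk_r(b$r_stim, b$r_stim_ids),
         sd_subj = b$sd_subj, sd_stim = b$sd_stim)
  }
  ground_truth(
    choice_A = lapply(l$choice_A, coef_from_list),
    choice_B = lapply(l$choice_B, coef_from_list),
    zib = zib_coefficient_set(zero = blk(l$zib$zero),
                              beta_part = blk(l$zib$beta_part),
                              phi = l$zib$phi),
    seed = l$seed
  )
}

#' Write / read posterior draws as long CSV
#'
#' Interchange layout: one row per (chain, draw, parameter).
#'
#' @param draws An `ft_draws`.
#' @param path File path.
#' @return `write_draws` returns `path` invisibly; `read_draws` an
#'   `ft_draws` (metadata limited to what the CSV carries).
#' @export
write_draws <- function(draws, path) {
  d <- draws$draws
  long <- tidyr::expand_grid(chain = seq_len(dim(d)[1]),
                             draw = seq_len(dim(d)[2]),
                             parameter = dimnames(d)[[3]])
  long$value <- as.vector(aperm(d, c(3, 2, 1)))
  readr::write_csv(long, path)
  invisible(path)
}

#' @rdname write_draws
#' @export
read_draws <- function(path) {
  long <- readr::read_csv(path, show_col_types = FALSE)
  chains <- max(long$chain); nd <- max(long$draw)
  pn <- unique(long$parameter)
  arr <- array(NA_real_, dim = c(chains, nd, length(pn)),
               dimnames = list(NULL, NULL, pn))
  arr[cbind(long$chain, long$draw, match(long$parameter, pn))] <- long$value
  structure(list(draws = arr,
                 schedule = mcmc_schedule(chains, 1, nd + 1),
                 seed = NA_integer_, divergent = rep(NA_integer_, chains),
                 treedepth = rep(NA_integer_, chains),
                 step_size = rep(NA_real_, chains), info = list()),
            class = "ft_draws")
}
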