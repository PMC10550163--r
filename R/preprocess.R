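# Cursor-trace preprocessing: screen-to-video coordinate conversion,
# Gaussian kernel density accumulation, the 1 : 0.8 : 0.6 face partition,
# and aggregation into per-session observation weights.

#' Screen / stimulus geometry
#'
#' Describes where the stimulus video sits on the screen. Coordinates are
#' 0-based, origin top-left, y increasing downward.
#'
#' @param screen Screen size `c(width, height)` in pixels.
#' @param origin Top-left corner of the video on screen, `c(x, y)`.
#' @param canvas Video size `c(width, height)`; default 600 x 800.
#' @return A list of class `ft_screen`.
#' @export
screen_config <- function(screen = c(1920, 1080), origin = c(660, 140),
                          canvas = c(600, 800)) {
  if (origin[1] < 0 || origin[2] < 0 ||
      origin[1] + canvas[1] > screen[1] || origin[2] + canvas[2] > screen[2]) {
    stop("stimulus rectangle must lie fully inside the screen", call. = FALSE)
  }
  structure(list(screen = screen, origin = origin, canvas = canvas),
            class = "ft_screen")
}

#' Convert a cursor trajectory from screen to video coordinates
#'
#' Translates each sample by minus the stimulus origin, superimposing the
#' cursor track onto the video frame. Samples falling outside the video
#' canvas are kept but flagged.
#'
#' @param trajectory Tibble with columns `t_ms`, `x_px`, `y_px` (screen
#'   coordinates); extra columns are preserved.
#' @param config A [screen_config()].
#' @return The trajectory with `x_px`, `y_px` in video coordinates and a
#'   logical `in_canvas` column.
#' @export
to_video_coords <- function(trajectory, config = screen_config()) {
  stopifnot(inherits(config, "ft_screen"))
  out <- dplyr::mutate(
    trajectory,
    x_px = .data$x_px - config$origin[1],
    y_px = .data$y_px - config$origin[2]
  )
  dplyr::mutate(out, in_canvas = .data$x_px >= 0 & .data$x_px < config$canvas[1] &
                  .data$y_px >= 0 & .data$y_px < config$canvas[2])
}

# discrete isotropic Gaussian kernel, truncated at 4 sigma, unit mass
gaussian_kernel <- function(sigma_px) {
  r <- ceiling(4 * sigma_px)
  g <- stats::dnorm(-r:r, 0, sigma_px)
  k <- outer(g, g)
  k / sum(k)
}

#' Accumulate a session's cursor density map
#'
#' Each in-canvas cursor sample deposits an isotropic Gaussian kernel of
#' unit mass (sd `sigma_px`, truncated at 4 sigma) at its position; the
#' session map is the sum over samples, so total mass equals the number of
#' in-canvas samples up to truncation at the canvas edge. Out-of-canvas
#' samples contribute nothing.
#'
#' @param trajectory Trajectory in video coordinates (see
#'   [to_video_coords()]); only `x_px`, `y_px` are used.
#' @param sigma_px Kernel standard deviation in pixels (default 10).
#' @param canvas Video size `c(width, height)`.
#' @return A list of class `ft_density` with elements `map` (height x
#'   width matrix, row r / column c holding the mass at video pixel
#'   (x = c - 1, y = r - 1)), `canvas` and `n_samples` (in-canvas count).
#' @export
accumulate_density <- function(trajectory, sigma_px = 10,
                               canvas = c(600, 800)) {
  if (!is.numeric(sigma_px) || sigma_px <= 0) {
    stop("`sigma_px` must be positive", call. = FALSE)
  }
  w <- canvas[1]; h <- canvas[2]
  map <- matrix(0, nrow = h, ncol = w)
  k <- gaussian_kernel(sigma_px)
  r <- (nrow(k) - 1L) / 2L
  xs <- round(trajectory$x_px); ys <- round(trajectory$y_px)
  keep <- xs >= 0 & xs < w & ys >= 0 & ys < h
  xs <- xs[keep]; ys <- ys[keep]
  for (i in seq_along(xs)) {
    rows <- (ys[i] - r):(ys[i] + r) + 1L
    cols <- (xs[i] - r):(xs[i] + r) + 1L
    rok <- rows >= 1L & rows <= h
    cok <- cols >= 1L & cols <= w
    map[rows[rok], cols[cok]] <- map[rows[rok], cols[cok]] +
      k[rok, cok, drop = FALSE]
  }
  structure(list(map = map, canvas = canvas, n_samples = length(xs)),
            class = "ft_density")
}

#' Partition a face into upper, middle and low bands
#'
#' The face bounding box is the axis-aligned box around all 68 landmarks
#' over *all* frames (so the partition is fixed within a session), split
#' top to bottom into three horizontal bands with heights in proportion
#' 1 : 0.8 : 0.6 — cuts at `top + h/2.4` and `top + 1.8 h/2.4`.
#'
#' @param video One stimulus: either a row of a [sim_stimuli()] tibble or
#'   its frames array `(n_frames, 68, 2)`.
#' @return A list of class `ft_partition` with `bbox` (named vector
#'   `left`, `top`, `right`, `bottom`) and `cuts` (the two y cut heights).
#' @export
partition_face <- function(video) {
  frames <- if (is.array(video) && length(dim(video)) == 3) video
    else if (is.list(video) && !is.null(video$frames)) {
      fr <- video$frames
      if (is.list(fr)) fr <- fr[[1]]
      fr
    } else stop("`video` must be a frames array or a stimulus row", call. = FALSE)
  if (dim(frames)[1] < 1) stop("video has no frames", call. = FALSE)
  if (dim(frames)[2] != 68) stop("each frame must have 68 points", call. = FALSE)
  xs <- frames[, , 1]; ys <- frames[, , 2]
  bbox <- c(left = min(xs), top = min(ys), right = max(xs), bottom = max(ys))
  hgt <- bbox[["bottom"]] - bbox[["top"]]
  if (hgt <= 0) stop("degenerate face bounding box (zero height)", call. = FALSE)
  cuts <- bbox[["top"]] + hgt * c(1, 1.8) / 2.4
  structure(list(bbox = bbox, cuts = cuts), class = "ft_partition")
}

#' Aggregate a density map into observation weights
#'
#' Each band weight is the fraction of the map's total mass falling inside
#' that band of the face bounding box; mass outside the box is discarded
#' (weights sum to at most 1). Pixel (x, y) belongs to the upper band when
#' `top <= y < cut1`, the middle when `cut1 <= y < cut2`, the low when
#' `cut2 <= y <= bottom`, with `left <= x <= right` throughout.
#'
#' @param map An [accumulate_density()] result.
#' @param partition A [partition_face()] result.
#' @return Named numeric `c(upper, middle, low)` with attributes
#'   `raw_mass` (band masses before normalisation), `total_mass` and
#'   `out_of_bbox` (the discarded fraction).
#' @export
aggregate_weights <- function(map, partition) {
  stopifnot(inherits(map, "ft_density"), inherits(partition, "ft_partition"))
  total <- sum(map$map)
  if (total <= 0) {
    warning("zero-mass density map (cursor never entered the canvas)",
            call. = FALSE)
    return(structure(c(upper = 0, middle = 0, low = 0),
                     raw_mass = c(upper = 0, middle = 0, low = 0),
                     total_mass = 0, out_of_bbox = 0))
  }
  b <- partition$bbox; cuts <- partition$cuts
  ycoord <- seq_len(nrow(map$map)) - 1
  xcoord <- seq_len(ncol(map$map)) - 1
  xin <- xcoord >= b[["left"]] & xcoord <= b[["right"]]
  band_mass <- function(ylo, yhi, closed_hi = FALSE) {
    yin <- if (closed_hi) ycoord >= ylo & ycoord <= yhi
      else ycoord >= ylo & ycoord < yhi
    sum(map$map[yin, xin, drop = FALSE])
  }
  raw <- c(upper = band_mass(b[["top"]], cuts[1]),
           middle = band_mass(cuts[1], cuts[2]),
           low = band_mass(cuts[2], b[["bottom"]], closed_hi = TRUE))
  structure(raw / total, raw_mass = raw, total_mass = total,
            out_of_bbox = 1 - sum(raw) / total)
}

#' Preprocess all cursor trajectories into observation weights
#'
#' Runs the full preprocessing chain per session: screen-to-video
#' conversion, Gaussian density accumulation (10 px sd by default), face
#' partition of the session's stimulus, and aggregation into the
#' (upper, middle, low) weight triple.
#'
#' @param trajectories Long tibble with `session_id`, `participant_id`,
#'   `stimulus_id`, `t_ms`, `x_px`, `y_px` (screen coordinates).
#' @param stimuli Stimulus tibble from [sim_stimuli()] (or equivalent) with
#'   `stimulus_id` and `frames`.
#' @param config A [screen_config()].
#' @param sigma_px Kernel sd in pixels (default 10).
#' @return A weights tibble: `session_id`, `participant_id`,
#'   `stimulus_id`, `w_upper`, `w_middle`, `w_low`, `raw_mass_total`,
#'   `out_of_bbox_fraction`.
#' @export
preprocess_trajectories <- function(trajectories, stimuli,
                                    config = screen_config(),
                                    sigma_px = 10) {
  parts <- setNames(
    lapply(stimuli$stimulus_id, function(id) {
      partition_face(stimuli$frames[[which(stimuli$stimulus_id == id)]])
    }),
    stimuli$stimulus_id
  )
  sessions <- dplyr::distinct(trajectories, .data$session_id,
                              .data$participant_id, .data$stimulus_id)
  rows <- lapply(seq_len(nrow(sessions)), function(i) {
    s <- sessions[i, ]
    traj <- dplyr::filter(trajectories, .data$session_id == s$session_id)
    vid <- to_video_coords(traj, config)
    dens <- accumulate_density(vid, sigma_px, config$canvas)
    w <- aggregate_weights(dens, parts[[s$stimulus_id]])
    tibble::tibble(
      session_id = s$session_id, participant_id = s$participant_id,
      stimulus_id = s$stimulus_id,
      w_upper = w[["upper"]], w_middle = w[["middle"]], w_low = w[["low"]],
      raw_mass_total = attr(w, "total_mass"),
      out_of_bbox_fraction = attr(w, "out_of_bbox")
    )
  })
  dplyr::bind_rows(rows)
}
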