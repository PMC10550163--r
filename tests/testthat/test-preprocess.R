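# Cursor-trace preprocessing: coordinate conversion, density accumulation,
# the 1 : 0.8 : 0.6 partition and weight aggregation.

traj <- function(x, y, t = seq_along(x)) {
  tibble::tibble(t_ms = t, x_px = x, y_px = y)
}

test_that("screen-to-video conversion translates and flags samples", {
  cfg <- screen_config(screen = c(1000, 1000), origin = c(100, 50),
                       canvas = c(600, 800))
  out <- to_video_coords(traj(c(100, 50), c(50, 20)), cfg)
  expect_equal(out$x_px, c(0, -50))
  expect_equal(out$y_px, c(0, -30))
  expect_equal(out$in_canvas, c(TRUE, FALSE))

  id <- screen_config(screen = c(1000, 1000), origin = c(0, 0),
                      canvas = c(600, 800))
  tr <- traj(c(10, 300), c(20, 700))
  out <- to_video_coords(tr, id)
  expect_equal(out$x_px, tr$x_px)
  expect_equal(out$y_px, tr$y_px)

  empty <- to_video_coords(traj(numeric(0), numeric(0)), cfg)
  expect_equal(nrow(empty), 0)
})

test_that("density accumulation deposits unit-mass kernels", {
  d <- accumulate_density(traj(300, 400), sigma_px = 10)
  peak <- which(d$map == max(d$map), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(401, 301))   # row = y + 1, col = x + 1
  expect_lt(abs(sum(d$map) - 1), 1e-3)

  d5 <- accumulate_density(traj(300, 400), sigma_px = 25)
  expect_lt(abs(sum(d5$map) - 1), 1e-3)

  d2 <- accumulate_density(traj(c(300, 300), c(400, 400)), sigma_px = 10)
  expect_equal(d2$map, 2 * d$map)

  # out-of-canvas samples deposit nothing
  d0 <- accumulate_density(traj(c(-50, 700), c(100, 100)), sigma_px = 10)
  expect_equal(sum(d0$map), 0)

  expect_error(accumulate_density(traj(1, 1), sigma_px = 0), "positive")
})

frames_with_bbox <- function(left, top, right, bottom) {
  f <- array(0, dim = c(1, 68, 2))
  f[1, , 1] <- seq(left, right, length.out = 68)
  f[1, , 2] <- seq(top, bottom, length.out = 68)
  f
}

test_that("face partition splits the bbox 1 : 0.8 : 0.6 top to bottom", {
  p <- partition_face(frames_with_bbox(100, 100, 300, 340))  # height 240
  expect_equal(unname(p$cuts), c(200, 280))                  # bands 100/80/60
  heights <- c(p$cuts[1] - p$bbox[["top"]],
               p$cuts[2] - p$cuts[1],
               p$bbox[["bottom"]] - p$cuts[2])
  expect_equal(heights / heights[1], c(1, 0.8, 0.6))

  p2 <- partition_face(frames_with_bbox(0, 0, 10, 2.4))
  expect_equal(unname(p2$cuts), c(1.0, 1.8))

  for (i in 1:5) {
    set.seed(i)
    bb <- sort(runif(2, 0, 700))
    p3 <- partition_face(frames_with_bbox(10, bb[1], 400, bb[2] + 10))
    h <- diff(c(p3$bbox[["top"]], p3$cuts, p3$bbox[["bottom"]]))
    expect_equal(h[2] / h[1], 0.8)
    expect_equal(h[3] / h[1], 0.6)
  }

  degenerate <- array(5, dim = c(1, 68, 2))
  expect_error(partition_face(degenerate), "degenerate")
})

test_that("weight aggregation normalises band masses and discards outside", {
  part <- partition_face(frames_with_bbox(100, 100, 300, 340))
  mk_map <- function(map) structure(list(map = map, canvas = c(600, 800),
                                         n_samples = 1), class = "ft_density")
  # all mass at one pixel inside the upper band
  m <- matrix(0, 800, 600); m[151, 201] <- 2.5
  w <- aggregate_weights(mk_map(m), part)
  expect_equal(unname(w), c(1, 0, 0), ignore_attr = TRUE)

  # all mass outside the bbox
  m <- matrix(0, 800, 600); m[700, 500] <- 1
  w <- aggregate_weights(mk_map(m), part)
  expect_equal(unname(w), c(0, 0, 0), ignore_attr = TRUE)
  expect_equal(attr(w, "out_of_bbox"), 1)

  # uniform density exactly tiling the bbox: weights 1/2.4, 0.8/2.4, 0.6/2.4
  m <- matrix(0, 800, 600)
  m[101:341, 101:301] <- 1
  w <- aggregate_weights(mk_map(m), part)
  expect_equal(unname(w), c(1, 0.8, 0.6) / 2.4, tolerance = 0.01, ignore_attr = TRUE)

  # zero-mass map warns and returns zeros
  expect_warning(w0 <- aggregate_weights(mk_map(matrix(0, 800, 600)), part),
                 "zero-mass")
  expect_equal(unname(w0), c(0, 0, 0), ignore_attr = TRUE)
})

test_that("weights conserve mass, are translation-equivariant and monotone", {
  stim <- sim_stimuli(1, "sadness", seed = 3)
  part <- partition_face(stim$frames[[1]])
  set.seed(42)
  for (i in 1:5) {
    tr <- traj(runif(60, 0, 600), runif(60, 0, 800))
    d <- accumulate_density(tr, 10)
    w <- aggregate_weights(d, part)
    expect_lt(abs(sum(w) + attr(w, "out_of_bbox") - 1), 1e-6)
  }

  # shifting the stimulus origin and the cursor together changes nothing
  tr_video <- traj(runif(40, 150, 450), runif(40, 250, 550))
  w_of <- function(origin) {
    cfg <- screen_config(screen = c(2000, 2000), origin = origin)
    scr <- traj(tr_video$x_px + origin[1], tr_video$y_px + origin[2])
    d <- accumulate_density(to_video_coords(scr, cfg), 10)
    aggregate_weights(d, part)
  }
  expect_equal(w_of(c(0, 0)), w_of(c(700, 900)))

  # adding in-band samples never decreases that band's weight
  centre_upper <- c((part$bbox[["left"]] + part$bbox[["right"]]) / 2,
                    (part$bbox[["top"]] + part$cuts[1]) / 2)
  base <- traj(runif(30, 0, 600), runif(30, 0, 800))
  w1 <- aggregate_weights(accumulate_density(base, 10), part)
  more <- rbind(base, traj(rep(centre_upper[1], 10), rep(centre_upper[2], 10),
                           t = 31:40))
  w2 <- aggregate_weights(accumulate_density(more, 10), part)
  expect_gte(w2[["upper"]], w1[["upper"]])
})
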