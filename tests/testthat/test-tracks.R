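# build a toy track CSV from closed-form paths x(t), y(t) at a given fps
write_toy_tracks <- function(path, fns, frames, fps = 30) {
  rows <- do.call(rbind, lapply(seq_along(fns), function(id) {
    tt <- frames / fps
    data.frame(frame = frames, id = id - 1,
               x = fns[[id]]$x(tt), y = fns[[id]]$y(tt))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  path
}

test_that("track tables are validated and canonicalized", {
  path <- tempfile(fileext = ".csv")
  df <- data.frame(frame = rep(0:9, 3), id = rep(c(7, 2, 31), each = 10),
                   x = rnorm(30), y = rnorm(30))
  df <- df[sample(nrow(df)), ]   # shuffled row order
  utils::write.csv(df, path, row.names = FALSE)
  tracks <- read_tracks(path, fps = 30)
  expect_equal(sort(unique(tracks$id)), 0:2)
  expect_equal(attr(tracks, "id_map")$original, c(2, 7, 31))
  expect_true(!is.unsorted(tracks$frame[tracks$id == 0]))

  bad <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(frame = 1, id = 1, x = 1), bad,
                   row.names = FALSE)
  expect_error(read_tracks(bad), "y")
  dup <- tempfile(fileext = ".csv")
  utils::write.csv(df[c(1, 1, 3), ], dup, row.names = FALSE)
  expect_error(read_tracks(dup), "duplicate")
  expect_error(read_tracks(tempfile()), "not found")
})

test_that("polynomial tracks are differentiated exactly", {
  path <- tempfile(fileext = ".csv")
  fns <- list(
    list(x = function(t) 3 + 2 * t, y = function(t) 1 - 4 * t),
    list(x = function(t) t^3 - t, y = function(t) 0.5 * t^2 + t)
  )
  write_toy_tracks(path, fns, frames = 0:59, fps = 30)
  vel <- savgol_velocities(read_tracks(path, fps = 30))
  lin <- vel[vel$id == 0, ]
  expect_equal(lin$vx, rep(2, nrow(lin)), tolerance = 1e-9)
  expect_equal(lin$vy, rep(-4, nrow(lin)), tolerance = 1e-9)
  cub <- vel[vel$id == 1, ]
  tt <- cub$frame / 30
  expect_equal(cub$vx, 3 * tt^2 - 1, tolerance = 1e-8)
  expect_equal(cub$vy, tt + 1, tolerance = 1e-8)
  # edge frames are dropped by the interior-only policy
  expect_equal(range(lin$frame), c(3, 56))
})

test_that("sinusoidal tracks match the analytic derivative closely", {
  path <- tempfile(fileext = ".csv")
  f <- 1   # Hz, well below the 30 fps Nyquist band of the 7-frame filter
  fns <- list(list(x = function(t) sin(2 * pi * f * t),
                   y = function(t) cos(2 * pi * f * t)))
  write_toy_tracks(path, fns, frames = 0:149, fps = 30)
  vel <- savgol_velocities(read_tracks(path, fps = 30))
  tt <- vel$frame / 30
  expect_equal(vel$vx, 2 * pi * f * cos(2 * pi * f * tt), tolerance = 0.01)
  expect_equal(vel$vy, -2 * pi * f * sin(2 * pi * f * tt), tolerance = 0.01)
})

test_that("short or gappy tracks are dropped with warnings", {
  path <- tempfile(fileext = ".csv")
  df <- rbind(data.frame(frame = 0:19, id = 0, x = rnorm(20), y = rnorm(20)),
              data.frame(frame = 0:3, id = 1, x = rnorm(4), y = rnorm(4)))
  utils::write.csv(df, path, row.names = FALSE)
  expect_warning(vel <- savgol_velocities(read_tracks(path)), "dropped id")
  expect_equal(unique(vel$id), 0)
})

test_that("windowing yields the documented sample count and drops gaps", {
  path <- tempfile(fileext = ".csv")
  fns <- replicate(3, list(x = function(t) cumsum(rep(0.1, length(t))) + sin(t),
                           y = function(t) cos(3 * t)), simplify = FALSE)
  write_toy_tracks(path, fns, frames = 0:1200, fps = 30)
  vel <- savgol_velocities(read_tracks(path, fps = 30))
  obs <- window_observations(vel, t_center = 20, half_width = 15, fps = 30)
  expect_equal(obs$T, 2 * 15 * 30 + 1)   # 901 samples
  expect_equal(obs$D, 6)                 # vx, vy per individual
  expect_error(window_observations(vel, t_center = 2, half_width = 15),
               "past the recording")
  # individual 2 loses a frame inside the window: dropped with a warning
  vel2 <- vel[!(vel$id == 2 & vel$frame == 600), ]
  attr(vel2, "fps") <- 30
  expect_warning(obs2 <- window_observations(vel2, 20, 15), "gaps")
  expect_equal(obs2$D, 4)
})

test_that("windowing a trajectory uses its own time base", {
  traj <- school_simulate(4, eta = 0.2, steps = 400, seed = 10,
                          self_check_burn_in = NULL)
  obs <- window_observations(traj, t_center = 20, half_width = 10)
  expect_equal(obs$T, 201)   # dt = 0.1 -> 10 samples per time unit
  expect_equal(obs$D, 8)
})

test_that("rescaling positions leaves redundancy and partitions unchanged", {
  path_px <- tempfile(fileext = ".csv")
  traj <- independent_groups(c(3, 3), eta = 0.2, steps = 700, seed = 11)
  df <- data.frame(frame = rep(0:700, 6),
                   id = rep(0:5, each = 701),
                   x = as.vector(traj$x), y = as.vector(traj$y))
  utils::write.csv(df, path_px, row.names = FALSE)
  analyse <- function(path, scale) {
    d <- utils::read.csv(path)
    d$x <- d$x * scale; d$y <- d$y * scale
    p2 <- tempfile(fileext = ".csv")
    utils::write.csv(d, p2, row.names = FALSE)
    vel <- savgol_velocities(read_tracks(p2, fps = 10))
    obs <- window_observations(vel, t_center = 35, half_width = 25, fps = 10)
    model <- estimate_gaussian_model(rank_gaussianize(obs))
    list(r = gaussian_relative_redundancy(model, seq_len(model$n)),
         labels = solve_hard(model, 2, restarts = 10, seed = 3)$hard_labels)
  }
  a <- analyse(path_px, 1)
  b <- analyse(path_px, 0.00042)   # pixels -> meters
  expect_equal(a$r, b$r, tolerance = 1e-10)
  expect_equal(a$labels, b$labels)
})
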