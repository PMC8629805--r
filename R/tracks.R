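#' Read a tracked-trajectory table
#'
#' Reads a delimited table of tracked positions with columns
#' `frame, id, x, y` (additional columns are kept). Rows are canonicalized
#' by sorting on `(id, frame)`; duplicate `(frame, id)` pairs are an error.
#' Ids are normalized to `0..n-1`; the original-to-normalized mapping is
#' attached as attribute `"id_map"`.
#'
#' @param path CSV file path.
#' @param fps frame rate of the recording (frames per second).
#' @return a `data.frame` of class `track_table` with attributes `fps` and
#'   `id_map`.
#' @export
read_tracks <- function(path, fps = 30) {
  if (!file.exists(path)) stop("track file not found: ", path)
  df <- utils::read.csv(path)
  required <- c("frame", "id", "x", "y")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("track table missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df[, c("frame", "id")]) > 0) {
    stop("duplicate (frame, id) pairs in track table")
  }
  ids <- sort(unique(df$id))
  id_map <- data.frame(original = ids, normalized = seq_along(ids) - 1L)
  df$id <- match(df$id, ids) - 1L
  df <- df[order(df$id, df$frame), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "fps") <- fps
  attr(df, "id_map") <- id_map
  class(df) <- c("track_table", "data.frame")
  df
}

#' Savitzky-Golay velocity estimation from tracks
#'
#' Estimates per-individual velocities as the smoothed first derivative of
#' position (a 3rd-order Savitzky-Golay filter over a 7-frame window by
#' default), scaled by the frame rate. Each individual's track is processed
#' per contiguous frame run; runs shorter than the filter window are dropped
#' with a warning, as are the `(window_frames - 1) / 2` edge frames of every
#' run, where the centered filter is undefined (interior-only edge policy).
#'
#' @param tracks a [read_tracks()] table (or a data frame with
#'   `frame, id, x, y`).
#' @param order polynomial order of the filter.
#' @param window_frames filter window length (odd).
#' @param fps frame rate; defaults to the table's `fps` attribute.
#' @return data frame `frame, id, x, y, vx, vy` restricted to interior
#'   frames, with attribute `fps`.
#' @export
savgol_velocities <- function(tracks, order = 3, window_frames = 7,
                              fps = attr(tracks, "fps")) {
  if (is.null(fps)) fps <- 30
  if (window_frames %% 2 == 0) stop("window_frames must be odd")
  if (order >= window_frames) stop("filter order must be below the window length")
  half <- (window_frames - 1) / 2
  out <- list()
  dropped <- integer(0)
  for (one_id in unique(tracks$id)) {
    tr <- tracks[tracks$id == one_id, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    runs <- split(seq_len(nrow(tr)), cumsum(c(1, diff(tr$frame) != 1)))
    kept <- FALSE
    for (run in runs) {
      if (length(run) < window_frames) next
      seg <- tr[run, , drop = FALSE]
      vx <- signal::sgolayfilt(seg$x, p = order, n = window_frames, m = 1) * fps
      vy <- signal::sgolayfilt(seg$y, p = order, n = window_frames, m = 1) * fps
      interior <- (half + 1):(nrow(seg) - half)
      out[[length(out) + 1]] <- data.frame(
        frame = seg$frame[interior], id = one_id,
        x = seg$x[interior], y = seg$y[interior],
        vx = vx[interior], vy = vy[interior])
      kept <- TRUE
    }
    if (!kept) dropped <- c(dropped, one_id)
  }
  if (length(dropped) > 0) {
    warning("dropped id(s) with no contiguous run of at least ",
            window_frames, " frames: ", paste(dropped, collapse = ", "))
  }
  if (length(out) == 0) stop("no individual has a track long enough to filter")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "fps") <- fps
  res
}

#' Windowed observation matrix around a time point
#'
#' Extracts the closed window `[t_center - half_width, t_center + half_width]`
#' (seconds) from a velocity table and assembles the `T x 2n` observation
#' matrix of planar velocity components (`T = 2 * half_width * fps + 1`).
#' Individuals missing any frame inside the window are dropped with a
#' warning (no interpolation).
#'
#' @param velocities output of [savgol_velocities()] (columns
#'   `frame, id, vx, vy`), or a [trajectory()] (then `t_center` and
#'   `half_width` are in the trajectory's time units, spacing `dt`).
#' @param t_center window center, seconds.
#' @param half_width window half-width, seconds (15 by default).
#' @param fps frame rate; defaults to the table's `fps` attribute.
#' @return an [observation_matrix()] with `k_i = 2` per retained individual;
#'   retained ids in attribute `"ids"`.
#' @export
window_observations <- function(velocities, t_center, half_width = 15,
                                fps = attr(velocities, "fps")) {
  if (inherits(velocities, "trajectory")) {
    traj <- velocities
    fps <- 1 / traj$dt
    f0 <- round((t_center - half_width) * fps) + 1L
    f1 <- round((t_center + half_width) * fps) + 1L
    if (f0 < 1 || f1 > nrow(traj$vx)) stop("window extends past the recording")
    vals <- matrix(0, f1 - f0 + 1L, 2 * traj$n)
    for (i in seq_len(traj$n)) {
      vals[, 2 * i - 1] <- traj$vx[f0:f1, i]
      vals[, 2 * i] <- traj$vy[f0:f1, i]
    }
    return(observation_matrix(vals, element_map_blocks(traj$n, 2),
                              units = "velocity"))
  }
  if (is.null(fps)) fps <- 30
  f0 <- round((t_center - half_width) * fps)
  f1 <- round((t_center + half_width) * fps)
  if (f0 < min(velocities$frame) || f1 > max(velocities$frame)) {
    stop("window extends past the recording")
  }
  frames <- f0:f1
  Tn <- length(frames)
  keep <- list()
  dropped <- integer(0)
  for (one_id in sort(unique(velocities$id))) {
    seg <- velocities[velocities$id == one_id &
                        velocities$frame >= f0 & velocities$frame <= f1, ]
    if (nrow(seg) == Tn && all(sort(seg$frame) == frames)) {
      seg <- seg[order(seg$frame), ]
      keep[[as.character(one_id)]] <- cbind(seg$vx, seg$vy)
    } else {
      dropped <- c(dropped, one_id)
    }
  }
  if (length(dropped) > 0) {
    warning("dropped individual(s) with gaps in the window: ",
            paste(dropped, collapse = ", "))
  }
  if (length(keep) == 0) stop("no individual fully observed in the window")
  vals <- do.call(cbind, keep)
  ids <- as.integer(names(keep))
  colnames(vals) <- as.vector(rbind(paste0("vx", ids), paste0("vy", ids)))
  out <- observation_matrix(vals, element_map_blocks(length(keep), 2),
                            units = "velocity")
  attr(out, "ids") <- ids
  out
}
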