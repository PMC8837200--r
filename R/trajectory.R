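#' Arena geometry for open-field, shoaling and emergence trials
#'
#' The open-field arena is a rectangular tank viewed from above, divided into
#' a square grid for area-coverage scoring. The "middle" zone is a centred
#' rectangle with the same aspect ratio as the arena, scaled by `1/sqrt(2)` on
#' each side so that its area equals exactly half the arena: the only similar
#' rectangle for which the inner zone is the same size as the border zone that
#' surrounds it. The shoaling partition splits the arena into three equal
#' rectangles along its long axis.
#'
#' @param width,height arena dimensions in cm (default 20 x 30).
#' @param cell_size grid cell side for area coverage, cm.
#' @return object of class `arena_spec`.
#' @export
arena_spec <- function(width = 20, height = 30, cell_size = 1) {
  stopifnot(width > 0, height > 0, cell_size > 0)
  s <- 1 / sqrt(2)
  mid_w <- width * s
  mid_h <- height * s
  structure(list(
    width = width, height = height, cell_size = cell_size,
    n_cells = ceiling(width / cell_size) * ceiling(height / cell_size),
    middle = c(xmin = (width - mid_w) / 2, xmax = (width + mid_w) / 2,
               ymin = (height - mid_h) / 2, ymax = (height + mid_h) / 2)
  ), class = "arena_spec")
}

#' @export
print.arena_spec <- function(x, ...) {
  cat(sprintf("arena %g x %g cm, %g cm grid (%d cells), middle zone = half the area\n",
              x$width, x$height, x$cell_size, x$n_cells))
  invisible(x)
}

#' Construct a trajectory
#'
#' A trajectory is a data frame of frame-indexed positions (cm) recorded at a
#' uniform frame rate.
#'
#' @param x,y positions in cm.
#' @param fps frames per second.
#' @return object of class `trajectory` (a data frame with columns
#'   `frame`, `t`, `x`, `y` and attribute `fps`).
#' @export
trajectory <- function(x, y, fps = 25) {
  stopifnot(length(x) == length(y), length(x) >= 1, fps > 0)
  out <- data.frame(frame = seq_along(x), t = (seq_along(x) - 1) / fps,
                    x = x, y = y)
  attr(out, "fps") <- fps
  class(out) <- c("trajectory", "data.frame")
  out
}

.traj_fps <- function(traj) {
  fps <- attr(traj, "fps")
  if (is.null(fps)) {
    if (nrow(traj) < 2) stop("cannot infer frame rate from a single frame")
    fps <- 1 / diff(traj$t[1:2])
  }
  fps
}

#' Read / write trajectory CSV files (columns frame, t, x, y)
#'
#' @param path file path.
#' @param fps frame rate used when the time column is absent.
#' @export
read_trajectory <- function(path, fps = NULL) {
  df <- utils::read.csv(path)
  stopifnot(all(c("x", "y") %in% names(df)))
  if (is.null(fps)) {
    fps <- if ("t" %in% names(df) && nrow(df) > 1) 1 / diff(df$t[1:2]) else 25
  }
  trajectory(df$x, df$y, fps = fps)
}

#' @rdname read_trajectory
#' @param traj a [trajectory()].
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' Total distance swum (cm)
#'
#' Sum of Euclidean displacements between consecutive frames.
#'
#' @param traj a [trajectory()].
#' @export
track_length <- function(traj) {
  if (nrow(traj) < 2) {
    warning("trajectory has a single frame; track length is 0")
    return(0)
  }
  sum(sqrt(diff(traj$x)^2 + diff(traj$y)^2))
}

## grid cell index (half-open cells [i, i+1); far boundary folded into the
## last cell) -- integer code col * n_rows + row
.cell_codes <- function(x, y, arena) {
  cs <- arena$cell_size
  nx <- ceiling(arena$width / cs)
  ny <- ceiling(arena$height / cs)
  cx <- pmin(floor(x / cs), nx - 1)
  cy <- pmin(floor(y / cs), ny - 1)
  cx * ny + cy
}

## Exact enumeration of grid cells traversed by a set of segments: each
## segment is split at every gridline crossing and the cell containing each
## piece is coded by the piece midpoint. Fully vectorised across segments.
.segments_cells <- function(x1, y1, x2, y2, arena) {
  cs <- arena$cell_size
  n <- length(x1)
  if (n == 0) return(integer(0))
  seg_id <- seq_len(n)

  cross_ts <- function(a1, a2) {
    lo <- ceiling(pmin(a1, a2) / cs)
    hi <- floor(pmax(a1, a2) / cs)
    cnt <- pmax(hi - lo + 1L, 0L)
    cnt[a1 == a2] <- 0L
    ks <- (sequence(cnt) - 1L) + rep(lo, cnt)
    id <- rep(seg_id, cnt)
    list(id = id, t = (ks * cs - a1[id]) / (a2[id] - a1[id]))
  }
  cx <- cross_ts(x1, x2)
  cy <- cross_ts(y1, y2)
  id <- c(seg_id, seg_id, cx$id, cy$id)
  t <- pmin(pmax(c(rep(0, n), rep(1, n), cx$t, cy$t), 0), 1)
  o <- order(id, t)
  id <- id[o]
  t <- t[o]
  keep <- c(TRUE, diff(id) != 0 | diff(t) > 1e-12)  # drop degenerate pieces
  id <- id[keep]
  t <- t[keep]
  same <- c(diff(id) == 0, FALSE)               # consecutive pair in same segment
  tm <- (t[same] + t[c(FALSE, same[-length(same)])]) / 2
  im <- id[same]
  .cell_codes(x1[im] + tm * (x2[im] - x1[im]),
              y1[im] + tm * (y2[im] - y1[im]), arena)
}

#' Proportion of the arena grid covered by a trajectory
#'
#' The arena is divided into square grid cells (1 cm by default) and the
#' proportion of distinct cells entered is returned. Cells are half-open
#' (`[i, i+1)`); points exactly on the far wall belong to the last cell.
#' Every cell traversed between consecutive frames is counted: segments are
#' split exactly at gridline crossings, so no intermediate cell can be
#' skipped however long the inter-frame displacement.
#'
#' @param traj a [trajectory()].
#' @param arena an [arena_spec()].
#' @return proportion in `[0, 1]`.
#' @export
area_covered <- function(traj, arena = arena_spec()) {
  .check_in_arena(traj, arena)
  x <- traj$x
  y <- traj$y
  n <- length(x)
  cells <- .cell_codes(x, y, arena)
  if (n > 1) {
    moved <- which(diff(x) != 0 | diff(y) != 0)
    cells <- c(cells, .segments_cells(x[moved], y[moved],
                                      x[moved + 1], y[moved + 1], arena))
  }
  length(unique(cells)) / arena$n_cells
}

.check_in_arena <- function(traj, arena) {
  if (any(traj$x < 0 | traj$x > arena$width |
            traj$y < 0 | traj$y > arena$height)) {
    stop("trajectory leaves the arena bounds")
  }
}

#' Number of freezing bouts
#'
#' A freezing bout is a maximal run of frames whose instantaneous velocity
#' (inter-frame displacement times frame rate, no smoothing) stays below
#' `velocity_threshold` for at least `min_duration` seconds. A run truncated
#' by the end of the trial still counts if it is long enough.
#'
#' @param traj a [trajectory()].
#' @param velocity_threshold cm/s.
#' @param min_duration seconds.
#' @return integer count.
#' @export
freezing_count <- function(traj, velocity_threshold = 4, min_duration = 2.5) {
  if (nrow(traj) < 2) return(0L)
  fps <- .traj_fps(traj)
  v <- sqrt(diff(traj$x)^2 + diff(traj$y)^2) * fps
  slow <- v < velocity_threshold
  r <- rle(slow)
  sum(r$values & (r$lengths / fps) >= min_duration)
}

#' Time spent in the middle zone (seconds)
#'
#' Total dwell time inside the centred middle-zone rectangle (each frame
#' contributes `1/fps` seconds).
#'
#' @inheritParams area_covered
#' @export
time_in_middle <- function(traj, arena = arena_spec()) {
  fps <- .traj_fps(traj)
  m <- arena$middle
  inside <- traj$x >= m["xmin"] & traj$x <= m["xmax"] &
    traj$y >= m["ymin"] & traj$y <= m["ymax"]
  sum(inside) / fps
}

#' Mean distance from the nearest wall (cm)
#'
#' @inheritParams area_covered
#' @export
mean_wall_distance <- function(traj, arena = arena_spec()) {
  mean(pmin(traj$x, arena$width - traj$x, traj$y, arena$height - traj$y))
}

#' Shoaling tendency (seconds)
#'
#' The arena is split into three equal rectangles along its long axis; the
#' statistic is time spent in the third nearest the shoal minus time spent in
#' the third farthest from it.
#'
#' @inheritParams area_covered
#' @param shoal_side which end of the long axis holds the shoal:
#'   `"high"` (large coordinate) or `"low"`.
#' @export
shoaling_tendency <- function(traj, arena = arena_spec(),
                              shoal_side = c("high", "low")) {
  shoal_side <- match.arg(shoal_side)
  fps <- .traj_fps(traj)
  long <- if (arena$height >= arena$width) traj$y else traj$x
  L <- max(arena$height, arena$width)
  near <- if (shoal_side == "high") long >= 2 * L / 3 else long <= L / 3
  far <- if (shoal_side == "high") long <= L / 3 else long >= 2 * L / 3
  (sum(near) - sum(far)) / fps
}

#' Pool per-frame displacement vectors from observed trajectories
#'
#' @param trajs a list of [trajectory()] objects (a single trajectory is
#'   promoted to a list).
#' @return object of class `step_distribution`: data frame of displacements
#'   `dx`, `dy` and their lengths `dist` (cm per frame).
#' @export
empirical_step_distribution <- function(trajs) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  if (length(trajs) == 0) stop("need at least one trajectory")
  steps <- do.call(rbind, lapply(trajs, function(tr) {
    if (nrow(tr) < 2) return(NULL)
    data.frame(dx = diff(tr$x), dy = diff(tr$y))
  }))
  if (is.null(steps) || nrow(steps) == 0) stop("no movement steps in input")
  steps$dist <- sqrt(steps$dx^2 + steps$dy^2)
  class(steps) <- c("step_distribution", "data.frame")
  steps
}

#' Synthetic per-frame step pool
#'
#' A synthetic stand-in for an empirical step distribution, for use when no
#' real tracking files are available: a two-component mixture of slow
#' (freeze-like) and fast (cruise) step lengths with uniform headings.
#' Step lengths are exponential with the given means.
#'
#' @param n number of steps.
#' @param slow_mean,fast_mean mean step length (cm/frame) of each component.
#' @param p_slow mixing weight of the slow component.
#' @param seed integer seed.
#' @return a `step_distribution`.
#' @export
synthetic_step_pool <- function(n = 5000, slow_mean = 0.1, fast_mean = 0.8,
                                p_slow = 0.35, seed = 1) {
  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(seed)
  comp <- stats::runif(n) < p_slow
  len <- stats::rexp(n, rate = 1 / ifelse(comp, slow_mean, fast_mean))
  ang <- stats::runif(n, 0, 2 * pi)
  steps <- data.frame(dx = len * cos(ang), dy = len * sin(ang), dist = len)
  class(steps) <- c("step_distribution", "data.frame")
  steps
}

#' Simulate a random swim through the arena
#'
#' Starting from the arena centre, displacement vectors are drawn at random
#' (with replacement) from the step pool. A draw that would take the fish out
#' of bounds is rejected and redrawn. Displacements longer than `max_part`
#' are subdivided into equal parts no longer than `max_part` so that the
#' recorded path visits every traversed grid cell. The walk terminates as
#' soon as its cumulative length reaches or exceeds `target_length`.
#'
#' @param steps a `step_distribution`.
#' @param arena an [arena_spec()].
#' @param target_length objective path length, cm.
#' @param seed integer seed.
#' @param fps nominal frame rate attached to the result.
#' @param max_part maximum recorded sub-step length, cm.
#' @param max_reject error out after this many consecutive rejections
#'   (degenerate step pool).
#' @return a [trajectory()].
#' @export
random_swim <- function(steps, arena = arena_spec(), target_length, seed = 1,
                        fps = 25, max_part = 1, max_reject = 1e5) {
  stopifnot(target_length > 0, nrow(steps) > 0)
  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(seed)

  ## Draw candidate steps in blocks; accept the prefix of each block that
  ## stays within bounds (a rejected draw is simply redrawn, so the accepted
  ## sequence is distributed exactly as one-at-a-time rejection sampling).
  pos <- c(arena$width / 2, arena$height / 2)
  acc_dx <- list()
  acc_dy <- list()
  total <- 0
  rejections <- 0L
  n_pool <- nrow(steps)
  block <- 512L
  while (total < target_length) {
    j <- sample.int(n_pool, block, replace = TRUE)
    px <- pos[1] + cumsum(steps$dx[j])
    py <- pos[2] + cumsum(steps$dy[j])
    bad <- which(px < 0 | px > arena$width | py < 0 | py > arena$height)
    k <- if (length(bad) > 0) bad[1] - 1L else block
    if (k > 0) {
      cum <- cumsum(steps$dist[j[seq_len(k)]])
      ## truncate the block at the termination point
      if (total + cum[k] >= target_length) {
        k <- which(total + cum >= target_length)[1]
      }
      take <- j[seq_len(k)]
      acc_dx[[length(acc_dx) + 1L]] <- steps$dx[take]
      acc_dy[[length(acc_dy) + 1L]] <- steps$dy[take]
      total <- total + sum(steps$dist[take])
      pos <- c(pos[1] + sum(steps$dx[take]), pos[2] + sum(steps$dy[take]))
      rejections <- 0L
    }
    if (length(bad) > 0 && total < target_length) {
      rejections <- rejections + 1L
      if (rejections >= max_reject) {
        stop("random_swim: ", max_reject, " consecutive rejections; ",
             "step pool appears degenerate for this arena")
      }
    }
  }

  ## subdivide accepted displacements into parts no longer than max_part
  dx <- unlist(acc_dx)
  dy <- unlist(acc_dy)
  d <- sqrt(dx^2 + dy^2)
  n_part <- pmax(1L, ceiling(d / max_part))
  idx <- rep(seq_along(dx), n_part)
  frac <- sequence(n_part) / rep(n_part, n_part)
  ## positions: origin of each accepted step + frac * displacement
  step_x0 <- cumsum(c(arena$width / 2, dx))[seq_along(dx)]
  step_y0 <- cumsum(c(arena$height / 2, dy))[seq_along(dy)]
  xs <- c(arena$width / 2, step_x0[idx] + frac * dx[idx])
  ys <- c(arena$height / 2, step_y0[idx] + frac * dy[idx])
  ## guard against floating-point drift just past the walls
  xs <- pmin(pmax(xs, 0), arena$width)
  ys <- pmin(pmax(ys, 0), arena$height)
  trajectory(xs, ys, fps = fps)
}

#' Fit the random-swim null model for area covered
#'
#' Simulates random swims over a grid of target track lengths (`n_lengths`
#' values evenly spaced across `length_range`, each repeated `n_reps` times),
#' scores the area covered of each, and fits area as a fourth-order
#' polynomial in track length by least squares.
#'
#' @param steps a `step_distribution`.
#' @param arena an [arena_spec()].
#' @param length_range numeric of length 2: the span of observed track
#'   lengths, cm.
#' @param n_lengths,n_reps grid resolution (default 100 x 5 = 500 swims).
#' @param seed integer seed.
#' @return object of class `null_area_model` with elements `coefficients`
#'   (degree-4 polynomial), `r_squared`, `length_range`, and the training
#'   data (`training`).
#' @export
fit_null_area_model <- function(steps, arena = arena_spec(),
                                length_range, n_lengths = 100, n_reps = 5,
                                seed = 1) {
  stopifnot(length(length_range) == 2, diff(length_range) > 0)
  lengths <- rep(seq(length_range[1], length_range[2], length.out = n_lengths),
                 times = n_reps)
  area <- vapply(seq_along(lengths), function(i) {
    sw <- random_swim(steps, arena, target_length = lengths[i],
                      seed = seed + i)
    area_covered(sw, arena)
  }, numeric(1))
  fit <- stats::lm(area ~ stats::poly(len, 4, raw = TRUE),
                   data = data.frame(len = lengths, area = area))
  if (anyNA(stats::coef(fit))) stop("degenerate length grid: singular fit")
  structure(list(
    coefficients = unname(stats::coef(fit)),
    r_squared = summary(fit)$r.squared,
    length_range = range(lengths),
    training = data.frame(track_length = lengths, area = area)
  ), class = "null_area_model")
}

#' @export
print.null_area_model <- function(x, ...) {
  cat(sprintf("random-swim null model: degree-4 polynomial, R^2 = %.3f, fitted on track lengths %.0f-%.0f cm\n",
              x$r_squared, x$length_range[1], x$length_range[2]))
  invisible(x)
}

#' Predicted null area covered at given track lengths
#'
#' @param object a `null_area_model`.
#' @param newdata numeric vector of track lengths (cm).
#' @param ... unused.
#' @export
predict.null_area_model <- function(object, newdata, ...) {
  drop(outer(newdata, 0:4, `^`) %*% object$coefficients)
}

#' Relative area covered
#'
#' Observed area covered minus the area expected for a random swim of the
#' same track length under the fitted null model. Positive values indicate
#' exploration-like space use; negative values indicate wall-following
#' flight-like paths. Track lengths outside the fitted range are flagged with
#' a warning but still scored.
#'
#' @param observed_area proportion in `[0, 1]`.
#' @param track_len track length, cm.
#' @param null a `null_area_model`.
#' @return proportion difference.
#' @export
relative_area <- function(observed_area, track_len, null) {
  outside <- track_len < null$length_range[1] | track_len > null$length_range[2]
  if (any(outside)) {
    warning(sum(outside), " track length(s) outside the fitted range; ",
            "null prediction extrapolated")
  }
  observed_area - predict(null, track_len)
}

#' Cap, log-transform and orient emergence times
#'
#' Emergence latencies are censored at the trial maximum (fish that never
#' emerge receive `max_time`), natural-log transformed, and optionally
#' multiplied by -1 so that high values denote rapid emergence.
#'
#' @param raw_times latencies in seconds, positive.
#' @param max_time censoring point, seconds.
#' @param negate flip the sign after transformation.
#' @return numeric vector of transformed values.
#' @export
prepare_emergence <- function(raw_times, max_time = 900, negate = FALSE) {
  if (any(raw_times <= 0, na.rm = TRUE)) stop("emergence times must be positive")
  out <- log(pmin(raw_times, max_time))
  if (negate) -out else out
}

#' Summarise an open-field trial
#'
#' @param traj a [trajectory()].
#' @param arena an [arena_spec()].
#' @param null optional `null_area_model`; when supplied, relative area
#'   covered is included.
#' @return one-row data frame of OFT traits.
#' @export
oft_summary <- function(traj, arena = arena_spec(), null = NULL) {
  tl <- track_length(traj)
  ac <- area_covered(traj, arena)
  out <- data.frame(
    track_length = tl,
    area_covered = ac,
    time_in_middle = time_in_middle(traj, arena),
    freezings = freezing_count(traj),
    mean_wall_distance = mean_wall_distance(traj, arena)
  )
  if (!is.null(null)) out$relative_area <- relative_area(ac, tl, null)
  out
}
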