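# Particle linking through time, sister-kinetochore pairing and
# inter-centromere stretch series with unstretched-state (T0)
# normalization.

.mutual_nn <- function(a, b, max_d) {
  # a, b: matrices with columns (y, x); returns data.frame(i, j, d) of
  # mutual nearest neighbours with distance <= max_d
  if (nrow(a) == 0 || nrow(b) == 0)
    return(data.frame(i = integer(), j = integer(), d = numeric()))
  dm <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  dm <- sqrt(dm)
  nn_ab <- apply(dm, 1, which.min)
  nn_ba <- apply(dm, 2, which.min)
  i <- seq_len(nrow(a))
  j <- nn_ab
  mutual <- nn_ba[j] == i & dm[cbind(i, j)] <= max_d
  data.frame(i = i[mutual], j = j[mutual], d = dm[cbind(i, j)][mutual])
}

#' Link detected particles into trajectories
#'
#' Greedy mutual-nearest-neighbour linking between consecutive frames:
#' particles in frame t+1 are assigned to particles in frame t when each
#' is the other's nearest neighbour and the displacement does not exceed
#' \code{max_disp_px}. Unmatched particles terminate or start tracks; no
#' gap closing. The assignment is deterministic given the input.
#'
#' @param detections data.frame with columns \code{frame, label, y_px,
#'   x_px} (e.g. the output of \code{\link{quantify_stack}}), or a list of
#'   \code{label_mask} objects (frames in order).
#' @param max_disp_px hard displacement limit per frame, px.
#' @return data.frame \code{track_id, frame, label, y_px, x_px}, ordered
#'   by track then frame.
#' @export
link_particles <- function(detections, max_disp_px = 5) {
  if (is.list(detections) && !is.data.frame(detections)) {
    detections <- do.call(rbind, lapply(seq_along(detections), function(t) {
      tb <- detections[[t]]$table
      if (nrow(tb) == 0) return(NULL)
      cbind(frame = t, tb[, c("label", "y_px", "x_px")])
    }))
  }
  stopifnot(all(c("frame", "label", "y_px", "x_px") %in% names(detections)))
  frames <- sort(unique(detections$frame))
  rows <- lapply(frames, function(f)
    detections[detections$frame == f, , drop = FALSE])
  next_id <- 1L
  out <- NULL
  prev <- NULL      # data.frame of previous frame rows + track_id
  for (k in seq_along(frames)) {
    cur <- rows[[k]]
    cur$track_id <- NA_integer_
    if (!is.null(prev) && nrow(prev) > 0 && nrow(cur) > 0) {
      m <- .mutual_nn(as.matrix(prev[, c("y_px", "x_px")]),
                      as.matrix(cur[, c("y_px", "x_px")]), max_disp_px)
      if (nrow(m)) cur$track_id[m$j] <- prev$track_id[m$i]
    }
    new <- is.na(cur$track_id)
    if (any(new)) {
      cur$track_id[new] <- seq.int(next_id, length.out = sum(new))
      next_id <- next_id + sum(new)
    }
    out <- rbind(out, cur)
    prev <- cur
  }
  out <- out[order(out$track_id, out$frame),
             c("track_id", "frame", "label", "y_px", "x_px")]
  rownames(out) <- NULL
  out
}

#' Pair sister kinetochores by mutual proximity
#'
#' Two particles form a sister pair when each is the other's nearest
#' neighbour and their separation falls inside the physical window
#' \code{[d_min_um, d_max_um]}; each particle enters at most one pair.
#' The default window of 0.5-2.5 um brackets published metaphase
#' inter-kinetochore distances.
#'
#' @param points data.frame of one frame's particle positions with columns
#'   \code{y_px, x_px} and an identifier column (\code{track_id} or
#'   \code{label}).
#' @param pixel_size_um pixel size used to convert separations to um.
#' @param d_min_um,d_max_um pairing window in um.
#' @return list with \code{pairs}: data.frame \code{pair_id, a, b,
#'   separation_um} (a, b are identifiers), and \code{unpaired}: vector of
#'   identifiers left unpaired.
#' @export
pair_sisters <- function(points, pixel_size_um, d_min_um = 0.5,
                         d_max_um = 2.5) {
  idcol <- if ("track_id" %in% names(points)) "track_id" else "label"
  ids <- points[[idcol]]
  xy <- as.matrix(points[, c("y_px", "x_px")]) * pixel_size_um
  if (nrow(xy) < 2)
    return(list(pairs = data.frame(pair_id = integer(), a = ids[0],
                                   b = ids[0], separation_um = numeric()),
                unpaired = ids))
  dm <- as.matrix(stats::dist(xy))
  diag(dm) <- Inf
  nn <- apply(dm, 1, which.min)
  i <- seq_len(nrow(xy))
  mutual <- nn[nn[i]] == i & i < nn[i]          # each mutual pair once
  m <- data.frame(i = i[mutual], j = nn[i][mutual],
                  d = dm[cbind(i, nn[i])][mutual])
  m <- m[m$d >= d_min_um & m$d <= d_max_um, , drop = FALSE]
  pairs <- data.frame(pair_id = seq_len(nrow(m)),
                      a = ids[m$i], b = ids[m$j],
                      separation_um = m$d)
  list(pairs = pairs, unpaired = setdiff(ids, c(pairs$a, pairs$b)))
}

#' Inter-centromere distance series of a sister pair
#'
#' @param traj_a,traj_b trajectory data.frames (rows of the
#'   \code{\link{link_particles}} output for one track each) sharing at
#'   least two frames.
#' @param pixel_size_um pixel size in um.
#' @param pair_id identifier stored in the result.
#' @return object of class \code{stretch_series}: list with
#'   \code{pair_id}, \code{frames}, \code{d_um}; pass to
#'   \code{\link{normalize_t0}} for the normalized series.
#' @export
intercentromere_series <- function(traj_a, traj_b, pixel_size_um,
                                   pair_id = 1L) {
  common <- intersect(traj_a$frame, traj_b$frame)
  if (length(common) < 2)
    stop("intercentromere_series: trajectories share fewer than 2 frames")
  common <- sort(common)
  ia <- match(common, traj_a$frame); ib <- match(common, traj_b$frame)
  d <- sqrt((traj_a$y_px[ia] - traj_b$y_px[ib])^2 +
            (traj_a$x_px[ia] - traj_b$x_px[ib])^2) * pixel_size_um
  structure(list(pair_id = pair_id, frames = common, d_um = d,
                 t0_index = NA_integer_, n = NULL),
            class = "stretch_series")
}

#' Normalize an inter-centromere series to its unstretched state (T0)
#'
#' T0 is the frame at which the pair is least stretched; by default the
#' minimum-distance frame (earliest frame on ties), or the first frame
#' with \code{mode = "first"} for sensitivity analysis. The normalized
#' series is \code{n(t) = d(t) / d(T0)}, so \code{n(T0) = 1} exactly.
#'
#' @param series a \code{stretch_series}.
#' @param mode \code{"min"} (default) or \code{"first"}.
#' @return the series with \code{t0_index} and \code{n} filled in.
#' @export
normalize_t0 <- function(series, mode = c("min", "first")) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "stretch_series"), length(series$d_um) > 0)
  t0 <- if (mode == "min") which.min(series$d_um) else 1L
  if (series$d_um[t0] == 0)
    stop("normalize_t0: zero distance at T0")
  series$t0_index <- t0
  series$n <- series$d_um / series$d_um[t0]
  series
}

#' @export
print.stretch_series <- function(x, ...) {
  cat("<stretch_series> pair ", x$pair_id, ", ", length(x$frames),
      " frames, d ", round(min(x$d_um), 3), "-", round(max(x$d_um), 3),
      " um", if (!is.na(x$t0_index)) paste0(", T0 at frame ",
                                            x$frames[x$t0_index]),
      "\n", sep = "")
  invisible(x)
}

#' Per-pair stretch summary
#'
#' @param series_list list of (normalized) \code{stretch_series}.
#' @param frame_interval_min frame interval used to report durations.
#' @return data.frame \code{pair_id, d_max_um, n_max, duration_min}.
#' @export
stretch_summary <- function(series_list, frame_interval_min = 6) {
  if (!length(series_list))
    return(data.frame(pair_id = integer(), d_max_um = numeric(),
                      n_max = numeric(), duration_min = numeric()))
  do.call(rbind, lapply(series_list, function(s) {
    n <- if (is.null(s$n)) normalize_t0(s)$n else s$n
    data.frame(pair_id = s$pair_id, d_max_um = max(s$d_um),
               n_max = max(n),
               duration_min = (length(s$frames) - 1) * frame_interval_min)
  }))
}

#' Intensity trend along a trajectory
#'
#' Fits a straight line to the kinetochore/cytoplasm ratio versus time for
#' one track; used to quantify the dynamic gain or loss of a kinetochore
#' protein over a movie.
#'
#' @param measurements data.frame with \code{frame} and \code{ratio}
#'   columns for one track (e.g. the quantification output subset to one
#'   \code{track_id} after linking).
#' @param frame_interval_min frame interval in min.
#' @return list \code{slope_per_min}, \code{intercept}.
#' @export
ratio_trend <- function(measurements, frame_interval_min = 6) {
  t <- (measurements$frame - min(measurements$frame)) * frame_interval_min
  fit <- stats::lm(measurements$ratio ~ t)
  list(slope_per_min = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}
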