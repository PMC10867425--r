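# Kinetochore quantification core: particle detection in the reference
# (centromere-marker) channel, mask transfer to the measurement channel,
# ring-shaped cytoplasm proxy and kinetochore/cytoplasm intensity ratios.
#
# Images are Y x X matrices; centroids are reported in 0-based pixel
# coordinates (y_px, x_px).

.pixel_grids <- function(d) {
  list(yy = matrix(rep(seq_len(d[1]), d[2]), d[1], d[2]),
       xx = matrix(rep(seq_len(d[2]), each = d[1]), d[1], d[2]))
}

.label_table <- function(labels) {
  d <- dim(labels)
  g <- .pixel_grids(d)
  sel <- labels > 0
  if (!any(sel))
    return(data.frame(label = integer(), area_px = integer(),
                      y_px = numeric(), x_px = numeric()))
  lv <- labels[sel]
  data.frame(label = as.integer(names(table(lv))),
             area_px = as.integer(table(lv)),
             y_px = as.numeric(tapply(g$yy[sel], lv, mean)) - 1,
             x_px = as.numeric(tapply(g$xx[sel], lv, mean)) - 1)
}

#' Detect kinetochore particles in a reference-channel image
#'
#' Pipeline: Gaussian smoothing at \code{edge_sigma}, Sobel gradient
#' magnitude, global threshold (Otsu on the normalized edge response by
#' default, or an absolute value), binary closing of the edge contours,
#' hole filling, watershed splitting of touching particles on the
#' distance map, and removal of components outside
#' \code{[min_size_px, max_size_px]}. The size ceiling discards the filled
#' outline of the whole cell, which otherwise enters the label set
#' whenever the reference channel carries visible cytoplasmic signal;
#' the watershed separates sister kinetochores whose edge contours fuse
#' at close separations.
#'
#' @param img 2-D non-negative image (Y x X matrix).
#' @param edge_sigma smoothing scale of the edge detector, in px. The
#'   default of 2 px (slightly above the width of a diffraction-limited
#'   spot) acts as a matched filter: it keeps detection exact on clean
#'   data while remaining usable down to signal-to-noise ratios around 3.
#' @param threshold \code{"otsu"} or an absolute value on the gradient
#'   magnitude scale.
#' @param min_size_px,max_size_px component area limits in px.
#' @param close_radius diameter of the closing brush in px (odd).
#' @param watershed_tolerance minimum distance-map depth between two
#'   touching particles for them to be split; set \code{Inf} to disable
#'   splitting.
#' @return object of class \code{label_mask}: list with \code{labels}
#'   (integer Y x X matrix, 0 = background, labels consecutive) and
#'   \code{table} (per label: \code{label, area_px, y_px, x_px}).
#' @export
detect_particles <- function(img, edge_sigma = 2, threshold = "otsu",
                             min_size_px = 4L, max_size_px = 400L,
                             close_radius = 3L, watershed_tolerance = 0.5) {
  stopifnot(is.matrix(img))
  empty <- structure(list(labels = matrix(0L, nrow(img), ncol(img)),
                          table = .label_table(matrix(0L, 1, 1))),
                     class = "label_mask")
  if (diff(range(img)) == 0) return(empty)
  sm <- EBImage::gblur(img, sigma = edge_sigma)
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  grad <- sqrt(EBImage::filter2(sm, kx)^2 + EBImage::filter2(sm, t(kx))^2)
  if (identical(threshold, "otsu")) {
    gn <- (grad - min(grad)) / diff(range(grad))
    thr <- EBImage::otsu(EBImage::as.Image(gn))
    bw <- gn > thr
  } else {
    bw <- grad > threshold
  }
  bw <- EBImage::closing(bw, EBImage::makeBrush(close_radius, "disc"))
  bw <- EBImage::fillHull(bw)
  lab <- if (is.finite(watershed_tolerance))
    EBImage::watershed(EBImage::distmap(bw), tolerance = watershed_tolerance)
  else EBImage::bwlabel(bw)
  if (max(lab) == 0) return(empty)
  lab <- matrix(as.integer(round(lab)), nrow(img), ncol(img))
  areas <- table(lab[lab > 0])
  # the size floor is applied to a particle's bright core (pixels above the
  # midpoint between its peak and the image median), not to its filled edge
  # contour, whose area the detector inflates even for sub-resolution noise
  med <- stats::median(img)
  core_px <- vapply(as.integer(names(areas)), function(l) {
    v <- img[lab == l]
    sum(v > (max(v) + med) / 2)
  }, numeric(1))
  keep <- as.integer(names(areas))[core_px >= min_size_px &
                                   areas <= max_size_px]
  lab[!(lab %in% keep)] <- 0L
  # relabel consecutively without re-merging watershed-split particles
  lab[lab > 0] <- match(lab[lab > 0], sort(keep))
  if (!any(lab > 0)) return(empty)
  structure(list(labels = lab, table = .label_table(lab)),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat("<label_mask> ", nrow(x$table), " particles\n", sep = "")
  invisible(x)
}

#' Mean intensity of an image under each label of a mask
#'
#' @param mask a \code{label_mask} (or integer label matrix).
#' @param img image of the same shape; typically the measurement channel
#'   onto which the reference-channel mask is transferred.
#' @return data.frame \code{label, mean}.
#' @export
measure_in_mask <- function(mask, img) {
  labels <- if (inherits(mask, "label_mask")) mask$labels else mask
  if (!all(dim(labels) == dim(img)))
    stop("measure_in_mask: mask and image shapes differ")
  sel <- labels > 0
  if (!any(sel)) return(data.frame(label = integer(), mean = numeric()))
  lv <- labels[sel]
  data.frame(label = as.integer(names(tapply(img[sel], lv, mean))),
             mean = as.numeric(tapply(img[sel], lv, mean)))
}

#' Replace detected particles by fixed circular apertures
#'
#' Mean-in-mask intensities depend on how far the morphological mask
#' extends down the flank of a diffraction-limited spot, which varies with
#' noise and threshold. Standardizing every particle to a circular
#' aperture of fixed radius centred on its detected centroid removes that
#' mask-extent bias and makes ratios comparable across spots and
#' conditions (standard aperture photometry). Where apertures would
#' overlap, pixels go to the nearest centroid.
#'
#' @param mask a \code{label_mask}.
#' @param radius_px aperture radius in px.
#' @return a \code{label_mask} with one disk per original label (labels
#'   preserved).
#' @export
aperture_mask <- function(mask, radius_px = 3) {
  stopifnot(inherits(mask, "label_mask"))
  d <- dim(mask$labels)
  out <- matrix(0L, d[1], d[2])
  tb <- mask$table
  if (nrow(tb) == 0)
    return(structure(list(labels = out, table = tb), class = "label_mask"))
  bestd <- matrix(Inf, d[1], d[2])
  g <- .pixel_grids(d)
  for (i in seq_len(nrow(tb))) {
    cy <- tb$y_px[i] + 1; cx <- tb$x_px[i] + 1   # back to 1-based
    y0 <- max(1, floor(cy - radius_px)); y1 <- min(d[1], ceiling(cy + radius_px))
    x0 <- max(1, floor(cx - radius_px)); x1 <- min(d[2], ceiling(cx + radius_px))
    for (y in y0:y1) for (x in x0:x1) {
      dd <- (y - cy)^2 + (x - cx)^2
      if (dd <= radius_px^2 && dd < bestd[y, x]) {
        bestd[y, x] <- dd
        out[y, x] <- tb$label[i]
      }
    }
  }
  structure(list(labels = out, table = .label_table(out)),
            class = "label_mask")
}

#' Segment the cell and build a ring-shaped cytoplasm proxy
#'
#' The cell mask comes from the smoothed measurement-channel image and an
#' Otsu threshold, keeping the largest connected component with holes
#' filled. The ring is the erosion of the cell mask by
#' \code{erode_outer_px} minus the erosion by \code{erode_inner_px}
#' (inner > outer), with all pixels near detected particles excluded, so
#' its mean intensity is a cytoplasm proxy uncontaminated by kinetochore
#' signal or the cell boundary.
#'
#' @param meas_img measurement-channel image (Y x X matrix).
#' @param smooth_sigma Gaussian smoothing before thresholding, px.
#' @param erode_outer_px,erode_inner_px ring geometry, px.
#' @param particle_mask optional \code{label_mask} of detected particles
#'   to exclude from the ring.
#' @param particle_exclude_px dilation radius applied to particles before
#'   exclusion, px.
#' @return list \code{cell} and \code{ring}, both logical Y x X matrices.
#' @export
cell_and_ring <- function(meas_img, smooth_sigma = 4,
                          erode_outer_px = 5, erode_inner_px = 15,
                          particle_mask = NULL, particle_exclude_px = 3) {
  stopifnot(is.matrix(meas_img), erode_inner_px > erode_outer_px)
  if (diff(range(meas_img)) == 0) stop("no cell detected")
  sm <- EBImage::gblur(meas_img, sigma = smooth_sigma)
  smn <- (sm - min(sm)) / diff(range(sm))
  bw <- smn > EBImage::otsu(EBImage::as.Image(smn))
  bw <- EBImage::fillHull(bw)
  lab <- EBImage::bwlabel(bw)
  if (max(lab) == 0) stop("no cell detected")
  areas <- table(lab[lab > 0])
  cell <- lab == as.integer(names(areas)[which.max(areas)])
  cell <- matrix(as.logical(cell), nrow(meas_img), ncol(meas_img))
  brush <- function(r) EBImage::makeBrush(2L * as.integer(r) + 1L, "disc")
  ring <- EBImage::erode(cell, brush(erode_outer_px)) &
    !EBImage::erode(cell, brush(erode_inner_px))
  ring <- matrix(as.logical(ring), nrow(meas_img), ncol(meas_img))
  if (!is.null(particle_mask)) {
    pm <- (if (inherits(particle_mask, "label_mask")) particle_mask$labels
           else particle_mask) > 0
    pm <- EBImage::dilate(pm, brush(particle_exclude_px))
    ring <- ring & !matrix(as.logical(pm), nrow(meas_img), ncol(meas_img))
  }
  if (!any(ring)) stop("ring empty after particle exclusion")
  list(cell = cell, ring = ring)
}

#' Estimate the camera background as the modal intensity outside the cell
#'
#' The mode is located as the peak of a kernel density estimate over the
#' extracellular pixels, which is robust to the Poisson skew of the
#' signal. Falls back to the median when fewer than 50 pixels lie outside
#' the cell.
#'
#' @param img image (Y x X matrix).
#' @param cell_mask logical matrix from \code{\link{cell_and_ring}}.
#' @return scalar background level.
#' @export
estimate_background <- function(img, cell_mask) {
  v <- img[!cell_mask]
  if (length(v) < 50) return(stats::median(v))
  d <- stats::density(v, n = 512)
  d$x[which.max(d$y)]
}

#' Kinetochore/cytoplasm intensity ratio
#'
#' @param mean_meas per-particle mean measurement-channel intensities.
#' @param ring_mean mean intensity of the cytoplasm ring.
#' @param background camera background; subtracted from both numerator and
#'   denominator so the ratio is independent of the camera offset. Set to
#'   0 to reproduce the no-subtraction convention.
#' @return numeric vector \code{(mean_meas - background) /
#'   (ring_mean - background)}.
#' @export
kc_cyto_ratio <- function(mean_meas, ring_mean, background = 0) {
  if (ring_mean <= background)
    stop("cytoplasm indistinguishable from background")
  (mean_meas - background) / (ring_mean - background)
}

#' Score kinetochore enrichment into crescent classes
#'
#' Monotone step mapping of the kinetochore/cytoplasm ratio to the
#' qualitative classes used for crescent scoring. Thresholds default to
#' the quartiles of a control (wild-type) ratio distribution.
#'
#' @param ratios numeric vector of ratios.
#' @param thresholds increasing numeric vector \code{c(t_none, t_low,
#'   t_med)}: below \code{t_none} is \code{none}, then \code{low},
#'   \code{medium}, \code{high}.
#' @param control optional control ratios from which thresholds are taken
#'   as the 25/50/75 percent quantiles when \code{thresholds} is missing.
#' @return ordered factor with levels \code{none < low < medium < high}.
#' @export
crescent_class <- function(ratios, thresholds = NULL, control = NULL) {
  if (is.null(thresholds)) {
    if (is.null(control))
      stop("crescent_class: provide thresholds or a control distribution")
    thresholds <- unname(stats::quantile(control, c(0.25, 0.5, 0.75)))
  }
  if (length(thresholds) != 3 || is.unsorted(thresholds, strictly = TRUE))
    stop("crescent_class: thresholds must be strictly increasing (t_none < t_low < t_med)")
  cut(ratios, breaks = c(-Inf, thresholds, Inf),
      labels = c("none", "low", "medium", "high"),
      right = FALSE, ordered_result = TRUE)
}

#' Quantify kinetochore/cytoplasm ratios in one two-channel frame
#'
#' Runs the full per-frame measurement: detect particles in the reference
#' channel, standardize them to fixed apertures, transfer to the
#' measurement channel, segment cell and cytoplasm ring, estimate the
#' background and form per-particle ratios.
#'
#' @param ref_img,meas_img reference and measurement channel images.
#' @param frame frame index stored in the output.
#' @param aperture_radius_px aperture radius (see
#'   \code{\link{aperture_mask}}); set \code{NULL} to measure over the raw
#'   morphological mask.
#' @param background override for the estimated background (e.g. 0 for no
#'   subtraction).
#' @param ... passed to \code{\link{detect_particles}}.
#' @param ring_args list of arguments for \code{\link{cell_and_ring}}.
#' @return data.frame with columns \code{frame, label, y_px, x_px,
#'   area_px, mean_ref, mean_meas, cyto_mean, background, ratio}.
#' @export
quantify_frame <- function(ref_img, meas_img, frame = 1L,
                           aperture_radius_px = 3, background = NULL,
                           ring_args = list(), ...) {
  det <- detect_particles(ref_img, ...)
  meas_mask <- if (is.null(aperture_radius_px)) det
               else aperture_mask(det, aperture_radius_px)
  cr <- do.call(cell_and_ring,
                c(list(meas_img = meas_img, particle_mask = meas_mask),
                  ring_args))
  bg <- if (is.null(background)) estimate_background(meas_img, cr$cell)
        else background
  ring_mean <- mean(meas_img[cr$ring])
  tb <- det$table
  if (nrow(tb) == 0)
    return(data.frame(frame = integer(), label = integer(), y_px = numeric(),
                      x_px = numeric(), area_px = integer(),
                      mean_ref = numeric(), mean_meas = numeric(),
                      cyto_mean = numeric(), background = numeric(),
                      ratio = numeric()))
  mref <- measure_in_mask(meas_mask, ref_img)
  mmeas <- measure_in_mask(meas_mask, meas_img)
  ord <- match(tb$label, mref$label)
  data.frame(frame = frame, label = tb$label, y_px = tb$y_px,
             x_px = tb$x_px, area_px = tb$area_px,
             mean_ref = mref$mean[ord], mean_meas = mmeas$mean[ord],
             cyto_mean = ring_mean, background = bg,
             ratio = kc_cyto_ratio(mmeas$mean[ord], ring_mean, bg))
}

#' Quantify a whole time-lapse stack
#'
#' Z-projects the stack, then applies \code{\link{quantify_frame}} to each
#' frame. The default projection for quantification is the mean: unlike a
#' maximum projection it adds no positive noise bias to the cytoplasm ring
#' and background, and since defocus attenuates kinetochore and cytoplasm
#' signal alike the kinetochore/cytoplasm ratio is preserved.
#'
#' @param stack an \code{image_stack} with reference and measurement
#'   channel roles set.
#' @param projection \code{"mean"} (default) or \code{"max"}.
#' @param ... passed to \code{\link{quantify_frame}}.
#' @return data.frame, one row per particle per frame.
#' @export
quantify_stack <- function(stack, projection = "mean", ...) {
  stopifnot(inherits(stack, "image_stack"))
  proj <- project_stack(stack, projection)
  rc <- stack$reference_channel; mc <- stack$measurement_channel
  if (is.na(rc) || is.na(mc))
    stop("quantify_stack: stack needs reference and measurement channels")
  res <- lapply(seq_len(dim(proj)[1]), function(t) {
    quantify_frame(proj[t, rc, , ], proj[t, mc, , ], frame = t, ...)
  })
  do.call(rbind, res)
}
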