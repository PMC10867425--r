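# ImageStack container and TIFF I/O.
#
# Images are stored as a 5-D array with axes T x Z x C x Y x X. Pixel
# indices in all output tables are 0-based; physical coordinates are
# index * pixel_size_um.

#' Construct an image stack
#'
#' @param data numeric array with axes T x Z x C x Y x X (missing leading
#'   axes of a 2-4D array are inserted with size 1, assuming the trailing
#'   axes are Y, X).
#' @param channel_names character vector, one per channel.
#' @param reference_channel,measurement_channel channel names (or indices)
#'   carrying the centromere-marker reference and the fusion-protein
#'   measurement signal.
#' @param pixel_size_um,z_step_um,frame_interval_min acquisition geometry;
#'   all positive.
#' @return object of class \code{image_stack}.
#' @export
image_stack <- function(data, channel_names = NULL,
                        reference_channel = 1L, measurement_channel = NULL,
                        pixel_size_um = 0.1, z_step_um = 0.6,
                        frame_interval_min = 6) {
  nd <- length(dim(data))
  if (is.null(dim(data)) || nd < 2 || nd > 5)
    stop("image_stack: data must be a 2- to 5-D array")
  if (nd < 5) {
    newdim <- c(rep(1L, 5 - nd), dim(data))
    data <- array(data, dim = newdim)
  }
  stopifnot(pixel_size_um > 0, z_step_um > 0, frame_interval_min > 0)
  nc <- dim(data)[3]
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(nc))
  if (length(channel_names) != nc)
    stop("image_stack: need one channel name per channel")
  resolve <- function(ch) {
    if (is.null(ch)) return(NA_integer_)
    if (is.character(ch)) {
      i <- match(ch, channel_names)
      if (is.na(i)) stop("image_stack: unknown channel '", ch, "'")
      return(i)
    }
    as.integer(ch)
  }
  structure(list(data = data, channel_names = channel_names,
                 reference_channel = resolve(reference_channel),
                 measurement_channel = resolve(
                   if (is.null(measurement_channel) && nc >= 2) 2L
                   else measurement_channel),
                 pixel_size_um = pixel_size_um, z_step_um = z_step_um,
                 frame_interval_min = frame_interval_min),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat("<image_stack> T=", d[1], " Z=", d[2], " C=", d[3],
      " Y=", d[4], " X=", d[5],
      "  pixel ", x$pixel_size_um, " um, frame ", x$frame_interval_min,
      " min\n", sep = "")
  invisible(x)
}

#' Project an image stack over Z
#'
#' @param stack an \code{image_stack}.
#' @param method \code{"max"} (default) or \code{"mean"} intensity
#'   projection.
#' @return numeric array T x C x Y x X.
#' @export
project_stack <- function(stack, method = c("max", "mean")) {
  method <- match.arg(method)
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  out <- array(0, dim = d[c(1, 3, 4, 5)])
  f <- if (method == "max") function(a) apply(a, c(2, 3), max)
       else function(a) apply(a, c(2, 3), mean)
  for (t in seq_len(d[1])) for (c in seq_len(d[3])) {
    planes <- stack$data[t, , c, , , drop = FALSE]
    dim(planes) <- d[c(2, 4, 5)]
    out[t, c, , ] <- if (d[2] == 1) planes[1, , ] else f(planes)
  }
  out
}

#' Write an image stack to TIFF with a JSON metadata sidecar
#'
#' Pages are written in T-major, then Z, then C order; the acquisition
#' geometry, axis sizes and channel roles go to \code{<path>.meta.json}
#' so that \code{\link{read_stack}} can restore the stack losslessly.
#' Intensities are stored as 32-bit floats.
#'
#' @param stack an \code{image_stack}.
#' @param path output TIFF path.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  pages <- list()
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) for (c in seq_len(d[3])) {
    img <- stack$data[t, z, c, , ]
    dim(img) <- d[4:5]
    pages[[length(pages) + 1]] <- img
  }
  offset <- min(stack$data)
  scale <- max(1e-12, max(stack$data) - offset)
  tiff::writeTIFF(lapply(pages, function(p) (p - offset) / scale), path,
                  bits.per.sample = 32L)
  meta <- list(dim = d, scale = scale, offset = offset,
               channel_names = stack$channel_names,
               reference_channel = stack$reference_channel,
               measurement_channel = stack$measurement_channel,
               pixel_size_um = stack$pixel_size_um,
               z_step_um = stack$z_step_um,
               frame_interval_min = stack$frame_interval_min)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack from TIFF
#'
#' Reads a TIFF written by \code{\link{write_stack}} (using its JSON
#' sidecar), or a plain single/multi-page TIFF, in which case the pages
#' are mapped to axes via \code{axes_hint} and the geometry arguments.
#'
#' @param path TIFF path.
#' @param axes_hint for plain TIFFs: integer vector \code{c(T, Z, C)}
#'   giving how pages factor into frames, planes and channels (T-major
#'   page order); defaults to all pages being time points of a
#'   single-channel, single-plane stack.
#' @param pixel_size_um,z_step_um,frame_interval_min geometry overrides
#'   for plain TIFFs.
#' @return an \code{image_stack}.
#' @export
read_stack <- function(path, axes_hint = NULL, pixel_size_um = 0.1,
                       z_step_um = 0.6, frame_interval_min = 6) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  metapath <- paste0(path, ".meta.json")
  if (file.exists(metapath)) {
    meta <- jsonlite::read_json(metapath, simplifyVector = TRUE)
    d <- as.integer(meta$dim)
    data <- array(0, dim = d)
    i <- 1
    off <- if (is.null(meta$offset)) 0 else meta$offset
    for (t in seq_len(d[1])) for (z in seq_len(d[2])) for (c in seq_len(d[3])) {
      data[t, z, c, , ] <- pages[[i]] * meta$scale + off
      i <- i + 1
    }
    return(image_stack(data, channel_names = meta$channel_names,
                       reference_channel = meta$reference_channel,
                       measurement_channel = meta$measurement_channel,
                       pixel_size_um = meta$pixel_size_um,
                       z_step_um = meta$z_step_um,
                       frame_interval_min = meta$frame_interval_min))
  }
  np <- length(pages)
  if (is.null(axes_hint)) axes_hint <- c(np, 1L, 1L)
  if (prod(axes_hint) != np)
    stop("read_stack: axes_hint ", paste(axes_hint, collapse = "x"),
         " does not match ", np, " pages; candidate factorizations: ",
         paste(apply(cbind(np, 1, 1), 1, paste, collapse = "x"),
               collapse = ", "))
  dyx <- dim(pages[[1]])
  data <- array(0, dim = c(axes_hint, dyx))
  i <- 1
  for (t in seq_len(axes_hint[1])) for (z in seq_len(axes_hint[2]))
    for (c in seq_len(axes_hint[3])) {
      data[t, z, c, , ] <- pages[[i]]
      i <- i + 1
    }
  image_stack(data, pixel_size_um = pixel_size_um, z_step_um = z_step_um,
              frame_interval_min = frame_interval_min)
}
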