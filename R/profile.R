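# 1D intensity profiles and their extraction from 2D micrographs along a
# traced cord polyline.

#' Construct a 1D intensity profile
#'
#' The fundamental container of the package: a calibrated line scan along a
#' neuronal cord. Positions are arc-length coordinates in micrometres,
#' strictly increasing with uniform spacing; intensities are non-negative
#' arbitrary units. The exclusion mask marks samples (cell bodies, image
#' artifacts, out-of-bounds regions) that are ignored by punctum detection
#' and by all PF/IPF sums.
#'
#' @param positions_um Strictly increasing, uniformly spaced positions (um).
#' @param intensities Non-negative intensities (AU), same length.
#' @param pixel_size_um Pixel size in um used for calibration.
#' @param exclude_mask Logical vector, `TRUE` = excluded; defaults to none.
#' @return Object of class `intensity_profile`.
#' @export
intensity_profile <- function(positions_um, intensities, pixel_size_um,
                              exclude_mask = NULL) {
  n <- length(positions_um)
  if (n < 2L) stop("a profile needs at least 2 samples", call. = FALSE)
  if (length(intensities) != n) {
    stop("positions and intensities must have equal length", call. = FALSE)
  }
  d <- diff(positions_um)
  if (any(d <= 0)) {
    stop("positions_um must be strictly increasing", call. = FALSE)
  }
  if (max(d) - min(d) > 1e-6 * max(d)) {
    stop("positions_um must be uniformly spaced", call. = FALSE)
  }
  if (any(!is.finite(intensities)) || any(intensities < 0)) {
    stop("intensities must be finite and non-negative", call. = FALSE)
  }
  if (is.null(exclude_mask)) exclude_mask <- rep(FALSE, n)
  stopifnot(is.logical(exclude_mask), length(exclude_mask) == n)
  structure(
    list(positions_um = as.numeric(positions_um),
         intensities = as.numeric(intensities),
         pixel_size_um = pixel_size_um,
         exclude_mask = exclude_mask),
    class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf(
    "<intensity_profile> %d samples, span %.2f-%.2f um, %d excluded\n",
    length(x$intensities), x$positions_um[1],
    x$positions_um[length(x$positions_um)], sum(x$exclude_mask)))
  invisible(x)
}

#' Construct a cord trace polyline
#'
#' Vertices are 0-based pixel coordinates with `x` = column and `y` = row,
#' pixel centres at integer coordinates. Consecutive vertices must be
#' distinct.
#'
#' @param x,y Numeric vertex coordinates (>= 2 vertices).
#' @return A two-column matrix of class `polyline` (columns `x`, `y`).
#' @export
polyline <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  m <- cbind(x = as.numeric(x), y = as.numeric(y))
  if (any(rowSums(abs(diff(m))) == 0)) {
    stop("consecutive polyline vertices must be distinct", call. = FALSE)
  }
  structure(m, class = c("polyline", class(m)))
}

as_polyline <- function(tr) {
  if (inherits(tr, "polyline")) return(tr)
  tr <- as.matrix(tr)
  if (ncol(tr) != 2L) stop("a trace needs two columns (x, y)", call. = FALSE)
  polyline(tr[, 1], tr[, 2])
}

# Segment bookkeeping: unit tangents, per-segment and cumulative lengths.
polyline_segments <- function(trace) {
  dv <- diff(unclass(trace))
  len <- sqrt(rowSums(dv^2))
  list(dir = dv / len, len = len, cum = c(0, cumsum(len)),
       total_len = sum(len))
}

# Point on the polyline at arc length s (pixels from the first vertex).
point_at_arclen <- function(trace, seg, s) {
  s <- min(max(s, 0), seg$total_len)
  k <- findInterval(s, seg$cum, rightmost.closed = TRUE)
  k <- min(k, length(seg$len))
  unclass(trace)[k, ] + (s - seg$cum[k]) * seg$dir[k, ]
}

# Unit tangent at arc length s (constant within a segment).
tangent_at_arclen <- function(seg, s) {
  k <- findInterval(min(max(s, 0), seg$total_len), seg$cum,
                    rightmost.closed = TRUE)
  seg$dir[min(k, length(seg$len)), ]
}

# Bilinear interpolation of image values at continuous 0-based (x = column,
# y = row) coordinates. Returns NA outside [0, nc-1] x [0, nr-1].
bilinear_interp <- function(image, x, y) {
  nr <- nrow(image); nc <- ncol(image)
  out <- rep(NA_real_, length(x))
  ok <- x >= 0 & x <= nc - 1 & y >= 0 & y <= nr - 1
  if (!any(ok)) return(out)
  xo <- x[ok]; yo <- y[ok]
  x0 <- pmin(floor(xo), nc - 2); y0 <- pmin(floor(yo), nr - 2)
  fx <- xo - x0; fy <- yo - y0
  i <- y0 + 1; j <- x0 + 1
  v <- (1 - fx) * (1 - fy) * image[cbind(i, j)] +
    fx * (1 - fy) * image[cbind(i, j + 1)] +
    (1 - fx) * fy * image[cbind(i + 1, j)] +
    fx * fy * image[cbind(i + 1, j + 1)]
  out[ok] <- v
  out
}

#' Extract a line-scan intensity profile along a traced cord
#'
#' Samples the trace polyline at uniform arc-length steps of (nominally) one
#' pixel with bilinear interpolation. At each sample the reported intensity
#' is the maximum over `2 * half_width_px + 1` points spaced 1 px apart
#' along the local perpendicular, which makes the scan robust to sub-pixel
#' tracing error on thin cords (set `aggregate = "mean"` for averaging
#' instead). Perpendicular points falling outside the image are ignored in
#' the aggregation rather than zero-filled; samples with no in-bounds point
#' at all are flagged in the exclusion mask.
#'
#' The step is adjusted to divide the total trace length evenly (step =
#' L / round(L) pixels), so the profile span equals the trace length exactly.
#'
#' @param image Numeric matrix (grayscale micrograph, AU).
#' @param trace A [polyline()] or two-column x,y matrix (0-based pixels).
#' @param pixel_size_um Micrometres per pixel (> 0).
#' @param half_width_px Half-width of the perpendicular scan in px (>= 0).
#' @param aggregate `"max"` (default) or `"mean"` across the perpendicular.
#' @return An [intensity_profile()].
#' @export
extract_profile <- function(image, trace, pixel_size_um, half_width_px = 2,
                            aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  stopifnot(is.matrix(image), is.numeric(image))
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be a positive number", call. = FALSE)
  }
  half_width_px <- as.integer(half_width_px)
  stopifnot(half_width_px >= 0L)
  trace <- as_polyline(trace)
  nr <- nrow(image); nc <- ncol(image)
  if (any(trace[, 1] < 0) || any(trace[, 1] > nc - 1) ||
      any(trace[, 2] < 0) || any(trace[, 2] > nr - 1)) {
    stop("trace lies outside image bounds", call. = FALSE)
  }

  seg <- polyline_segments(trace)
  n_steps <- max(1L, as.integer(round(seg$total_len)))
  step <- seg$total_len / n_steps
  s <- (0:n_steps) * step

  offs <- seq(-half_width_px, half_width_px)
  inten <- numeric(length(s))
  excl <- logical(length(s))
  for (k in seq_along(s)) {
    p <- point_at_arclen(trace, seg, s[k])
    tg <- tangent_at_arclen(seg, s[k])
    nx <- -tg[2]; ny <- tg[1]
    vals <- bilinear_interp(image, p[1] + offs * nx, p[2] + offs * ny)
    vals <- vals[!is.na(vals)]
    if (!length(vals)) {
      inten[k] <- 0
      excl[k] <- TRUE
    } else {
      inten[k] <- if (aggregate == "max") max(vals) else mean(vals)
    }
  }
  # positions offset by half a step so spacing stays uniform and positive
  intensity_profile((s + step / 2) * pixel_size_um, pmax(inten, 0),
                    pixel_size_um, exclude_mask = excl)
}

#' Mask profile regions (cell bodies, artifacts) from quantification
#'
#' Sets the exclusion mask on the union of the given micrometre intervals.
#' Masked samples are excluded from punctum detection and from all PF/IPF
#' sums downstream, mirroring the practice of quantifying synaptic signal
#' outside of cell bodies.
#'
#' @param profile An [intensity_profile()].
#' @param intervals_um List of `c(start, end)` pairs (um), start < end,
#'   within the profile span.
#' @return The profile with an updated exclusion mask.
#' @export
mask_regions <- function(profile, intervals_um) {
  stopifnot(inherits(profile, "intensity_profile"))
  if (!length(intervals_um)) return(profile)
  if (is.numeric(intervals_um) && length(intervals_um) == 2L) {
    intervals_um <- list(intervals_um)
  }
  pos <- profile$positions_um
  span <- range(pos)
  mask <- profile$exclude_mask
  for (iv in intervals_um) {
    if (length(iv) != 2L || !is.numeric(iv)) {
      stop("each interval must be numeric c(start, end)", call. = FALSE)
    }
    if (iv[1] >= iv[2]) {
      stop(sprintf("inverted interval [%g, %g]: start must be < end",
                   iv[1], iv[2]), call. = FALSE)
    }
    if (iv[2] < span[1] || iv[1] > span[2]) {
      stop(sprintf("interval [%g, %g] lies outside the profile span [%g, %g]",
                   iv[1], iv[2], span[1], span[2]), call. = FALSE)
    }
    mask <- mask | (pos >= iv[1] & pos <= iv[2])
  }
  profile$exclude_mask <- mask
  profile
}
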