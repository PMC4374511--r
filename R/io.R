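# Format plumbing: strict readers and writers for the package's on-disk
# artifacts. Malformed input is rejected with a descriptive error, never
# silently coerced.

#' Read a grayscale TIFF micrograph
#'
#' Accepts single-plane 8- or 16-bit grayscale TIFFs and returns the image
#' as a numeric matrix in native integer units. RGB / multi-channel and
#' multi-plane files are rejected.
#'
#' @param path Path to a TIFF file.
#' @return Numeric matrix (rows x cols, AU).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  planes <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (length(planes) != 1L) {
    stop("expected a single-plane TIFF, got ", length(planes), " planes",
         call. = FALSE)
  }
  img <- planes[[1]]
  if (length(dim(img)) == 3L) {
    stop("expected a single-channel grayscale TIFF, got ", dim(img)[3],
         " channels (RGB/RGBA input is not supported)", call. = FALSE)
  }
  storage.mode(img) <- "double"
  img
}

#' Write a grayscale 16-bit TIFF
#'
#' Values are clamped to `[0, 65535]` and rounded to integers.
#'
#' @param image Numeric matrix (AU).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(is.matrix(image))
  v <- round(pmin(pmax(image, 0), 65535))
  tiff::writeTIFF(v / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a cord trace
#'
#' JSON traces are a list of `[x, y]` pairs; CSV traces have columns
#' `x`, `y`. Coordinates are 0-based pixels, x = column.
#'
#' @param path Path to a `.json` or `.csv` trace file.
#' @return A [polyline()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    m <- jsonlite::fromJSON(path)
    if (!is.matrix(m) || ncol(m) != 2L) {
      stop("trace JSON must be a list of [x, y] pairs", call. = FALSE)
    }
    polyline(m[, 1], m[, 2])
  } else {
    d <- utils::read.csv(path)
    if (!all(c("x", "y") %in% names(d))) {
      stop("trace CSV must have columns x, y", call. = FALSE)
    }
    polyline(d$x, d$y)
  }
}

#' Write a cord trace as JSON
#' @param trace A [polyline()].
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  trace <- as_polyline(trace)
  jsonlite::write_json(unname(apply(unclass(trace), 1, c, simplify = FALSE)),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read / write intensity profiles as CSV
#'
#' Profile CSVs have columns `position_um`, `intensity` and optionally
#' `excluded` (0/1). Positions must be strictly increasing and uniformly
#' spaced; shuffled or corrupted files are rejected.
#'
#' @param path CSV path.
#' @param pixel_size_um Pixel size recorded on the returned profile; by
#'   default inferred from the position spacing.
#' @return [intensity_profile()] for `read_profile()`.
#' @export
read_profile <- function(path, pixel_size_um = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- utils::read.csv(path)
  need <- c("position_um", "intensity")
  if (!all(need %in% names(d))) {
    stop("profile CSV must have columns position_um, intensity",
         call. = FALSE)
  }
  if (any(diff(d$position_um) <= 0)) {
    stop("profile positions must be strictly increasing (rows out of order?)",
         call. = FALSE)
  }
  if (is.null(pixel_size_um)) pixel_size_um <- stats::median(diff(d$position_um))
  mask <- if ("excluded" %in% names(d)) d$excluded != 0 else NULL
  intensity_profile(d$position_um, d$intensity, pixel_size_um,
                    exclude_mask = mask)
}

#' @rdname read_profile
#' @param profile An [intensity_profile()].
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "intensity_profile"))
  utils::write.csv(
    data.frame(position_um = profile$positions_um,
               intensity = profile$intensities,
               excluded = as.integer(profile$exclude_mask)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a ground-truth punctum table as CSV
#' @param truth A `scene_truth` from [make_profile()] or [make_image()].
#' @param path Output CSV path (columns `position_um`, `amplitude`).
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "scene_truth"))
  utils::write.csv(
    data.frame(position_um = truth$punctum_positions_um,
               amplitude = truth$punctum_amplitudes),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a ground-truth punctum table written by [write_truth()]
#' @param path CSV path.
#' @return Data.frame with columns `position_um`, `amplitude`.
#' @export
read_truth <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("position_um", "amplitude") %in% names(d))) {
    stop("truth CSV must have columns position_um, amplitude", call. = FALSE)
  }
  d
}
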