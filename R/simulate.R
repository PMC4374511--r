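# Synthetic-scene generation: 1D line-scan profiles and 2D micrographs with
# ground-truth punctum tables. Stands in for undeposited imaging data so the
# whole quantification pipeline can be exercised against known truth.

# Deterministic child seed for independent sub-streams (placement vs noise),
# kept below 2^31 - 1.
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) %% 1048573) * 2039 + 7919 * stream) %% 2147483629L
}

# Evaluate `expr` under a pinned, seeded RNG without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

# Uniform punctum placement along [margin, span - margin] with a minimum
# pairwise separation enforced by rejection sampling. Returns sorted
# positions; may return fewer than n if the cord is too crowded to fit them.
place_puncta <- function(n, span_um, min_sep_um = 2, margin_um = 2) {
  if (n == 0L || span_um <= 2 * margin_um) return(numeric(0))
  pos <- numeric(0)
  attempts <- 0L
  while (length(pos) < n && attempts < 1000L * n) {
    cand <- stats::runif(1, margin_um, span_um - margin_um)
    if (!length(pos) || min(abs(pos - cand)) >= min_sep_um) pos <- c(pos, cand)
    attempts <- attempts + 1L
  }
  sort(pos)
}

# Poisson-Gaussian camera model applied to a clean signal in AU.
# gain is AU per photon: y = gain * Pois(s / gain) + N(0, read_sd).
# gain = 0 switches the photon branch off.
apply_camera_noise <- function(signal, gain, read_sd) {
  y <- signal
  if (gain > 0) y <- gain * stats::rpois(length(signal), signal / gain)
  if (read_sd > 0) y <- y + stats::rnorm(length(signal), 0, read_sd)
  pmax(y, 0)
}

new_scene_truth <- function(positions, amplitudes, preset, seed,
                            soma_positions = numeric(0)) {
  stopifnot(length(positions) == length(amplitudes))
  structure(
    list(punctum_positions_um = positions,
         punctum_amplitudes = amplitudes,
         soma_positions_um = soma_positions,
         preset = preset,
         seed = as.integer(seed)),
    class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("<scene_truth> preset=%s seed=%d puncta=%d soma_blobs=%d\n",
              x$preset$name, x$seed, length(x$punctum_positions_um),
              length(x$soma_positions_um)))
  invisible(x)
}

# Draw punctum count, positions and raw amplitudes for one scene. Cord
# above-offset signal is later scaled by (1 - soma_fraction); the removed
# share reappears as soma blobs placed at the cord ends.
draw_scene <- function(preset, length_um, seed) {
  with_seed(child_seed(seed, 1L), {
    n <- stats::rpois(1, preset$punctum_density * length_um)
    pos <- place_puncta(n, length_um)
    amp <- pmax(stats::rnorm(length(pos), preset$amplitude_mean,
                             preset$amplitude_sd), 0)
    list(positions = pos, amplitudes = amp)
  })
}

#' Simulate a 1D line-scan intensity profile with ground truth
#'
#' Generates one synthetic line-scan along a cord of the given length. The
#' punctum count is Poisson with mean `punctum_density * length_um`; puncta
#' are placed uniformly with a 2 um minimum separation (rejection sampling)
#' and rendered as Gaussian bumps of width `punctum_sigma_um` on top of
#' `diffuse_level + camera_offset`. For presets with `soma_fraction > 0`,
#' that fraction of the above-offset signal is moved into two wide soma
#' blobs near the profile ends and the cord signal is scaled down
#' accordingly. Poisson shot noise (scaled by `noise_gain`) and Gaussian
#' read noise are then applied.
#'
#' Placement and noise use independent seeded sub-streams, so the punctum
#' configuration is reusable across noise realisations. Identical arguments
#' give bit-identical output.
#'
#' @param preset A [genotype_preset()].
#' @param length_um Cord length in micrometres (> 0).
#' @param pixel_size_um Sampling step in micrometres per pixel (> 0).
#' @param seed Integer seed; required for reproducibility.
#' @return A list with elements `profile` (an [intensity_profile()]) and
#'   `truth` (a `scene_truth` with punctum positions/amplitudes, soma
#'   positions, preset and seed).
#' @examples
#' sc <- make_profile(preset_library()$wild_type, 100, 0.1, seed = 1)
#' length(sc$truth$punctum_positions_um)
#' @export
make_profile <- function(preset, length_um, pixel_size_um, seed) {
  stopifnot(inherits(preset, "genotype_preset"))
  if (!is.numeric(length_um) || length_um <= 0) {
    stop("length_um must be a positive number", call. = FALSE)
  }
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be a positive number", call. = FALSE)
  }
  if (missing(seed) || is.null(seed)) stop("seed must be given", call. = FALSE)
  seed <- as.integer(seed)

  n_px <- max(2L, as.integer(round(length_um / pixel_size_um)))
  positions <- (seq_len(n_px) - 0.5) * pixel_size_um

  sc <- draw_scene(preset, length_um, seed)
  # clean above-offset cord signal at full (unscaled) strength
  unscaled <- rep(preset$diffuse_level, n_px)
  for (i in seq_along(sc$positions)) {
    unscaled <- unscaled + sc$amplitudes[i] *
      exp(-(positions - sc$positions[i])^2 / (2 * preset$punctum_sigma_um^2))
  }
  clean <- unscaled * (1 - preset$soma_fraction)

  soma_pos <- numeric(0)
  if (preset$soma_fraction > 0) {
    unscaled_total <- sum(unscaled)
    soma_sigma_um <- 2
    soma_pos <- c(min(4, length_um / 4), length_um - min(4, length_um / 4))
    soma_total <- preset$soma_fraction * unscaled_total
    soma_amp <- soma_total * pixel_size_um /
      (length(soma_pos) * sqrt(2 * pi) * soma_sigma_um)
    for (sp in soma_pos) {
      clean <- clean + soma_amp *
        exp(-(positions - sp)^2 / (2 * soma_sigma_um^2))
    }
  }

  clean <- clean + preset$camera_offset
  noisy <- with_seed(child_seed(seed, 2L), {
    apply_camera_noise(clean, preset$noise_gain, preset$read_noise_sd)
  })

  list(profile = intensity_profile(positions, noisy, pixel_size_um),
       truth = new_scene_truth(sc$positions,
                               sc$amplitudes * (1 - preset$soma_fraction),
                               preset, seed, soma_positions = soma_pos))
}

#' Simulate a 2D grayscale micrograph with ground truth
#'
#' 2D counterpart of [make_profile()] for end-to-end tests of profile
#' extraction. The cord is rendered as a Gaussian ridge of cross-section
#' `cord_sigma_um` along the trace polyline; puncta are isotropic 2D
#' Gaussians centred on the trace at their arc-length positions; for
#' `soma_fraction > 0` the corresponding share of the above-offset signal
#' is rendered as two large blobs at the trace endpoints. The camera noise
#' model is identical to [make_profile()].
#'
#' @param preset A [genotype_preset()].
#' @param shape_px Integer vector `c(rows, cols)`.
#' @param trace A [polyline()] in pixel coordinates (0-based, x = column),
#'   lying inside the image bounds.
#' @param pixel_size_um Micrometres per pixel (> 0).
#' @param seed Integer seed.
#' @param cord_sigma_um Cross-sectional width of the diffuse cord ridge (um).
#' @return List with `image` (numeric matrix, AU) and `truth`
#'   (`scene_truth`; punctum positions are arc-length um along the trace).
#' @export
make_image <- function(preset, shape_px, trace, pixel_size_um, seed,
                       cord_sigma_um = 0.3) {
  stopifnot(inherits(preset, "genotype_preset"))
  shape_px <- as.integer(shape_px)
  if (length(shape_px) != 2L || any(shape_px <= 0L)) {
    stop("shape_px must be positive c(rows, cols)", call. = FALSE)
  }
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be a positive number", call. = FALSE)
  }
  trace <- as_polyline(trace)
  nr <- shape_px[1]; nc <- shape_px[2]
  if (any(trace[, 1] < 0) || any(trace[, 1] > nc - 1) ||
      any(trace[, 2] < 0) || any(trace[, 2] > nr - 1)) {
    stop("trace lies outside image bounds", call. = FALSE)
  }
  seed <- as.integer(seed)

  seg <- polyline_segments(trace)
  length_um <- seg$total_len * pixel_size_um
  sc <- draw_scene(preset, length_um, seed)

  # pixel-centre coordinate grids (0-based, x = column, y = row)
  xs <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  ys <- matrix(rep(0:(nr - 1), times = nc), nr, nc)

  # diffuse ridge: distance from each pixel to the polyline
  d <- dist_to_polyline(xs, ys, trace)
  cord_sigma_px <- cord_sigma_um / pixel_size_um
  clean <- preset$diffuse_level * exp(-d^2 / (2 * cord_sigma_px^2))

  sigma_px <- preset$punctum_sigma_um / pixel_size_um
  for (i in seq_along(sc$positions)) {
    p <- point_at_arclen(trace, seg, sc$positions[i] / pixel_size_um)
    clean <- clean + sc$amplitudes[i] *
      exp(-((xs - p[1])^2 + (ys - p[2])^2) / (2 * sigma_px^2))
  }

  unscaled_total <- sum(clean)
  clean <- clean * (1 - preset$soma_fraction)

  soma_pos <- numeric(0)
  if (preset$soma_fraction > 0) {
    soma_sigma_px <- 2 / pixel_size_um
    ends <- trace[c(1, nrow(trace)), , drop = FALSE]
    soma_total <- preset$soma_fraction * unscaled_total
    soma_amp <- soma_total / (nrow(ends) * 2 * pi * soma_sigma_px^2)
    for (k in seq_len(nrow(ends))) {
      clean <- clean + soma_amp *
        exp(-((xs - ends[k, 1])^2 + (ys - ends[k, 2])^2) /
              (2 * soma_sigma_px^2))
    }
    soma_pos <- c(0, length_um)
  }

  clean <- clean + preset$camera_offset
  noisy <- with_seed(child_seed(seed, 2L), {
    matrix(apply_camera_noise(as.vector(clean), preset$noise_gain,
                              preset$read_noise_sd), nr, nc)
  })

  list(image = noisy,
       truth = new_scene_truth(sc$positions,
                               sc$amplitudes * (1 - preset$soma_fraction),
                               preset, seed, soma_positions = soma_pos))
}

# Minimum Euclidean distance from points (x, y) to a polyline, via
# point-to-segment projection over all segments.
dist_to_polyline <- function(x, y, trace) {
  d2 <- NULL
  for (k in seq_len(nrow(trace) - 1L)) {
    a <- trace[k, ]; b <- trace[k + 1L, ]
    vx <- b[1] - a[1]; vy <- b[2] - a[2]
    len2 <- vx^2 + vy^2
    t <- pmin(pmax(((x - a[1]) * vx + (y - a[2]) * vy) / len2, 0), 1)
    dk2 <- (x - (a[1] + t * vx))^2 + (y - (a[2] + t * vy))^2
    d2 <- if (is.null(d2)) dk2 else pmin(d2, dk2)
  }
  sqrt(d2)
}
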