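# Punctum calling and per-animal quantification.
#
# The two reported statistics are puncta number (PN) and synaptic enrichment
# (SE). Both derive from splitting the line scan into punctal fluorescence
# (PF; samples inside called punctum extents) and inter-punctal fluorescence
# (IPF; samples between puncta). A candidate peak is called a punctum when
# its peak intensity divided by the average IPF is >= 2 (inclusive); SE is
# the ratio of summed PF to summed IPF over a 100-um analysis window. PF and
# IPF are mutually defining, so the calling rule is resolved by a fixed-point
# iteration that only ever shrinks the punctal set.

#' Quantification parameters
#'
#' @param ratio_threshold Punctum-calling threshold on peak / average IPF;
#'   inclusive, must be > 1. Default 2.
#' @param window_length_um Length of the analysis window for PN and SE (um),
#'   centred on the profile midpoint. Default 100.
#' @param window_offset_um Shift of the window centre from the profile
#'   midpoint (um). Default 0.
#' @param min_separation_um Minimum separation between candidate peaks (um);
#'   of two closer local maxima only the higher survives (ties: the leftmost).
#'   Default 1.
#' @param min_prominence Minimum topographic prominence of a candidate (AU).
#'   Default 0: the ratio rule alone governs calling.
#' @param extent_rule Punctum boundary rule; only `"half_max"` is defined:
#'   the maximal contiguous interval around the peak where intensity stays at
#'   or above `avg_ipf + (peak - avg_ipf) / 2`.
#' @param max_iterations Cap on fixed-point iterations in [call_puncta()].
#' @param smooth_window_um Optional moving-average pre-smoothing window (um);
#'   `0` (default) disables smoothing.
#' @param subtract_offset Camera offset (AU) subtracted from intensities
#'   before any ratio or sum is formed; default 0 (off).
#' @return Object of class `quant_params`.
#' @export
quant_params <- function(ratio_threshold = 2,
                         window_length_um = 100,
                         window_offset_um = 0,
                         min_separation_um = 1,
                         min_prominence = 0,
                         extent_rule = "half_max",
                         max_iterations = 100L,
                         smooth_window_um = 0,
                         subtract_offset = 0) {
  if (!is.numeric(ratio_threshold) || ratio_threshold <= 1) {
    stop("ratio_threshold must be > 1", call. = FALSE)
  }
  if (!is.numeric(window_length_um) || window_length_um <= 0) {
    stop("window_length_um must be > 0", call. = FALSE)
  }
  max_iterations <- as.integer(max_iterations)
  if (max_iterations < 1L) stop("max_iterations must be >= 1", call. = FALSE)
  extent_rule <- match.arg(extent_rule, "half_max")
  stopifnot(min_separation_um >= 0, min_prominence >= 0,
            smooth_window_um >= 0, subtract_offset >= 0)
  structure(
    list(ratio_threshold = ratio_threshold,
         window_length_um = window_length_um,
         window_offset_um = window_offset_um,
         min_separation_um = min_separation_um,
         min_prominence = min_prominence,
         extent_rule = extent_rule,
         max_iterations = max_iterations,
         smooth_window_um = smooth_window_um,
         subtract_offset = subtract_offset),
    class = "quant_params")
}

# Working intensities after optional offset subtraction and smoothing.
prepared_intensities <- function(profile, params) {
  y <- profile$intensities
  if (params$subtract_offset > 0) y <- pmax(y - params$subtract_offset, 0)
  if (params$smooth_window_um > 0) {
    w <- max(1L, as.integer(round(params$smooth_window_um /
                                    profile$pixel_size_um)))
    if (w %% 2L == 0L) w <- w + 1L
    if (w > 1L) y <- stats::filter(y, rep(1 / w, w), sides = 2) |>
        (\(z) ifelse(is.na(z), y, as.numeric(z)))()
  }
  y
}

# Local maxima (with plateau handling) inside one run of consecutive
# unmasked samples. Returns indices relative to the run. Run endpoints are
# never maxima; a plateau reports its centre sample.
run_local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  peaks <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] > y[i - 1L]) {
      j <- i
      while (j < n && y[j + 1L] == y[i]) j <- j + 1L
      if (j <= n - 1L && y[j + 1L] < y[i]) {
        peaks <- c(peaks, (i + j) %/% 2L)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  peaks
}

# Topographic prominence of peak at index p within run values y: height
# above the higher of the two key saddles (minima between the peak and the
# nearest strictly higher sample on each side, or the run edge).
peak_prominence <- function(y, p) {
  n <- length(y)
  li <- p
  while (li > 1L && y[li - 1L] <= y[p]) li <- li - 1L
  left_min <- min(y[li:p])
  ri <- p
  while (ri < n && y[ri + 1L] <= y[p]) ri <- ri + 1L
  right_min <- min(y[p:ri])
  y[p] - max(left_min, right_min)
}

#' Detect candidate peaks on a profile
#'
#' Finds all unmasked interior local maxima (plateaus report their centre
#' sample), filters by topographic prominence, and enforces the minimum
#' separation: a maximum is suppressed when a strictly higher local maximum
#' — or an equally high one to its left — lies within `min_separation_um`.
#' Masked samples split the profile into independent runs; run boundaries do
#' not generate candidates.
#'
#' @param profile An [intensity_profile()].
#' @param params A [quant_params()].
#' @return A data.frame with columns `index`, `position_um`, `intensity`,
#'   `prominence`, ordered by position.
#' @export
detect_candidates <- function(profile, params = quant_params()) {
  stopifnot(inherits(profile, "intensity_profile"),
            inherits(params, "quant_params"))
  keep <- !profile$exclude_mask
  if (!any(keep)) stop("profile is fully masked", call. = FALSE)
  y <- prepared_intensities(profile, params)
  pos <- profile$positions_um

  runs <- rle(keep)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  idx <- integer(0)
  prom <- numeric(0)
  for (r in which(runs$values)) {
    a <- starts[r]; b <- ends[r]
    pk <- run_local_maxima(y[a:b])
    for (p in pk) {
      pr <- peak_prominence(y[a:b], p)
      if (pr >= params$min_prominence) {
        idx <- c(idx, a + p - 1L)
        prom <- c(prom, pr)
      }
    }
  }
  if (length(idx) > 1L && params$min_separation_um > 0) {
    keep_pk <- vapply(seq_along(idx), function(i) {
      near <- abs(pos[idx] - pos[idx[i]]) < params$min_separation_um &
        seq_along(idx) != i
      if (!any(near)) return(TRUE)
      higher <- y[idx[near]] > y[idx[i]]
      equal_left <- y[idx[near]] == y[idx[i]] & idx[near] < idx[i]
      !any(higher | equal_left)
    }, logical(1))
    idx <- idx[keep_pk]
    prom <- prom[keep_pk]
  }
  data.frame(index = idx, position_um = pos[idx], intensity = y[idx],
             prominence = prom)
}

#' Punctum extent by the half-max rule
#'
#' The extent of a punctum is the maximal contiguous interval of samples
#' around the peak whose intensity stays at or above
#' `avg_ipf + (peak - avg_ipf) / 2` (half way between baseline and peak).
#' The walk stops at masked samples; the extent is never empty (minimum one
#' sample, the peak itself).
#'
#' @param profile An [intensity_profile()].
#' @param peak_index Sample index of the candidate peak.
#' @param avg_ipf Current average inter-punctal fluorescence (AU, >= 0).
#' @param params A [quant_params()].
#' @return Integer vector `c(start, end)` of sample indices (inclusive).
#' @export
punctum_extent <- function(profile, peak_index, avg_ipf,
                           params = quant_params()) {
  y <- prepared_intensities(profile, params)
  keep <- !profile$exclude_mask
  n <- length(y)
  thr <- avg_ipf + (y[peak_index] - avg_ipf) / 2
  a <- peak_index
  while (a > 1L && keep[a - 1L] && y[a - 1L] >= thr) a <- a - 1L
  b <- peak_index
  while (b < n && keep[b + 1L] && y[b + 1L] >= thr) b <- b + 1L
  c(a, b)
}

# Extents for a set of peak indices under a given avg_ipf, clipped so that
# extents of adjacent puncta never overlap: an overlapping pair is split at
# the lowest sample between the two peaks (ties: leftmost).
extents_for <- function(profile, peaks, avg_ipf, params) {
  if (!length(peaks)) return(matrix(integer(0), ncol = 2))
  peaks <- sort(peaks)
  ext <- t(vapply(peaks, function(p) {
    punctum_extent(profile, p, avg_ipf, params)
  }, integer(2)))
  if (nrow(ext) > 1L) {
    y <- prepared_intensities(profile, params)
    for (i in seq_len(nrow(ext) - 1L)) {
      if (ext[i, 2] >= ext[i + 1L, 1]) {
        between <- (peaks[i] + 1L):(peaks[i + 1L] - 1L)
        cut <- if (length(between)) between[which.min(y[between])] else peaks[i]
        ext[i, 2] <- max(min(ext[i, 2], cut - 1L), peaks[i])
        ext[i + 1L, 1] <- min(max(ext[i + 1L, 1], cut + 1L), peaks[i + 1L])
      }
    }
  }
  ext
}

# Logical vector: TRUE on samples covered by any extent row.
extent_mask <- function(n, ext) {
  m <- logical(n)
  for (i in seq_len(nrow(ext))) m[ext[i, 1]:ext[i, 2]] <- TRUE
  m
}

#' Call puncta by the peak / average-IPF ratio rule
#'
#' Implements the punctum definition: a candidate peak is a punctum when its
#' peak intensity divided by the average inter-punctal fluorescence is at or
#' above the threshold (default 2, inclusive). Because the IPF baseline is
#' itself defined by which samples are punctal, the rule is resolved by a
#' fixed point: starting from all candidates, the IPF implied by the current
#' set is computed (extents and the mean outside them are mutually
#' dependent, so they are iterated to convergence first); candidates whose
#' peak falls below the ratio against that converged IPF are dropped and the
#' loop repeats until the set is unchanged. Dropping a (dim) punctum moves
#' its samples into the IPF, so the set only ever shrinks and the iteration
#' terminates in at most one pass per candidate.
#'
#' @param profile An [intensity_profile()].
#' @param params A [quant_params()].
#' @return A list with `puncta` (data.frame: `peak_position_um`,
#'   `peak_intensity`, `peak_index`, `ratio`, `extent_start_um`,
#'   `extent_end_um`, `extent_start_index`, `extent_end_index`), `avg_ipf`
#'   (AU), and `flags` (named logical: `zero_ipf`, `not_converged`).
#' @export
call_puncta <- function(profile, params = quant_params()) {
  cand <- detect_candidates(profile, params)
  y <- prepared_intensities(profile, params)
  keep <- !profile$exclude_mask
  pos <- profile$positions_um
  n <- length(y)
  flags <- c(zero_ipf = FALSE, not_converged = FALSE)

  # IPF implied by a punctal set: iterate extents <-> mean-outside-extents
  # to a fixed point, starting from the global unmasked mean.
  implied_ipf <- function(peaks) {
    ipf <- mean(y[keep])
    for (i in seq_len(params$max_iterations)) {
      ext <- extents_for(profile, peaks, ipf, params)
      outside <- keep & !extent_mask(n, ext)
      if (!any(outside)) return(list(ipf = NA_real_, ext = ext, ok = TRUE))
      new_ipf <- mean(y[outside])
      if (isTRUE(all.equal(new_ipf, ipf, tolerance = 1e-12))) {
        return(list(ipf = new_ipf, ext = ext, ok = TRUE))
      }
      ipf <- new_ipf
    }
    list(ipf = ipf, ext = extents_for(profile, peaks, ipf, params), ok = FALSE)
  }

  peaks <- cand$index
  avg_ipf <- mean(y[keep])
  ext <- extents_for(profile, peaks, avg_ipf, params)
  for (it in seq_len(params$max_iterations)) {
    st <- implied_ipf(peaks)
    if (!st$ok) flags["not_converged"] <- TRUE
    if (is.na(st$ipf)) {
      flags["zero_ipf"] <- TRUE
      break
    }
    avg_ipf <- st$ipf
    ext <- st$ext
    retained <- peaks[y[peaks] / avg_ipf >= params$ratio_threshold]
    if (identical(retained, peaks)) break
    peaks <- retained
    if (it == params$max_iterations) flags["not_converged"] <- TRUE
  }
  ext <- extents_for(profile, peaks, avg_ipf, params)

  if (length(peaks)) {
    puncta <- data.frame(
      peak_position_um = pos[peaks],
      peak_intensity = y[peaks],
      peak_index = peaks,
      ratio = y[peaks] / avg_ipf,
      extent_start_um = pos[ext[, 1]],
      extent_end_um = pos[ext[, 2]],
      extent_start_index = ext[, 1],
      extent_end_index = ext[, 2])
  } else {
    puncta <- data.frame(
      peak_position_um = numeric(0), peak_intensity = numeric(0),
      peak_index = integer(0), ratio = numeric(0),
      extent_start_um = numeric(0), extent_end_um = numeric(0),
      extent_start_index = integer(0), extent_end_index = integer(0))
  }
  list(puncta = puncta, avg_ipf = avg_ipf, flags = flags)
}

#' Synaptic enrichment and puncta number over the analysis window
#'
#' The analysis window is `window_length_um` long (default 100 um), centred
#' on the profile midpoint; if the profile is shorter the whole profile is
#' used and flagged as truncated. Within the window, total PF is the sum of
#' unmasked intensities inside punctum extents, total IPF the sum outside
#' them; SE = total PF / total IPF. PN counts puncta whose peak lies in the
#' window. With no puncta in the window SE is defined as 0 (flagged); with
#' an empty IPF the ratio is undefined and reported as `NA` (flagged).
#'
#' @param profile An [intensity_profile()].
#' @param called Result of [call_puncta()] on the same profile.
#' @param params A [quant_params()].
#' @return Object of class `profile_quant`: a list with `pn`, `se`,
#'   `total_pf`, `total_ipf`, `avg_ipf`, `window_um` (`c(start, end)`),
#'   `flags` (named logical: `no_puncta`, `zero_ipf`, `window_truncated`,
#'   `all_masked`, `not_converged`) and the punctum table `puncta`.
#' @export
synaptic_enrichment <- function(profile, called, params = quant_params()) {
  stopifnot(inherits(profile, "intensity_profile"))
  y <- prepared_intensities(profile, params)
  pos <- profile$positions_um
  keep <- !profile$exclude_mask
  n <- length(y)

  span <- c(pos[1], pos[n])
  centre <- mean(span) + params$window_offset_um
  w <- c(centre - params$window_length_um / 2,
         centre + params$window_length_um / 2)
  truncated <- FALSE
  if (w[1] < span[1] || w[2] > span[2]) {
    w <- c(max(w[1], span[1]), min(w[2], span[2]))
    truncated <- TRUE
  }
  in_win <- pos >= w[1] & pos <= w[2]
  if (!any(in_win)) stop("analysis window is empty", call. = FALSE)

  flags <- c(no_puncta = FALSE,
             zero_ipf = unname(called$flags["zero_ipf"]),
             window_truncated = truncated,
             all_masked = FALSE,
             not_converged = unname(called$flags["not_converged"]))

  if (!any(keep & in_win)) {
    flags["all_masked"] <- TRUE
    out <- list(pn = 0L, se = NA_real_, total_pf = 0, total_ipf = 0,
                avg_ipf = called$avg_ipf, window_um = w, flags = flags,
                puncta = called$puncta)
    class(out) <- "profile_quant"
    return(out)
  }

  pm <- logical(n)
  if (nrow(called$puncta)) {
    ext <- cbind(called$puncta$extent_start_index,
                 called$puncta$extent_end_index)
    pm <- extent_mask(n, ext)
  }
  total_pf <- sum(y[keep & in_win & pm])
  total_ipf <- sum(y[keep & in_win & !pm])
  pn <- sum(called$puncta$peak_position_um >= w[1] &
              called$puncta$peak_position_um <= w[2])

  if (pn == 0L) {
    flags["no_puncta"] <- TRUE
    se <- 0
  } else if (total_ipf == 0) {
    flags["zero_ipf"] <- TRUE
    se <- NA_real_
  } else {
    se <- total_pf / total_ipf
  }
  out <- list(pn = as.integer(pn), se = se, total_pf = total_pf,
              total_ipf = total_ipf, avg_ipf = called$avg_ipf,
              window_um = w, flags = flags, puncta = called$puncta)
  class(out) <- "profile_quant"
  out
}

#' @export
print.profile_quant <- function(x, ...) {
  cat(sprintf(
    "<profile_quant> PN = %d, SE = %s (window %.1f-%.1f um)\n",
    x$pn, ifelse(is.na(x$se), "NA", sprintf("%.3f", x$se)),
    x$window_um[1], x$window_um[2]))
  fl <- names(x$flags)[x$flags]
  if (length(fl)) cat("  flags:", paste(fl, collapse = ", "), "\n")
  invisible(x)
}

#' Quantify one animal's line scan
#'
#' Composition of [detect_candidates()], [call_puncta()] and
#' [synaptic_enrichment()]: the full per-animal measurement, deterministic
#' for fixed input and parameters.
#'
#' @param profile An [intensity_profile()].
#' @param params A [quant_params()].
#' @return A `profile_quant` (see [synaptic_enrichment()]).
#' @examples
#' sc <- make_profile(preset_library()$wild_type, 120, 0.1, seed = 7)
#' quantify_animal(sc$profile)
#' @export
quantify_animal <- function(profile, params = quant_params()) {
  called <- call_puncta(profile, params)
  synaptic_enrichment(profile, called, params)
}

#' @rdname quantify_animal
#' @param quant A `profile_quant`.
#' @param animal_id Identifier recorded in the row.
#' @return `as_quant_row()`: a one-row data.frame suitable for the
#'   per-animal CSV (columns `animal_id`, `pn`, `se`, `total_pf`,
#'   `total_ipf`, `avg_ipf`, `window_start_um`, `window_end_um`, `flags`).
#' @export
as_quant_row <- function(quant, animal_id = NA_character_) {
  stopifnot(inherits(quant, "profile_quant"))
  data.frame(
    animal_id = animal_id,
    pn = quant$pn,
    se = quant$se,
    total_pf = quant$total_pf,
    total_ipf = quant$total_ipf,
    avg_ipf = quant$avg_ipf,
    window_start_um = quant$window_um[1],
    window_end_um = quant$window_um[2],
    flags = paste(names(quant$flags)[quant$flags], collapse = ";"))
}
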