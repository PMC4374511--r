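# Independent oracles used by the test suite. Each reimplements the checked
# quantity by brute force (dense resampling, exhaustive search, subset
# enumeration, direct summation, permutation), staying structurally
# independent of the package code paths it verifies.

# --- profile extraction: dense-resampling oracle ---------------------------
# Walks the polyline at 0.01-px arc-length steps, then linearly interpolates
# the bracketing dense points to evaluate any arc-length position; each
# perpendicular sample is bilinearly interpolated on its own.
oracle_extract_profile <- function(image, trace, pixel_size_um,
                                   half_width_px) {
  tr <- unclass(punctaquant::polyline(trace[, 1], trace[, 2]))
  # dense resampling of the polyline
  dense <- list(tr[1, , drop = FALSE])
  for (k in seq_len(nrow(tr) - 1L)) {
    a <- tr[k, ]; b <- tr[k + 1L, ]
    len <- sqrt(sum((b - a)^2))
    ts <- unique(c(seq(0.01 / len, 1, by = 0.01 / len), 1))
    dense[[k + 1L]] <- cbind(a[1] + ts * (b[1] - a[1]),
                             a[2] + ts * (b[2] - a[2]))
  }
  dense <- do.call(rbind, dense)
  darc <- c(0, cumsum(sqrt(rowSums(diff(dense)^2))))
  total <- darc[length(darc)]

  n_steps <- max(1L, as.integer(round(total)))
  step <- total / n_steps
  s <- (0:n_steps) * step

  interp1 <- function(img, x, y) {
    nr <- nrow(img); nc <- ncol(img)
    if (x < 0 || x > nc - 1 || y < 0 || y > nr - 1) return(NA_real_)
    x0 <- min(floor(x), nc - 2); y0 <- min(floor(y), nr - 2)
    fx <- x - x0; fy <- y - y0
    (1 - fx) * (1 - fy) * img[y0 + 1, x0 + 1] +
      fx * (1 - fy) * img[y0 + 1, x0 + 2] +
      (1 - fx) * fy * img[y0 + 2, x0 + 1] +
      fx * fy * img[y0 + 2, x0 + 2]
  }
  point_at <- function(si) {
    i <- findInterval(min(max(si, 0), total), darc, rightmost.closed = TRUE)
    i <- min(i, nrow(dense) - 1L)
    w <- if (darc[i + 1L] > darc[i]) (si - darc[i]) / (darc[i + 1L] - darc[i]) else 0
    dense[i, ] + w * (dense[i + 1L, ] - dense[i, ])
  }
  tangent_at <- function(si) {
    # direction of the segment the arc position falls in
    i <- findInterval(min(max(si, 0), total), darc, rightmost.closed = TRUE)
    i <- min(i, nrow(dense) - 1L)
    d <- dense[i + 1L, ] - dense[i, ]
    d / sqrt(sum(d^2))
  }
  vals <- numeric(length(s))
  for (k in seq_along(s)) {
    p <- point_at(s[k]); tg <- tangent_at(s[k])
    offs <- seq(-half_width_px, half_width_px)
    v <- vapply(offs, function(o) {
      interp1(image, p[1] - o * tg[2], p[2] + o * tg[1])
    }, numeric(1))
    v <- v[!is.na(v)]
    vals[k] <- if (length(v)) max(v) else 0
  }
  list(positions_um = (s + step / 2) * pixel_size_um, intensities = vals)
}

# --- candidate detection: exhaustive O(n^2) oracle -------------------------
# Tests every sample directly against the definitions: plateau-aware local
# maxima inside unmasked runs, prominence by exhaustive valley search, and
# the order-free separation rule (suppressed iff a strictly higher maximum,
# or an equally high one to the left, lies within min_separation_um).
oracle_candidates <- function(profile, params) {
  y <- profile$intensities
  if (params$subtract_offset > 0) y <- pmax(y - params$subtract_offset, 0)
  keep <- !profile$exclude_mask
  pos <- profile$positions_um
  n <- length(y)
  run_id <- cumsum(c(TRUE, diff(keep) != 0))
  maxima <- integer(0)
  for (i in seq_len(n)) {
    if (!keep[i]) next
    # plateau of equal values around i within the same run
    l <- i
    while (l > 1L && keep[l - 1L] && run_id[l - 1L] == run_id[i] &&
           y[l - 1L] == y[i]) l <- l - 1L
    r <- i
    while (r < n && keep[r + 1L] && run_id[r + 1L] == run_id[i] &&
           y[r + 1L] == y[i]) r <- r + 1L
    left_ok <- l > 1L && keep[l - 1L] && run_id[l - 1L] == run_id[i] &&
      y[l - 1L] < y[i]
    right_ok <- r < n && keep[r + 1L] && run_id[r + 1L] == run_id[i] &&
      y[r + 1L] < y[i]
    if (left_ok && right_ok && i == (l + r) %/% 2L) maxima <- c(maxima, i)
  }
  # exhaustive prominence
  prom <- vapply(maxima, function(p) {
    run <- which(keep & run_id == run_id[p])
    left <- run[run < p & y[run] > y[p]]
    lo <- if (length(left)) max(left) + 1L else min(run)
    right <- run[run > p & y[run] > y[p]]
    hi <- if (length(right)) min(right) - 1L else max(run)
    y[p] - max(min(y[lo:p]), min(y[p:hi]))
  }, numeric(1))
  maxima <- maxima[prom >= params$min_prominence]
  prom <- prom[prom >= params$min_prominence]
  if (length(maxima) > 1L && params$min_separation_um > 0) {
    drop <- vapply(seq_along(maxima), function(i) {
      any(vapply(seq_along(maxima), function(j) {
        j != i &&
          abs(pos[maxima[j]] - pos[maxima[i]]) < params$min_separation_um &&
          (y[maxima[j]] > y[maxima[i]] ||
             (y[maxima[j]] == y[maxima[i]] && maxima[j] < maxima[i]))
      }, logical(1)))
    }, logical(1))
    maxima <- maxima[!drop]
  }
  maxima
}

# --- punctum extent: linear left/right walk oracle -------------------------
oracle_extent <- function(profile, peak, avg_ipf) {
  y <- profile$intensities
  keep <- !profile$exclude_mask
  thr <- avg_ipf + (y[peak] - avg_ipf) / 2
  a <- peak
  while (a > 1L && keep[a - 1L] && y[a - 1L] >= thr) a <- a - 1L
  b <- peak
  while (b < length(y) && keep[b + 1L] && y[b + 1L] >= thr) b <- b + 1L
  c(a, b)
}

# Extents for a peak set under an IPF estimate, overlap split at the lowest
# inter-peak sample, mirroring the documented boundary rule.
oracle_extents_for <- function(profile, peaks, avg_ipf) {
  if (!length(peaks)) return(matrix(integer(0), ncol = 2))
  peaks <- sort(peaks)
  ext <- t(vapply(peaks, function(p) oracle_extent(profile, p, avg_ipf),
                  integer(2)))
  y <- profile$intensities
  if (nrow(ext) > 1L) {
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

# IPF implied by a fixed punctal subset: iterate extents <-> mean-outside to
# a fixed point starting from the global unmasked mean.
oracle_subset_ipf <- function(profile, peaks, max_iter = 60) {
  y <- profile$intensities
  keep <- !profile$exclude_mask
  ipf <- mean(y[keep])
  for (it in seq_len(max_iter)) {
    ext <- oracle_extents_for(profile, peaks, ipf)
    inside <- logical(length(y))
    for (i in seq_len(nrow(ext))) inside[ext[i, 1]:ext[i, 2]] <- TRUE
    out <- keep & !inside
    if (!any(out)) return(NA_real_)
    new_ipf <- mean(y[out])
    if (isTRUE(all.equal(new_ipf, ipf, tolerance = 1e-12))) return(new_ipf)
    ipf <- new_ipf
  }
  ipf
}

# Exhaustive subset-enumeration oracle for punctum calling: over all 2^k
# subsets of the k candidates, keep the self-consistent ones (every member's
# peak / implied-IPF ratio >= threshold) and return those of maximal size.
oracle_call_subsets <- function(profile, params) {
  cand <- punctaquant::detect_candidates(profile, params)$index
  k <- length(cand)
  if (k == 0L) return(list(integer(0)))
  y <- profile$intensities
  consistent <- list()
  for (code in 0:(2^k - 1)) {
    sel <- cand[bitwAnd(bitwShiftR(code, 0:(k - 1)), 1L) == 1L]
    ipf <- oracle_subset_ipf(profile, sel)
    if (is.na(ipf)) next
    if (all(y[sel] / ipf >= params$ratio_threshold)) {
      consistent[[length(consistent) + 1L]] <- sel
    }
  }
  sizes <- vapply(consistent, length, integer(1))
  consistent[sizes == max(sizes)]
}

# --- synaptic enrichment: direct-summation oracle --------------------------
oracle_se <- function(profile, quant) {
  y <- profile$intensities
  pos <- profile$positions_um
  keep <- !profile$exclude_mask
  w <- quant$window_um
  inside <- logical(length(y))
  if (nrow(quant$puncta)) {
    for (i in seq_len(nrow(quant$puncta))) {
      inside[quant$puncta$extent_start_index[i]:
               quant$puncta$extent_end_index[i]] <- TRUE
    }
  }
  pf <- 0; ipf <- 0; pn <- 0L
  for (i in seq_along(y)) {
    if (pos[i] < w[1] || pos[i] > w[2] || !keep[i]) next
    if (inside[i]) pf <- pf + y[i] else ipf <- ipf + y[i]
  }
  for (i in seq_len(nrow(quant$puncta))) {
    p <- quant$puncta$peak_position_um[i]
    if (p >= w[1] && p <= w[2]) pn <- pn + 1L
  }
  se <- if (pn == 0L) 0 else if (ipf == 0) NA_real_ else pf / ipf
  list(pn = pn, se = se, total_pf = pf, total_ipf = ipf)
}

# --- permutation oracle for the two-sample t-test --------------------------
oracle_perm_p <- function(a, b, n_perm = 20000, seed = 1) {
  pooled_t <- function(x, y) {
    nx <- length(x); ny <- length(y)
    sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
      (nx + ny - 2)
    (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  }
  obs <- abs(pooled_t(a, b))
  z <- c(a, b)
  na <- length(a)
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(z), na)
    if (abs(pooled_t(z[idx], z[-idx])) >= obs - 1e-12) hits <- hits + 1L
  }
  hits / n_perm
}

# --- shared fixtures -------------------------------------------------------
# Preset with ratios straddling the threshold, noiseless: used wherever the
# oracle needs exactly reproducible candidate sets.
straddle_preset <- function() {
  genotype_preset("straddle", punctum_density = 0.25,
                  amplitude_mean = 50, amplitude_sd = 25,
                  punctum_sigma_um = 0.5, diffuse_level = 20,
                  camera_offset = 10, noise_gain = 0, read_noise_sd = 0)
}

# Noisy wild-type-like preset for stochastic properties.
wt_preset <- function() preset_library()$wild_type
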