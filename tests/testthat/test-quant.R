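# Helper: profile from raw intensities at 0.1-um spacing.
raw_profile <- function(y, px = 0.1) {
  intensity_profile((seq_along(y) - 0.5) * px, y, px)
}

# Helper: flat baseline with a single-sample spike (avg IPF = baseline
# exactly, so the calling ratio is peak / baseline with no shoulder bias).
spike_profile <- function(peak, baseline, n = 201, at = 101) {
  y <- rep(baseline, n)
  y[at] <- peak
  raw_profile(y)
}

test_that("monotone profiles have no candidate peaks", {
  expect_identical(nrow(detect_candidates(raw_profile(1:50))), 0L)
  expect_identical(nrow(detect_candidates(raw_profile(50:1))), 0L)
  expect_identical(nrow(detect_candidates(raw_profile(rep(3, 50)))), 0L)
})

test_that("a single noiseless bump yields one candidate at its centre", {
  x <- (1:300 - 0.5) * 0.1
  y <- 10 + 40 * exp(-(x - 15)^2 / (2 * 0.5^2))
  cand <- detect_candidates(raw_profile(y))
  expect_identical(nrow(cand), 1L)
  expect_equal(cand$position_um, 15, tolerance = 0.05)
})

test_that("plateau maxima report their centre sample", {
  y <- c(1, 1, 5, 5, 5, 1, 1)
  cand <- detect_candidates(raw_profile(y))
  expect_identical(cand$index, 4L)
})

test_that("candidate detection matches the exhaustive oracle on seeded profiles", {
  params <- quant_params(min_separation_um = 1.5, min_prominence = 3)
  for (s in 1:30) {
    sc <- make_profile(wt_preset(), 40, 0.1, seed = s)
    pr <- sc$profile
    if (s %% 3 == 0) pr <- mask_regions(pr, list(c(12, 18)))
    got <- detect_candidates(pr, params)$index
    expect_identical(got, oracle_candidates(pr, params), label = paste("seed", s))
  }
})

test_that("flat profiles call no puncta", {
  q <- quantify_animal(raw_profile(rep(6, 400)))
  expect_identical(q$pn, 0L)
  expect_identical(q$se, 0)
  expect_true(q$flags["no_puncta"])
})

test_that("a triangular peak of height 10 on baseline 4 is one punctum", {
  y <- rep(4, 400)
  y[196:206] <- c(4 + 1.2 * (1:5), 10, 4 + 1.2 * (5:1))
  called <- call_puncta(raw_profile(y))
  expect_identical(nrow(called$puncta), 1L)
  expect_equal(called$puncta$ratio, 2.5, tolerance = 0.05)
})

test_that("the calling threshold is inclusive at ratio exactly 2", {
  called <- call_puncta(spike_profile(8, 4))
  expect_identical(nrow(called$puncta), 1L)
  expect_equal(called$puncta$ratio, 2)
  # just below threshold: rejected
  expect_identical(nrow(call_puncta(spike_profile(7.99, 4))$puncta), 0L)
})

test_that("punctum calling matches the subset-enumeration oracle", {
  params <- quant_params()
  tested <- 0L
  for (s in 1:40) {
    sc <- make_profile(straddle_preset(), 30, 0.1, seed = s)
    cand <- detect_candidates(sc$profile, params)
    if (nrow(cand) > 10L) next
    got <- sort(call_puncta(sc$profile, params)$puncta$peak_index)
    best <- oracle_call_subsets(sc$profile, params)
    expect_identical(length(got), length(best[[1]]),
                     label = paste("size, seed", s))
    expect_true(any(vapply(best, function(b) identical(sort(b), got),
                           logical(1))), label = paste("membership, seed", s))
    tested <- tested + 1L
  }
  expect_gte(tested, 30L)
})

test_that("punctum extent recovers the FWHM of a Gaussian punctum", {
  x <- (1:400 - 0.5) * 0.1
  sigma <- 0.8
  y <- 10 + 60 * exp(-(x - 20)^2 / (2 * sigma^2))
  pr <- raw_profile(y)
  called <- call_puncta(pr)
  width <- called$puncta$extent_end_um - called$puncta$extent_start_um
  # FWHM = 2 sqrt(2 ln 2) sigma, allowing a little for the elevated IPF
  # baseline (Gaussian shoulders raise avg_ipf slightly above 10)
  expect_equal(width, 2.3548 * sigma, tolerance = 0.1)
})

test_that("a degenerate peak of baseline height gets a single-sample extent", {
  pr <- spike_profile(8, 8)  # no local maximum at all -> no candidates
  expect_identical(nrow(detect_candidates(pr)), 0L)
  # direct extent query with peak == avg_ipf: half-max threshold == peak
  pr2 <- spike_profile(9, 8)
  ext <- punctum_extent(pr2, 101L, 9)
  expect_identical(ext, c(101L, 101L))
})

test_that("extents match a linear left/right walk oracle", {
  for (s in 1:15) {
    sc <- make_profile(wt_preset(), 40, 0.1, seed = 100 + s)
    called <- call_puncta(sc$profile)
    ipf <- called$avg_ipf
    for (i in seq_len(nrow(called$puncta))) {
      raw <- oracle_extent(sc$profile, called$puncta$peak_index[i], ipf)
      got <- c(called$puncta$extent_start_index[i],
               called$puncta$extent_end_index[i])
      # package extents may only be clipped inwards by the overlap rule
      expect_gte(got[1], raw[1])
      expect_lte(got[2], raw[2])
      expect_true(got[1] <= called$puncta$peak_index[i] &&
                    got[2] >= called$puncta$peak_index[i])
    }
    # when no extents touch, the walk oracle must agree exactly
    ext <- cbind(called$puncta$extent_start_index,
                 called$puncta$extent_end_index)
    if (nrow(ext) > 1L && all(diff(as.vector(t(ext))) > 0)) {
      raws <- t(vapply(called$puncta$peak_index, function(p) {
        oracle_extent(sc$profile, p, ipf)
      }, integer(2)))
      overlap_free <- all(raws[-nrow(raws), 2] < raws[-1, 1])
      if (overlap_free) expect_identical(ext, raws)
    }
  }
})

test_that("extents of distinct puncta are disjoint", {
  for (s in 1:15) {
    sc <- make_profile(preset_library()$enlarged_puncta, 60, 0.1, seed = s)
    p <- call_puncta(sc$profile)$puncta
    if (nrow(p) < 2) next
    expect_true(all(p$extent_start_index[-1] > p$extent_end_index[-nrow(p)]))
  }
})

test_that("synaptic enrichment is total PF over total IPF", {
  # bookkeeping example: punctal samples sum 300, inter-punctal sum 100
  y <- rep(1, 150)
  y[71:80] <- 30  # plateau punctum: 10 samples x 30 = 300 AU
  pr <- raw_profile(y, px = 0.1)
  q <- quantify_animal(pr, quant_params(window_length_um = 15))
  expect_identical(q$pn, 1L)
  expect_equal(q$total_pf, 300)
  expect_equal(q$total_ipf, 140 * 1)
  expect_equal(q$se, 300 / 140)
})

test_that("synaptic enrichment matches the direct-summation oracle", {
  for (s in 1:25) {
    sc <- make_profile(wt_preset(), 120, 0.1, seed = 200 + s)
    pr <- if (s %% 4 == 0) mask_regions(sc$profile, list(c(30, 40))) else sc$profile
    q <- quantify_animal(pr)
    o <- oracle_se(pr, q)
    expect_identical(q$pn, o$pn)
    expect_equal(q$total_pf, o$total_pf, tolerance = 1e-12)
    expect_equal(q$total_ipf, o$total_ipf, tolerance = 1e-12)
    expect_equal(q$se, o$se, tolerance = 1e-12)
  }
})

test_that("two well-separated peaks give PN = 2", {
  x <- (1:1200 - 0.5) * 0.1
  y <- 5 + 50 * exp(-(x - 40)^2 / (2 * 0.5^2)) +
    55 * exp(-(x - 80)^2 / (2 * 0.5^2))
  q <- quantify_animal(raw_profile(y))
  expect_identical(q$pn, 2L)
})

test_that("PN and SE are invariant under intensity gain but not offset", {
  sc <- make_profile(wt_preset(), 120, 0.1, seed = 33)
  q0 <- quantify_animal(sc$profile)
  for (c_gain in c(0.1, 10)) {
    pr <- sc$profile
    pr$intensities <- pr$intensities * c_gain
    q <- quantify_animal(pr)
    expect_identical(q$pn, q0$pn)
    expect_equal(q$se, q0$se, tolerance = 1e-12)
  }
  # a large additive offset dilutes the ratio rule and must change the result
  pr <- sc$profile
  pr$intensities <- pr$intensities + 500
  q_off <- quantify_animal(pr)
  expect_false(q_off$pn == q0$pn && isTRUE(all.equal(q_off$se, q0$se)))
})

test_that("PN is additive across profiles joined by a long flat spacer", {
  x1 <- (1:500 - 0.5) * 0.1
  y1 <- 5 + 60 * exp(-(x1 - 15)^2 / (2 * 0.4^2)) +
    70 * exp(-(x1 - 35)^2 / (2 * 0.4^2))
  y2 <- 5 + 80 * exp(-(x1 - 25)^2 / (2 * 0.4^2))
  params <- quant_params(window_length_um = 1000)
  pn1 <- quantify_animal(raw_profile(y1), params)$pn
  pn2 <- quantify_animal(raw_profile(y2), params)$pn
  joined <- raw_profile(c(y1, rep(5, 400), y2))
  expect_identical(quantify_animal(joined, params)$pn, pn1 + pn2)
})

test_that("the fixed point terminates within the candidate count", {
  # descending peak heights on a shared baseline force sequential dropping
  x <- (1:2000 - 0.5) * 0.1
  y <- rep(10, 2000)
  for (i in 1:8) {
    y <- y + (34 - 3 * i) * exp(-(x - 20 * i)^2 / (2 * 0.5^2))
  }
  called <- call_puncta(raw_profile(y), quant_params(max_iterations = 9))
  expect_false(called$flags["not_converged"])
})

test_that("window handling: truncation and centring", {
  sc <- make_profile(wt_preset(), 60, 0.1, seed = 4)
  q <- quantify_animal(sc$profile)  # default window 100 > span 60
  expect_true(q$flags["window_truncated"])
  expect_equal(q$window_um, range(sc$profile$positions_um))
  q2 <- quantify_animal(sc$profile, quant_params(window_length_um = 30))
  expect_false(q2$flags["window_truncated"])
  expect_equal(mean(q2$window_um), 30, tolerance = 0.01)
  expect_equal(diff(q2$window_um), 30)
})

test_that("mean SE rises with punctum amplitude and falls with diffuse level", {
  base <- list(punctum_density = 0.3, amplitude_sd = 10,
               punctum_sigma_um = 0.5, camera_offset = 10,
               noise_gain = 1, read_noise_sd = 2)
  mean_se <- function(amp, diff_level) {
    p <- do.call(genotype_preset,
                 c(list(name = "v", amplitude_mean = amp,
                        diffuse_level = diff_level), base))
    mean(vapply(1:50, function(s) {
      quantify_animal(make_profile(p, 60, 0.1, seed = s)$profile,
                      quant_params(window_length_um = 50))$se
    }, numeric(1)))
  }
  expect_gt(mean_se(220, 20), mean_se(150, 20))
  expect_gt(mean_se(150, 12), mean_se(150, 25))
})
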