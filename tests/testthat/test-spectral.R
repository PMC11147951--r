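test_that("cosine taper matches the split-cosine-bell ramp", {
  x <- rep(1, 100)
  tapered <- cosine_taper(x, 0.1)
  # exactly the first and last 10 points are scaled
  expect_equal(which(tapered != x), c(1:10, 91:100))
  # the ramp is R's split cosine bell (independent oracle: stats::spec.taper)
  expect_equal(tapered, as.numeric(stats::spec.taper(x, 0.1)),
               tolerance = 1e-12)
  # p = 0 leaves the series untouched; zeros stay zeros
  expect_identical(cosine_taper(x, 0), x)
  expect_equal(cosine_taper(rep(0, 50), 0.3), rep(0, 50))
  expect_error(cosine_taper(x, 0.6), "0, 0.5")
  expect_error(cosine_taper(x, -0.1), "0, 0.5")
})

test_that("raw periodogram concentrates a pure tone in its bin", {
  n <- 144
  for (k in c(3L, 10L, 31L)) {
    x <- cos(2 * pi * k * (0:(n - 1)) / n)
    ps <- smoothed_periodogram(x, span = 1, taper_p = 0)
    # oracle: direct DFT magnitude
    direct <- Mod(fft(x - mean(x)))^2 / n
    expect_equal(ps$power, direct[2:(n / 2 + 1)], tolerance = 1e-10)
    expect_equal(which.max(ps$power), k)
    off <- ps$power[-k]
    expect_lt(max(off), 1e-9 * ps$power[k])
  }
})

test_that("raw periodogram satisfies Parseval's identity on white noise", {
  set.seed(99)
  for (n in c(64L, 144L)) {
    x <- rnorm(n)
    ps <- smoothed_periodogram(x, span = 1, taper_p = 0)
    xd <- x - mean(x)
    # two-sided power: interior bins count twice, Nyquist once
    two_sided <- 2 * sum(ps$power[-(n / 2)]) + ps$power[n / 2]
    expect_equal(two_sided, sum(xd^2), tolerance = 1e-6 * sum(xd^2))
  }
})

test_that("constant input yields an all-zero spectrum", {
  ps <- smoothed_periodogram(rep(3.2, 144), span = 10, taper_p = 0.1)
  expect_true(all(abs(ps$power) < 1e-24))
  expect_equal(ps$freq_index, 1:72)
})

test_that("smoothed periodogram agrees with the reference implementation", {
  set.seed(5)
  x <- rnorm(144)
  ref <- function(x, spans, taper) {
    stats::spec.pgram(stats::ts(x), spans = spans, taper = taper,
                      demean = TRUE, detrend = FALSE, fast = FALSE,
                      plot = FALSE)$spec
  }
  # untapered, unsmoothed: bit-comparable
  mine <- smoothed_periodogram(x, span = 1, taper_p = 0)
  expect_equal(mine$power, ref(x, NULL, 0), tolerance = 1e-10)
  # tapered + Daniell-smoothed: identical up to the reference's constant
  # taper power correction
  mine <- smoothed_periodogram(x, span = 10, taper_p = 0.1)
  r <- mine$power / ref(x, 10, 0.1)
  expect_lt(diff(range(r)), 1e-9)
})

test_that("series length and span are validated", {
  expect_error(smoothed_periodogram(rnorm(7)), "too short")
  expect_error(smoothed_periodogram(rnorm(145)), "even")
  expect_error(smoothed_periodogram(rnorm(16), span = 0), "positive")
  expect_error(smoothed_periodogram(rnorm(10), span = 12), "exceeds")
})

test_that("featurize yields 288 named features from 576 coefficients", {
  prof <- compute_shape(random_seq(147, seed = 8), toy_table())
  fv <- featurize(prof)
  expect_equal(nrow(fv), 288L)
  expect_identical(fv$feature, nf_feature_names())
  expect_equal(attr(fv, "n_two_sided"), 576L)
  expect_equal(unname(attr(fv, "n_used")), rep(144L, 4))
  expect_true(all(is.finite(fv$power)) && all(fv$power >= 0))
  # deterministic
  expect_identical(featurize(prof), fv)
  # only 147-bp profiles are accepted
  expect_error(featurize(compute_shape(random_seq(100, seed = 1), toy_table())),
               "147")
})

test_that("feature vectors are invariant under reverse complement", {
  tab <- toy_table()
  for (seed in 1:8) {
    s <- random_seq(147, seed = 200 + seed)
    f1 <- featurize(compute_shape(s, tab))
    f2 <- featurize(compute_shape(revcomp(s), tab))
    expect_lt(max(abs(f1$power - f2$power)), 1e-9)
  }
})

test_that("power scales quadratically with the shape values", {
  tab <- toy_table()
  prof <- compute_shape(random_seq(147, seed = 31), tab)
  f1 <- featurize(prof)
  scaled <- prof
  scaled$HelT <- prof$HelT * 3
  f2 <- featurize(scaled)
  helt <- f1$shape == "HelT"
  expect_equal(f2$power[helt], 9 * f1$power[helt],
               tolerance = 1e-9)
  expect_equal(f2$power[!helt], f1$power[!helt], tolerance = 1e-12)
})

test_that("spectral features are more shift-stable than raw profiles", {
  # the motivation for the PSD step: circularly shifting a periodic pattern
  # barely moves the spectrum while the per-position values change a lot
  n <- 144
  base <- sin(2 * pi * 14 * (0:(n - 1)) / n)
  shifted <- base[c(6:n, 1:5)]
  ps1 <- smoothed_periodogram(base, span = 1, taper_p = 0)
  ps2 <- smoothed_periodogram(shifted, span = 1, taper_p = 0)
  rel_spec <- max(abs(ps1$power - ps2$power)) / max(ps1$power)
  rel_raw <- max(abs(base - shifted)) / max(abs(base))
  expect_lt(rel_spec, 1e-9)
  expect_gt(rel_raw, 0.5)
})

test_that("batch featurization equals per-sequence featurization", {
  tab <- toy_table()
  ts <- gen_training_set(synthetic_spec(n_pos = 3, n_neg = 3, seed = 5))
  wide <- featurize_set(ts, tab)
  expect_identical(names(wide)[1:2], c("id", "label"))
  for (i in seq_len(nrow(ts))) {
    single <- featurize(compute_shape(ts$seq[i], tab))
    expect_equal(as.numeric(wide[i, nf_feature_names()]), single$power,
                 tolerance = 1e-12)
  }
})
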