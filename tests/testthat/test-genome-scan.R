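# a deterministic stand-in for the classifier: labels windows by their
# 0-based start position
stub <- function(nucleosomal_starts) {
  function(starts) as.integer(starts %in% nucleosomal_starts)
}

test_that("low-resolution scan writes window labels to central segments", {
  L <- 1047L
  s <- stats::setNames(random_seq(L, seed = 1), "chr1")
  starts <- seq.int(0L, L - 147L, by = 50L)
  expect_length(starts, 19L)                       # floor((1047-147)/50) + 1
  track <- scan_low_res(s, step = 50, classify = stub(starts[c(TRUE, FALSE)]))
  expect_equal(nrow(track), 950L)                  # 19 windows x 50 bp
  # window k covers positions start_k + 48 .. start_k + 97
  expect_equal(min(track$pos), 48L)
  expect_equal(max(track$pos), starts[19] + 97L)
  for (k in c(1L, 7L, 19L)) {
    seg <- track$value[track$pos %in% (starts[k] + 48:97)]
    expect_equal(seg, rep(as.numeric(k %% 2L), 50L), info = paste("window", k))
  }
  expect_true(all(track$value %in% c(0, 1)))
})

test_that("references shorter than one window give an empty track with a warning", {
  expect_warning(
    track <- scan_low_res(c(tiny = random_seq(100, seed = 2)),
                          step = 50, classify = stub(integer())),
    "shorter than one"
  )
  expect_equal(nrow(track), 0L)
})

test_that("windows containing N leave gaps instead of scores", {
  s <- random_seq(1047, seed = 3)
  substr(s, 201, 210) <- "NNNNNNNNNN"              # hits windows starting 100..200
  track <- scan_low_res(c(chr1 = s), step = 50,
                        classify = stub(seq.int(0L, 900L, 50L)))
  masked_windows <- c(100L, 150L, 200L)
  for (w in masked_windows) {
    expect_equal(sum(track$pos %in% (w + 48:97)), 0L, info = paste("window", w))
  }
  clean <- setdiff(seq.int(0L, 900L, 50L), masked_windows)
  expect_equal(nrow(track), 50L * length(clean))
})

test_that("high-resolution scores are per-bp vote fractions", {
  L <- 1047L
  s <- stats::setNames(random_seq(L, seed = 4), "chr1")
  p <- 500L
  grid <- seq.int(0L, L - 147L, by = 7L)
  covering <- grid[grid >= p - 146L & grid <= p]
  expect_length(covering, 21L)                     # 147 / 7 windows
  track <- scan_high_res(s, step = 7, classify = stub(covering[1:14]))
  score <- track$value[track$pos == p]
  expect_equal(score, 14 / 21)
  expect_equal(round(score, 2), 0.67)
  # all windows nucleosomal -> vote fraction 1 everywhere
  full <- scan_high_res(s, step = 7, classify = stub(grid))
  expect_true(all(full$value == 1))
  # scores live on the per-coverage grid {0, 1/c, ..., 1}
  rnd <- scan_high_res(s, step = 7, classify = stub(grid[c(TRUE, FALSE, TRUE)]))
  cov <- window_coverage(rnd$pos, step = 7L, region_length = L)
  expect_true(all(abs(rnd$value * cov - round(rnd$value * cov)) < 1e-9))
  # a non-divisor step is rejected
  expect_error(scan_high_res(s, step = 10, classify = stub(grid)), "divisor")
})

test_that("masked windows drop out of numerator and denominator", {
  L <- 588L
  s <- random_seq(L, seed = 6)
  substr(s, 295, 295) <- "N"                       # 0-based position 294
  grid <- seq.int(0L, L - 147L, by = 7L)
  track <- scan_high_res(c(chr1 = s), step = 7, classify = stub(grid))
  # windows overlapping the N (starts 148..294 on the grid) are excluded;
  # every remaining evaluated window voted nucleosomal, so scores are 1
  expect_true(all(track$value == 1))
  expect_false(294L %in% track$pos)
  # coverage at a bp next to the masked run is reduced but nonzero
  expect_true(154L %in% track$pos)
})

test_that("edge base pairs keep their true coverage unless dropped", {
  L <- 588L
  s <- stats::setNames(random_seq(L, seed = 7), "chr1")
  grid <- seq.int(0L, L - 147L, by = 7L)
  track <- scan_high_res(s, step = 7, classify = stub(grid))
  expect_equal(track$value[track$pos == 0L], 1)    # single covering window
  expect_equal(window_coverage(0L, step = 7L, region_length = L), 1L)
  trimmed <- scan_high_res(s, step = 7, classify = stub(grid),
                           drop_partial = TRUE)
  expect_equal(min(trimmed$pos), 140L)             # first fully covered bp
  expect_equal(
    unique(window_coverage(trimmed$pos, step = 7L, region_length = L)), 21L
  )
})

test_that("window coverage matches brute-force enumeration", {
  brute <- function(pos, step, L, window = 147L, phase = 0L) {
    starts <- seq.int(phase, L - window, by = step)
    sum(starts <= pos & pos < starts + window)
  }
  for (cfg in list(c(7L, 588L), c(21L, 1047L), c(49L, 700L), c(147L, 500L))) {
    step <- cfg[1]; L <- cfg[2]
    got <- window_coverage(0:(L - 1L), step = step, region_length = L)
    want <- vapply(0:(L - 1L), brute, integer(1), step = step, L = L)
    expect_equal(got, want, info = paste("step", step))
  }
  # the canonical interior coverage at step 7 is 147/7 = 21
  expect_equal(window_coverage(293L, step = 7L, region_length = 1047L), 21L)
})

test_that("scanning a reverse complement mirrors the high-res track", {
  L <- 588L                                        # (L - 147) divisible by 7
  s <- random_seq(L, seed = 8)
  model <- separable_model()
  tab <- toy_table()
  fwd <- scan_high_res(c(chr = s), model, tab, step = 7)
  rev <- scan_high_res(c(chr = revcomp(s)), model, tab, step = 7)
  mirrored <- rev$value[match(L - 1L - fwd$pos, rev$pos)]
  expect_equal(fwd$value, mirrored, tolerance = 1e-12)
})

test_that("tracks round-trip through bedGraph and look up with gap semantics", {
  track <- new_track(tibble::tibble(
    chrom = c("a", "a", "a", "b"), pos = c(10L, 11L, 13L, 2L),
    value = c(1, 1, 0.5, 2)
  ))
  expect_equal(track_values(track, "a", c(10L, 12L, 13L)), c(1, NA, 0.5))
  path <- tempfile(fileext = ".bedgraph")
  write_track(track, path)
  lines <- readLines(path)
  expect_equal(lines[1], "a\t10\t12\t1")           # run collapsing
  reread <- read_bedgraph(path)
  expect_equal(reread$value, track$value)
  expect_equal(reread$pos, track$pos)
  # bigWig round trip
  bw <- tempfile(fileext = ".bw")
  write_track(track, bw)
  gr <- rtracklayer::import.bw(bw)
  expect_equal(sum(GenomicRanges::width(gr) * gr$score),
               sum(track$value))
})
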