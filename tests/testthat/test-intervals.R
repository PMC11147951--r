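test_that("BED and narrowPeak records parse with 0-based half-open semantics", {
  bed6 <- write_bed(c(
    "chr1\t100\t229\texon1\t0\t+",
    "chr1\t5000\t8000\tgene1\t0\t-",
    "chr2\t10\t20\tx\t0\t."
  ))
  iv <- read_intervals(bed6)
  expect_equal(iv$start, c(100L, 5000L, 10L))
  expect_equal(iv$strand, c("+", "-", "."))
  expect_true(all(is.na(iv$point_source_offset)))

  np <- write_bed(c(
    "chr1\t1000\t1500\tpeak1\t900\t.\t5.2\t-1\t-1\t75",
    "chr1\t2000\t2400\tpeak2\t800\t.\t4.0\t-1\t-1\t-1"
  ))
  peaks <- read_intervals(np)
  expect_equal(peaks$point_source_offset, c(75L, NA_integer_))

  bed3 <- write_bed(c("# comment", "track name=t", "chr1\t5\t9"))
  expect_equal(nrow(read_intervals(bed3)), 1L)

  expect_error(read_intervals(write_bed("chr1\t50\t40")), "line 1.*start")
  expect_error(read_intervals(write_bed(c("chr1\t1\t2", "chr1\tx\t9"))),
               "line 2.*malformed")
  expect_error(read_intervals(write_bed("chr1\t1\t2\tn")), "columns")
})

test_that("anchor modes follow the declared conventions", {
  iv <- read_intervals(write_bed(c(
    "chr1\t100\t229\texon\t0\t+",
    "chr1\t5000\t8000\tgene\t0\t-"
  )))
  expect_equal(anchors(iv, "midpoint")$anchor, c(164L, 6500L))
  expect_equal(anchors(iv, "five_prime")$anchor, c(100L, 7999L))
  expect_equal(anchors(iv, "junction")$anchor, c(100L, 7999L))

  np <- read_intervals(write_bed(
    c("chr1\t1000\t1500\tp\t0\t+\t1\t-1\t-1\t75",
      "chr1\t2000\t2400\tq\t0\t+\t1\t-1\t-1\t-1")
  ))
  expect_error(anchors(np, "point_source"), "fallback")
  a <- anchors(np, "point_source", fallback = TRUE)
  expect_equal(a$anchor, c(1075L, 2200L))          # summit; midpoint fallback
})

test_that("mean profiles aggregate strand-aware windows over defined values", {
  # constant track: profile is flat with n = 1
  const <- new_track(tibble::tibble(chrom = "c", pos = 0:999, value = 0.4))
  one <- new_interval_set(tibble::tibble(
    chrom = "c", start = 480L, end = 520L, name = "i", strand = "+",
    point_source_offset = NA_integer_
  ))
  prof <- mean_profile(const, one, mode = "midpoint", flank = 20)
  expect_equal(prof$offset, -20:20)
  expect_true(all(prof$mean == 0.4))
  expect_true(all(prof$n == 1L))

  # minus-strand interval over a linear ramp: the profile is the ramp
  # reversed (oracle: direct index arithmetic)
  ramp <- new_track(tibble::tibble(chrom = "c", pos = 0:999, value = 0:999))
  minus <- new_interval_set(tibble::tibble(
    chrom = "c", start = 480L, end = 520L, name = "i", strand = "-",
    point_source_offset = NA_integer_
  ))
  prof <- mean_profile(ramp, minus, mode = "midpoint", flank = 10)
  anchor <- 480L + 20L
  expect_equal(prof$mean, as.numeric(anchor - (-10:10)))

  # two intervals average position-wise; gaps count only where defined
  gappy <- new_track(tibble::tibble(chrom = "c", pos = c(100L, 200L),
                                    value = c(1, 3)))
  two <- new_interval_set(tibble::tibble(
    chrom = "c", start = c(98L, 198L), end = c(103L, 203L),
    name = c("a", "b"), strand = c("+", "+"),
    point_source_offset = NA_integer_
  ))
  prof <- mean_profile(gappy, two, mode = "midpoint", flank = 2)
  expect_equal(prof$mean[prof$offset == 0], 2)     # (1 + 3) / 2
  expect_equal(prof$n[prof$offset == 0], 2L)
  expect_equal(prof$n[prof$offset == 1], 0L)
  expect_true(is.na(prof$mean[prof$offset == 1]))

  # intervals on unknown chromosomes are skipped with a message
  stray <- new_interval_set(tibble::tibble(
    chrom = c("c", "zz"), start = c(480L, 5L), end = c(520L, 10L),
    name = c("a", "b"), strand = "+", point_source_offset = NA_integer_
  ))
  expect_message(mean_profile(const, stray, flank = 5), "skipping 1")
})

test_that("profiles of strand-randomized anchors are symmetric on symmetric tracks", {
  set.seed(21)
  vals <- rep(c(0, 1), length.out = 2000)          # symmetric 2-periodic track
  track <- new_track(tibble::tibble(chrom = "c", pos = 0:1999, value = vals))
  n <- 200
  starts <- sample(500:1500, n, replace = TRUE) * 1L
  iv <- new_interval_set(tibble::tibble(
    chrom = "c", start = starts, end = starts + 20L,
    name = as.character(seq_len(n)),
    strand = sample(c("+", "-"), n, replace = TRUE),
    point_source_offset = NA_integer_
  ))
  prof <- mean_profile(track, iv, mode = "five_prime", flank = 50)
  asym <- abs(prof$mean - rev(prof$mean))
  expect_lt(max(asym), 0.15)                       # sampling tolerance at n=200
})

test_that("quantile split partitions by length with remainder to early groups", {
  mk <- function(lens) new_interval_set(tibble::tibble(
    chrom = "c", start = 0L, end = as.integer(lens),
    name = as.character(seq_along(lens)), strand = "+",
    point_source_offset = NA_integer_
  ))
  q4 <- quantile_split(mk(8:1), 4)                 # lengths 8..1, input order
  expect_equal(split(q4$end, q4$length_group),
               list(`1` = c(2L, 1L), `2` = c(4L, 3L), `3` = c(6L, 5L),
                    `4` = c(8L, 7L)))
  q5 <- quantile_split(mk(c(5, 1, 4, 2, 3)), 4)
  expect_equal(as.integer(table(q5$length_group)), c(2L, 1L, 1L, 1L))
  ties <- quantile_split(mk(rep(7, 6)), 3)
  expect_equal(ties$length_group, rep(1:3, each = 2))  # ties keep input order
  # partition: no loss, no duplication
  expect_setequal(ties$name, as.character(1:6))
  summ <- attr(q4, "group_summary")
  expect_equal(summ$median_length, c(1.5, 3.5, 5.5, 7.5))
  expect_error(quantile_split(mk(1:3), 4), "fewer intervals")
})

test_that("DHS score counts files, not peaks, and matches brute force", {
  dir <- tempfile("panel")
  # one file with two overlapping peaks counts once
  f1 <- write_bed(c("c\t100\t200", "c\t150\t260"))
  t1 <- dhs_score(f1)
  expect_true(all(track_values(t1, "c", 100:259) == 1))
  expect_equal(track_values(t1, "c", 260L), 0)     # default 0, not a gap

  # brute-force oracle on a random toy panel
  set.seed(31)
  files <- character(4)
  peaks <- list()
  for (i in 1:4) {
    k <- sample(1:3, 1)
    st <- sample(0:300, k); w <- sample(20:80, k, replace = TRUE)
    peaks[[i]] <- cbind(st, st + w)
    files[i] <- write_bed(sprintf("c\t%d\t%d", st, st + w))
  }
  track <- dhs_score(files)
  brute <- vapply(0:400, function(p) {
    sum(vapply(peaks, function(m) any(m[, 1] <= p & p < m[, 2]), TRUE))
  }, 0)
  expect_equal(track_values(track, "c", 0:400), as.numeric(brute))
  expect_true(all(track$value >= 1 & track$value <= 4))
  expect_error(dhs_score(file.path(dir, "absent.bed")), "absent.bed")
})

test_that("synthetic peak panels reproduce the worked count examples", {
  for (n_cov in c(403L, 5L, 0L)) {
    paths <- gen_peak_panel(n_files = 403, covered_bp = 1234,
                            n_covering = n_cov, seed = 17 + n_cov)
    track <- dhs_score(paths)
    expect_equal(track_values(track, "toy1", 1234L), as.numeric(n_cov))
    expect_true(nrow(track) == 0 || max(track$value) <= 403)
    unlink(dirname(paths[1]), recursive = TRUE)
  }
})
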