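#' Split-cosine-bell taper
#'
#' Scales the first and last `floor(p * n)` points of a series by a half-cosine
#' ramp rising from 0 to 1, leaving the middle untouched. This is the standard
#' taper applied before a periodogram to reduce spectral leakage.
#'
#' @param series Numeric vector.
#' @param p Fraction of the series tapered at each end, in `[0, 0.5]`.
#' @return Numeric vector of the same length.
#' @export
cosine_taper <- function(series, p) {
  stopifnot(is.numeric(series))
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 0.5) {
    stop("taper fraction p must be in [0, 0.5], got ", p, call. = FALSE)
  }
  n <- length(series)
  m <- floor(n * p)
  if (m == 0L) return(series)
  w <- 0.5 * (1 - cos(pi * seq(0.5, by = 1, length.out = m) / m))
  series[seq_len(m)] <- series[seq_len(m)] * w
  series[(n - m + 1L):n] <- series[(n - m + 1L):n] * rev(w)
  series
}

#' Smoothed periodogram of a numeric series
#'
#' Estimates the power spectral density as: demean, split-cosine-bell taper,
#' discrete Fourier periodogram (`power = |DFT|^2 / n`), then smoothing with a
#' modified Daniell kernel of total span `span` (half-weight endpoints; a span
#' of 10 gives an 11-weight kernel). The zero-frequency bin is replaced by the
#' mean of its neighbours before smoothing and is never returned; smoothing is
#' applied circularly over the full two-sided periodogram, which for a real
#' series is equivalent to reflection at the one-sided spectrum boundaries.
#' Bins `1..n/2` (Nyquist included) are returned.
#'
#' With `span = 1` and `taper_p = 0` the result is the raw periodogram and
#' satisfies Parseval's identity: the two-sided power sums to the sum of
#' squares of the demeaned series.
#'
#' @param series Numeric vector of even length >= 8.
#' @param span Total smoothing span (positive integer; 1 disables smoothing).
#' @param taper_p Taper fraction per end, in `[0, 0.5]`.
#' @return A tibble of class `power_spectrum` with columns `freq_index`
#'   (`1..n/2`, cycles per `n` positions) and `power`; attribute `n_used`
#'   records the series length entering the transform.
#' @export
smoothed_periodogram <- function(series, span = 10, taper_p = 0.1) {
  stopifnot(is.numeric(series))
  n <- length(series)
  if (n < 8L) stop("series too short for a periodogram: ", n, call. = FALSE)
  if (n %% 2L != 0L) stop("series length must be even, got ", n, call. = FALSE)
  span <- as.integer(span)
  if (is.na(span) || span < 1L) stop("span must be a positive integer", call. = FALSE)
  if (span %/% 2L * 2L + 1L > n) {
    stop("smoothing span ", span, " exceeds series length ", n, call. = FALSE)
  }
  pw <- psd_matrix(matrix(series, ncol = 1L), span = span, taper_p = taper_p)
  out <- tibble::tibble(freq_index = seq_len(n %/% 2L), power = pw[, 1L])
  structure(out, n_used = n, class = c("power_spectrum", class(out)))
}

# Column-wise smoothed periodogram: x is an n x m matrix of series; returns an
# (n/2) x m matrix of one-sided power (bins 1..n/2).
psd_matrix <- function(x, span = 10, taper_p = 0.1) {
  n <- nrow(x)
  x <- sweep(x, 2L, colMeans(x))
  m <- floor(n * taper_p)
  if (m > 0L) {
    w <- 0.5 * (1 - cos(pi * seq(0.5, by = 1, length.out = m) / m))
    x[seq_len(m), ] <- x[seq_len(m), , drop = FALSE] * w
    x[(n - m + 1L):n, ] <- x[(n - m + 1L):n, , drop = FALSE] * rev(w)
  }
  pg <- Mod(stats::mvfft(x))^2 / n
  pg[1L, ] <- (pg[2L, ] + pg[n, ]) / 2
  hw <- as.integer(span) %/% 2L
  if (hw >= 1L) {
    k <- stats::kernel("modified.daniell", hw)
    wts <- k[-k$m:k$m]
    sm <- matrix(0, n, ncol(x))
    for (j in -k$m:k$m) {
      idx <- ((seq_len(n) - 1L + j) %% n) + 1L
      sm <- sm + wts[j + k$m + 1L] * pg[idx, , drop = FALSE]
    }
    pg <- sm
  }
  pg[2:(n %/% 2L + 1L), , drop = FALSE]
}

#' Canonical names of the 288 spectral features
#'
#' Feature-major (MGW, ProT, HelT, Roll), frequency-ascending (`1..72`).
#' `HelT_5` is the power of the HelT profile at frequency index 5, i.e. about
#' 5 cycles per 147 bp.
#'
#' @return Character vector of length 288.
#' @export
nf_feature_names <- function() {
  as.vector(vapply(shape_channel_names(),
                   function(f) paste0(f, "_", 1:72), character(72)))
}

shape_channel_names <- function() c("MGW", "ProT", "HelT", "Roll")

#' Spectral feature vector of a 147-bp shape profile
#'
#' Converts a [shape_profile][compute_shape] of a 147-bp sequence into the 288
#' power-spectral-density features used by the classifier. Each channel's
#' defined values are standardised to an even series length of 144 (see the
#' methods vignette: MGW/ProT duplicate their central value, HelT/Roll drop
#' theirs — both edits commute with positional reversal, so reverse-complement
#' sequences map to identical feature vectors under a
#' reverse-complement-symmetric table). Each 144-long series
#' is passed through [smoothed_periodogram()] and frequency bins `1..72` are
#' retained, giving 4 x 144 = 576 two-sided coefficients halved to 288
#' one-sided features.
#'
#' @param profile A `shape_profile` from a 147-bp sequence.
#' @param span,taper_p Periodogram smoothing span and taper fraction.
#' @return A tibble of class `nf_features` with 288 rows and columns `feature`
#'   (e.g. `"HelT_5"`), `shape`, `freq_index`, `power`; attributes
#'   `n_two_sided` (576) and `n_used` (per-channel series lengths).
#' @export
featurize <- function(profile, span = 10, taper_p = 0.1) {
  stopifnot(inherits(profile, "shape_profile"))
  L <- attr(profile, "seq_length")
  if (L != 147L) {
    stop("featurize requires a 147-bp profile, got length ", L, call. = FALSE)
  }
  series <- lapply(shape_channel_names(), function(f) {
    standardize_series(profile[[f]][!is.na(profile[[f]])], f)
  })
  names(series) <- shape_channel_names()
  pw <- psd_matrix(do.call(cbind, series), span = span, taper_p = taper_p)
  pw <- pw[1:72, , drop = FALSE]
  out <- tibble::tibble(
    feature = nf_feature_names(),
    shape = rep(shape_channel_names(), each = 72L),
    freq_index = rep(1:72, times = 4L),
    power = as.vector(pw)
  )
  structure(out,
            n_two_sided = 4L * 144L,
            n_used = vapply(series, length, integer(1L)),
            class = c("nf_features", class(out)))
}

# Standardise a channel's defined values to an even length of 144.
# MGW/ProT carry 143 values: duplicate the central (72nd) value. HelT/Roll
# carry 145: drop the central (73rd) value. Both edits are fixed points of
# positional reversal, so reversing the input reverses the output exactly.
standardize_series <- function(vals, channel) {
  n <- length(vals)
  if (n == 143L) {
    c(vals[1:72], vals[72L], vals[73:143])
  } else if (n == 145L) {
    vals[-73L]
  } else if (n == 144L) {
    vals
  } else {
    stop("unexpected defined-value count ", n, " for channel ", channel,
         call. = FALSE)
  }
}

#' Spectral feature matrix for a set of sequences
#'
#' Batch version of [compute_shape()] + [featurize()]: one row per input
#' sequence, one column per spectral feature, in wide (model-ready) layout.
#'
#' @param seqs Sequences: a character vector (optionally named), a
#'   `Biostrings::DNAStringSet`, or a tibble/data.frame with columns `id`,
#'   `seq` and optionally `label`.
#' @param table A [pentamer_tbl][load_pentamer_table].
#' @param span,taper_p Periodogram parameters.
#' @return A tibble with columns `id`, `label` (if supplied) and the 288
#'   feature columns `MGW_1 .. Roll_72`.
#' @export
featurize_set <- function(seqs, table, span = 10, taper_p = 0.1) {
  if (inherits(seqs, "DNAStringSet")) {
    seqs <- tibble::tibble(
      id = names(seqs) %||% as.character(seq_along(seqs)),
      seq = as.character(seqs)
    )
  } else if (is.character(seqs)) {
    seqs <- tibble::tibble(
      id = names(seqs) %||% as.character(seq_along(seqs)),
      seq = unname(seqs)
    )
  }
  stopifnot(is.data.frame(seqs), all(c("id", "seq") %in% names(seqs)))
  lens <- nchar(seqs$seq)
  if (any(lens != 147L)) {
    stop("all sequences must be 147 bp; found length ", lens[lens != 147L][1L],
         call. = FALSE)
  }
  fm <- window_feature_matrix(seqs$seq, table, span = span, taper_p = taper_p)
  out <- tibble::as_tibble(fm)
  out <- dplyr::bind_cols(tibble::tibble(id = as.character(seqs$id)), out)
  if ("label" %in% names(seqs)) {
    out <- dplyr::bind_cols(out[, "id"], tibble::tibble(label = seqs$label),
                            out[, nf_feature_names()])
  }
  out
}

# Vectorised feature computation for many 147-bp windows at once. `windows` is
# a character vector of 147-mers over ACGT (NA allowed for masked windows).
# Returns an n x 288 matrix (rows with masked windows are NA).
window_feature_matrix <- function(windows, table, span = 10, taper_p = 0.1) {
  nwin <- length(windows)
  out <- matrix(NA_real_, nwin, 288L,
                dimnames = list(NULL, nf_feature_names()))
  ok <- !is.na(windows)
  if (!any(ok)) return(out)
  codes <- base_codes(paste(windows[ok], collapse = ""))
  cm <- matrix(codes, nrow = 147L)
  valid <- !apply(is.na(cm), 2L, any)
  if (!any(valid)) return(out)
  cm <- cm[, valid, drop = FALSE]
  lk <- table_lookup(table)
  idx <- 256L * cm[1:143, , drop = FALSE] + 64L * cm[2:144, , drop = FALSE] +
    16L * cm[3:145, , drop = FALSE] + 4L * cm[4:146, , drop = FALSE] +
    cm[5:147, , drop = FALSE] + 1L
  mgw <- matrix(lk$MGW[idx], 143L); prot <- matrix(lk$ProT[idx], 143L)
  h1 <- matrix(lk$HelT1[idx], 143L); h2 <- matrix(lk$HelT2[idx], 143L)
  r1 <- matrix(lk$Roll1[idx], 143L); r2 <- matrix(lk$Roll2[idx], 143L)
  if (anyNA(mgw) || anyNA(prot) || anyNA(h1) || anyNA(r1)) {
    stop("pentamer missing from table; use a complete table", call. = FALSE)
  }
  helt <- step_to_position_matrix(h1, h2)
  roll <- step_to_position_matrix(r1, r2)
  std143 <- function(m) {
    rbind(m[1:72, , drop = FALSE],
          m[72L, , drop = FALSE],
          m[73:143, , drop = FALSE])
  }
  blocks <- list(MGW = std143(mgw), ProT = std143(prot),
                 HelT = helt[-73L, , drop = FALSE],
                 Roll = roll[-73L, , drop = FALSE])
  feat <- do.call(rbind, lapply(blocks, function(b) {
    psd_matrix(b, span = span, taper_p = taper_p)[1:72, , drop = FALSE]
  }))
  res <- matrix(NA_real_, nwin, 288L)
  res_ok <- which(ok)[valid]
  res[res_ok, ] <- t(feat)
  dimnames(res) <- list(NULL, nf_feature_names())
  res
}

# Matrix analogue of step_to_position() for L = 147: h1/h2 are 143 x n
# matrices of per-pentamer step predictions; returns the 145 x n per-position
# values (positions 2..146).
step_to_position_matrix <- function(h1, h2) {
  n_pent <- 143L
  n_step <- 144L
  step <- matrix(0, n_step, ncol(h1))
  step[1L, ] <- h1[1L, ]
  step[n_step, ] <- h2[n_pent, ]
  step[2:(n_step - 1L), ] <- (h2[1:(n_pent - 1L), , drop = FALSE] +
                                h1[2:n_pent, , drop = FALSE]) / 2
  pos <- matrix(0, 145L, ncol(h1))
  pos[1L, ] <- step[1L, ]
  pos[145L, ] <- step[n_step, ]
  pos[2:144L, ] <- (step[1:143L, , drop = FALSE] +
                      step[2:144L, , drop = FALSE]) / 2
  pos
}
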