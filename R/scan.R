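#' Low-resolution NF score scan
#'
#' Slides a 147-bp window along each reference sequence in steps of `step`
#' (default 50) bp, classifies every window, and writes the window's binary
#' label (1 = nucleosomal, 0 = linker) to its central `step` base pairs: for
#' the default step the segment covers window offsets 48..97 (centred,
#' left-biased by one since `147 - 50` is odd). Windows containing non-`ACGT`
#' bases are excluded and leave gaps, as do the flanks not covered by any
#' central segment.
#'
#' @param genome A FASTA path, `Biostrings::DNAStringSet`, or named character
#'   vector of reference sequences.
#' @param model An [nf_model][nf_train] (ignored if `classify` is given).
#' @param table A [pentamer_tbl][load_pentamer_table].
#' @param step Step size in bp (> 0).
#' @param phase 0-based genome offset of the first window (the window grid).
#' @param classify Optional stub classifier for testing: a
#'   `function(starts)` of 0-based window starts returning 0/1 labels,
#'   bypassing the model.
#' @param span,taper_p Periodogram parameters forwarded to featurization.
#' @return An [nf_track][new_track] with values in `{0, 1}`.
#' @export
scan_low_res <- function(genome, model = NULL, table = NULL, step = 50,
                         phase = 0, classify = NULL, span = 10,
                         taper_p = 0.1) {
  seqs <- read_genome(genome)
  window <- 147L
  if (step <= 0 || step > window) {
    stop("step must be in 1..", window, ", got ", step, call. = FALSE)
  }
  step <- as.integer(step)
  offset <- (window - step) %/% 2L
  rows <- purrr::imap(seqs, function(s, nm) {
    w <- scan_windows(s, nm, window, step, phase, model, table, classify,
                      span, taper_p)
    if (is.null(w)) return(NULL)
    keep <- !is.na(w$label)
    if (!any(keep)) return(NULL)
    starts <- w$starts[keep]
    labels <- w$label[keep]
    tibble::tibble(
      chrom = nm,
      pos = as.integer(rep(starts + offset, each = step) +
                         rep(seq_len(step) - 1L, length(starts))),
      value = rep(labels, each = step)
    )
  })
  new_track(dplyr::bind_rows(rows), default_value = NA_real_,
            mode = "low_res")
}

#' High-resolution NF score scan
#'
#' Slides a 147-bp window in steps of `step` bp (default 7), which must divide
#' 147 so the window grid tiles evenly. The score at each base pair is the
#' fraction of evaluated windows covering it that were classified nucleosomal
#' — interior base pairs sit in exactly `147 / step` windows (21 for step 7),
#' e.g. 14 nucleosomal calls out of 21 give 14/21 = 0.67. Windows containing
#' non-`ACGT` bases are excluded from both numerator and denominator; edge
#' base pairs covered by fewer windows use their actual coverage as
#' denominator unless `drop_partial` is set.
#'
#' @inheritParams scan_low_res
#' @param drop_partial If `TRUE`, report only base pairs with full
#'   (`147 / step`) coverage.
#' @return An [nf_track][new_track] with values in `[0, 1]`.
#' @export
scan_high_res <- function(genome, model = NULL, table = NULL, step = 7,
                          phase = 0, classify = NULL, drop_partial = FALSE,
                          span = 10, taper_p = 0.1) {
  window <- 147L
  step <- as.integer(step)
  if (step <= 0 || window %% step != 0L) {
    stop("high-resolution step must be a divisor of the window size of 147 bp",
         " (got ", step, ")", call. = FALSE)
  }
  seqs <- read_genome(genome)
  full_cov <- window %/% step
  rows <- purrr::imap(seqs, function(s, nm) {
    w <- scan_windows(s, nm, window, step, phase, model, table, classify,
                      span, taper_p)
    if (is.null(w)) return(NULL)
    keep <- !is.na(w$label)
    if (!any(keep)) return(NULL)
    L <- nchar(s)
    num <- den <- numeric(L + 1L)     # difference arrays over 0-based pos
    starts <- w$starts[keep]
    labels <- w$label[keep]
    den[starts + 1L] <- den[starts + 1L] + 1
    den[starts + window + 1L] <- den[starts + window + 1L] - 1
    num[starts + 1L] <- num[starts + 1L] + labels
    num[starts + window + 1L] <- num[starts + window + 1L] - labels
    den <- cumsum(den)[seq_len(L)]
    num <- cumsum(num)[seq_len(L)]
    covered <- if (drop_partial) den == full_cov else den > 0
    if (!any(covered)) return(NULL)
    tibble::tibble(chrom = nm, pos = which(covered) - 1L,
                   value = num[covered] / den[covered])
  })
  new_track(dplyr::bind_rows(rows), default_value = NA_real_,
            mode = "high_res")
}

# classify all complete windows of one reference sequence; returns NULL (with
# a warning) when the sequence is shorter than one window, else a list with
# 0-based window `starts` and per-window `label` (NA = masked window).
scan_windows <- function(s, nm, window, step, phase, model, table, classify,
                         span, taper_p) {
  L <- nchar(s)
  if (L < window + phase) {
    warning("reference '", nm, "' (", L, " bp) is shorter than one ", window,
            "-bp window; empty track", call. = FALSE)
    return(NULL)
  }
  starts <- seq.int(phase, L - window, by = step)      # 0-based
  wins <- substring(s, starts + 1L, starts + window)
  masked <- grepl("[^ACGTacgt]", wins)
  label <- rep(NA_integer_, length(starts))
  if (!is.null(classify)) {
    lab <- classify(starts)
    stopifnot(length(lab) == length(starts))
    label[!masked] <- as.integer(lab[!masked])
  } else {
    if (is.null(model) || is.null(table)) {
      stop("either a model and pentamer table or a `classify` function is required",
           call. = FALSE)
    }
    if (any(!masked)) {
      wins[masked] <- NA_character_
      fm <- window_feature_matrix(wins, table, span = span, taper_p = taper_p)
      ok <- !masked
      prob <- stats::predict(model$forest, fm[ok, , drop = FALSE],
                             type = "prob")[, "nucleosomal"]
      label[ok] <- as.integer(prob >= 0.5)
    }
  }
  list(starts = starts, label = label)
}

#' Number of scan windows covering a position
#'
#' Counts complete 147-bp windows on the step grid that contain a given
#' 0-based base-pair position — 21 for any interior base pair at step 7.
#'
#' @param position 0-based position (vectorised).
#' @param step Step size in bp.
#' @param region_length Reference length in bp.
#' @param window Window size (default 147).
#' @param phase 0-based grid offset.
#' @return Integer count(s).
#' @export
window_coverage <- function(position, step, region_length, window = 147L,
                            phase = 0L) {
  stopifnot(all(position >= 0), all(position < region_length))
  s_min <- pmax(phase, position - window + 1L)
  s_max <- pmin(position, region_length - window)
  lo <- ceiling((s_min - phase) / step)
  hi <- floor((s_max - phase) / step)
  as.integer(pmax(0, hi - lo + 1))
}

# Accept a FASTA path, DNAStringSet, or (named) character vector; return a
# named character vector of uppercase sequences.
read_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    out <- toupper(as.character(genome))
  } else if (is.character(genome) && length(genome) == 1L &&
             file.exists(genome)) {
    ss <- Biostrings::readDNAStringSet(genome)
    out <- toupper(as.character(ss))
    names(out) <- sub("\\s.*$", "", names(ss))
  } else if (is.character(genome)) {
    out <- toupper(genome)
    if (is.null(names(out))) names(out) <- paste0("seq", seq_along(out))
  } else {
    stop("genome must be a FASTA path, DNAStringSet, or character vector",
         call. = FALSE)
  }
  if (length(out) == 0L) stop("empty genome", call. = FALSE)
  out
}

#' Write sequences as FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  tmp <- paste0(path, ".tmp", Sys.getpid())
  Biostrings::writeXStringSet(ss, tmp)
  file.rename(tmp, path)
  invisible(path)
}
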