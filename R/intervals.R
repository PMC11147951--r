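#' Read genomic intervals from BED or narrowPeak
#'
#' Accepts BED3, BED6 and narrowPeak (BED6+4) files. Coordinates are kept
#' 0-based half-open, as in the source format. For narrowPeak, column 10 is
#' parsed as the point-source (summit) offset relative to `start`; the
#' sentinel `-1` is recorded as missing and falls back to the interval
#' midpoint when anchoring with `point_source` mode and `fallback = TRUE`.
#'
#' @param path Path to a tab-separated BED3/BED6/narrowPeak file (`#` and
#'   `track`/`browser` lines are skipped).
#' @return A tibble of class `interval_set` with columns `chrom`, `start`,
#'   `end`, `name`, `strand` (`+`, `-` or `.`) and `point_source_offset`
#'   (`NA` when absent).
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) stop("interval file not found: ", path, call. = FALSE)
  lines <- readr::read_lines(path)
  keep <- nzchar(trimws(lines)) & !grepl("^(#|track\\b|browser\\b)", lines)
  line_no <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (length(fields) == 0L) {
    return(new_interval_set(tibble::tibble(
      chrom = character(), start = integer(), end = integer(),
      name = character(), strand = character(),
      point_source_offset = integer()
    )))
  }
  arity <- lengths(fields)
  if (!all(arity %in% c(3L, 6L, 10L))) {
    bad <- which(!arity %in% c(3L, 6L, 10L))[1L]
    stop(path, " line ", line_no[bad], ": ", arity[bad],
         " columns; expected BED3 (3), BED6 (6) or narrowPeak (10)",
         call. = FALSE)
  }
  col <- function(i, default = NA_character_) {
    vapply(fields, function(f) if (length(f) >= i) f[[i]] else default, "")
  }
  start <- suppressWarnings(as.integer(col(2L)))
  end <- suppressWarnings(as.integer(col(3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L) {
    stop(path, " line ", line_no[bad[1L]], ": malformed coordinates",
         call. = FALSE)
  }
  bad <- which(start >= end)
  if (length(bad) > 0L) {
    stop(path, " line ", line_no[bad[1L]], ": start (", start[bad[1L]],
         ") must be < end (", end[bad[1L]], ")", call. = FALSE)
  }
  strand <- ifelse(arity >= 6L, col(6L), ".")
  if (!all(strand %in% c("+", "-", "."))) {
    bad <- which(!strand %in% c("+", "-", "."))[1L]
    stop(path, " line ", line_no[bad], ": invalid strand '", strand[bad], "'",
         call. = FALSE)
  }
  pso <- ifelse(arity == 10L, suppressWarnings(as.integer(col(10L))),
                NA_integer_)
  pso[!is.na(pso) & pso < 0L] <- NA_integer_        # -1 sentinel -> missing
  too_big <- !is.na(pso) & pso >= (end - start)
  if (any(too_big)) {
    stop(path, " line ", line_no[which(too_big)[1L]],
         ": point-source offset outside the interval", call. = FALSE)
  }
  new_interval_set(tibble::tibble(
    chrom = col(1L), start = start, end = end,
    name = ifelse(arity >= 6L, col(4L), NA_character_),
    strand = strand, point_source_offset = pso
  ))
}

new_interval_set <- function(df) {
  out <- tibble::as_tibble(df)
  if (!"strand" %in% names(out)) out$strand <- "."
  if (!"name" %in% names(out)) out$name <- NA_character_
  if (!"point_source_offset" %in% names(out)) {
    out$point_source_offset <- NA_integer_
  }
  structure(out, class = unique(c("interval_set", class(out))))
}

#' Anchor positions of an interval set
#'
#' Reduces each interval to the single base pair that profiles are aligned on:
#' `point_source` uses the narrowPeak summit (`start + offset`), `midpoint`
#' uses `start + floor((end - start) / 2)` (left-biased for even lengths),
#' `five_prime` is `start` on `+`/`.` and `end - 1` on `-`, and `junction` is
#' an alias of `five_prime` named for exon-start (intron/exon boundary)
#' semantics.
#'
#' @param intervals An [interval_set][read_intervals] (or any data frame with
#'   the same columns).
#' @param mode One of `"point_source"`, `"midpoint"`, `"five_prime"`,
#'   `"junction"`.
#' @param fallback With `mode = "point_source"`, fall back to the midpoint for
#'   intervals whose summit offset is missing (narrowPeak `-1`).
#' @return The input tibble with an added integer `anchor` column (0-based).
#' @export
anchors <- function(intervals, mode = c("point_source", "midpoint",
                                        "five_prime", "junction"),
                    fallback = FALSE) {
  mode <- match.arg(mode)
  iv <- new_interval_set(intervals)
  mid <- iv$start + (iv$end - iv$start) %/% 2L
  anchor <- switch(
    mode,
    midpoint = mid,
    five_prime = ,
    junction = ifelse(iv$strand == "-", iv$end - 1L, iv$start),
    point_source = {
      a <- iv$start + iv$point_source_offset
      if (anyNA(a)) {
        if (!fallback) {
          stop(sum(is.na(a)), " interval(s) lack a point-source offset; ",
               "set fallback = TRUE to use midpoints", call. = FALSE)
        }
        a[is.na(a)] <- mid[is.na(a)]
      }
      a
    }
  )
  iv$anchor <- as.integer(anchor)
  iv
}

#' Split intervals into length quantile groups
#'
#' Ranks intervals by length (ties keep input order) and cuts them into `q`
#' near-equal groups, the remainder going to the earliest (shortest) groups.
#'
#' @param intervals An [interval_set][read_intervals].
#' @param q Number of groups (>= 2; at most the number of intervals).
#' @return The input tibble with added `length_group` (integer 1..q, 1 =
#'   shortest); the attribute `group_summary` tabulates each group's size,
#'   length range and median length.
#' @export
quantile_split <- function(intervals, q) {
  iv <- new_interval_set(intervals)
  q <- as.integer(q)
  if (q < 2L) stop("q must be >= 2", call. = FALSE)
  n <- nrow(iv)
  if (n < q) stop("fewer intervals (", n, ") than groups (", q, ")",
                  call. = FALSE)
  len <- iv$end - iv$start
  ord <- order(len)                                  # stable: ties keep input order
  sizes <- rep(n %/% q, q) + c(rep(1L, n %% q), rep(0L, q - n %% q))
  grp_sorted <- rep(seq_len(q), times = sizes)
  grp <- integer(n)
  grp[ord] <- grp_sorted
  iv$length_group <- grp
  summ <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(length_group = grp, length = len),
                    .data$length_group),
    n = dplyr::n(), min_length = min(.data$length),
    max_length = max(.data$length),
    median_length = stats::median(.data$length), .groups = "drop"
  )
  structure(iv, group_summary = summ)
}

#' Strand-aware mean profile of a track around anchors
#'
#' For every interval, extracts track values at `anchor - flank ..
#' anchor + flank`, flips the window for `-` strand intervals so offsets run
#' 5' to 3', and averages per offset over the values that are defined
#' (gaps and off-chromosome positions are excluded from both mean and `n`).
#' Unstranded (`.`) intervals are treated as `+` and counted in a message.
#'
#' @param track An [nf_track][new_track].
#' @param intervals An [interval_set][read_intervals].
#' @param mode Anchor mode, see [anchors()].
#' @param flank Half-width of the profile in bp.
#' @param fallback Passed to [anchors()].
#' @return A tibble of class `mean_profile` with columns `offset`
#'   (`-flank..flank`), `mean` (`NA` where `n = 0`) and `n`.
#' @export
mean_profile <- function(track, intervals, mode = "midpoint", flank = 250,
                         fallback = FALSE) {
  stopifnot(inherits(track, "nf_track"))
  iv <- anchors(intervals, mode = mode, fallback = fallback)
  if (nrow(iv) == 0L) stop("no intervals to profile", call. = FALSE)
  unknown <- setdiff(unique(iv$chrom), unique(track$chrom))
  if (length(unknown) > 0L) {
    skipped <- sum(iv$chrom %in% unknown)
    message("mean_profile: skipping ", skipped,
            " interval(s) on reference(s) absent from the track: ",
            paste(utils::head(unknown, 3L), collapse = ", "))
    iv <- iv[!iv$chrom %in% unknown, ]
    if (nrow(iv) == 0L) stop("no intervals left to profile", call. = FALSE)
  }
  n_unstranded <- sum(iv$strand == ".")
  if (n_unstranded > 0L) {
    message("mean_profile: treating ", n_unstranded,
            " unstranded interval(s) as + strand")
  }
  flank <- as.integer(flank)
  offsets <- -flank:flank
  width <- length(offsets)
  acc_sum <- numeric(width)
  acc_n <- integer(width)
  for (chrom in unique(iv$chrom)) {
    sub <- iv[iv$chrom == chrom, ]
    pos <- rep(sub$anchor, each = width) +
      rep(offsets, nrow(sub)) * rep(ifelse(sub$strand == "-", -1L, 1L),
                                    each = width)
    vals <- matrix(track_values(track, chrom, pos), nrow = width)
    ok <- !is.na(vals)
    acc_sum <- acc_sum + rowSums(vals * ok, na.rm = TRUE)
    acc_n <- acc_n + rowSums(ok)
  }
  out <- tibble::tibble(
    offset = offsets,
    mean = ifelse(acc_n > 0L, acc_sum / pmax(acc_n, 1L), NA_real_),
    n = acc_n
  )
  structure(out, flank = flank, mode = mode, n_intervals = nrow(iv),
            class = c("mean_profile", class(out)))
}

#' Export a mean profile as TSV
#' @param profile A [mean_profile][mean_profile].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "mean_profile"))
  atomic_write_lines(
    c("offset\tmean\tn",
      paste(profile$offset,
            ifelse(is.na(profile$mean), "NA", format_num(profile$mean)),
            profile$n, sep = "\t")),
    path
  )
  invisible(path)
}

#' Multi-sample DNase peak count score
#'
#' The DHS score at a base pair is the number of peak files (cell lines) with
#' at least one peak overlapping that base pair: overlapping peaks within one
#' file count once, and a panel of 403 files yields scores in `0..403`, with
#' 403 meaning every cell line is accessible there. Base pairs outside all
#' peaks score 0.
#'
#' @param peak_files Character vector of BED/narrowPeak paths (one per
#'   sample).
#' @return An [nf_track][new_track] of integer counts with
#'   `default_value = 0` (rows only where the count is positive).
#' @export
dhs_score <- function(peak_files) {
  stopifnot(length(peak_files) >= 1L)
  cov <- NULL
  for (f in peak_files) {
    iv <- tryCatch(read_intervals(f), error = function(e) {
      stop("dhs_score: failed reading '", f, "': ", conditionMessage(e),
           call. = FALSE)
    })
    if (nrow(iv) == 0L) next
    # per-file dedup: reduce to the union of covered bases before counting
    rl <- lapply(split(iv, iv$chrom), function(d) {
      IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end))
    })
    cov_f <- lapply(rl, IRanges::coverage)
    cov <- if (is.null(cov)) {
      cov_f
    } else {
      merge_coverage(cov, cov_f)
    }
  }
  if (is.null(cov)) {
    return(new_track(tibble::tibble(chrom = character(), pos = integer(),
                                    value = numeric()),
                     default_value = 0, mode = "dhs"))
  }
  rows <- purrr::imap(cov, function(rle, chrom) {
    v <- as.integer(rle)
    nz <- which(v > 0L)
    tibble::tibble(chrom = chrom, pos = nz - 1L, value = v[nz])
  })
  new_track(dplyr::bind_rows(rows), default_value = 0, mode = "dhs")
}

merge_coverage <- function(a, b) {
  for (chrom in names(b)) {
    if (is.null(a[[chrom]])) {
      a[[chrom]] <- b[[chrom]]
    } else {
      la <- length(a[[chrom]]); lb <- length(b[[chrom]])
      n <- max(la, lb)
      pad <- function(r, n) {
        if (length(r) < n) c(r, S4Vectors::Rle(0L, n - length(r))) else r
      }
      a[[chrom]] <- pad(a[[chrom]], n) + pad(b[[chrom]], n)
    }
  }
  a
}
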