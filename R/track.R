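#' Genome score tracks
#'
#' A track is a tibble with columns `chrom`, `pos` (0-based) and `value`,
#' carrying one row per covered base pair. Base pairs without a row are gaps:
#' for NF score tracks a gap means "no prediction" (`default_value = NA`),
#' while for DHS count tracks every base pair outside a peak scores 0
#' (`default_value = 0`). The distinction is stored on the object so
#' aggregation never silently confuses the two.
#'
#' @param df Data frame with `chrom`, `pos`, `value`.
#' @param default_value Value implied at base pairs without a row (`NA` = gap).
#' @param mode Free-text label (`"low_res"`, `"high_res"`, `"dhs"`, ...).
#' @return A tibble of class `nf_track`.
#' @export
new_track <- function(df, default_value = NA_real_, mode = "custom") {
  if (nrow(df) == 0L) {
    df <- tibble::tibble(chrom = character(), pos = integer(),
                         value = numeric())
  }
  stopifnot(all(c("chrom", "pos", "value") %in% names(df)))
  out <- tibble::as_tibble(df[, c("chrom", "pos", "value")])
  out$chrom <- as.character(out$chrom)
  out$pos <- as.integer(out$pos)
  out <- dplyr::arrange(out, .data$chrom, .data$pos)
  structure(out, default_value = default_value, mode = mode,
            class = c("nf_track", class(out)))
}

#' Look up track values at positions
#'
#' @param track An [nf_track][new_track].
#' @param chrom Single chromosome name.
#' @param pos Integer vector of 0-based positions.
#' @return Numeric vector: track values, with the track's default (gap `NA` or
#'   0) where no row exists.
#' @export
track_values <- function(track, chrom, pos) {
  stopifnot(inherits(track, "nf_track"))
  sub <- track[track$chrom == chrom, ]
  out <- sub$value[match(pos, sub$pos)]
  default <- attr(track, "default_value")
  if (!is.na(default)) out[is.na(out)] <- default
  out
}

#' Write a track as bedGraph or bigWig
#'
#' Consecutive equal-valued base pairs are collapsed into runs, giving a
#' sorted, non-overlapping 4-column bedGraph. `.bw`/`.bigwig` paths are
#' written through rtracklayer.
#'
#' @param track An [nf_track][new_track].
#' @param path Output path ending in `.bedgraph`/`.bdg` or `.bw`/`.bigwig`.
#' @param seqlengths Optional named vector of reference lengths (required for
#'   bigWig; defaults to `max(pos) + 1` per chromosome).
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path, seqlengths = NULL) {
  stopifnot(inherits(track, "nf_track"))
  runs <- track_runs(track)
  if (grepl("\\.(bw|bigwig)$", tolower(path))) {
    sl <- seqlengths %||% vapply(
      split(track$pos, track$chrom), function(p) max(p) + 1L, integer(1L)
    )
    gr <- GenomicRanges::GRanges(
      seqnames = runs$chrom,
      ranges = IRanges::IRanges(start = runs$start + 1L, end = runs$end),
      score = runs$value, seqlengths = sl
    )
    rtracklayer::export.bw(gr, path)
  } else {
    atomic_write_lines(
      paste(runs$chrom, runs$start, runs$end, format_num(runs$value),
            sep = "\t"),
      path
    )
  }
  invisible(path)
}

# collapse a per-bp track into bedGraph-style runs (0-based half-open)
track_runs <- function(track) {
  if (nrow(track) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), value = numeric()))
  }
  dplyr::bind_rows(lapply(split(track, track$chrom), function(d) {
    d <- d[order(d$pos), ]
    new_run <- c(TRUE, diff(d$pos) != 1L | d$value[-1L] != d$value[-nrow(d)])
    grp <- cumsum(new_run)
    tibble::tibble(
      chrom = d$chrom[1L],
      start = d$pos[!duplicated(grp)],
      end = d$pos[rev(!duplicated(rev(grp)))] + 1L,
      value = d$value[!duplicated(grp)]
    )
  }))
}

#' Read a bedGraph file as a per-bp track
#'
#' @param path 4-column bedGraph (no header; track lines not supported).
#' @param default_value Gap semantics of the resulting track (see
#'   [new_track()]).
#' @return An [nf_track][new_track].
#' @export
read_bedgraph <- function(path, default_value = NA_real_) {
  d <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "value"),
    col_types = "ciid", progress = FALSE
  )
  per_bp <- tidyr::unnest(
    dplyr::mutate(d, pos = purrr::map2(.data$start, .data$end - 1L, seq)),
    "pos"
  )
  new_track(per_bp[, c("chrom", "pos", "value")],
            default_value = default_value, mode = "bedgraph")
}
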