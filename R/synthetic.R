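#' Specification of a synthetic training benchmark
#'
#' Describes balanced two-class sets of 147-bp sequences emulating the shape
#' of an MNase-derived nucleosome benchmark: the nucleosomal class carries an
#' `AA`/`TT` dinucleotide placed with elevated probability on a ~10-bp grid
#' (the rotational positioning signal), the linker class is background
#' sequence with one embedded stiff poly(dA:dT) tract that disfavours
#' wrapping.
#'
#' @param n_pos,n_neg Numbers of nucleosomal / linker sequences.
#' @param seq_length Sequence length in bp (147, the nucleosomal wrap).
#' @param period Dinucleotide periodicity of the nucleosomal class in bp.
#' @param amplitude Probability of placing an `AA`/`TT` at each grid position,
#'   in `[0, 1]`.
#' @param polyA_tract Length range (`c(min, max)`) of the linker class's
#'   poly(dA:dT) tract.
#' @param gc_skew Probability shift from A/T toward G/C in the background
#'   composition (0 = uniform 0.25 each).
#' @param seed Integer seed; all generation is deterministic given the spec.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_pos = 100, n_neg = 100, seq_length = 147,
                           period = 10, amplitude = 0.8,
                           polyA_tract = c(20, 40), gc_skew = 0,
                           seed = 1L) {
  stopifnot(n_pos >= 0, n_neg >= 0, period >= 2,
            amplitude >= 0, amplitude <= 1,
            length(polyA_tract) == 2L, polyA_tract[1L] <= polyA_tract[2L],
            polyA_tract[2L] < seq_length)
  structure(
    list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
         seq_length = as.integer(seq_length), period = as.integer(period),
         amplitude = amplitude, polyA_tract = as.integer(polyA_tract),
         gc_skew = gc_skew, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

base_probs <- function(gc_skew) {
  p <- c(A = 0.25 - gc_skew / 2, C = 0.25 + gc_skew / 2,
         G = 0.25 + gc_skew / 2, T = 0.25 - gc_skew / 2)
  p / sum(p)
}

#' Generate a labeled synthetic training set
#'
#' Nucleosomal sequences (label 1): background bases with an `AA` or `TT`
#' dinucleotide written at each position of a per-sequence random-phase
#' `period`-bp grid with probability `amplitude`. Because the phase is random,
#' the class signal is positionally shifted between sequences and is only
#' recoverable through the power spectrum — exactly the property the
#' featurization is built for. Linker sequences (label 0): background bases
#' with one poly(dA) or poly(dT) tract of random length in `polyA_tract`
#' embedded at a random position.
#'
#' @param spec A [synthetic_spec()].
#' @return A tibble with columns `id`, `seq`, `label`, byte-identical across
#'   runs for a fixed spec.
#' @export
gen_training_set <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  bases <- c("A", "C", "G", "T")
  pr <- base_probs(spec$gc_skew)
  L <- spec$seq_length
  pos_seqs <- character(spec$n_pos)
  for (i in seq_len(spec$n_pos)) {
    s <- sample(bases, L, replace = TRUE, prob = pr)
    phase <- sample.int(spec$period, 1L)
    grid <- seq.int(phase, L - 1L, by = spec$period)
    place <- grid[stats::runif(length(grid)) < spec$amplitude]
    for (g in place) s[g:(g + 1L)] <- sample(c("A", "T"), 1L)
    pos_seqs[i] <- paste(s, collapse = "")
  }
  neg_seqs <- character(spec$n_neg)
  for (i in seq_len(spec$n_neg)) {
    s <- sample(bases, L, replace = TRUE, prob = pr)
    tract_len <- sample(seq.int(spec$polyA_tract[1L], spec$polyA_tract[2L]), 1L)
    at <- sample.int(L - tract_len + 1L, 1L)
    s[at:(at + tract_len - 1L)] <- sample(c("A", "T"), 1L)
    neg_seqs[i] <- paste(s, collapse = "")
  }
  tibble::tibble(
    id = c(sprintf("nuc_%04d", seq_len(spec$n_pos)),
           sprintf("link_%04d", seq_len(spec$n_neg))),
    seq = c(pos_seqs, neg_seqs),
    label = rep(c(1L, 0L), c(spec$n_pos, spec$n_neg))
  )
}

#' Generate a toy pentamer shape table
#'
#' Complete 1024-entry tables for testing and simulation:
#' * `constant` — every field of every pentamer equals `value`;
#' * `at_content` — every field increases monotonically with the pentamer's
#'   A/T count (which is reverse-complement invariant, so the table is
#'   rc-symmetric by construction);
#' * `rc_symmetric_random` — independent Gaussian values per
#'   reverse-complement pair, assigned so that a sequence and its reverse
#'   complement always yield mirrored shape profiles: MGW/ProT/Roll-pair and
#'   HelT-pair values of a pentamer and its reverse complement are equal with
#'   the two step values swapped.
#'
#' @param mode One of `"constant"`, `"at_content"`, `"rc_symmetric_random"`.
#' @param seed Integer seed (used by `rc_symmetric_random`).
#' @param value Constant for `mode = "constant"`.
#' @return A [pentamer_tbl][load_pentamer_table] flagged `rc_symmetric`.
#' @export
gen_toy_pentamer_table <- function(mode = c("rc_symmetric_random", "constant",
                                            "at_content"),
                                   seed = 1L, value = 1) {
  mode <- match.arg(mode)
  pents <- all_pentamers()
  n <- length(pents)
  if (mode == "constant") {
    tbl <- tibble::tibble(
      pentamer = pents,
      MGW = rep(value, n), ProT = rep(value, n),
      HelT1 = rep(value, n), HelT2 = rep(value, n),
      Roll1 = rep(value, n), Roll2 = rep(value, n)
    )
  } else if (mode == "at_content") {
    at <- vapply(strsplit(pents, ""), function(ch) sum(ch %in% c("A", "T")),
                 integer(1L))
    tbl <- tibble::tibble(
      pentamer = pents,
      MGW = 4 + at, ProT = -10 + 2 * at,
      HelT1 = 34 + at, HelT2 = 34 + at,
      Roll1 = -2 + at, Roll2 = -2 + at
    )
  } else {
    set.seed(as.integer(seed))
    rc <- vapply(pents, revcomp, "")
    canonical <- pmin(pents, rc)
    reps <- unique(canonical)
    draw <- function(mu, sd) {
      v <- stats::rnorm(length(reps), mu, sd)
      names(v) <- reps
      v
    }
    mgw_r <- draw(5, 0.5); prot_r <- draw(-7, 3)
    h1_r <- draw(34, 2); h2_r <- draw(34, 2)
    r1_r <- draw(0, 3); r2_r <- draw(0, 3)
    is_canon <- pents == canonical
    tbl <- tibble::tibble(
      pentamer = pents,
      MGW = unname(mgw_r[canonical]),
      ProT = unname(prot_r[canonical]),
      HelT1 = unname(ifelse(is_canon, h1_r[canonical], h2_r[canonical])),
      HelT2 = unname(ifelse(is_canon, h2_r[canonical], h1_r[canonical])),
      Roll1 = unname(ifelse(is_canon, r1_r[canonical], r2_r[canonical])),
      Roll2 = unname(ifelse(is_canon, r2_r[canonical], r1_r[canonical]))
    )
  }
  new_pentamer_tbl(tbl, source = paste0("synthetic:", mode),
                   rc_symmetric = TRUE)
}

#' Generate a toy genome with nucleosome-favourable islands
#'
#' Builds a background emulating linker-like sequence (uniform-composition
#' background with a poly(dA:dT) tract embedded roughly every 150 bp) and
#' plants `n_islands` non-overlapping 147-bp nucleosome-favourable islands
#' carrying the periodic dinucleotide signal of the positive training class.
#' A truth table records island coordinates for scanner validation.
#'
#' @param length Genome length in bp (>= 147).
#' @param n_islands Number of embedded islands.
#' @param seed Integer seed.
#' @param island_length Island width in bp (default 147).
#' @param period,amplitude Periodic signal parameters, as in
#'   [gen_training_set()].
#' @param tract_every Mean spacing of background poly(dA:dT) tracts in bp; set
#'   `Inf` for a plain uniform background.
#' @param chrom Reference name used in the truth table.
#' @return A list with `genome` (named character vector of one sequence) and
#'   `truth` (an [interval_set][read_intervals] of island coordinates,
#'   0-based half-open, strand `+`).
#' @export
gen_toy_genome <- function(length, n_islands, seed = 1L, island_length = 147L,
                           period = 10L, amplitude = 0.8, tract_every = 150,
                           chrom = "toy1") {
  length <- as.integer(length)
  if (length < 147L) stop("genome length must be >= 147", call. = FALSE)
  n_islands <- as.integer(n_islands)
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  s <- sample(bases, length, replace = TRUE)
  if (is.finite(tract_every) && tract_every > 0) {
    n_tracts <- max(0L, as.integer(round(length / tract_every)))
    for (i in seq_len(n_tracts)) {
      tl <- sample(20:40, 1L)
      at <- sample.int(length - tl + 1L, 1L)
      s[at:(at + tl - 1L)] <- sample(c("A", "T"), 1L)
    }
  }
  # place non-overlapping islands on a slot grid, then fill with the periodic
  # positive-class signal
  n_slots <- length %/% (island_length + 20L)
  if (n_islands > n_slots) {
    stop("cannot place ", n_islands, " non-overlapping islands of ",
         island_length, " bp in ", length, " bp", call. = FALSE)
  }
  slots <- sort(sample.int(n_slots, n_islands))
  starts <- (slots - 1L) * (island_length + 20L) +
    sample.int(20L, n_islands, replace = TRUE)      # 0-based island starts
  for (st in starts) {
    # islands are positive-class material through and through: fresh
    # background (clearing any tract that landed here) plus the periodic
    # dinucleotide signal
    s[(st + 1L):(st + island_length)] <- sample(bases, island_length,
                                                replace = TRUE)
    phase <- sample.int(period, 1L)
    grid <- seq.int(phase, island_length - 1L, by = period)
    place <- grid[stats::runif(base::length(grid)) < amplitude]
    for (g in place) {
      s[st + g + 0:1] <- sample(c("A", "T"), 1L)
    }
  }
  genome <- stats::setNames(paste(s, collapse = ""), chrom)
  truth <- new_interval_set(tibble::tibble(
    chrom = chrom, start = as.integer(starts),
    end = as.integer(starts + island_length),
    name = sprintf("island_%04d", seq_len(n_islands)), strand = "+",
    point_source_offset = NA_integer_
  ))
  list(genome = genome, truth = truth)
}

#' Generate a panel of peak files for DHS score testing
#'
#' Writes `n_files` BED files of random peaks such that exactly `n_covering`
#' of them contain a peak overlapping the base pair `covered_bp`, and the
#' remaining files avoid it.
#'
#' @param n_files Number of files (cell lines).
#' @param covered_bp 0-based base pair that `n_covering` files must cover.
#' @param n_covering Number of files covering `covered_bp`
#'   (`0 <= n_covering <= n_files`).
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @param chrom Reference name.
#' @param region_length Coordinate space for the random peaks.
#' @return Character vector of the file paths written.
#' @export
gen_peak_panel <- function(n_files, covered_bp, n_covering, seed = 1L,
                           dir = tempfile("peaks"), chrom = "toy1",
                           region_length = 10000L) {
  n_files <- as.integer(n_files)
  n_covering <- as.integer(n_covering)
  covered_bp <- as.integer(covered_bp)
  if (n_covering > n_files || n_covering < 0L) {
    stop("n_covering must be in 0..n_files", call. = FALSE)
  }
  stopifnot(covered_bp >= 0L, covered_bp < region_length)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(seed))
  covering <- seq_len(n_files) <= n_covering
  paths <- character(n_files)
  for (i in seq_len(n_files)) {
    peaks <- list()
    if (covering[i]) {
      w <- sample(50:200, 1L)
      off <- sample.int(w, 1L) - 1L
      st <- max(0L, covered_bp - off)
      peaks[[1L]] <- c(st, st + w)
    }
    # a few extra peaks that must not touch covered_bp
    for (k in seq_len(sample.int(3L, 1L))) {
      w <- sample(50:200, 1L)
      st <- sample.int(region_length - w, 1L) - 1L
      if (st <= covered_bp && covered_bp < st + w) next
      peaks[[base::length(peaks) + 1L]] <- c(st, st + w)
    }
    paths[i] <- file.path(dir, sprintf("cell_%03d.bed", i))
    lines <- vapply(peaks, function(p) paste(chrom, p[1L], p[2L], sep = "\t"),
                    "")
    atomic_write_lines(lines, paths[i])
  }
  paths
}
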