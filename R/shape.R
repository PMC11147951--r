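#' Compute DNA shape profiles from sequence via pentamer lookup
#'
#' Maps a DNA sequence to per-position structural parameters using a pentamer
#' lookup table. MGW (minor groove width) and ProT (propeller twist) at
#' position `i` are read from the pentamer centred at `i`, so they are defined
#' at positions `3..L-2`. HelT (helix twist) and Roll are base-pair-step
#' parameters: every pentamer predicts the two steps flanking its centre, each
#' step value is the mean over all pentamers predicting it, and the value
#' reported at position `i` is the mean of the step(s) flanking `i` that carry
#' a prediction. That leaves positions `2..L-1` defined, so for a 147-bp
#' sequence the four channels carry 143, 143, 145 and 145 values — 576 in
#' total, i.e. `4*147 - 12`.
#'
#' Sequences must be pure `ACGT` (case-insensitive). Ambiguity codes,
#' including `N`, are an error at this layer: window masking is the genome
#' scanner's job, keeping featurization unambiguous.
#'
#' @param seq A single DNA string (length >= 5) over `ACGT`, any case.
#' @param table A [pentamer_tbl][load_pentamer_table].
#' @return A tibble of class `shape_profile` with one row per sequence
#'   position (1-based `pos`) and columns `MGW`, `ProT`, `HelT`, `Roll`;
#'   positions outside each channel's defined range are `NA`. The attribute
#'   `seq_length` records `L`.
#' @examples
#' tab <- gen_toy_pentamer_table("at_content")
#' prof <- compute_shape(strrep("ACGT", 40), tab)
#' dplyr::summarise(prof, dplyr::across(MGW:Roll, ~sum(!is.na(.x))))
#' @export
compute_shape <- function(seq, table) {
  stopifnot(is.character(seq), length(seq) == 1L)
  L <- nchar(seq)
  if (L < 5L) stop("sequence must be at least 5 bp, got ", L, call. = FALSE)
  codes <- base_codes(seq)
  if (anyNA(codes)) {
    bad <- which(is.na(codes))[1L]
    stop("non-ACGT base '", substr(seq, bad, bad), "' at position ", bad,
         "; mask or split the sequence before computing shape", call. = FALSE)
  }
  ch <- shape_channels_from_codes(codes, table_lookup(table))
  out <- tibble::tibble(
    pos = seq_len(L),
    MGW = pad_channel(ch$MGW, L, 3L),
    ProT = pad_channel(ch$ProT, L, 3L),
    HelT = pad_channel(ch$HelT, L, 2L),
    Roll = pad_channel(ch$Roll, L, 2L)
  )
  structure(out, seq_length = L,
            class = c("shape_profile", class(out)))
}

pad_channel <- function(vals, L, first_defined) {
  out <- rep(NA_real_, L)
  out[first_defined + seq_along(vals) - 1L] <- vals
  out
}

# Core channel computation on integer base codes (0..3). Returns the defined
# values only: MGW/ProT for positions 3..L-2, HelT/Roll for positions 2..L-1.
shape_channels_from_codes <- function(codes, lookup) {
  L <- length(codes)
  n_pent <- L - 4L
  idx <- 256L * codes[1:n_pent] + 64L * codes[2:(n_pent + 1L)] +
    16L * codes[3:(n_pent + 2L)] + 4L * codes[4:(n_pent + 3L)] +
    codes[5:(n_pent + 4L)] + 1L
  mgw <- lookup$MGW[idx]
  prot <- lookup$ProT[idx]
  h1 <- lookup$HelT1[idx]; h2 <- lookup$HelT2[idx]
  r1 <- lookup$Roll1[idx]; r2 <- lookup$Roll2[idx]
  if (anyNA(c(mgw, prot, h1, h2, r1, r2))) {
    stop("pentamer missing from table for this sequence; use a complete table",
         call. = FALSE)
  }
  list(
    MGW = mgw, ProT = prot,
    HelT = step_to_position(h1, h2, L),
    Roll = step_to_position(r1, r2, L)
  )
}

# h1[c]/h2[c] are the predictions of the pentamer centred at position c+2
# (c = 1..L-4) for the steps (c+1, c+2) and (c+2, c+3). Steps 2..L-2 carry
# predictions; per-position values are the mean of the defined flanking steps,
# leaving positions 2..L-1 defined (L-2 values).
step_to_position <- function(h1, h2, L) {
  n_pent <- L - 4L
  n_step <- L - 3L                     # steps 2 .. L-2
  step <- numeric(n_step)
  step[1L] <- h1[1L]
  step[n_step] <- h2[n_pent]
  if (n_step > 2L) {
    step[2:(n_step - 1L)] <- (h2[1:(n_pent - 1L)] + h1[2:n_pent]) / 2
  }
  n_pos <- L - 2L                      # positions 2 .. L-1
  pos <- numeric(n_pos)
  pos[1L] <- step[1L]
  pos[n_pos] <- step[n_step]
  if (n_pos > 2L) {
    pos[2:(n_pos - 1L)] <- (step[1:(n_step - 1L)] + step[2:n_step]) / 2
  }
  pos
}

#' Reverse complement of a DNA string
#' @param seq A DNA string over `ACGTacgt`.
#' @return The reverse complement, uppercase.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(seq))))
}
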