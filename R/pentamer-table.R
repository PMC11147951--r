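#' Load a pentamer DNA-shape lookup table
#'
#' Reads the TSV dialect used to distribute pentamer shape tables: a header
#' line `pentamer MGW ProT HelT1 HelT2 Roll1 Roll2`, one row per 5-mer over
#' `ACGT`, `#` comment lines, and optional `##key=value` metadata comments
#' (e.g. `##rc_symmetric=true`, `##source=...`). MGW (minor groove width,
#' angstroms) and ProT (propeller twist, degrees) are per-base-pair values at
#' the pentamer centre; HelT (helix twist) and Roll carry two values each, for
#' the two base-pair steps flanking the centre.
#'
#' @param path Path to the TSV file.
#' @param strict If `TRUE` (default), require all 1024 pentamers.
#' @return A tibble of class `pentamer_tbl` with columns `pentamer`, `MGW`,
#'   `ProT`, `HelT1`, `HelT2`, `Roll1`, `Roll2`, and attributes `source`,
#'   `rc_symmetric` and `complete`.
#' @seealso [gen_toy_pentamer_table()], [write_pentamer_table()],
#'   [compute_shape()]
#' @export
load_pentamer_table <- function(path, strict = TRUE) {
  if (!file.exists(path)) {
    stop("pentamer table file not found: ", path, call. = FALSE)
  }
  lines <- readr::read_lines(path)
  meta_lines <- grep("^##", lines, value = TRUE)
  meta <- parse_meta_comments(meta_lines)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0L) stop("pentamer table is empty: ", path, call. = FALSE)

  fields <- strsplit(body, "\t", fixed = TRUE)
  arity <- lengths(fields)
  if (any(arity != 7L)) {
    bad <- which(arity != 7L)[1L]
    stop("pentamer table row ", bad, " has ", arity[bad],
         " columns; expected 7 (pentamer MGW ProT HelT1 HelT2 Roll1 Roll2)",
         call. = FALSE)
  }
  header <- fields[[1L]]
  expected <- c("pentamer", "MGW", "ProT", "HelT1", "HelT2", "Roll1", "Roll2")
  if (!identical(header, expected)) {
    stop("pentamer table header must be: ", paste(expected, collapse = " "),
         call. = FALSE)
  }
  rows <- fields[-1L]
  pent <- toupper(vapply(rows, `[[`, "", 1L))
  bad_key <- pent[nchar(pent) != 5L | grepl("[^ACGT]", pent)]
  if (length(bad_key) > 0L) {
    stop("invalid pentamer key (must be 5 characters over ACGT): ",
         bad_key[1L], call. = FALSE)
  }
  dup <- pent[duplicated(pent)]
  if (length(dup) > 0L) {
    stop("duplicate pentamer key: ", dup[1L], call. = FALSE)
  }
  num <- matrix(
    suppressWarnings(as.numeric(unlist(lapply(rows, `[`, 2:7)))),
    ncol = 6L, byrow = TRUE
  )
  if (anyNA(num)) {
    bad <- which(apply(is.na(num), 1L, any))[1L]
    stop("non-numeric shape value in row for pentamer ", pent[bad],
         call. = FALSE)
  }
  tbl <- tibble::tibble(
    pentamer = pent,
    MGW = num[, 1L], ProT = num[, 2L],
    HelT1 = num[, 3L], HelT2 = num[, 4L],
    Roll1 = num[, 5L], Roll2 = num[, 6L]
  )
  complete <- nrow(tbl) == 1024L
  if (strict && !complete) {
    missing <- setdiff(all_pentamers(), tbl$pentamer)
    stop("pentamer table incomplete: ", length(missing),
         " missing pentamer(s), e.g. ",
         paste(utils::head(missing, 5L), collapse = ", "),
         call. = FALSE)
  }
  new_pentamer_tbl(
    tbl,
    source = meta[["source"]] %||% path,
    rc_symmetric = isTRUE(tolower(meta[["rc_symmetric"]] %||% "false") %in%
                            c("true", "1", "yes"))
  )
}

#' Write a pentamer table to the TSV dialect
#'
#' @param table A `pentamer_tbl`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pentamer_table <- function(table, path) {
  stopifnot(inherits(table, "pentamer_tbl"))
  hdr <- c(
    paste0("##source=", attr(table, "source") %||% "unknown"),
    paste0("##rc_symmetric=", tolower(as.character(isTRUE(attr(table, "rc_symmetric")))))
  )
  body <- paste(
    table$pentamer,
    format_num(table$MGW), format_num(table$ProT),
    format_num(table$HelT1), format_num(table$HelT2),
    format_num(table$Roll1), format_num(table$Roll2),
    sep = "\t"
  )
  atomic_write_lines(
    c(hdr, paste(c("pentamer", "MGW", "ProT", "HelT1", "HelT2", "Roll1", "Roll2"),
                 collapse = "\t"), body),
    path
  )
  invisible(path)
}

format_num <- function(x) sprintf("%.15g", x)

new_pentamer_tbl <- function(tbl, source = "unknown", rc_symmetric = FALSE) {
  tbl <- tibble::as_tibble(tbl)
  structure(
    tbl,
    source = source,
    rc_symmetric = rc_symmetric,
    complete = nrow(tbl) == 1024L,
    lookup = build_lookup(tbl),
    class = c("pentamer_tbl", class(tbl))
  )
}

parse_meta_comments <- function(lines) {
  lines <- sub("^##", "", lines)
  kv <- strsplit(lines, "=", fixed = TRUE)
  kv <- kv[lengths(kv) >= 2L]
  out <- lapply(kv, function(x) paste(x[-1L], collapse = "="))
  names(out) <- vapply(kv, `[[`, "", 1L)
  out
}

#' All 1024 pentamers over ACGT
#' @return Character vector of length 1024, in lexicographic order.
#' @export
all_pentamers <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(p5 = b, p4 = b, p3 = b, p2 = b, p1 = b,
                   stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3, g$p4, g$p5)
}

# base-4 code of each pentamer, 1-based: A=0, C=1, G=2, T=3, first base most
# significant. Missing pentamers are NA in the lookup arrays.
pentamer_code <- function(pent) {
  m <- matrix(base_codes(paste(pent, collapse = "")), nrow = 5L)
  as.integer(256L * m[1L, ] + 64L * m[2L, ] + 16L * m[3L, ] + 4L * m[4L, ] +
               m[5L, ] + 1L)
}

# per-character 0..3 codes of a DNA string; NA for anything outside ACGTacgt
base_codes <- function(seq) {
  map <- rep(NA_integer_, 127L)
  map[utf8ToInt("A")] <- 0L; map[utf8ToInt("a")] <- 0L
  map[utf8ToInt("C")] <- 1L; map[utf8ToInt("c")] <- 1L
  map[utf8ToInt("G")] <- 2L; map[utf8ToInt("g")] <- 2L
  map[utf8ToInt("T")] <- 3L; map[utf8ToInt("t")] <- 3L
  ints <- utf8ToInt(seq)
  ints[ints > 127L] <- 127L
  map[ints]
}

build_lookup <- function(tbl) {
  code <- pentamer_code(tbl$pentamer)
  mk <- function(col) {
    v <- rep(NA_real_, 1024L)
    v[code] <- tbl[[col]]
    v
  }
  list(MGW = mk("MGW"), ProT = mk("ProT"),
       HelT1 = mk("HelT1"), HelT2 = mk("HelT2"),
       Roll1 = mk("Roll1"), Roll2 = mk("Roll2"))
}

table_lookup <- function(table) {
  lk <- attr(table, "lookup")
  if (is.null(lk)) lk <- build_lookup(table)
  lk
}

`%||%` <- function(a, b) if (is.null(a)) b else a
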