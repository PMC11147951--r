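#' Resolved run configuration
#'
#' Collects the method's constants and the run's paths in one serializable
#' object: 147-bp window, steps of 50 (low resolution) and 7 (high
#' resolution), taper 0.1, smoothing span 10, 500 trees. Values given in a
#' flat `key = value` config file are overridden by values passed directly
#' (mirroring "CLI flag beats config file").
#'
#' @param ... Named overrides of the defaults (unknown keys are an error).
#' @param file Optional path to a flat `key = value` config file.
#' @return A named list of class `nf_config`.
#' @export
nf_config <- function(..., file = NULL) {
  defaults <- list(
    window = 147L, step_low = 50L, step_high = 7L,
    taper = 0.1, span = 10L, n_trees = 500L, seed = 1L,
    phase = 0L, flank = 250L, mode = "low",
    table = NA_character_, model = NA_character_, fasta = NA_character_,
    intervals = NA_character_, out = NA_character_,
    log_level = "info"
  )
  from_file <- if (!is.null(file)) read_config(file) else list()
  overrides <- list(...)
  cfg <- defaults
  for (src in list(from_file, overrides)) {
    unknown <- setdiff(names(src), names(defaults))
    if (length(unknown) > 0L) {
      stop("unknown config key: ", unknown[1L], call. = FALSE)
    }
    for (k in names(src)) {
      cfg[[k]] <- coerce_like(src[[k]], defaults[[k]])
    }
  }
  validate_config(cfg)
  structure(cfg, class = "nf_config")
}

coerce_like <- function(value, template) {
  if (length(value) == 1L && is.character(value) && value == "NA") value <- NA
  if (is.integer(template)) as.integer(value)
  else if (is.double(template)) as.double(value)
  else as.character(value)
}

validate_config <- function(cfg) {
  if (cfg$window != 147L) stop("config: window must be 147", call. = FALSE)
  if (cfg$taper < 0 || cfg$taper > 0.5) {
    stop("config: taper must be in [0, 0.5]", call. = FALSE)
  }
  if (cfg$span < 1L) stop("config: span must be >= 1", call. = FALSE)
  if (cfg$n_trees < 1L) stop("config: n_trees must be >= 1", call. = FALSE)
  if (cfg$step_low < 1L || cfg$step_low > cfg$window) {
    stop("config: step_low must be in 1..147", call. = FALSE)
  }
  if (cfg$window %% cfg$step_high != 0L) {
    stop("config: step_high must be a divisor of the 147-bp window",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Read / write a flat key-value config file
#'
#' One `key = value` pair per line; `#` comments and blank lines ignored.
#'
#' @param path Config file path.
#' @return `read_config`: a named list of strings. `write_config`: `path`,
#'   invisibly.
#' @export
read_config <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z_]+)\\s*=\\s*(.*?)\\s*$", lines))
  bad <- which(lengths(kv) != 3L)
  if (length(bad) > 0L) {
    stop("config line not of the form key = value: ", lines[bad[1L]],
         call. = FALSE)
  }
  stats::setNames(lapply(kv, `[[`, 3L), vapply(kv, `[[`, "", 2L))
}

#' @rdname read_config
#' @param config An [nf_config][nf_config].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "nf_config"))
  vals <- vapply(config, function(v) {
    if (is.na(v)) "NA" else format_num_or_chr(v)
  }, "")
  atomic_write_lines(paste(names(config), vals, sep = " = "), path)
  invisible(path)
}

format_num_or_chr <- function(v) {
  if (is.numeric(v)) format_num(v) else as.character(v)
}
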