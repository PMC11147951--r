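#' @importFrom rlang .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
ggplot2::autoplot

#' @export
generics::tidy

#' @export
generics::glance

# write lines atomically: temp file in the target directory, then rename
atomic_write_lines <- function(lines, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tmp <- file.path(dirname(path),
                   paste0(".", basename(path), ".tmp", Sys.getpid()))
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    stop("failed to write ", path, call. = FALSE)
  }
  invisible(path)
}
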