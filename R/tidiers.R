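#' Tidy a fitted NF model into its feature importance table
#'
#' @param x An [nf_model][nf_train].
#' @param ... Unused.
#' @return The [feature_importance()] tibble (descending Gini importance).
#' @export
tidy.nf_model <- function(x, ...) feature_importance(x)

#' One-row summary of a fitted NF model
#'
#' @param x An [nf_model][nf_train].
#' @param ... Unused.
#' @return A tibble with `n_trees`, `mtry`, `seed`, `n_train`, `n_nucleosomal`,
#'   `n_linker` and the out-of-bag error estimate `oob_error`.
#' @export
glance.nf_model <- function(x, ...) {
  tibble::tibble(
    n_trees = x$n_trees,
    mtry = x$mtry,
    seed = x$seed,
    n_train = x$n_train,
    n_nucleosomal = as.integer(x$class_counts[["nucleosomal"]]),
    n_linker = as.integer(x$class_counts[["linker"]]),
    oob_error = x$forest$err.rate[x$n_trees, "OOB"]
  )
}

#' Per-fold metrics of a cross-validation run
#'
#' @param x An [nf_cv][cross_validate].
#' @param ... Unused.
#' @return A long tibble with `fold`, `metric`, `value`.
#' @export
tidy.nf_cv <- function(x, ...) {
  tidyr::pivot_longer(x$folds, -"fold", names_to = "metric",
                      values_to = "value")
}

#' One-row cross-validation summary
#'
#' @param x An [nf_cv][cross_validate].
#' @param ... Unused.
#' @return A tibble with one `<metric>_mean` / `<metric>_sd` pair per metric
#'   plus `k` and the pooled confusion counts.
#' @export
glance.nf_cv <- function(x, ...) {
  s <- x$summary
  wide <- stats::setNames(
    as.list(c(s$mean, s$sd)),
    c(paste0(s$metric, "_mean"), paste0(s$metric, "_sd"))
  )
  dplyr::bind_cols(tibble::as_tibble(wide), tibble::tibble(k = x$k),
                   x$confusion)
}

#' Export a cross-validation report as TSV
#'
#' Two-column layout (`metric`, `mean (+/- sd)`) mirroring the conventional
#' performance table of the method.
#'
#' @param cv An [nf_cv][cross_validate].
#' @param path Output path.
#' @param digits Rounding for display.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(cv, path, digits = 4) {
  stopifnot(inherits(cv, "nf_cv"))
  s <- cv$summary
  atomic_write_lines(
    c("metric\tmean\tsd",
      paste(s$metric, round(s$mean, digits), round(s$sd, digits), sep = "\t")),
    path
  )
  invisible(path)
}

#' Export a feature importance table as TSV
#'
#' Columns `rank`, `shape`, `freq_index`, `importance`, mirroring the
#' conventional top-feature table (mean decrease in Gini impurity).
#'
#' @param model An [nf_model][nf_train].
#' @param path Output path.
#' @param top_n Number of rows to write (default all 288).
#' @return `path`, invisibly.
#' @export
write_importance <- function(model, path, top_n = Inf) {
  imp <- feature_importance(model)
  imp <- utils::head(imp, top_n)
  atomic_write_lines(
    c("rank\tfeature\tshape\tfreq_index\tgini_importance",
      paste(seq_len(nrow(imp)), imp$feature, imp$shape, imp$freq_index,
            round(imp$importance, 4), sep = "\t")),
    path
  )
  invisible(path)
}

#' Save / load a fitted NF model
#'
#' A single-file serialization with an embedded format version and the
#' training metadata, so a loaded model refuses silently mismatched formats.
#'
#' @param model An [nf_model][nf_train].
#' @param path Output path (`.rds`).
#' @return `path` invisibly (`save_model`); the model (`load_model`).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "nf_model"))
  payload <- list(format = "nf_model/1", model = model)
  tmp <- paste0(path, ".tmp", Sys.getpid())
  saveRDS(payload, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$format, "nf_model/1")) {
    stop("not an nf_model file (format tag missing or unsupported): ", path,
         call. = FALSE)
  }
  payload$model
}
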