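# Shared fixtures, built lazily once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, build) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, build(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

toy_table <- function(mode = "rc_symmetric_random", seed = 7) {
  fixture(paste0("table_", mode, "_", seed),
          function() gen_toy_pentamer_table(mode, seed = seed))
}

# small labeled feature set with a clear class margin (shared by classifier
# and CV tests)
separable_features <- function() {
  fixture("separable_features", function() {
    ts <- gen_training_set(synthetic_spec(n_pos = 60, n_neg = 60, seed = 11))
    featurize_set(ts, toy_table())
  })
}

# forest trained on the separable fixture (shared by scan tests)
separable_model <- function() {
  fixture("separable_model",
          function() nf_train(separable_features(), n_trees = 200, seed = 2))
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# feature tibble with no sequence behind it: N(0,1) features, a class shift of
# `delta` added to the columns in `shifted`, for classifier-layer tests
craft_feature_set <- function(n_per_class, shifted, delta, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  m <- matrix(abs(rnorm(n * 288)), n, 288,
              dimnames = list(NULL, nf_feature_names()))
  label <- rep(c(1L, 0L), each = n_per_class)
  m[label == 1L, shifted] <- m[label == 1L, shifted] + delta
  dplyr::bind_cols(
    tibble::tibble(id = as.character(seq_len(n)), label = label),
    tibble::as_tibble(m)
  )
}

write_bed <- function(lines, path = tempfile(fileext = ".bed")) {
  writeLines(lines, path)
  path
}
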