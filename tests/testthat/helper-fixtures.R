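# Shared synthetic fixtures, generated once per test session into a
# temporary directory.

fixture_env <- new.env()

# Small two-modality dataset (32x32, 10 images per class x modality) plus its
# preprocessed counterpart.
small_dataset <- function() {
  if (is.null(fixture_env$small)) {
    dir <- file.path(tempdir(), "lwunet-small")
    m <- generate_dataset(10, size = 32, seed = 42, out_dir = dir,
                          train_fraction = 0.8)
    pm <- preprocess_dataset(m, size = 32, out_dir = file.path(dir, "proc"))
    fixture_env$small <- list(raw = m, proc = pm, dir = dir)
  }
  fixture_env$small
}

md5_tree <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  vapply(files, function(f) as.character(tools::md5sum(f)), "")
}
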