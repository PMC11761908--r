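#' Dataset manifests
#'
#' A dataset manifest is the unit every pipeline stage consumes and produces:
#' a data frame with columns `path`, `modality` (`"MGI"` or `"USI"`),
#' `label` (`"benign"` or `"malignant"`), `split` (`"train"` or `"test"`) and
#' `fold` (an integer fold id, or `"none"` when no fold is assigned).
#' Manifests are stored as plain CSV with exactly that header.
#'
#' @param records data frame with the five manifest columns.
#' @param image_size edge length, in pixels, of the images the manifest refers to.
#' @param seed integer seed the images were generated with (or `NA`).
#' @return A `lwunet_manifest`: the validated data frame with `image_size` and
#'   `seed` attached as attributes.
#' @export
manifest <- function(records, image_size = NA_integer_, seed = NA_integer_) {
  cols <- c("path", "modality", "label", "split", "fold")
  lw_assert(is.data.frame(records), "manifest records must be a data frame")
  lw_assert(all(cols %in% names(records)),
            "manifest needs columns: ", paste(cols, collapse = ", "))
  records <- records[, cols]
  records$path <- as.character(records$path)
  records$modality <- as.character(records$modality)
  records$label <- as.character(records$label)
  records$split <- as.character(records$split)
  records$fold <- as.character(records$fold)
  lw_assert(!anyDuplicated(records$path), "manifest paths must be unique")
  lw_assert(all(records$modality %in% LWUNET_MODALITIES),
            "unknown modality tag in manifest")
  lw_assert(all(records$label %in% LWUNET_LABELS),
            "unknown label in manifest")
  lw_assert(all(records$split %in% c("train", "test")),
            "split must be 'train' or 'test'")
  structure(records,
            image_size = as.integer(image_size),
            seed = as.integer(seed),
            class = c("lwunet_manifest", "data.frame"))
}

#' @rdname manifest
#' @param path file to read from / write to.
#' @export
read_manifest <- function(path) {
  lw_assert(file.exists(path), "manifest file not found: ", path,
            class = "lwunet_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  side <- paste0(path, ".json")
  image_size <- NA_integer_; seed <- NA_integer_
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    if (!is.null(meta$image_size)) image_size <- as.integer(meta$image_size)
    if (!is.null(meta$seed)) seed <- as.integer(meta$seed)
  }
  manifest(df, image_size = image_size, seed = seed)
}

#' @rdname manifest
#' @param m a `lwunet_manifest`.
#' @export
write_manifest <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = FALSE, quote = FALSE)
  meta <- list(image_size = attr(m, "image_size"), seed = attr(m, "seed"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
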