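#' Write a dataset to a directory
#'
#' Serialises a dataset as: `hierarchy.csv` (two-column delimited text,
#' header `class_id,superclass_id`), one raw little-endian float64 tensor
#' file plus an int32 label file per split, an optional prototype tensor,
#' and `manifest.json` recording shapes, dtypes, split tags, the generator
#' config and seed. The round trip through [read_dataset()] is bit-exact.
#'
#' @param ds A `synthetic_dataset`, or a list with elements `train`, `test`
#'   (stimulus sets) and `hierarchy`.
#' @param directory Target directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(ds, directory) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  hierarchy <- ds$hierarchy
  validate_hierarchy(hierarchy)
  readr::write_csv(tibble::as_tibble(hierarchy)[, c("class_id", "superclass_id")],
                   file.path(directory, "hierarchy.csv"))

  splits <- list()
  for (tag in c("train", "test")) {
    set <- ds[[tag]]
    stopifnot(inherits(set, "stimulus_set"))
    img_file <- paste0(tag, "_images.bin")
    lab_file <- paste0(tag, "_labels.bin")
    con <- file(file.path(directory, img_file), "wb")
    writeBin(as.double(set$images), con, size = 8, endian = "little")
    close(con)
    con <- file(file.path(directory, lab_file), "wb")
    writeBin(as.integer(set$labels), con, size = 4, endian = "little")
    close(con)
    splits[[tag]] <- list(images = img_file, labels = lab_file,
                          shape = dim(set$images), dtype = "float64",
                          label_dtype = "int32", split_tag = set$split_tag)
  }

  manifest <- list(format = "degensim-dataset", version = 1L, splits = splits)
  if (!is.null(ds$prototypes)) {
    con <- file(file.path(directory, "prototypes.bin"), "wb")
    writeBin(as.double(ds$prototypes), con, size = 8, endian = "little")
    close(con)
    manifest$prototypes <- list(file = "prototypes.bin", shape = dim(ds$prototypes),
                                dtype = "float64")
  }
  if (!is.null(ds$config)) {
    manifest$generator_config <- unclass(ds$config)
    manifest$seed <- ds$config$seed
  }
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(directory)
}

manifest_field <- function(manifest, field, where) {
  if (is.null(manifest[[field]])) {
    abort(sprintf("Dataset manifest is missing required field `%s`%s.",
                  field, where),
          class = "degensim_format_error")
  }
  manifest[[field]]
}

#' Read a dataset written by [write_dataset()]
#'
#' @param directory Directory containing `manifest.json`, `hierarchy.csv`
#'   and the tensor files.
#' @return A `synthetic_dataset` list (`train`, `test`, `hierarchy`, and
#'   `prototypes`/`config` when present in the container).
#' @export
read_dataset <- function(directory) {
  manifest_path <- file.path(directory, "manifest.json")
  if (!file.exists(manifest_path)) {
    abort(sprintf("No manifest.json found in `%s`.", directory),
          class = "degensim_format_error")
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  hier_path <- file.path(directory, "hierarchy.csv")
  if (!file.exists(hier_path)) {
    abort("Dataset directory is missing hierarchy.csv.",
          class = "degensim_format_error")
  }
  h <- readr::read_csv(hier_path, col_types = "ii")
  K <- as.integer(table(h$superclass_id)[1])
  hierarchy <- make_hierarchy(length(unique(h$superclass_id)), K)
  if (!identical(hierarchy$class_id, as.integer(h$class_id)) ||
      !identical(hierarchy$superclass_id, as.integer(h$superclass_id))) {
    # Non-balanced or reordered hierarchies round-trip as stored.
    hierarchy <- structure(tibble::as_tibble(h),
                           class = c("class_hierarchy", class(tibble::tibble())),
                           n_classes = nrow(h),
                           n_superclasses = length(unique(h$superclass_id)))
  }

  splits <- manifest_field(manifest, "splits", "")
  out <- list(hierarchy = hierarchy)
  for (tag in c("train", "test")) {
    sp <- manifest_field(splits, tag, " (splits)")
    shape <- as.integer(manifest_field(sp, "shape", sprintf(" (splits$%s)", tag)))
    img_file <- manifest_field(sp, "images", sprintf(" (splits$%s)", tag))
    lab_file <- manifest_field(sp, "labels", sprintf(" (splits$%s)", tag))
    n_vals <- prod(shape)
    con <- file(file.path(directory, img_file), "rb")
    imgs <- readBin(con, "double", n = n_vals, size = 8, endian = "little")
    close(con)
    if (length(imgs) != n_vals) {
      abort(sprintf("Tensor file `%s` is truncated.", img_file),
            class = "degensim_format_error")
    }
    con <- file(file.path(directory, lab_file), "rb")
    labels <- readBin(con, "integer", n = shape[1], size = 4, endian = "little")
    close(con)
    out[[tag]] <- stimulus_set(array(imgs, dim = shape), labels, hierarchy,
                               sp$split_tag %||% tag)
  }
  if (!is.null(manifest$prototypes)) {
    shape <- as.integer(manifest$prototypes$shape)
    con <- file(file.path(directory, manifest$prototypes$file), "rb")
    out$prototypes <- array(readBin(con, "double", n = prod(shape), size = 8,
                                    endian = "little"), dim = shape)
    close(con)
  }
  if (!is.null(manifest$generator_config)) {
    gc <- manifest$generator_config
    out$config <- structure(gc, class = "generator_config")
  }
  structure(out, class = "synthetic_dataset")
}
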