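# Format plumbing: binary images and maps as PNG / TIFF / NIfTI, run
# configuration as YAML/JSON, manifests with checksums.

img_format <- function(path) {
  p <- tolower(path)
  if (grepl("\\.png$", p)) "png"
  else if (grepl("\\.tiff?$", p)) "tiff"
  else if (grepl("\\.nii(\\.gz)?$", p)) "nifti"
  else stop("unsupported image format: ", path)
}

#' Read a (binary) marker image or volume
#'
#' Reads PNG (2D), TIFF (2D or multi-frame stack) or NIfTI (2D/3D). With
#' `binarize = TRUE` (default) the image is thresholded at 0.5 of its value
#' range into 0/1 integers; multi-channel images are averaged first.
#'
#' @param path file path; format detected from the extension.
#' @param binarize threshold into a 0/1 integer image.
#' @return integer (binarized) or numeric matrix/array.
#' @export
read_marker_image <- function(path, binarize = TRUE) {
  fmt <- img_format(path)
  x <- switch(fmt,
    png = {
      v <- png::readPNG(path)
      if (length(dim(v)) == 3) v <- apply(v, c(1, 2), mean)
      v
    },
    tiff = {
      v <- tiff::readTIFF(path, all = TRUE)
      if (is.list(v)) {
        v <- lapply(v, function(f)
          if (length(dim(f)) == 3) apply(f, c(1, 2), mean) else f)
        if (length(v) == 1) v[[1]]
        else array(unlist(v), c(dim(v[[1]]), length(v)))
      } else v
    },
    nifti = {
      v <- RNifti::readNifti(path)
      a <- as.array(v)
      if (length(dim(a)) > 3) a <- array(a, dim(a)[1:3])
      drop(a)
    })
  if (binarize) {
    hi <- max(x)
    x <- (x > (if (hi > 0) hi / 2 else 0.5)) * 1L
    storage.mode(x) <- "integer"
  }
  x
}

#' Write an image or map
#'
#' PNG stores values scaled to `[0, 1]`; TIFF stores 32-bit floats (stacks
#' for 3D arrays); NIfTI stores the raw array.
#'
#' @param x numeric matrix or 3D array.
#' @param path output path; format from the extension.
#' @return the path, invisibly.
#' @export
write_image <- function(x, path) {
  fmt <- img_format(path)
  if (fmt == "png") {
    if (length(dim(x)) != 2) stop("PNG supports 2D images only")
    v <- matrix(as.numeric(x), nrow(x), ncol(x))
    hi <- max(v)
    if (hi > 1) v <- v / hi
    png::writePNG(v, path)
  } else if (fmt == "tiff") {
    xs <- if (length(dim(x)) == 3)
      lapply(seq_len(dim(x)[3]), function(z) matrix(as.numeric(x[, , z]),
                                                    dim(x)[1], dim(x)[2]))
    else matrix(as.numeric(x), nrow(x), ncol(x))
    tiff::writeTIFF(xs, path, bits.per.sample = 32, reduce = FALSE)
  } else {
    RNifti::writeNifti(RNifti::asNifti(x), path)
  }
  invisible(path)
}

#' Read a run configuration
#'
#' YAML or JSON file with command-specific parameter blocks (`simulation`,
#' `estimator`, `inference`, `objects`), a global `seed`, and an
#' `output_dir`.
#'
#' @param path configuration file (`.yaml`, `.yml` or `.json`).
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", tolower(path))) yaml::read_yaml(path)
  else if (grepl("\\.json$", tolower(path)))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else stop("unsupported configuration format: ", path)
  if (!is.list(cfg)) stop("malformed configuration: ", path)
  cfg
}

# Fixed-precision numeric formatting so CSV outputs are byte-stable.
format_numeric_df <- function(df, digits = 10) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- sprintf(paste0("%.", digits, "g"), df[[j]])
  }
  df
}

# Write a manifest CSV (one row per file, with md5 checksums) and a
# provenance JSON sufficient to re-run the stage.
write_manifest <- function(dir, files, extra_cols = NULL, params = list(),
                           stage = "stage") {
  man <- data.frame(file = basename(files),
                    md5 = unname(tools::md5sum(files)),
                    stringsAsFactors = FALSE)
  if (!is.null(extra_cols)) man <- cbind(extra_cols, man)
  man_path <- file.path(dir, "manifest.csv")
  write.csv(format_numeric_df(man), man_path, row.names = FALSE, quote = FALSE)
  prov <- list(stage = stage, package = "markload",
               version = as.character(packageVersion("markload")),
               parameters = params)
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(man_path)
}
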