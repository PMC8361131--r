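#' Write a numeric matrix as an NPY (v1.0) float64 array
#'
#' Minimal NPY writer for lossless storage of stimulus luminance matrices
#' (no NPY package exists in the supporting R stack). Arrays are written as
#' little-endian float64 in Fortran (column-major) order, which is R's
#' native layout, so round-trips are bit-exact.
#'
#' @param x Numeric matrix.
#' @param path Output path, conventionally ending in `.npy`.
#' @return `path`, invisibly.
#' @export
write_npy <- function(x, path) {
  stopifnot(is.matrix(x), is.numeric(x))
  header <- sprintf(
    "{'descr': '<f8', 'fortran_order': True, 'shape': (%d, %d), }",
    nrow(x), ncol(x))
  # pad with spaces so magic + header is a multiple of 64 bytes, '\n' last
  pad <- 64L - ((10L + nchar(header, type = "bytes") + 1L) %% 64L)
  header <- paste0(header, strrep(" ", pad %% 64L), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, utf8ToInt("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header, type = "bytes")), con, size = 2,
           endian = "little")
  writeChar(header, con, eos = NULL)
  writeBin(as.vector(x), con, size = 8, endian = "little")
  invisible(path)
}

#' Read an NPY float64 array written by [write_npy()]
#'
#' Supports the subset of NPY v1.0 this package writes: little-endian
#' float64, 2-D shape, either storage order.
#'
#' @param path Path to a `.npy` file.
#' @return A numeric matrix.
#' @export
read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8)
  if (!identical(magic[1:6], as.raw(c(0x93, utf8ToInt("NUMPY")))))
    stop("not an NPY file: ", path, call. = FALSE)
  hlen <- readBin(con, "integer", 1, size = 2, endian = "little",
                  signed = FALSE)
  header <- readChar(con, hlen, useBytes = TRUE)
  if (!grepl("'descr':\\s*'<f8'", header))
    stop("unsupported NPY dtype in ", path, " (only '<f8' is supported)",
         call. = FALSE)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shp <- regmatches(header, regexpr("\\(([0-9]+),\\s*([0-9]+)\\s*,?\\)",
                                    header))
  dims <- as.integer(strsplit(gsub("[()]", "", shp), ",")[[1]])
  if (length(dims) != 2L)
    stop("unsupported NPY shape in ", path, " (only 2-D arrays)",
         call. = FALSE)
  vals <- readBin(con, "numeric", prod(dims), size = 8, endian = "little")
  if (fortran) matrix(vals, dims[1], dims[2])
  else t(matrix(vals, dims[2], dims[1]))
}

#' Write a stimulus set to disk
#'
#' Each image is stored losslessly as an NPY float64 array plus an 8-bit PNG
#' preview (tone-mapped by a 1/2.2 gamma for display only), with a manifest
#' CSV listing `filename, smoothness_index, bumpiness_index, view_index,
#' seed`.
#'
#' @param images List of `stimulus_image` objects.
#' @param directory Output directory (created if absent).
#' @return The manifest path, invisibly.
#' @export
write_stimulus_set <- function(images, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", length(images))
  for (i in seq_along(images)) {
    img <- images[[i]]
    stopifnot(inherits(img, "stimulus_image"))
    stem <- sprintf("stim_s%02d_b%02d_v%02d", img$smoothness_index,
                    img$bumpiness_index, img$view_index)
    write_npy(img$pixels, file.path(directory, paste0(stem, ".npy")))
    preview <- (img$pixels / max(img$pixels, 1e-12))^(1 / 2.2)
    png::writePNG(preview, file.path(directory, paste0(stem, ".png")))
    rows[[i]] <- data.frame(filename = paste0(stem, ".npy"),
                            smoothness_index = img$smoothness_index,
                            bumpiness_index = img$bumpiness_index,
                            view_index = img$view_index,
                            seed = img$seed)
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(directory, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a stimulus set written by [write_stimulus_set()]
#'
#' The object mask is recovered as the strictly positive support of the
#' stored luminance array (background is exactly 0 by construction).
#'
#' @param directory Directory containing `manifest.csv` and the NPY arrays.
#' @return A list of `stimulus_image` objects (empty if the directory has no
#'   manifest and no images).
#' @export
read_stimulus_set <- function(directory) {
  mpath <- file.path(directory, "manifest.csv")
  if (!file.exists(mpath)) {
    if (length(list.files(directory, pattern = "\\.npy$")) > 0L)
      stop("stimulus directory has NPY files but no manifest.csv: ",
           directory, call. = FALSE)
    return(list())
  }
  manifest <- utils::read.csv(mpath)
  needed <- c("filename", "smoothness_index", "bumpiness_index",
              "view_index", "seed")
  if (!all(needed %in% names(manifest)))
    stop("manifest.csv is missing columns: ",
         paste(setdiff(needed, names(manifest)), collapse = ", "),
         call. = FALSE)
  out <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    f <- file.path(directory, manifest$filename[i])
    if (!file.exists(f))
      stop("manifest row ", i, " references a missing file: ",
           manifest$filename[i], call. = FALSE)
    px <- read_npy(f)
    out[[i]] <- new_stimulus_image(px, px > 0,
                                   manifest$smoothness_index[i],
                                   manifest$bumpiness_index[i],
                                   manifest$view_index[i],
                                   manifest$seed[i])
  }
  out
}
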