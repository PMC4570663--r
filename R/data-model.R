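#' Grayscale CT volume
#'
#' Container for a 3D 8-bit X-ray CT grayscale volume.  The array is indexed
#' `[j, i, k]`: `j` is the image row (y), `i` the image column (x) and `k` the
#' slice (z).  All indices are 1-based, following R convention.  Physical
#' coordinates are `index * voxel_size_um`, attached to voxel centres.
#'
#' @param data 3D numeric array of integer intensities in `[0, 255]`.
#' @param voxel_size_um Edge length of a voxel in micrometres (default 15.8,
#'   the working resolution of the CT/SEM-EDX setup this package targets).
#'
#' @return An object of class `grayscale_volume`: the integer array with
#'   attributes `voxel_size_um`.
#' @export
#' @examples
#' vol <- grayscale_volume(array(0:7, dim = c(2, 2, 2)))
#' dim(vol)
grayscale_volume <- function(data, voxel_size_um = DEFAULT_VOXEL_UM) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array", call. = FALSE)
  }
  if (any(dim(data) < 1L)) stop("all three dimensions must be >= 1", call. = FALSE)
  if (anyNA(data)) stop("volume intensities must not contain NA", call. = FALSE)
  if (any(data < 0 | data > 255) || any(data != round(data))) {
    stop("volume intensities must be integers in [0, 255]", call. = FALSE)
  }
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      !is.finite(voxel_size_um) || voxel_size_um <= 0) {
    stop("`voxel_size_um` must be a positive scalar", call. = FALSE)
  }
  out <- array(as.integer(round(data)), dim = dim(data))
  attr(out, "voxel_size_um") <- as.numeric(voxel_size_um)
  class(out) <- c("grayscale_volume", class(out))
  out
}

#' @export
print.grayscale_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<grayscale_volume> %d x %d x %d voxels (%.1f um/voxel), intensity range [%d, %d]\n",
    d[1], d[2], d[3], attr(x, "voxel_size_um"), min(x), max(x)
  ))
  invisible(x)
}

#' Elemental count map on one cut face
#'
#' A 2D map of characteristic X-ray counts (or any non-negative concentration
#' proxy) for a single element on a single cut face, with an optional logical
#' mask marking valid pixels (broken-slice regions are masked out).
#'
#' @param data Numeric matrix of non-negative values; `NA` cells are treated
#'   as masked out.
#' @param element Element label, e.g. `"C"`, `"Si"`, `"Fe"`, `"O"`.
#' @param pixel_size_um Pixel edge in micrometres; must equal the CT
#'   `voxel_size_um` when map and volume are used together.
#' @param mask Optional logical matrix, same shape as `data`; `TRUE` marks a
#'   valid pixel.  Defaults to `!is.na(data)`.
#'
#' @return An object of class `element_map` (the matrix with attributes
#'   `element`, `pixel_size_um`, `mask`).
#' @export
element_map <- function(data, element, pixel_size_um = DEFAULT_VOXEL_UM,
                        mask = NULL) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(mask)) mask <- !is.na(data)
  if (!is.logical(mask) || !identical(dim(mask), dim(data))) {
    stop("`mask` must be a logical matrix with the shape of `data`", call. = FALSE)
  }
  mask <- mask & !is.na(data)
  if (any(data[mask] < 0)) {
    stop(sprintf("element map '%s' contains negative counts", element), call. = FALSE)
  }
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    stop("`pixel_size_um` must be a positive scalar", call. = FALSE)
  }
  out <- data
  out[!mask] <- NA_real_
  attr(out, "element") <- as.character(element)
  attr(out, "pixel_size_um") <- as.numeric(pixel_size_um)
  attr(out, "mask") <- mask
  class(out) <- c("element_map", class(out))
  out
}

#' @export
print.element_map <- function(x, ...) {
  cat(sprintf(
    "<element_map> %s: %d x %d pixels (%.1f um), %d masked out\n",
    attr(x, "element"), nrow(x), ncol(x), attr(x, "pixel_size_um"),
    sum(!attr(x, "mask"))
  ))
  invisible(x)
}

map_mask <- function(map) {
  m <- attr(map, "mask")
  if (is.null(m)) !is.na(unclass(map)) else m
}

#' Read a grayscale volume from an image stack
#'
#' Reads a numbered stack of single-channel 8-bit PNG or TIFF slices (one file
#' per slice, lexicographic filename order defining the slice index), or a
#' single multi-page TIFF.
#'
#' @param path Character vector of file paths, a glob pattern, or a single
#'   multi-page TIFF path.
#' @param voxel_size_um Voxel edge in micrometres.
#'
#' @return A [grayscale_volume()].
#' @export
read_volume <- function(path, voxel_size_um = DEFAULT_VOXEL_UM) {
  files <- path
  if (length(path) == 1L && grepl("[*?\\[]", path)) {
    files <- Sys.glob(path)
    if (length(files) == 0L) stop("no files match pattern: ", path, call. = FALSE)
  }
  missing <- files[!file.exists(files)]
  if (length(missing)) stop("missing file(s): ", paste(missing, collapse = ", "), call. = FALSE)
  files <- sort(files)

  if (length(files) == 1L && grepl("\\.tiff?$", files, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(files, all = TRUE, as.is = TRUE)
    slices <- lapply(seq_along(pages), function(p) {
      check_slice_8bit(pages[[p]], sprintf("%s [page %d]", files, p))
    })
  } else {
    slices <- lapply(files, function(f) check_slice_8bit(read_slice_file(f), f))
  }
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1]
    lab <- if (length(files) > 1L) files[bad] else sprintf("%s [page %d]", files, bad)
    stop(sprintf(
      "inconsistent slice dimensions: %s is %d x %d, expected %d x %d",
      lab, dims[1, bad], dims[2, bad], dims[1, 1], dims[2, 1]
    ), call. = FALSE)
  }
  vol <- array(0L, dim = c(dims[1, 1], dims[2, 1], length(slices)))
  for (k in seq_along(slices)) vol[, , k] <- slices[[k]]
  grayscale_volume(vol, voxel_size_um)
}

read_slice_file <- function(f) {
  if (grepl("\\.png$", f, ignore.case = TRUE)) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3L) stop(f, ": not a single-channel image", call. = FALSE)
    img * 255
  } else if (grepl("\\.tiff?$", f, ignore.case = TRUE)) {
    tiff::readTIFF(f, as.is = TRUE)
  } else {
    stop(f, ": unsupported image format (use PNG or TIFF)", call. = FALSE)
  }
}

check_slice_8bit <- function(img, label) {
  if (length(dim(img)) != 2L) stop(label, ": not a single-channel image", call. = FALSE)
  if (any(abs(img - round(img)) > 1e-9) || any(img < 0) || any(img > 255)) {
    stop(label, ": not an 8-bit grayscale image (values outside integer [0,255])",
         call. = FALSE)
  }
  matrix(as.integer(round(img)), nrow(img), ncol(img))
}

#' Write a grayscale volume as an 8-bit slice stack
#'
#' @param volume A [grayscale_volume()].
#' @param dir Output directory (created if needed).
#' @param format `"tiff"` or `"png"`.
#' @param prefix Filename prefix; files are `<prefix>_<k>.<ext>` with
#'   zero-padded `k`.
#' @return Invisibly, the written file paths.
#' @export
write_volume <- function(volume, dir, format = c("tiff", "png"), prefix = "slice") {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nk <- dim(volume)[3]
  ext <- if (format == "tiff") "tif" else "png"
  paths <- file.path(dir, sprintf("%s_%04d.%s", prefix, seq_len(nk), ext))
  for (k in seq_len(nk)) {
    img <- unclass(volume)[, , k] / 255
    if (format == "tiff") {
      tiff::writeTIFF(img, paths[k], bits.per.sample = 8L)
    } else {
      png::writePNG(img, paths[k])
    }
  }
  invisible(paths)
}

#' Write a predicted concentration block
#'
#' Writes a 3D array of predicted concentrations as a 32-bit float TIFF stack,
#' optionally with one CSV matrix per slice.
#'
#' @param block 3D numeric array.
#' @param dir Output directory.
#' @param prefix Filename prefix.
#' @param csv Also write per-slice CSV matrices.
#' @return Invisibly, the written TIFF paths.
#' @export
write_prediction_stack <- function(block, dir, prefix = "pred", csv = FALSE) {
  stopifnot(is.array(block), length(dim(block)) == 3L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nk <- dim(block)[3]
  paths <- file.path(dir, sprintf("%s_%04d.tif", prefix, seq_len(nk)))
  for (k in seq_len(nk)) {
    tiff::writeTIFF(block[, , k], paths[k], bits.per.sample = 32L,
                    sample.format = "float", reduce = TRUE)
    if (csv) {
      write.table(block[, , k],
                  file.path(dir, sprintf("%s_%04d.csv", prefix, k)),
                  sep = ",", row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(paths)
}

#' Read an elemental map from a CSV matrix
#'
#' The expected dialect is a plain rectangular numeric CSV without header (one
#' row per image row).  Empty cells become masked-out pixels; an optional
#' companion mask file is a CSV of 0/1 of the same shape.
#'
#' @param path CSV file path.
#' @param element Element label to attach.
#' @param mask_path Optional CSV of 0/1 values; 1 marks valid pixels.
#' @param pixel_size_um Pixel edge in micrometres.
#' @return An [element_map()].
#' @export
read_element_map <- function(path, element, mask_path = NULL,
                             pixel_size_um = DEFAULT_VOXEL_UM) {
  mat <- read_csv_matrix(path)
  mask <- NULL
  if (!is.null(mask_path)) {
    mm <- read_csv_matrix(mask_path)
    if (!identical(dim(mm), dim(mat))) {
      stop("mask shape differs from map shape: ", mask_path, call. = FALSE)
    }
    mask <- !is.na(mm) & mm != 0
  }
  element_map(mat, element = element, pixel_size_um = pixel_size_um, mask = mask)
}

read_csv_matrix <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  # trailing comma sentinel keeps empty last cells (strsplit drops them)
  cells <- strsplit(paste0(lines, ","), ",", fixed = TRUE)
  ncols <- lengths(cells)
  if (length(unique(ncols)) != 1L) {
    stop(sprintf("ragged CSV %s: row %d has %d cells, expected %d",
                 path, which(ncols != ncols[1])[1], ncols[ncols != ncols[1]][1],
                 ncols[1]), call. = FALSE)
  }
  flat <- trimws(unlist(cells))
  vals <- suppressWarnings(as.numeric(flat))
  bad <- which(is.na(vals) & nzchar(flat))
  if (length(bad)) {
    stop(sprintf("non-numeric cell '%s' in %s", flat[bad[1]], path), call. = FALSE)
  }
  matrix(vals, nrow = length(lines), byrow = TRUE)
}

#' Write an elemental map as CSV
#'
#' Masked-out pixels are written as empty cells, the inverse of
#' [read_element_map()].
#'
#' @param map An [element_map()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_element_map <- function(map, path) {
  m <- unclass(map)
  attr(m, "element") <- attr(m, "pixel_size_um") <- attr(m, "mask") <- NULL
  txt <- apply(m, 1L, function(row) {
    row <- ifelse(is.na(row), "",
                  format(row, trim = TRUE, scientific = FALSE, digits = 15))
    paste(row, collapse = ",")
  })
  writeLines(txt, path)
  invisible(path)
}

#' Crop a rectangular window from a matrix
#'
#' @param x Matrix (or `element_map`); the window must lie fully inside it.
#' @param origin `(row, col)` of the top-left corner, 1-based.
#' @param shape `(rows, cols)` of the window.
#' @return The cropped matrix (attributes of `element_map`s are preserved,
#'   with the mask cropped alongside).
#' @export
crop_region <- function(x, origin, shape) {
  stopifnot(length(origin) == 2L, length(shape) == 2L)
  origin <- as.integer(origin); shape <- as.integer(shape)
  if (any(origin < 1L) || any(shape < 1L) ||
      origin[1] + shape[1] - 1L > nrow(x) || origin[2] + shape[2] - 1L > ncol(x)) {
    stop(sprintf(
      "crop window rows %d..%d, cols %d..%d exceeds the %d x %d array",
      origin[1], origin[1] + shape[1] - 1L, origin[2], origin[2] + shape[2] - 1L,
      nrow(x), ncol(x)
    ), call. = FALSE)
  }
  rows <- origin[1] + seq_len(shape[1]) - 1L
  cols <- origin[2] + seq_len(shape[2]) - 1L
  if (inherits(x, "element_map")) {
    element_map(unclass(x)[rows, cols, drop = FALSE],
                element = attr(x, "element"),
                pixel_size_um = attr(x, "pixel_size_um"),
                mask = map_mask(x)[rows, cols, drop = FALSE])
  } else {
    x[rows, cols, drop = FALSE]
  }
}

#' A face: grayscale plane plus its element maps
#'
#' Bundles the CT grayscale values on (the registered plane of) one cut face
#' with the elemental maps measured on that face, and the face's nominal slice
#' position.
#'
#' @param gray Numeric matrix of grayscale values on the face.
#' @param maps Named list of [element_map()]s sharing `gray`'s shape.
#' @param z Nominal slice index of the face in the volume (1-based).
#' @param id Face identifier.
#' @param orientation Optional `plane_orientation` locating the face.
#' @return An object of class `aligned_face`.
#' @export
aligned_face <- function(gray, maps, z, id = NULL, orientation = NULL) {
  stopifnot(is.matrix(gray))
  if (is.null(names(maps)) || any(!nzchar(names(maps)))) {
    names(maps) <- vapply(maps, attr, "", "element")
  }
  for (m in maps) {
    if (!identical(dim(unclass(m)), dim(gray))) {
      stop("element map shape differs from grayscale plane shape", call. = FALSE)
    }
  }
  structure(
    list(gray = gray, maps = maps, z = as.numeric(z),
         id = if (is.null(id)) sprintf("z%g", z) else id,
         orientation = orientation),
    class = "aligned_face"
  )
}

#' An ordered set of faces
#'
#' @param faces List of [aligned_face()]s with strictly increasing `z`.
#' @param slice_gap Nominal slice thickness in CT layers (default 15).
#' @param kerf_gap Nominal material lost to the saw between slices, in CT
#'   layers (default 50).
#' @return An object of class `layer_set`.
#' @export
layer_set <- function(faces, slice_gap = 15, kerf_gap = 50) {
  z <- vapply(faces, function(f) f$z, 0)
  if (any(diff(z) <= 0)) stop("face z positions must be strictly increasing", call. = FALSE)
  els <- lapply(faces, function(f) sort(names(f$maps)))
  if (length(unique(els)) != 1L) {
    stop("every face must carry the same element set", call. = FALSE)
  }
  structure(list(faces = faces, z = z, slice_gap = slice_gap, kerf_gap = kerf_gap,
                 elements = els[[1]]),
            class = "layer_set")
}

#' @export
print.layer_set <- function(x, ...) {
  cat(sprintf("<layer_set> %d faces at z = %s; elements: %s\n",
              length(x$faces), paste(x$z, collapse = ", "),
              paste(x$elements, collapse = ", ")))
  invisible(x)
}
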