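#' Read a 3-D volume from a TIFF stack or MetaImage file
#'
#' Supported inputs: a directory of single-slice 8-bit TIFF files (sorted by
#' filename, one z-slice each), a multipage 8-bit TIFF, or a MetaImage
#' `.mhd` header with its `.raw` payload. 8-bit data are preserved exactly.
#' For TIFF input, spacing/origin may be given explicitly or via a JSON
#' sidecar (`<stack>.json` with fields `spacing_mm`, `origin_mm`); MetaImage
#' carries its own `ElementSpacing`/`Offset`.
#'
#' @param path file or directory path.
#' @param spacing,origin optional overrides (mm).
#' @return a `voxel_image`.
#' @export
read_volume <- function(path, spacing = NULL, origin = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file or directory: %s", path))
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0L) stop(sprintf("no TIFF slices found in %s", path))
    slices <- lapply(files, function(f) tiff::readTIFF(f, as.is = TRUE))
    img <- stack_slices(slices)
    side <- read_sidecar(file.path(path, "volume.json"))
  } else if (grepl("\\.mhd$", path, ignore.case = TRUE)) {
    return(read_metaimage(path, spacing = spacing, origin = origin))
  } else {
    slices <- tiff::readTIFF(path, as.is = TRUE, all = TRUE)
    if (!is.list(slices)) slices <- list(slices)
    img <- stack_slices(slices)
    side <- read_sidecar(paste0(tools::file_path_sans_ext(path), ".json"))
  }
  spacing <- spacing %||% side$spacing_mm %||% 1
  origin <- origin %||% side$origin_mm %||% c(0, 0, 0)
  voxel_image(img, spacing, origin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_sidecar <- function(path) {
  if (file.exists(path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else NULL
}

stack_slices <- function(slices) {
  dims <- vapply(slices, function(s) dim(s)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent slice dimensions in TIFF stack")
  if (any(vapply(slices, function(s) length(dim(s)) != 2L, logical(1))))
    stop("unsupported TIFF layout: expected single-channel grayscale slices")
  arr <- array(0, c(dim(slices[[1]]), length(slices)))
  for (k in seq_along(slices)) arr[, , k] <- slices[[k]]
  if (min(arr) < 0 || max(arr) > 255)
    stop("unsupported bit depth: expected 8-bit grayscale (0..255)")
  arr
}

#' Write a volume as a multipage 8-bit TIFF plus JSON sidecar
#'
#' @param img a `voxel_image` with values in \[0, 255\].
#' @param path output `.tif` path; a `<path sans ext>.json` sidecar records
#'   spacing and origin.
#' @export
write_volume_tiff <- function(img, path) {
  stopifnot(is_voxel_image(img))
  v <- img$data
  if (min(v) < 0 || max(v) > 255)
    stop("volume values must lie in [0, 255] for 8-bit TIFF output")
  d <- dim(v)
  slices <- lapply(seq_len(d[3]), function(k)
    matrix(round(v[, , k]) / 255, d[1], d[2]))
  tiff::writeTIFF(slices, path, bits.per.sample = 8L)
  jsonlite::write_json(
    list(spacing_mm = img$spacing, origin_mm = img$origin),
    paste0(tools::file_path_sans_ext(path), ".json"),
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' MetaImage (.mhd/.raw) I/O
#'
#' Minimal MetaImage support: 3-D `MET_UCHAR`, `MET_FLOAT` or `MET_DOUBLE`
#' volumes with an uncompressed local `.raw` payload, as written by common
#' image-analysis toolchains.
#'
#' @param path `.mhd` header path.
#' @param spacing,origin optional overrides of the header values (mm).
#' @return a `voxel_image`.
#' @export
read_metaimage <- function(path, spacing = NULL, origin = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = " "), "")
  get <- function(k) if (k %in% keys) vals[match(k, keys)] else NULL
  ndims <- as.integer(get("NDims") %||% "3")
  if (ndims != 3L) stop("only 3-D MetaImage volumes are supported")
  dimsz <- as.integer(strsplit(trimws(get("DimSize")), "\\s+")[[1]])
  sp <- as.numeric(strsplit(trimws(get("ElementSpacing") %||% "1 1 1"),
                            "\\s+")[[1]])
  off <- as.numeric(strsplit(trimws(get("Offset") %||% "0 0 0"), "\\s+")[[1]])
  etype <- get("ElementType") %||% "MET_UCHAR"
  raw_file <- get("ElementDataFile")
  if (is.null(raw_file)) stop("malformed MetaImage header: no ElementDataFile")
  raw_path <- file.path(dirname(path), raw_file)
  n <- prod(dimsz)
  dat <- switch(etype,
    MET_UCHAR = as.numeric(readBin(raw_path, "integer", n, size = 1L,
                                   signed = FALSE)),
    MET_FLOAT = readBin(raw_path, "numeric", n, size = 4L),
    MET_DOUBLE = readBin(raw_path, "numeric", n, size = 8L),
    stop(sprintf("unsupported MetaImage ElementType: %s", etype)))
  if (length(dat) != n) stop("MetaImage payload shorter than DimSize implies")
  if (max(abs(sp - sp[1])) > 1e-12)
    stop("anisotropic MetaImage spacing is not supported")
  voxel_image(array(dat, dimsz), spacing %||% sp[1], origin %||% off)
}

#' @rdname read_metaimage
#' @param img a `voxel_image`.
#' @param element_type `"MET_UCHAR"` (rounds to 8-bit), `"MET_FLOAT"` or
#'   `"MET_DOUBLE"`.
#' @export
write_metaimage <- function(img, path,
                            element_type = c("MET_DOUBLE", "MET_FLOAT",
                                             "MET_UCHAR")) {
  stopifnot(is_voxel_image(img))
  element_type <- match.arg(element_type)
  raw_name <- paste0(basename(tools::file_path_sans_ext(path)), ".raw")
  d <- dim(img$data)
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste("DimSize =", paste(d, collapse = " ")),
           paste("ElementSpacing =",
                 paste(rep(format(img$spacing, digits = 17), 3),
                       collapse = " ")),
           paste("Offset =",
                 paste(format(img$origin, digits = 17), collapse = " ")),
           paste("ElementType =", element_type),
           paste("ElementDataFile =", raw_name))
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  v <- as.vector(img$data)
  if (element_type == "MET_UCHAR") {
    writeBin(as.integer(round(v)), con, size = 1L)
  } else {
    writeBin(as.numeric(v), con,
             size = if (element_type == "MET_FLOAT") 4L else 8L)
  }
  invisible(path)
}

#' Load-displacement curve CSV I/O
#'
#' Two-column CSV with header `displacement_mm,load_N`.
#'
#' @param path CSV path.
#' @return data.frame with columns `displacement_mm`, `load_N`.
#' @export
read_load_curve <- function(path) {
  x <- utils::read.csv(path)
  if (!all(c("displacement_mm", "load_N") %in% names(x)))
    stop("curve CSV must have columns displacement_mm, load_N")
  x[, c("displacement_mm", "load_N")]
}

#' @rdname read_load_curve
#' @param curve data.frame with `displacement_mm` and `load_N`.
#' @export
write_load_curve <- function(curve, path) {
  utils::write.csv(curve[, c("displacement_mm", "load_N")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read/write landmark sets
#'
#' CSV with columns `name,x_mm,y_mm,z_mm`, or JSON of named length-3 arrays.
#'
#' @param path file path (`.csv` or `.json`).
#' @return 3 x 3 numeric matrix, rownames = landmark names.
#' @export
read_landmarks <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    m <- do.call(rbind, x)
  } else {
    x <- utils::read.csv(path)
    m <- as.matrix(x[, c("x_mm", "y_mm", "z_mm")])
    rownames(m) <- x$name
  }
  storage.mode(m) <- "double"
  m
}

#' @rdname read_landmarks
#' @param landmarks points-by-3 matrix with rownames.
#' @export
write_landmarks <- function(landmarks, path) {
  df <- data.frame(name = rownames(landmarks) %||%
                     paste0("p", seq_len(nrow(landmarks))),
                   x_mm = landmarks[, 1], y_mm = landmarks[, 2],
                   z_mm = landmarks[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
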