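#' Read a volume from an NRRD file
#'
#' Minimal NRRD reader covering the subset used for reference volumes:
#' attached headers (data after the blank line) or detached `.nhdr` headers
#' (`data file:` relative to the header), `raw` and `gzip` encodings,
#' little/big endian, integer and floating-point types. The voxel size is
#' taken from `spacings` (or the diagonal of `space directions`) when
#' present.
#'
#' @param path NRRD file path.
#' @return list with `data` (array) and `voxel_size_um`.
#' @export
read_nrrd <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  # header ends at the first blank line
  nl <- which(bytes == as.raw(10L))
  hdr_end <- NA_integer_
  prev <- 0L
  for (k in nl) {
    if (k == prev + 1L || (k == prev + 2L && bytes[k - 1L] == as.raw(13L))) {
      hdr_end <- k; break
    }
    prev <- k
  }
  has_data <- !is.na(hdr_end)
  hdr_raw <- if (has_data) bytes[seq_len(hdr_end)] else bytes
  lines <- strsplit(rawToChar(hdr_raw), "\r?\n")[[1]]
  if (!grepl("^NRRD000", lines[1])) stop("not an NRRD file: ", path)
  fields <- list()
  for (line in lines[-1]) {
    if (line == "" || grepl("^#", line)) next
    kv <- regmatches(line, regexpr(":=?", line), invert = TRUE)[[1]]
    if (length(kv) == 2L)
      fields[[tolower(trimws(kv[1]))]] <- trimws(kv[2])
  }
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  type <- tolower(fields$type)
  enc <- tolower(fields$encoding %||% "raw")
  endian <- if (grepl("big", tolower(fields$endian %||% "little"))) "big" else "little"
  tinfo <- switch(type,
    "uchar" = , "uint8" = , "unsigned char" = list(what = "integer", size = 1, signed = FALSE),
    "short" = , "int16" = , "signed short" = list(what = "integer", size = 2, signed = TRUE),
    "ushort" = , "uint16" = , "unsigned short" = list(what = "integer", size = 2, signed = FALSE),
    "int" = , "int32" = , "signed int" = list(what = "integer", size = 4, signed = TRUE),
    "uint" = , "uint32" = , "unsigned int" = list(what = "integer", size = 4, signed = TRUE),
    "float" = list(what = "numeric", size = 4, signed = TRUE),
    "double" = list(what = "numeric", size = 8, signed = TRUE),
    stop("unsupported NRRD type: ", type))
  n <- prod(sizes)
  if (!is.null(fields[["data file"]])) {
    dpath <- file.path(dirname(path), fields[["data file"]])
    payload <- readBin(dpath, "raw", n = file.info(dpath)$size)
  } else {
    if (!has_data) stop("attached NRRD header has no data section: ", path)
    payload <- bytes[(hdr_end + 1L):length(bytes)]
  }
  if (enc == "gzip") payload <- memDecompress(payload, type = "gzip")
  data <- readBin(payload, tinfo$what, n = n, size = tinfo$size,
                  signed = tinfo$signed, endian = endian)
  if (length(data) < n) stop("truncated NRRD data in ", path)
  vox <- 10
  if (!is.null(fields$spacings)) {
    sp <- suppressWarnings(as.numeric(strsplit(trimws(fields$spacings), "\\s+")[[1]]))
    if (any(is.finite(sp))) vox <- sp[is.finite(sp)][1]
  }
  # NRRD is fastest-axis-first; R arrays fill the first dimension fastest too
  list(data = array(data, dim = sizes), voxel_size_um = vox)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an array to an NRRD file (attached header)
#'
#' @param data numeric/integer array.
#' @param path output path.
#' @param voxel_size_um voxel spacing recorded in the header.
#' @param type "float", "double", or "int32".
#' @param encoding "raw" or "gzip".
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(data, path, voxel_size_um = 10, type = "float",
                       encoding = c("gzip", "raw")) {
  encoding <- match.arg(encoding)
  sizes <- dim(data)
  size <- switch(type, float = 4L, double = 8L, int32 = 4L,
                 stop("unsupported type: ", type))
  what <- if (type == "int32") as.integer(data) else as.numeric(data)
  hdr <- c("NRRD0004",
           "# historeg volume",
           paste("type:", switch(type, float = "float", double = "double",
                                 int32 = "int")),
           paste("dimension:", length(sizes)),
           paste("sizes:", paste(sizes, collapse = " ")),
           paste("spacings:", paste(rep(voxel_size_um, length(sizes)),
                                    collapse = " ")),
           "endian: little",
           paste("encoding:", encoding),
           "")
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con, sep = "\n")
  payload <- writeBin(what, raw(), size = size, endian = "little")
  if (encoding == "gzip") payload <- memCompress(payload, type = "gzip")
  writeBin(payload, con)
  invisible(path)
}

#' Read an atlas volume (NRRD pair or raw + JSON sidecar)
#'
#' `intensity_path`/`labels_path` may be NRRD files, or raw little-endian
#' binary arrays accompanied by a JSON sidecar `<file>.json` holding
#' `{shape, voxel_size_um, dtype}` (dtype "float32", "float64" or "int32";
#' column-major, first axis fastest).
#'
#' @param intensity_path,labels_path volume files.
#' @return an [atlas_volume()].
#' @export
read_volume <- function(intensity_path, labels_path) {
  rd <- function(p, integer) {
    if (grepl("\\.(nrrd|nhdr)$", p, ignore.case = TRUE)) {
      v <- read_nrrd(p)
      return(v)
    }
    side <- jsonlite::fromJSON(paste0(p, ".json"))
    dtype <- side$dtype %||% "float64"
    tinfo <- switch(dtype,
      float32 = list(what = "numeric", size = 4),
      float64 = list(what = "numeric", size = 8),
      int32 = list(what = "integer", size = 4),
      stop("unsupported dtype: ", dtype))
    n <- prod(side$shape)
    data <- readBin(p, tinfo$what, n = n, size = tinfo$size, endian = "little")
    list(data = array(data, dim = side$shape),
         voxel_size_um = side$voxel_size_um %||% 10)
  }
  int <- rd(intensity_path, FALSE)
  lab <- rd(labels_path, TRUE)
  labels <- array(as.integer(round(lab$data)), dim(lab$data))
  atlas_volume(intensity = int$data, labels = labels,
               voxel_size_um = int$voxel_size_um)
}

LABEL_TIFF_SCALE <- 2^24

#' Write a section image to TIFF or PNG
#'
#' TIFF stores 32-bit float with intensities min-max normalized to \[0, 1\]
#' unless already in range; PNG stores an 8-bit preview.
#'
#' @param image 2D numeric matrix.
#' @param path output path ending in .tif/.tiff or .png.
#' @param normalize rescale to \[0, 1\] before writing (default: only if
#'   out of range).
#' @return `path`, invisibly.
#' @export
write_section_image <- function(image, path, normalize = NULL) {
  stopifnot_image(image)
  rng <- range(image)
  if (is.null(normalize)) normalize <- rng[1] < 0 || rng[2] > 1
  img <- if (normalize && rng[2] > rng[1]) (image - rng[1]) / (rng[2] - rng[1])
         else clamp(image, 0, 1)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(img, path)
  } else {
    tiff::writeTIFF(img, path, bits.per.sample = 32L)
  }
  invisible(path)
}

#' Read a section image from TIFF or PNG
#' @param path image file path.
#' @return 2D numeric matrix (first channel if multichannel).
#' @export
read_section_image <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
         else tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}

#' Write a label image
#'
#' Stored as 32-bit float TIFF with values `id / 2^24` — exact for integer
#' ids below 2^24 — because the TIFF writer accepts only \[0, 1\] data.
#'
#' @param labels integer matrix.
#' @param path output .tif/.tiff path.
#' @return `path`, invisibly.
#' @export
write_label_image <- function(labels, path) {
  if (any(labels < 0) || any(labels >= LABEL_TIFF_SCALE))
    stop("label ids must be in [0, 2^24)")
  tiff::writeTIFF(labels / LABEL_TIFF_SCALE, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read a label image written by [write_label_image()]
#' @param path .tif/.tiff path.
#' @return integer matrix.
#' @export
read_label_image <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  matrix(as.integer(round(img * LABEL_TIFF_SCALE)), nrow(img), ncol(img))
}

#' Write a pose file
#'
#' One JSON per experiment: `{ap_max, sections: [{file, x_angle_deg,
#' y_angle_deg, ap_index}]}`. This is also the fine-tuning override format:
#' users edit the JSON between prediction and alignment.
#'
#' @param poses named list of [slice_pose()] (names = section file names).
#' @param ap_max maximum AP index of the volume.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_pose_file <- function(poses, ap_max, path) {
  secs <- lapply(names(poses), function(nm) {
    p <- poses[[nm]]
    list(file = nm, x_angle_deg = p$x_angle_deg, y_angle_deg = p$y_angle_deg,
         ap_index = p$ap_index)
  })
  jsonlite::write_json(list(ap_max = ap_max, sections = secs), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pose file
#' @param path JSON path written by [write_pose_file()].
#' @return list with `ap_max` and `poses` (named list of [slice_pose()]).
#' @export
read_pose_file <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  secs <- obj$sections
  poses <- lapply(seq_len(nrow(secs)), function(i)
    slice_pose(secs$x_angle_deg[i], secs$y_angle_deg[i], secs$ap_index[i]))
  names(poses) <- secs$file
  list(ap_max = obj$ap_max, poses = poses)
}

#' Write a detections CSV (`section,x_min,y_min,x_max,y_max,confidence`)
#' @param detections detections data.frame.
#' @param path output CSV path.
#' @param section section identifier recorded per row.
#' @return `path`, invisibly.
#' @export
write_detections_csv <- function(detections, path, section = "section") {
  df <- cbind(section = rep(section, nrow(detections)),
              detections[, c("x_min", "y_min", "x_max", "y_max", "confidence")])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a detections CSV
#' @param path CSV path.
#' @return detections data.frame.
#' @export
read_detections_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
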