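#' Read and write hyperspectral cubes in ENVI format
#'
#' Minimal ENVI support: a text \code{.hdr} companion plus a raw binary file
#' with BSQ/BIL/BIP interleave and float32/float64/int16/int32 sample types,
#' little or big endian. The wavelength block populates the wavenumber axis;
#' a nonstandard \code{pixel size} header entry carries um/px (default 1
#' when absent).
#'
#' @param path path to the binary file (the header is \code{path + ".hdr"},
#'   or \code{path} with its extension replaced by \code{.hdr}).
#' @return a \code{\link{hyper_cube}}.
#' @export
read_envi <- function(path) {
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path))
    hdr_path <- sub("\\.[^.]*$", ".hdr", path)
  if (!file.exists(hdr_path)) stop("ENVI header not found for ", path)
  hdr <- parse_envi_header(hdr_path)
  rows <- as.integer(hdr$lines); cols <- as.integer(hdr$samples)
  bands <- as.integer(hdr$bands)
  dtype <- as.integer(hdr[["data type"]])
  spec <- switch(as.character(dtype),
                 "2" = list(what = integer(), size = 2),
                 "3" = list(what = integer(), size = 4),
                 "4" = list(what = numeric(), size = 4),
                 "5" = list(what = numeric(), size = 8),
                 stop("unsupported ENVI data type ", dtype))
  endian <- if (!is.null(hdr[["byte order"]]) &&
                as.integer(hdr[["byte order"]]) == 1) "big" else "little"
  n <- rows * cols * bands
  raw <- readBin(path, spec$what, n = n, size = spec$size, endian = endian)
  if (length(raw) < n) stop("ENVI binary shorter than header promises")
  interleave <- tolower(if (is.null(hdr$interleave)) "bsq" else hdr$interleave)
  vals <- array(0, c(rows, cols, bands))
  if (interleave == "bsq") {
    a <- array(raw, c(cols, rows, bands))            # sample, line, band
    vals <- aperm(a, c(2, 1, 3))
  } else if (interleave == "bil") {
    a <- array(raw, c(cols, bands, rows))
    vals <- aperm(a, c(3, 1, 2))
  } else if (interleave == "bip") {
    a <- array(raw, c(bands, cols, rows))
    vals <- aperm(a, c(3, 2, 1))
  } else stop("unsupported interleave ", interleave)
  wn <- if (!is.null(hdr$wavelength))
    as.numeric(strsplit(gsub("[{}\n ]", "", hdr$wavelength), ",")[[1]])
  else seq_len(bands)
  ps <- if (!is.null(hdr[["pixel size"]])) as.numeric(hdr[["pixel size"]]) else 1
  hyper_cube(vals, wn, ps)
}

parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  txt <- paste(lines, collapse = "\n")
  txt <- sub("^\\s*ENVI\\s*\n", "", txt)
  # join {...} blocks onto one logical entry
  out <- list()
  pos <- gregexpr("(?m)^\\s*([^=\n{}]+?)\\s*=\\s*", txt, perl = TRUE)
  keys <- regmatches(txt, pos)[[1]]
  pos <- pos[[1]]
  starts <- as.integer(pos)
  lens <- attr(pos, "match.length")
  ends <- c(starts[-1] - 1, nchar(txt))
  for (i in seq_along(starts)) {
    key <- tolower(trimws(sub("=\\s*$", "", keys[i])))
    val <- substr(txt, starts[i] + lens[i], ends[i])
    out[[key]] <- trimws(val)
  }
  out
}

#' @rdname read_envi
#' @param cube a \code{\link{hyper_cube}} to write.
#' @param data_type 4 (float32) or 5 (float64).
#' @export
write_envi <- function(cube, path, data_type = 4) {
  stopifnot(inherits(cube, "hyper_cube"), data_type %in% c(4, 5))
  d <- dim(cube$values)
  hdr <- c("ENVI",
           paste0("samples = ", d[2]),
           paste0("lines = ", d[1]),
           paste0("bands = ", d[3]),
           "header offset = 0",
           "file type = ENVI Standard",
           paste0("data type = ", data_type),
           "interleave = bsq",
           "byte order = 0",
           paste0("pixel size = ", format(cube$pixel_size, digits = 12)),
           paste0("wavelength = {\n ",
                  paste(format(cube$wavenumbers, digits = 12),
                        collapse = ", "), "}"))
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(path, "wb")
  on.exit(close(con))
  a <- aperm(cube$values, c(2, 1, 3))               # sample-fastest, BSQ
  writeBin(as.numeric(a), con, size = if (data_type == 4) 4 else 8,
           endian = "little")
  invisible(path)
}

#' Read and write hyperspectral cubes as plain-text CSV
#'
#' A simple matrix dialect: one comment line \code{# rmireg-cube
#' rows=<r> cols=<c> pixel_size=<p>}, then a CSV whose header row holds the
#' wavenumbers and whose data rows are the pixels in row-major order.
#'
#' @param path file path.
#' @return a \code{\link{hyper_cube}}.
#' @export
read_cube_csv <- function(path) {
  meta <- readLines(path, n = 1)
  if (!grepl("^# *rmireg-cube", meta)) stop("not an rmireg cube CSV")
  get <- function(key) {
    m <- regmatches(meta, regexpr(paste0(key, "=[-0-9.eE+]+"), meta))
    if (!length(m)) stop("cube CSV metadata missing ", key)
    as.numeric(sub(".*=", "", m))
  }
  rows <- get("rows"); cols <- get("cols"); ps <- get("pixel_size")
  tab <- utils::read.csv(path, skip = 1, check.names = FALSE)
  wn <- as.numeric(colnames(tab))
  m <- as.matrix(tab)
  if (nrow(m) != rows * cols) stop("cube CSV row count mismatch")
  vals <- array(0, c(rows, cols, ncol(m)))
  for (b in seq_len(ncol(m)))
    vals[, , b] <- matrix(m[, b], rows, cols, byrow = TRUE)
  hyper_cube(vals, wn, ps)
}

#' @rdname read_cube_csv
#' @param cube a \code{\link{hyper_cube}} to write.
#' @export
write_cube_csv <- function(cube, path) {
  stopifnot(inherits(cube, "hyper_cube"))
  d <- dim(cube$values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rmireg-cube rows=%d cols=%d pixel_size=%s",
                     d[1], d[2], format(cube$pixel_size, digits = 12)), con)
  m <- matrix(aperm(cube$values, c(2, 1, 3)), d[1] * d[2], d[3])
  colnames(m) <- format(cube$wavenumbers, digits = 12, trim = TRUE)
  utils::write.csv(as.data.frame(m), con, row.names = FALSE)
  invisible(path)
}

#' Read and write RGB images as PNG
#'
#' 8-bit PNG; grayscale files are expanded to three channels, alpha is
#' dropped.
#'
#' @param path file path.
#' @param pixel_size um/px to attach (default 1).
#' @return an \code{\link{rgb_image}}.
#' @export
read_rgb_png <- function(path, pixel_size = 1) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 2L) v <- array(rep(v, 3), c(dim(v), 3))
  if (dim(v)[3] > 3L) v <- v[, , 1:3, drop = FALSE]
  rgb_image(round_half_up(v * 255), pixel_size)
}

#' @rdname read_rgb_png
#' @param he an \code{\link{rgb_image}} to write.
#' @export
write_rgb_png <- function(he, path) {
  stopifnot(inherits(he, "rgb_image"))
  png::writePNG(he$values / 255, path)
  invisible(path)
}

#' Read and write foreground masks as single-channel PNG
#'
#' Gray level 0 is background, 255 (white) is foreground.
#'
#' @param path file path.
#' @return logical matrix (\code{TRUE} = foreground).
#' @export
read_mask_png <- function(path) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 3L) v <- v[, , 1]
  v >= 0.5
}

#' @rdname read_mask_png
#' @param mask logical matrix to write.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' Read and write index images as PNG plus JSON sidecar
#'
#' The label value is stored as the PNG gray level; \code{k},
#' \code{modality} and \code{pixel_size} go into \code{path + ".json"}.
#'
#' @param path PNG file path.
#' @return an \code{\link{index_image}}.
#' @export
read_index_png <- function(path) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 3L) v <- v[, , 1]
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  index_image(round_half_up(v * 255), meta$k, meta$modality, meta$pixel_size)
}

#' @rdname read_index_png
#' @param img an \code{\link{index_image}} to write.
#' @export
write_index_png <- function(img, path) {
  stopifnot(inherits(img, "index_image"), img$k <= 255)
  png::writePNG(img$labels / 255, path)
  jsonlite::write_json(list(k = img$k, modality = img$modality,
                            pixel_size = img$pixel_size),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Serialize a similarity transform as JSON
#'
#' Writes \code{tx}, \code{ty}, \code{theta_deg}, \code{scale} and, when the
#' image shapes are given, the full 3x3 homogeneous matrix.
#'
#' @param t a \code{\link{similarity_transform}}.
#' @param path output path.
#' @param template_shape,moving_shape optional (rows, cols) shapes for the
#'   matrix form.
#' @export
write_transform_json <- function(t, path, template_shape = NULL,
                                 moving_shape = NULL) {
  stopifnot(inherits(t, "similarity_transform"))
  obj <- list(tx = t$tx, ty = t$ty, theta_deg = t$theta, scale = t$s)
  if (!is.null(template_shape) && !is.null(moving_shape))
    obj$matrix <- transform_matrix(t, template_shape, moving_shape)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  similarity_transform(obj$tx, obj$ty, obj$theta_deg, obj$scale)
}
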