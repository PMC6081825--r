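#' Read and write images, label masks and probability maps
#'
#' File conventions used across the package and its command-line surface:
#' RGB images are 8-bit PNG; label masks are 16-bit single-channel binary PGM
#' (P5, big-endian, maxval 65535 — no installed R package writes 16-bit PNG);
#' probability maps are PFM (portable float map, 32-bit little-endian floats).
#'
#' @param image integer array H x W x 3 with values in 0..255.
#' @param path file path.
#' @return `read_image` returns an integer H x W x 3 array in 0..255;
#'   `read_mask` an integer matrix; `read_probmap` a numeric matrix.
#' @name image-io
NULL

#' @rdname image-io
#' @export
write_image <- function(image, path) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  png::writePNG(array(image / 255, dim = dim(image)), path)
  invisible(path)
}

#' @rdname image-io
#' @export
read_image <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  if (dim(x)[3] == 4L) x <- x[, , 1:3, drop = FALSE]
  array(as.integer(round(x * 255)), dim = dim(x))
}

#' @rdname image-io
#' @param gray numeric matrix in [0, 1] (e.g. a [nuclear_channel()] image).
#' @export
write_grayscale <- function(gray, path) {
  stopifnot(is.matrix(gray), all(gray >= 0), all(gray <= 1))
  png::writePNG(gray, path)
  invisible(path)
}

#' @rdname image-io
#' @param image2,mask2 RGB image and label mask for the QC overlay.
#' @details `write_overlay` draws instance boundaries (thickness 1) in green
#'   over the RGB image — a quick visual QC of a segmentation.
#' @export
write_overlay <- function(image2, mask2, path) {
  stopifnot(length(dim(image2)) == 3L, identical(dim(image2)[1:2], dim(mask2)))
  rgb <- image2 / 255
  edge <- boundary_from_mask(mask2, 1L)
  rgb[, , 1][edge] <- 0
  rgb[, , 2][edge] <- 1
  rgb[, , 3][edge] <- 0
  png::writePNG(rgb, path)
  invisible(path)
}

#' @rdname image-io
#' @param mask integer matrix of instance labels (0 = background), < 65536.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask), all(mask >= 0), all(mask < 65536))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n65535\n", ncol(mask), nrow(mask)), con,
            eos = NULL, useBytes = TRUE)
  # PGM is row-major; R matrices are column-major
  v <- as.integer(t(mask))
  writeBin(v, con, size = 2L, endian = "big", useBytes = TRUE)
  invisible(path)
}

# Pull `n` whitespace-separated header tokens off a raw vector; returns the
# tokens and the offset of the first payload byte (one separator consumed).
pnm_header <- function(raw, n_tokens) {
  tokens <- character(0)
  i <- 1L
  cur <- character(0)
  while (length(tokens) < n_tokens) {
    ch <- rawToChar(raw[i])
    if (grepl("[ \t\r\n]", ch)) {
      if (nchar(cur)) { tokens <- c(tokens, cur); cur <- character(0) }
    } else cur <- paste0(cur, ch)
    i <- i + 1L
  }
  list(tokens = tokens, offset = i)
}

#' @rdname image-io
#' @export
read_mask <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  hd <- pnm_header(raw, 4L)
  if (!identical(hd$tokens[1], "P5")) stop("not a binary PGM mask file: ", path)
  w <- as.integer(hd$tokens[2]); h <- as.integer(hd$tokens[3])
  maxval <- as.integer(hd$tokens[4])
  size <- if (maxval > 255) 2L else 1L
  v <- readBin(raw[hd$offset:length(raw)], what = "integer", n = w * h,
               size = size, signed = FALSE, endian = "big")
  matrix(v, nrow = h, ncol = w, byrow = TRUE)
}

#' @rdname image-io
#' @param prob numeric matrix with values in [0, 1].
#' @export
write_probmap <- function(prob, path) {
  stopifnot(is.matrix(prob))
  con <- file(path, "wb")
  on.exit(close(con))
  # PFM: "Pf", "W H", negative scale = little-endian, rows bottom-to-top
  writeChar(sprintf("Pf\n%d %d\n-1.0\n", ncol(prob), nrow(prob)), con,
            eos = NULL, useBytes = TRUE)
  v <- as.numeric(t(prob[nrow(prob):1, , drop = FALSE]))
  writeBin(v, con, size = 4L, endian = "little", useBytes = TRUE)
  invisible(path)
}

#' @rdname image-io
#' @export
read_probmap <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  hd <- pnm_header(raw, 4L)
  if (!identical(hd$tokens[1], "Pf")) stop("not a PFM probability map: ", path)
  w <- as.integer(hd$tokens[2]); h <- as.integer(hd$tokens[3])
  endian <- if (as.numeric(hd$tokens[4]) < 0) "little" else "big"
  v <- readBin(raw[hd$offset:length(raw)], what = "numeric", n = w * h,
               size = 4L, endian = endian)
  m <- matrix(v, nrow = h, ncol = w, byrow = TRUE)
  m[h:1, , drop = FALSE]
}
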