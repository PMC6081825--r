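#' Optical-density colour decomposition of H&E tiles
#'
#' In transmitted-light microscopy, stain absorbance follows the Beer-Lambert
#' law: the optical density OD = -log(I/I0) of a pixel is linear in the stain
#' concentrations, with each stain contributing along a fixed unit direction in
#' (R, G, B) OD space. Decomposition is a per-pixel least-squares solve of
#' OD = S c for the 3 x 2 stain matrix S, yielding a hematoxylin (DNA) and an
#' eosin (protein/cytoplasm) concentration map. Negative residues are clipped:
#' stain amounts are physically non-negative. The hematoxylin map, rescaled to
#' [0, 1], is the default single-channel network input.
#'
#' @details The default stain matrix uses the published Ruifrok-Johnston H&E
#' optical-density vectors, column-normalised to unit length. It can be
#' overridden by a 6-number plain-text config (row-major 3 x 2, rows = R, G, B;
#' columns = hematoxylin, eosin), see [read_stain_matrix()].
#' @name color-decomposition
NULL

#' Construct or validate a 3 x 2 stain matrix
#'
#' @param h,e length-3 non-negative optical-density direction vectors for
#'   hematoxylin and eosin; normalised to unit length.
#' @return a 3 x 2 matrix of class `nf_stains`, columns `H` and `E`.
#' @examples
#' S <- stain_matrix()          # Ruifrok-Johnston H&E defaults
#' colSums(S^2)                 # unit columns
#' @export
stain_matrix <- function(h = c(0.65, 0.70, 0.29), e = c(0.07, 0.99, 0.11)) {
  stopifnot(length(h) == 3L, length(e) == 3L, all(h >= 0), all(e >= 0),
            sum(h) > 0, sum(e) > 0)
  S <- cbind(H = h / sqrt(sum(h^2)), E = e / sqrt(sum(e^2)))
  # reject collinear columns: decomposition would be degenerate
  cross <- S[, 1] / sqrt(sum(S[, 1]^2)) - S[, 2] / sqrt(sum(S[, 2]^2))
  if (sqrt(sum(cross^2)) < 1e-6)
    stop("degenerate stain matrix: columns are collinear")
  structure(S, class = c("nf_stains", class(S)))
}

#' @rdname stain_matrix
#' @param path text file holding 6 whitespace-separated numbers, row-major
#'   3 x 2 (rows R, G, B; columns hematoxylin, eosin).
#' @export
read_stain_matrix <- function(path) {
  v <- scan(path, what = numeric(), quiet = TRUE, comment.char = "#")
  if (length(v) != 6L) stop("stain matrix config must hold exactly 6 numbers")
  m <- matrix(v, nrow = 3L, ncol = 2L, byrow = TRUE)
  stain_matrix(h = m[, 1], e = m[, 2])
}

#' @rdname stain_matrix
#' @param S a stain matrix.
#' @export
write_stain_matrix <- function(S, path) {
  writeLines(apply(format(S, digits = 10), 1, paste, collapse = " "), path)
  invisible(path)
}

#' Convert between 8-bit RGB intensities and optical density
#'
#' `rgb_to_od` maps intensity I in 0..255 to OD = -log((I + 1)/256): a unit
#' offset guards I = 0 (OD = log 256, about 5.55) and white maps to exactly 0,
#' keeping OD non-negative. `od_to_rgb` is its exact inverse on continuous
#' intensities, I = 256 exp(-OD) - 1.
#'
#' @param image numeric array (any shape) of intensities in [0, 255].
#' @param od numeric array of non-negative optical densities.
#' @return array of the same shape.
#' @export
rgb_to_od <- function(image) {
  stopifnot(all(image >= 0), all(image <= 255))
  -log((image + 1) / 256)
}

#' @rdname rgb_to_od
#' @export
od_to_rgb <- function(od) {
  stopifnot(all(od >= 0))
  256 * exp(-od) - 1
}

#' Decompose an RGB tile into hematoxylin and eosin concentration maps
#'
#' Per-pixel least squares of the OD vector onto the stain matrix columns;
#' negative concentrations are clipped to zero.
#'
#' @param image integer/numeric H x W x 3 array, intensities in [0, 255].
#' @param stains a [stain_matrix()].
#' @return list with numeric H x W matrices `h` and `e` (optical density).
#' @export
decompose <- function(image, stains = stain_matrix()) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L,
            inherits(stains, "nf_stains"))
  od <- rgb_to_od(image)
  H <- dim(image)[1]; W <- dim(image)[2]
  odm <- matrix(od, ncol = 3L)                      # (H*W) x 3
  pinv <- solve(crossprod(stains), t(stains))       # 2 x 3
  conc <- odm %*% t(pinv)                           # (H*W) x 2
  conc[conc < 0] <- 0
  list(h = matrix(conc[, 1], H, W), e = matrix(conc[, 2], H, W))
}

#' Nuclear (hematoxylin) channel of an H&E tile
#'
#' The hematoxylin concentration map min-max rescaled to [0, 1] per tile; the
#' default network input after colour decomposition. A constant-OD tile (e.g.
#' pure white) has no dynamic range and returns all zeros.
#'
#' @inheritParams decompose
#' @return numeric H x W matrix in [0, 1].
#' @export
nuclear_channel <- function(image, stains = stain_matrix()) {
  h <- decompose(image, stains)$h
  rng <- range(h)
  if (diff(rng) <= 0) return(matrix(0, nrow(h), ncol(h)))
  (h - rng[1]) / diff(rng)
}
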