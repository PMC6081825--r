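#' Post-processing parameters
#'
#' @param prob_threshold foreground threshold in (0, 1); pixels with
#'   probability >= threshold are foreground (ties go to foreground — fixed
#'   for bit-reproducibility).
#' @param min_object_area objects smaller than this (pixels) are merged into
#'   their largest touching watershed neighbour, or removed if isolated.
#'   Default 20 px, about a 2.5 micron diameter disc at 0.5 micron/pixel.
#' @param marker_h h-maxima suppression depth (pixels) on the distance
#'   transform; larger values merge nearby markers and split less.
#' @return an `nf_postprocess_params` list.
#' @export
postprocess_params <- function(prob_threshold = 0.5, min_object_area = 20L,
                               marker_h = 2) {
  stopifnot(prob_threshold > 0, prob_threshold < 1, min_object_area >= 0,
            marker_h >= 0)
  structure(list(prob_threshold = prob_threshold,
                 min_object_area = as.integer(min_object_area),
                 marker_h = marker_h),
            class = "nf_postprocess_params")
}

#' Threshold a probability map
#'
#' @param prob numeric matrix in [0, 1].
#' @param threshold in (0, 1); a pixel is foreground iff prob >= threshold.
#' @return logical matrix.
#' @export
binarize <- function(prob, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  stopifnot(all(prob >= 0), all(prob <= 1))
  prob >= threshold
}

#' Split a foreground mask into nuclei by marker-controlled watershed
#'
#' Computes the Euclidean distance transform of the foreground, suppresses
#' shallow maxima by depth `marker_h` (h-maxima via morphological
#' reconstruction), labels the surviving maxima as markers, and floods the
#' negated distance transform from the markers, constrained to the
#' foreground. Components below `min_object_area` are merged into the
#' neighbouring label with the longest shared border, or dropped if isolated.
#'
#' @param foreground logical matrix.
#' @param params a [postprocess_params()].
#' @return integer label matrix, labels consecutive from 1.
#' @export
watershed_split <- function(foreground, params = postprocess_params()) {
  stopifnot(is.matrix(foreground))
  foreground <- foreground > 0
  if (!any(foreground)) return(matrix(0L, nrow(foreground), ncol(foreground)))
  dist <- .cpp_edt(foreground)
  h <- max(params$marker_h, 1e-6)
  rec <- .cpp_reconstruct(pmax(dist - h, 0), dist)
  markers_bin <- (dist - rec) >= h - 1e-9 & foreground
  if (!any(markers_bin)) markers_bin <- dist == max(dist)
  markers <- .cpp_label(markers_bin, 8L)
  lab <- .cpp_watershed(dist, markers, foreground)
  lab <- merge_small_objects(lab, params$min_object_area)
  relabel_consecutive(lab)
}

# merge labels below min_area into the touching label with the longest shared
# border; isolated small labels are removed
merge_small_objects <- function(lab, min_area) {
  if (min_area <= 0) return(lab)
  repeat {
    areas <- tabulate(lab[lab > 0L])
    small <- which(areas > 0L & areas < min_area)
    if (length(small) == 0L) break
    k <- small[which.min(areas[small])]
    px <- which(lab == k)
    H <- nrow(lab); W <- ncol(lab)
    rows <- (px - 1L) %% H + 1L
    cols <- (px - 1L) %/% H + 1L
    nb <- integer(0)
    for (dr in -1:1)
      for (dc in -1:1) {
        rr <- rows + dr; cc <- cols + dc
        ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
        v <- lab[cbind(rr[ok], cc[ok])]
        nb <- c(nb, v[v > 0L & v != k])
      }
    if (length(nb) == 0L) {
      lab[px] <- 0L
    } else {
      tb <- tabulate(nb)
      lab[px] <- which.max(tb)
    }
  }
  lab
}

relabel_consecutive <- function(lab) {
  present <- sort(unique(lab[lab > 0L]))
  if (length(present) == 0L) return(lab)
  remap <- integer(max(present))
  remap[present] <- seq_along(present)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  lab
}

#' Probability map to instance labels
#'
#' [binarize()] followed by [watershed_split()]; labels consecutive from 1.
#'
#' @param prob numeric matrix in [0, 1].
#' @param params a [postprocess_params()].
#' @return integer label matrix.
#' @export
segment <- function(prob, params = postprocess_params()) {
  watershed_split(binarize(prob, params$prob_threshold), params)
}

#' End-to-end prediction of a foreground probability map
#'
#' Applies the colour-decomposition front-end where the model expects one
#' channel, reflect-pads the tile to the model's divisibility requirement,
#' runs the forward pass (for a fusion model: region and boundary nets, then
#' the fusion net on their stacked outputs), and crops back.
#'
#' @param model an `nf_model` or `nf_fusion_model`.
#' @param image integer H x W x 3 RGB array in 0..255.
#' @param stains stain matrix for the decomposition front-end.
#' @return numeric H x W foreground-probability matrix.
#' @export
predict_probmap <- function(model, image, stains = stain_matrix()) {
  if (inherits(model, "nf_fusion_model")) {
    base <- model$region
    x <- if (base$in_channels == 1L) nuclear_channel(image, stains)
         else image / 255
    f <- 2^max(base$downs, model$fusion$downs)
    px <- pad_reflect(x, f)
    pr <- forward(model$region, px)
    pb <- forward(model$boundary, px)
    fin <- array(c(pr[, , 2L], pb[, , 2L]), dim = c(dim(pr)[1:2], 2L))
    pf <- forward(model$fusion, fin)
    return(crop_to(pf[, , 2L], dim(image)[1:2]))
  }
  stopifnot(inherits(model, "nf_model"))
  x <- if (model$in_channels == 1L) nuclear_channel(image, stains)
       else image / 255
  px <- pad_reflect(x, 2^model$downs)
  p <- forward(model, px)
  if (model$multitask) p <- p$region
  crop_to(p[, , 2L], dim(image)[1:2])
}

# reflect-pad an H x W matrix or H x W x C array so both sides are multiples
# of f; content sits in the top-left corner
pad_reflect <- function(x, f) {
  d <- dim(x)
  H <- d[1]; W <- d[2]
  Hp <- ceiling(H / f) * f
  Wp <- ceiling(W / f) * f
  if (Hp == H && Wp == W) return(x)
  ridx <- rep(c(seq_len(H), rev(seq_len(H))), length.out = Hp)
  cidx <- rep(c(seq_len(W), rev(seq_len(W))), length.out = Wp)
  if (length(d) == 2L) x[ridx, cidx, drop = FALSE]
  else x[ridx, cidx, , drop = FALSE]
}

crop_to <- function(x, hw) {
  if (length(dim(x)) == 2L) x[seq_len(hw[1]), seq_len(hw[2]), drop = FALSE]
  else x[seq_len(hw[1]), seq_len(hw[2]), , drop = FALSE]
}
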