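#' Synthetic H&E scene specification
#'
#' Declares the stated world for a seeded synthetic histology tile: elliptical
#' nuclei of random size, eccentricity and orientation; a chosen fraction
#' placed to overlap a neighbour (the touching-nuclei regime the fusion
#' network targets); a chosen fraction rendered vesicular (pale chromatin
#' interior, dark 2-px rim) versus hyperchromatic (uniformly dark); stains
#' rendered through the two-stain Beer-Lambert model with Gaussian sensor
#' noise. Defaults emulate 0.5 micron/pixel tissue: nuclear semi-major axes of
#' 5-9 px (5-9 microns diameter), hematoxylin OD 0.6-1.2 inside nuclei over an
#' eosin background OD of 0.25.
#'
#' @param height,width tile size in pixels.
#' @param n_nuclei number of nuclei to place.
#' @param radius_range (min, max) semi-major axis in pixels; min >= 2 and
#'   max < min(height, width)/2.
#' @param eccentricity_range (min, max) in [0, 1).
#' @param overlap_fraction fraction of nuclei placed to overlap a neighbour.
#' @param vesicular_fraction fraction rendered as pale interior + dark rim.
#' @param hematoxylin_od_range (min, max) per-nucleus optical density.
#' @param eosin_background_od OD of the cytoplasm/stroma background.
#' @param noise_sd Gaussian noise standard deviation, 0-255 intensity units.
#' @param seed integer seed; identical specs generate bit-identical scenes.
#' @return a validated `nf_scene_spec` list.
#' @export
scene_spec <- function(height = 128L, width = 128L, n_nuclei = 25L,
                       radius_range = c(5, 9),
                       eccentricity_range = c(0, 0.7),
                       overlap_fraction = 0.25,
                       vesicular_fraction = 0.2,
                       hematoxylin_od_range = c(0.6, 1.2),
                       eosin_background_od = 0.25,
                       noise_sd = 3,
                       seed = 1L) {
  spec <- list(height = as.integer(height), width = as.integer(width),
               n_nuclei = as.integer(n_nuclei),
               radius_range = as.numeric(radius_range),
               eccentricity_range = as.numeric(eccentricity_range),
               overlap_fraction = overlap_fraction,
               vesicular_fraction = vesicular_fraction,
               hematoxylin_od_range = as.numeric(hematoxylin_od_range),
               eosin_background_od = eosin_background_od,
               noise_sd = noise_sd, seed = as.integer(seed))
  stopifnot(
    spec$height >= 8L, spec$width >= 8L, spec$n_nuclei >= 0L,
    spec$radius_range[1] >= 2,
    spec$radius_range[2] >= spec$radius_range[1],
    spec$radius_range[2] < min(spec$height, spec$width) / 2,
    spec$eccentricity_range[1] >= 0, spec$eccentricity_range[2] < 1,
    spec$overlap_fraction >= 0, spec$overlap_fraction <= 1,
    spec$vesicular_fraction >= 0, spec$vesicular_fraction <= 1,
    spec$hematoxylin_od_range[1] >= 0,
    spec$hematoxylin_od_range[2] >= spec$hematoxylin_od_range[1],
    spec$eosin_background_od >= 0, spec$noise_sd >= 0
  )
  structure(spec, class = "nf_scene_spec")
}

#' Render an H&E image from stain optical-density fields
#'
#' Forward Beer-Lambert model: each RGB channel attenuates along its stain
#' directions, intensity = 256 exp(-(h S\[c,H\] + e S\[c,E\])) - 1, the exact
#' inverse of [rgb_to_od()] (zero OD maps to white, 255). With
#' `quantize = TRUE` intensities are rounded to the nearest integer in 0..255.
#'
#' @param h_od,e_od numeric matrices of non-negative optical density, same
#'   shape (hematoxylin and eosin concentration fields).
#' @param stains a [stain_matrix()].
#' @param quantize round to 8-bit integers (default). Use `FALSE` for
#'   continuous intensities, e.g. when checking decomposition round trips.
#' @return H x W x 3 intensity array in [0, 255].
#' @export
render_he <- function(h_od, e_od, stains = stain_matrix(), quantize = TRUE) {
  if (!identical(dim(h_od), dim(e_od)))
    stop("h_od and e_od must have identical shapes")
  stopifnot(all(h_od >= 0), all(e_od >= 0))
  img <- array(unlist(lapply(1:3, function(ch) {
    od_to_rgb(h_od * stains[ch, 1] + e_od * stains[ch, 2])
  }), use.names = FALSE), dim = c(nrow(h_od), ncol(h_od), 3L))
  if (quantize) img <- array(as.integer(pmin(pmax(round(img), 0), 255)),
                             dim = dim(img))
  img
}

# Rasterise one rotated ellipse into the running nearest-centre assignment.
# lab/bestd are modified copies returned to the caller.
rasterise_ellipse <- function(lab, bestd, cy, cx, a, b, theta, label) {
  H <- nrow(lab); W <- ncol(lab)
  r0 <- max(1L, floor(cy - a)); r1 <- min(H, ceiling(cy + a))
  c0 <- max(1L, floor(cx - a)); c1 <- min(W, ceiling(cx + a))
  if (r0 > r1 || c0 > c1) return(list(lab = lab, bestd = bestd))
  ys <- r0:r1; xs <- c0:c1
  dy <- outer(ys - cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cx)
  u <- cos(theta) * dx + sin(theta) * dy
  v <- -sin(theta) * dx + cos(theta) * dy
  inside <- (u / a)^2 + (v / b)^2 <= 1
  d2 <- dx^2 + dy^2
  sub <- lab[ys, xs, drop = FALSE]
  bd <- bestd[ys, xs, drop = FALSE]
  take <- inside & d2 < bd
  sub[take] <- label
  bd[take] <- d2[take]
  lab[ys, xs] <- sub
  bestd[ys, xs] <- bd
  list(lab = lab, bestd = bestd)
}

#' Generate a seeded synthetic H&E scene with instance ground truth
#'
#' Places nuclei sequentially. A nucleus drawn as an "overlapper" (probability
#' `overlap_fraction`) is placed at centre distance 0.65-0.85 times the sum of
#' minor semi-axes from a partner, which guarantees mask contact; other nuclei
#' keep a clearance margin so they never touch. Contested pixels go to the
#' nucleus with the nearest centre, so the mask stays a partition. Stain OD
#' fields get a global +-5% scale jitter (staining batch effect), are rendered
#' through [render_he()], and Gaussian noise is added before 8-bit rounding.
#'
#' @param spec a [scene_spec()].
#' @return an `nf_scene`: list with `image` (H x W x 3 integer), `mask`
#'   (integer matrix, labels consecutive from 1), `touching_pairs` (2-column
#'   matrix of 8-adjacent label pairs), the noise-free stain fields `h_od`,
#'   `e_od` (post-jitter), and `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "nf_scene_spec"))
  with_seed(spec$seed, {
    H <- spec$height; W <- spec$width; n <- spec$n_nuclei
    lab <- matrix(0L, H, W)
    bestd <- matrix(Inf, H, W)
    nuclei <- list()
    attempts <- 0L
    budget <- 10L * max(n, 1L)
    touched <- logical(0)
    i <- 0L
    while (i < n) {
      a <- runif(1, spec$radius_range[1], spec$radius_range[2])
      ecc <- runif(1, spec$eccentricity_range[1], spec$eccentricity_range[2])
      b <- a * sqrt(1 - ecc^2)
      theta <- runif(1, 0, pi)
      overlapper <- i > 0L && rbinom(1, 1, spec$overlap_fraction) == 1L
      placed <- FALSE
      while (!placed) {
        attempts <- attempts + 1L
        if (attempts > budget)
          stop("over-dense scene spec: could not place ", n, " nuclei within ",
               budget, " attempts")
        if (overlapper) {
          pool <- if (any(touched)) which(touched) else seq_along(nuclei)
          j <- pool[sample.int(length(pool), 1L)]
          pj <- nuclei[[j]]
          ang <- runif(1, 0, 2 * pi)
          d <- runif(1, 0.65, 0.85) * (b + pj$b)
          cy <- pj$cy + d * sin(ang)
          cx <- pj$cx + d * cos(ang)
          if (cy < 2 || cy > H - 1 || cx < 2 || cx > W - 1) next
        } else {
          cy <- runif(1, 2, H - 1)
          cx <- runif(1, 2, W - 1)
          ok <- TRUE
          for (p in nuclei) {
            if (sqrt((cy - p$cy)^2 + (cx - p$cx)^2) <= a + p$a + 2) {
              ok <- FALSE; break
            }
          }
          if (!ok) next
        }
        placed <- TRUE
      }
      i <- i + 1L
      nuclei[[i]] <- list(cy = cy, cx = cx, a = a, b = b, theta = theta,
                          od = runif(1, spec$hematoxylin_od_range[1],
                                     spec$hematoxylin_od_range[2]),
                          vesicular = rbinom(1, 1, spec$vesicular_fraction) == 1L)
      touched <- c(touched, overlapper)
      if (overlapper) touched[j] <- TRUE
      res <- rasterise_ellipse(lab, bestd, cy, cx, a, b, theta, i)
      lab <- res$lab; bestd <- res$bestd
    }

    # drop labels that lost every pixel to neighbours; relabel consecutively
    present <- sort(unique(lab[lab > 0L]))
    if (length(present) > 0L) {
      remap <- integer(max(present))
      remap[present] <- seq_along(present)
      lab[lab > 0L] <- remap[lab[lab > 0L]]
      nuclei <- nuclei[present]
    } else nuclei <- list()

    # stain OD fields
    h_od <- matrix(0, H, W)
    for (k in seq_along(nuclei)) {
      p <- nuclei[[k]]
      px <- which(lab == k)
      if (p$vesicular) {
        rows <- (px - 1L) %% H + 1L
        cols <- (px - 1L) %/% H + 1L
        dyv <- rows - p$cy; dxv <- cols - p$cx
        u <- cos(p$theta) * dxv + sin(p$theta) * dyv
        v <- -sin(p$theta) * dxv + cos(p$theta) * dyv
        ai <- max(p$a - 2, 0.5); bi <- max(p$b - 2, 0.5)
        interior <- (u / ai)^2 + (v / bi)^2 <= 1
        h_od[px[interior]] <- p$od * 0.25
        h_od[px[!interior]] <- p$od
      } else {
        h_od[px] <- p$od
      }
    }
    e_od <- matrix(spec$eosin_background_od, H, W)
    jitter <- runif(1, 0.95, 1.05)
    h_od <- h_od * jitter
    e_od <- e_od * jitter

    img <- render_he(h_od, e_od, quantize = FALSE)
    if (spec$noise_sd > 0)
      img <- img + array(rnorm(length(img), 0, spec$noise_sd), dim = dim(img))
    img <- array(as.integer(pmin(pmax(round(img), 0), 255)), dim = dim(img))

    structure(list(image = img, mask = lab,
                   touching_pairs = touching_pairs(lab),
                   h_od = h_od, e_od = e_od, spec = spec),
              class = "nf_scene")
  })
}

#' Label pairs with 8-adjacent contact in an instance mask
#'
#' @param mask integer label matrix (0 = background).
#' @return 2-column integer matrix of sorted (smaller, larger) label pairs,
#'   one row per touching pair; zero rows if none touch.
#' @export
touching_pairs <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pairs <- matrix(integer(0), ncol = 2)
  shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  for (s in shifts) {
    dr <- s[1]; dc <- s[2]
    r1 <- 1:(H - dr); r2 <- (1 + dr):H
    if (dc >= 0) { c1 <- 1:(W - dc); c2 <- (1 + dc):W }
    else { c1 <- (1 - dc):W; c2 <- 1:(W + dc) }
    a <- mask[r1, c1, drop = FALSE]
    b <- mask[r2, c2, drop = FALSE]
    sel <- a > 0L & b > 0L & a != b
    if (any(sel))
      pairs <- rbind(pairs, cbind(pmin(a[sel], b[sel]), pmax(a[sel], b[sel])))
  }
  if (nrow(pairs) == 0L)
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("a", "b"))))
  up <- unique(pairs)
  up <- up[order(up[, 1], up[, 2]), , drop = FALSE]
  dimnames(up) <- list(NULL, c("a", "b"))
  up
}

#' Split scenes into disjoint training and test partitions
#'
#' Scene-level split: nuclei from the same tile are never used for both
#' training and testing.
#'
#' @param scenes list of scenes (or any list).
#' @param ratio training fraction in (0, 1); 0.5 gives the 50/50 protocol.
#' @param seed integer seed; identical seeds give identical splits.
#' @return list with `train` and `test` sub-lists.
#' @export
split_dataset <- function(scenes, ratio = 0.5, seed = 1L) {
  stopifnot(ratio > 0, ratio < 1)
  n <- length(scenes)
  if (n < 2L) stop("need at least 2 scenes to split")
  n_train <- min(max(round(ratio * n), 1L), n - 1L)
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = scenes[sort(idx)], test = scenes[sort(setdiff(seq_len(n), idx))])
}

#' Write / read a scene as image + mask + JSON sidecar
#'
#' @param scene an `nf_scene`.
#' @param dir output directory (created if missing).
#' @param stem file stem; writes `<stem>.png`, `<stem>_mask.pgm`,
#'   `<stem>.json`.
#' @return invisibly, the three paths.
#' @export
write_scene <- function(scene, dir, stem) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_img <- file.path(dir, paste0(stem, ".png"))
  p_msk <- file.path(dir, paste0(stem, "_mask.pgm"))
  p_json <- file.path(dir, paste0(stem, ".json"))
  write_image(scene$image, p_img)
  write_mask(scene$mask, p_msk)
  side <- list(spec = unclass(scene$spec),
               touching_pairs = unname(apply(scene$touching_pairs, 1, c,
                                             simplify = FALSE)))
  writeLines(jsonlite::toJSON(side, auto_unbox = TRUE, digits = NA), p_json)
  invisible(c(image = p_img, mask = p_msk, sidecar = p_json))
}

#' @rdname write_scene
#' @export
read_scene <- function(dir, stem) {
  img <- read_image(file.path(dir, paste0(stem, ".png")))
  msk <- read_mask(file.path(dir, paste0(stem, "_mask.pgm")))
  side <- jsonlite::fromJSON(file.path(dir, paste0(stem, ".json")),
                             simplifyVector = TRUE)
  tp <- side$touching_pairs
  tp <- if (length(tp) == 0) matrix(integer(0), ncol = 2)
        else matrix(as.integer(unlist(tp)), ncol = 2, byrow = TRUE)
  dimnames(tp) <- list(NULL, c("a", "b"))
  spec <- do.call(scene_spec, side$spec[c("height", "width", "n_nuclei",
    "radius_range", "eccentricity_range", "overlap_fraction",
    "vesicular_fraction", "hematoxylin_od_range", "eosin_background_od",
    "noise_sd", "seed")])
  structure(list(image = img, mask = msk, touching_pairs = tp, spec = spec),
            class = "nf_scene")
}
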