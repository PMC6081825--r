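# Independent brute-force oracles used across the suite. These deliberately
# share no code with the implementation paths they check.

# Exhaustive 8-adjacency scan: every pixel against its 8 neighbours.
oracle_touching_pairs <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- character(0)
  out <- matrix(integer(0), ncol = 2)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    a <- mask[i, j]
    if (a == 0L) next
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > H || jj < 1 || jj > W) next
      b <- mask[ii, jj]
      if (b == 0L || b == a) next
      key <- paste(min(a, b), max(a, b))
      if (!key %in% seen) {
        seen <- c(seen, key)
        out <- rbind(out, c(min(a, b), max(a, b)))
      }
    }
  }
  if (nrow(out)) out <- out[order(out[, 1], out[, 2]), , drop = FALSE]
  dimnames(out) <- list(NULL, c("a", "b"))
  out
}

# IoU table between all gt/pred label pairs, by explicit pixel sets.
oracle_iou_table <- function(gt, pred) {
  ng <- max(gt, 0L); np <- max(pred, 0L)
  m <- matrix(0, ng, np)
  if (ng == 0L || np == 0L) return(m)
  for (g in seq_len(ng)) for (p in seq_len(np)) {
    A <- which(gt == g); B <- which(pred == p)
    u <- length(union(A, B))
    m[g, p] <- if (u > 0) length(intersect(A, B)) / u else 0
  }
  m
}

# Optimal one-to-one assignment TP count by exhaustive recursion over all
# injective gt -> pred mappings restricted to pairs with IoU > threshold.
oracle_optimal_tp <- function(gt, pred, threshold = 0.5) {
  ioum <- oracle_iou_table(gt, pred)
  ng <- nrow(ioum); np <- ncol(ioum)
  if (ng == 0L || np == 0L) return(0L)
  best <- 0L
  recur <- function(g, used, count) {
    if (count + (ng - g + 1L) <= best) return()   # bound
    if (g > ng) { best <<- max(best, count); return() }
    recur(g + 1L, used, count)                    # leave g unmatched
    for (p in seq_len(np)) {
      if (!used[p] && ioum[g, p] > threshold) {
        used[p] <- TRUE
        recur(g + 1L, used, count + 1L)
        used[p] <- FALSE
      }
    }
  }
  recur(1L, logical(np), 0L)
  best
}

# Random label mask with n blob-like objects (rectangles jittered), may touch.
random_object_mask <- function(H, W, n, seed) {
  set.seed(seed)
  m <- matrix(0L, H, W)
  for (k in seq_len(n)) {
    h <- sample(3:7, 1); w <- sample(3:7, 1)
    i <- sample(seq_len(H - h), 1); j <- sample(seq_len(W - w), 1)
    m[i:(i + h), j:(j + w)] <- k
  }
  # relabel to consecutive non-empty labels
  present <- sort(unique(m[m > 0L]))
  remap <- integer(max(c(present, 1L)))
  remap[present] <- seq_along(present)
  m[m > 0L] <- remap[m[m > 0L]]
  m
}

disc_mask <- function(H, W, cy, cx, r) {
  outer(seq_len(H), seq_len(W), function(i, j) (i - cy)^2 + (j - cx)^2 <= r^2)
}

# Nearest-centre partition of a fused two-disc blob.
oracle_nearest_centre <- function(fg, c1, c2) {
  H <- nrow(fg); W <- ncol(fg)
  d1 <- outer(seq_len(H), seq_len(W), function(i, j) (i - c1[1])^2 + (j - c1[2])^2)
  d2 <- outer(seq_len(H), seq_len(W), function(i, j) (i - c2[1])^2 + (j - c2[2])^2)
  lab <- matrix(0L, H, W)
  lab[fg & d1 <= d2] <- 1L
  lab[fg & d1 > d2] <- 2L
  lab
}

# Tiny seeded scenes shared by several files.
small_scene <- function(seed, n = 8L, hw = 64L, overlap = 0.3) {
  generate_scene(scene_spec(height = hw, width = hw, n_nuclei = n,
                            overlap_fraction = overlap, seed = seed))
}
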