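#' @export
print.nf_scene <- function(x, ...) {
  cat(sprintf("<nf_scene> %d x %d px, %d nuclei, %d touching pair%s (seed %d)\n",
              nrow(x$mask), ncol(x$mask), max(x$mask, 0L),
              nrow(x$touching_pairs),
              if (nrow(x$touching_pairs) == 1L) "" else "s", x$spec$seed))
  invisible(x)
}

#' @export
print.nf_scene_spec <- function(x, ...) {
  cat(sprintf(paste0("<nf_scene_spec> %d x %d px, %d nuclei, overlap %.2f, ",
                     "vesicular %.2f, noise sd %.1f, seed %d\n"),
              x$height, x$width, x$n_nuclei, x$overlap_fraction,
              x$vesicular_fraction, x$noise_sd, x$seed))
  invisible(x)
}

#' @export
print.nf_model <- function(x, ...) {
  what <- if (x$family == "enet") "ENet-style asymmetric"
          else sprintf("symmetric %d+%d module", x$n_modules, x$n_modules)
  cat(sprintf("<nf_model> %s encoder-decoder%s: %d ops, %s parameters, in=%d ch, /%d downsampling\n",
              what, if (x$multitask) " (multitask)" else "",
              length(x$ops), format(parameter_count(x), big.mark = ","),
              x$in_channels, 2^x$downs))
  invisible(x)
}

#' @export
print.nf_fusion_model <- function(x, ...) {
  cat("<nf_fusion_model> region + boundary + fusion networks\n")
  for (nm in c("region", "boundary", "fusion")) {
    cat(" ", nm, ": ")
    print(x[[nm]])
  }
  invisible(x)
}

#' @export
print.nf_match <- function(x, ...) {
  m <- compute_metrics(x)
  cat(sprintf("<nf_match> gt=%d pred=%d | TP=%d FP=%d FN=%d | P=%.3f R=%.3f F1=%.3f\n",
              x$n_gt, x$n_pred, x$tp, x$fp, x$fn,
              m["precision"], m["recall"], m["f1"]))
  invisible(x)
}
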