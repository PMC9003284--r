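# End-to-end segmentation pipeline: preprocess -> LTP sharpness -> blur
# mask -> adaptive PCNN -> binarize/clean -> final mask, plus evaluation
# against ground truth. Deterministic: identical input + config give an
# identical result.

#' Pipeline configuration
#'
#' @param descriptor a [descriptor_config()].
#' @param median_window preprocessing median-filter window (odd, >= 3).
#' @param TdLTP fixed sharpness threshold for [blur_mask()], or `NULL` for
#'   the adaptive twice-the-mean threshold.
#' @param edge_threshold fixed threshold for [binarize_and_clean()], or
#'   `NULL` for adaptive.
#' @param pcnn_init threshold initialization, `"gamma"` or `"max"`.
#' @param max_iters PCNN iteration cap.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(descriptor = descriptor_config(),
                            median_window = 3L, TdLTP = NULL,
                            edge_threshold = NULL,
                            pcnn_init = c("gamma", "max"),
                            max_iters = 256L) {
  stopifnot(inherits(descriptor, "descriptor_config"))
  structure(list(descriptor = descriptor,
                 median_window = as.integer(median_window), TdLTP = TdLTP,
                 edge_threshold = edge_threshold,
                 pcnn_init = match.arg(pcnn_init),
                 max_iters = as.integer(max_iters)),
            class = "pipeline_config")
}

with_stage <- function(stage, expr) {
  withCallingHandlers(
    expr,
    error = function(e) {
      stop(errorCondition(paste0("[stage: ", stage, "] ", conditionMessage(e)),
                          class = c("focusfield_stage_error", class(e))))
    })
}

#' Segment the in-focus region of a partially defocused image
#'
#' Runs the full stage sequence exactly once: grayscale conversion, median
#' filtering, min-max normalization, LTP sharpness map, blur masking,
#' adaptive PCNN parameter estimation, the PCNN firing loop, and edge-map
#' binarization/cleanup. All intermediates are returned.
#'
#' @param img matrix or RGB array.
#' @param cfg a [pipeline_config()].
#' @return object of class `segmentation_result` with fields `mask`
#'   (logical, sharp = `TRUE`), `sharpness`, `blur_masked`, `edge`,
#'   `firing` (iteration matrix) and `provenance` (config plus the derived
#'   PCNN parameters).
#' @export
segment <- function(img, cfg = pipeline_config()) {
  g <- with_stage("preprocess", {
    gg <- to_grayscale(img)
    gg <- median_filter(gg, cfg$median_window)
    normalize_gray(gg)
  })
  s <- with_stage("sharpness", sharpness_map(g, cfg$descriptor))
  bm <- with_stage("blur-mask", blur_mask(g, s, cfg$TdLTP))
  params <- with_stage("parameter-estimation",
                       estimate_params(g, init = cfg$pcnn_init,
                                       max_iters = cfg$max_iters))
  run <- with_stage("pcnn", pcnn_run(bm, params))
  mask <- with_stage("binarize", binarize_and_clean(run$edge,
                                                    cfg$edge_threshold))
  structure(list(mask = mask, sharpness = s, blur_masked = bm,
                 edge = run$edge, firing = run$state$f,
                 provenance = list(
                   config = cfg,
                   params = params[c("F_E", "C", "delta", "Td_min")],
                   TdLTP = bm$TdLTP)),
            class = "segmentation_result")
}

#' Evaluate a segmentation result against a ground-truth mask
#'
#' Reports the full metric suite under both polarity conventions: sharp
#' region as positive class, and blurred region as positive class.
#'
#' @param result a [segment()] result or a logical mask.
#' @param gt ground-truth mask, sharp = `TRUE`/white.
#' @param kappa_sq F-measure weight.
#' @return list with elements `sharp` and `blurred`, each a
#'   [metrics_report()].
#' @export
evaluate <- function(result, gt, kappa_sq = 0.3) {
  mask <- if (inherits(result, "segmentation_result")) result$mask else result
  list(sharp = metrics_report(mask, gt, kappa_sq),
       blurred = metrics_report(!mask, !gt, kappa_sq))
}

#' @export
print.segmentation_result <- function(x, ...) {
  p <- x$provenance$params
  cat("focusfield segmentation:", nrow(x$mask), "x", ncol(x$mask),
      "| sharp fraction", round(mean(x$mask), 4), "\n")
  cat(sprintf("  F_E = %.4f  C = %.4f  delta = %.4f  Td_min = %.4f  TdLTP = %.4f\n",
              p$F_E, p$C, p$delta, p$Td_min, x$provenance$TdLTP))
  invisible(x)
}
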