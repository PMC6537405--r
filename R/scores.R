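#' Per-image log pixel ratio
#'
#' The assay's single-image statistic: `ln(numerator / denominator + 1)`
#' on summed foreground pixel counts. A zero denominator is replaced by an
#' integer pseudocount (default 1 px) to keep the logarithm finite; for
#' realistic areas (1e3-1e6 px) the pseudocount is negligible.
#'
#' @param numerator_px,denominator_px non-negative pixel counts.
#' @param pseudocount denominator floor (default 1).
#' @return a non-negative number.
#' @export
image_log_ratio <- function(numerator_px, denominator_px, pseudocount = 1L) {
  if (numerator_px < 0 || denominator_px < 0)
    stop("pixel counts must be non-negative")
  log1p(numerator_px / max(denominator_px, pseudocount))
}

new_image_ratio <- function(metric, num, den, pseudocount, key = NULL) {
  structure(list(key = key, metric = metric,
                 numerator_px = num, denominator_px = den,
                 log_ratio = image_log_ratio(num, den, pseudocount)),
            class = "image_ratio")
}

#' Viability ratio of one position
#'
#' Ratio of Hoechst-labeled (all-nuclei) pixels to overlap-corrected
#' dead-cell pixels, as `ln(ratio + 1)`. In co-culture mode the
#' GFP-subtracted target-cell areas are used instead, so the score reflects
#' the unlabeled (melanoma) population only.
#'
#' @param areas a [measure_areas()] result.
#' @param coculture use [coculture_areas()] target arithmetic.
#' @param pseudocount denominator floor.
#' @return an `image_ratio` (fields `metric`, `numerator_px`,
#'   `denominator_px`, `log_ratio`).
#' @export
viability_ratio <- function(areas, coculture = FALSE, pseudocount = 1L) {
  stopifnot(inherits(areas, "channel_areas"))
  if (!"nuclear" %in% names(areas$area))
    stop("viability needs the nuclear channel")
  if (coculture) {
    cc <- coculture_areas(areas)
    new_image_ratio("viability", cc$hoechst_target, cc$ethd_target,
                    pseudocount, areas$key)
  } else {
    new_image_ratio("viability", areas$area[["nuclear"]], dead_area(areas),
                    pseudocount, areas$key)
  }
}

#' Proliferation ratio of one position
#'
#' The default orientation is EdU over Hoechst (`ln(EdU/Hoechst + 1)`): the
#' fraction-like quantity that falls when S-phase is suppressed, matching
#' the downward dose trend of proliferation read-outs. The literal
#' Hoechst-over-EdU orientation is available as `"hoechst_over_edu"`; which
#' one a given dataset used is the most consequential configuration switch
#' in the pipeline, so it is logged with the run.
#'
#' @param areas a [measure_areas()] result.
#' @param orientation `"edu_over_hoechst"` (default) or
#'   `"hoechst_over_edu"`.
#' @param pseudocount denominator floor.
#' @return an `image_ratio`.
#' @export
proliferation_ratio <- function(areas,
                                orientation = c("edu_over_hoechst",
                                                "hoechst_over_edu"),
                                pseudocount = 1L) {
  stopifnot(inherits(areas, "channel_areas"))
  orientation <- match.arg(orientation)
  if (!"proliferation" %in% names(areas$area))
    stop("proliferation needs the proliferation (EdU) channel")
  if (!"nuclear" %in% names(areas$area))
    stop("proliferation needs the nuclear channel")
  edu <- areas$area[["proliferation"]]
  hoe <- areas$area[["nuclear"]]
  if (orientation == "edu_over_hoechst")
    new_image_ratio("proliferation", edu, hoe, pseudocount, areas$key)
  else
    new_image_ratio("proliferation", hoe, edu, pseudocount, areas$key)
}

#' Plate layout
#'
#' Maps wells to treatment labels and designates exactly one vehicle
#' (DMSO) control treatment, to which all scores are normalized.
#'
#' @param assignments named character vector: `well -> treatment`.
#' @param control_label the control treatment label; must appear among the
#'   assignments.
#' @return an object of class `plate_layout`.
#' @export
plate_layout <- function(assignments, control_label) {
  stopifnot(is.character(assignments), length(assignments) >= 1L,
            !is.null(names(assignments)), is.character(control_label),
            length(control_label) == 1L)
  if (!control_label %in% assignments)
    stop("control treatment '", control_label,
         "' does not appear among the well assignments")
  structure(list(assignments = assignments, control_label = control_label),
            class = "plate_layout")
}

#' Per-treatment scores normalized to the vehicle control
#'
#' Per-image log-ratios are averaged over all images of a treatment, and
#' each treatment mean is divided by the control (DMSO) mean, so the
#' control score is exactly 1. The SEM is the per-image SD over sqrt(n),
#' scaled by the control mean (the control mean is treated as a constant).
#' Images whose *nuclear* channel was declared signal-free are excluded
#' (no cells found there); zero signal on a marker channel simply
#' contributes zero pixels and stays in.
#'
#' @param ratios data frame with columns `well`, `position`, `metric`,
#'   `log_ratio` and (optionally) `nuclear_has_signal`.
#' @param layout a [plate_layout()].
#' @return a data frame of class `treatment_scores` with columns
#'   `treatment`, `metric`, `score`, `sem`, `n_images`, `n_positions`,
#'   ordered by treatment then metric.
#' @export
treatment_scores <- function(ratios, layout) {
  stopifnot(is.data.frame(ratios), inherits(layout, "plate_layout"))
  need <- c("well", "position", "metric", "log_ratio")
  if (!all(need %in% names(ratios)))
    stop("ratios must have columns: ", paste(need, collapse = ", "))
  if ("nuclear_has_signal" %in% names(ratios))
    ratios <- ratios[ratios$nuclear_has_signal %in% TRUE, , drop = FALSE]
  ratios <- ratios[is.finite(ratios$log_ratio), , drop = FALSE]
  unknown <- setdiff(unique(ratios$well), names(layout$assignments))
  if (length(unknown))
    stop("wells without a layout assignment: ", paste(unknown, collapse = ", "))
  ratios$treatment <- unname(layout$assignments[ratios$well])
  ctrl <- layout$control_label
  out <- do.call(rbind, lapply(sort(unique(ratios$metric)), function(met) {
    sub <- ratios[ratios$metric == met, , drop = FALSE]
    cvals <- sub$log_ratio[sub$treatment == ctrl]
    if (length(cvals) == 0L)
      stop("control has no usable image for metric '", met, "'")
    cmean <- mean(cvals)
    if (cmean == 0) stop("control has no signal for metric '", met, "'")
    do.call(rbind, lapply(sort(unique(sub$treatment)), function(tr) {
      v <- sub$log_ratio[sub$treatment == tr]
      npos <- length(unique(paste(sub$well[sub$treatment == tr],
                                  sub$position[sub$treatment == tr])))
      data.frame(treatment = tr, metric = met,
                 score = mean(v) / cmean,
                 sem = if (length(v) > 1L)
                   stats::sd(v) / sqrt(length(v)) / cmean else 0,
                 n_images = length(v), n_positions = npos,
                 stringsAsFactors = FALSE)
    }))
  }))
  out <- out[order(out$treatment, out$metric), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("treatment_scores", "data.frame")
  out
}

#' @export
print.treatment_scores <- function(x, digits = 4, ...) {
  cat("Treatment scores (control-normalized)\n")
  y <- as.data.frame(x)
  y$score <- signif(y$score, digits)
  y$sem <- signif(y$sem, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Bar plot of treatment scores with SEM bars
#'
#' @param x a [treatment_scores()] data frame.
#' @param metric which metric to plot (default: first present).
#' @param ... passed to [graphics::barplot()].
#' @export
plot.treatment_scores <- function(x, metric = NULL, ...) {
  y <- as.data.frame(x)
  if (is.null(metric)) metric <- y$metric[1L]
  y <- y[y$metric == metric, , drop = FALSE]
  mids <- graphics::barplot(y$score, names.arg = y$treatment,
                            ylab = paste(metric, "score"),
                            ylim = c(0, max(y$score + y$sem) * 1.15), ...)
  graphics::arrows(mids, y$score - y$sem, mids, y$score + y$sem,
                   angle = 90, code = 3, length = 0.05)
  invisible(mids)
}
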