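#' Analyze one position's channel stacks (in memory)
#'
#' The core per-position computation, shared by the batch pipeline and the
#' in-memory simulation tests: correct every plane, estimate one threshold
#' per channel stack from its central slices, segment every slice with that
#' threshold, and measure areas and pairwise intersections. A pure function
#' of its inputs — the unit of parallelism.
#'
#' @param stacks named list `role -> image_stack` for one position.
#' @param correction a [correction_params()].
#' @param threshold list of threshold settings (see [run_config()]).
#' @param key optional identifier carried into the result.
#' @return list with `areas` ([measure_areas()]), `decisions` (named list
#'   of `threshold_decision`).
#' @export
analyze_stacks <- function(stacks, correction = correction_params(),
                           threshold = list(), key = NULL) {
  stopifnot(is.list(stacks), length(stacks) >= 1L, !is.null(names(stacks)))
  th <- utils::modifyList(list(method = "yen", signal_fold = 10,
                               central_fraction = 0.2, n_bins = 256L),
                          threshold)
  decisions <- list(); masks <- list()
  for (ro in names(stacks)) {
    st <- stacks[[ro]]
    planes <- if (inherits(st, "image_stack")) st$planes else st
    corrected <- lapply(planes, correct_illumination, params = correction)
    dec <- estimate_stack_threshold(corrected,
                                    central_fraction = th$central_fraction,
                                    n_bins = th$n_bins,
                                    signal_fold = th$signal_fold,
                                    method = th$method)
    decisions[[ro]] <- dec
    masks[[ro]] <- lapply(corrected, segment_foreground, decision = dec)
  }
  list(areas = measure_areas(masks, key = key), decisions = decisions)
}

#' Analyze one well/position from a dataset on disk
#'
#' @param manifest a [discover_dataset()] result.
#' @param well,position the position key.
#' @param config a [run_config()].
#' @return as [analyze_stacks()].
#' @export
analyze_position <- function(manifest, well, position, config) {
  m <- manifest$manifest
  roles <- sort(unique(m$role[m$well == well & m$position == position]))
  if (length(roles) == 0L) stop("no channels for ", well, "/p", position)
  stacks <- stats::setNames(lapply(roles, function(ro)
    read_stack(manifest, well, position, ro)), roles)
  analyze_stacks(stacks, correction = config$correction,
                 threshold = config$threshold,
                 key = paste0(well, "/", position))
}

# flatten one position's result into a one-row data frame
position_row <- function(well, position, treatment, res, score_opts) {
  areas <- res$areas
  row <- data.frame(well = well, position = position,
                    treatment = treatment, n_slices = areas$n_slices,
                    stringsAsFactors = FALSE)
  for (ro in names(areas$area)) {
    row[[paste0("area_", ro)]] <- areas$area[[ro]]
    dec <- res$decisions[[ro]]
    row[[paste0("threshold_", ro)]] <- dec$threshold
    row[[paste0("has_signal_", ro)]] <- dec$has_signal
    row[[paste0("fold_", ro)]] <- dec$fold_over_background
  }
  for (nm in names(areas$intersections))
    row[[paste0("inter_", gsub("&", ".", nm, fixed = TRUE))]] <-
      areas$intersections[[nm]]
  row$nuclear_has_signal <- res$decisions[["nuclear"]]$has_signal
  has_death <- any(c("dead_membrane", "dead_apoptotic") %in%
                     names(areas$area))
  if (has_death) {
    v <- viability_ratio(areas, coculture = isTRUE(score_opts$coculture),
                         pseudocount = score_opts$pseudocount)
    row$viability_log_ratio <- v$log_ratio
    row$dead_px <- v$denominator_px
  }
  if ("proliferation" %in% names(areas$area)) {
    p <- proliferation_ratio(areas, orientation = score_opts$orientation,
                             pseudocount = score_opts$pseudocount)
    row$proliferation_log_ratio <- p$log_ratio
  }
  row
}

images_to_ratios <- function(images) {
  long <- list()
  if ("viability_log_ratio" %in% names(images))
    long$viability <- data.frame(well = images$well,
                                 position = images$position,
                                 metric = "viability",
                                 log_ratio = images$viability_log_ratio,
                                 nuclear_has_signal = images$nuclear_has_signal,
                                 stringsAsFactors = FALSE)
  if ("proliferation_log_ratio" %in% names(images))
    long$proliferation <- data.frame(well = images$well,
                                     position = images$position,
                                     metric = "proliferation",
                                     log_ratio = images$proliferation_log_ratio,
                                     nuclear_has_signal = images$nuclear_has_signal,
                                     stringsAsFactors = FALSE)
  do.call(rbind, long)
}

#' Run the full batch pipeline on a dataset
#'
#' Discovers the TIFF tree, validates that every discovered well has a
#' layout assignment and that control wells are present (a hard error
#' before any image is read), analyzes every position (in parallel when
#' `n_workers > 1`; results are merged by key sort, so the output is
#' independent of worker count and scheduling), and writes the results
#' directory: `images.csv` (the auditable per-position areas,
#' intersections, thresholds and log-ratios), `scores.csv` (per-treatment
#' scores), `decisions.csv`, `rejects.csv`, `quarantine.csv` (positions
#' whose analysis failed; the run continues without them) and
#' `config.json` (the configuration snapshot). Every number in
#' `scores.csv` is recomputable from `images.csv` with a few lines of R.
#'
#' @param config a [run_config()].
#' @return invisibly, list with `images`, `scores`, `quarantined`,
#'   `manifest`, `output_dir`.
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  manifest <- discover_dataset(config$input_dir, config$channel_tokens)
  m <- manifest$manifest
  wells <- sort(unique(m$well))
  unassigned <- setdiff(wells, names(config$layout$assignments))
  if (length(unassigned))
    stop("wells without a layout assignment: ",
         paste(unassigned, collapse = ", "))
  treatments <- config$layout$assignments[wells]
  if (!config$layout$control_label %in% treatments)
    stop("no control ('", config$layout$control_label,
         "') wells in the dataset")
  keys <- unique(m[c("well", "position")])
  keys <- keys[order(keys$well, keys$position), , drop = FALSE]
  worker <- function(i) {
    w <- keys$well[i]; p <- keys$position[i]
    tryCatch(list(ok = TRUE, well = w, position = p,
                  res = analyze_position(manifest, w, p, config)),
             error = function(e) list(ok = FALSE, well = w, position = p,
                                      error = conditionMessage(e)))
  }
  results <- if (config$n_workers > 1L)
    parallel::mclapply(seq_len(nrow(keys)), worker,
                       mc.cores = config$n_workers)
  else lapply(seq_len(nrow(keys)), worker)
  ok <- vapply(results, function(r) isTRUE(r$ok), FALSE)
  quarantined <- if (any(!ok))
    data.frame(well = vapply(results[!ok], `[[`, "", "well"),
               position = vapply(results[!ok], `[[`, 0L, "position"),
               error = vapply(results[!ok], `[[`, "", "error"),
               stringsAsFactors = FALSE)
  else data.frame(well = character(0), position = integer(0),
                  error = character(0))
  results <- results[ok]
  if (length(results) == 0L) stop("every position failed analysis")
  images <- do.call(rbind, lapply(results, function(r)
    position_row(r$well, r$position,
                 unname(config$layout$assignments[[r$well]]), r$res,
                 config$score)))
  rownames(images) <- NULL
  ratios <- images_to_ratios(images)
  scores <- treatment_scores(ratios, config$layout)
  decisions <- do.call(rbind, lapply(results, function(r) {
    do.call(rbind, lapply(names(r$res$decisions), function(ro) {
      d <- r$res$decisions[[ro]]
      data.frame(well = r$well, position = r$position, role = ro,
                 method = d$method, threshold = d$threshold,
                 background_mean = d$background_mean,
                 fold_over_background = d$fold_over_background,
                 has_signal = d$has_signal,
                 central_slices = paste(d$central_slices, collapse = ";"),
                 stringsAsFactors = FALSE)
    }))
  }))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(images, file.path(out, "images.csv"), row.names = FALSE)
  write_scores_table(scores, file.path(out, "scores.csv"))
  utils::write.csv(decisions, file.path(out, "decisions.csv"),
                   row.names = FALSE)
  utils::write.csv(manifest$rejects, file.path(out, "rejects.csv"),
                   row.names = FALSE)
  utils::write.csv(quarantined, file.path(out, "quarantine.csv"),
                   row.names = FALSE)
  jsonlite::write_json(c(list(package_version =
                                as.character(utils::packageVersion("cellfate3d"))),
                         config_as_list(config)),
                       file.path(out, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(images = images, scores = scores,
                 quarantined = quarantined, manifest = manifest,
                 output_dir = out))
}
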