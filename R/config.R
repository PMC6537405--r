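#' Assemble and validate a pipeline run configuration
#'
#' All knobs of a batch run in one validated object, serialized verbatim
#' into the results directory for auditability.
#'
#' @param input_dir directory of TIFF slices.
#' @param output_dir results directory (created; inputs are never modified
#'   in place).
#' @param channel_tokens named character vector `role -> filename token`.
#' @param layout a [plate_layout()].
#' @param correction a [correction_params()].
#' @param threshold list: `method` (`"yen"`/`"robust_background"`),
#'   `signal_fold`, `central_fraction`, `n_bins`.
#' @param score list: `orientation` (proliferation ratio orientation),
#'   `pseudocount`, `coculture` (use GFP-subtracted target arithmetic).
#' @param n_workers parallel workers (processes, one position each).
#' @return object of class `run_config`.
#' @export
run_config <- function(input_dir, output_dir, channel_tokens, layout,
                       correction = correction_params(),
                       threshold = list(),
                       score = list(),
                       n_workers = 1L) {
  threshold <- utils::modifyList(list(method = "yen", signal_fold = 10,
                                      central_fraction = 0.2,
                                      n_bins = 256L), threshold)
  score <- utils::modifyList(list(orientation = "edu_over_hoechst",
                                  pseudocount = 1L, coculture = FALSE),
                             score)
  cfg <- structure(list(input_dir = input_dir, output_dir = output_dir,
                        channel_tokens = channel_tokens, layout = layout,
                        correction = correction, threshold = threshold,
                        score = score, n_workers = as.integer(n_workers)),
                   class = "run_config")
  validate_config(cfg)
  cfg
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (!dir.exists(cfg$input_dir))
    stop("input_dir does not exist: ", cfg$input_dir)
  if (!inherits(cfg$layout, "plate_layout")) stop("layout must be a plate_layout")
  if (!inherits(cfg$correction, "correction_params"))
    stop("correction must be correction_params")
  if (!"nuclear" %in% names(cfg$channel_tokens))
    stop("the nuclear channel is mandatory for any scoring run")
  if (!cfg$threshold$method %in% c("yen", "robust_background"))
    stop("unknown threshold method: ", cfg$threshold$method)
  if (cfg$threshold$central_fraction <= 0 || cfg$threshold$central_fraction > 1)
    stop("central_fraction must be in (0, 1]")
  if (!cfg$score$orientation %in% c("edu_over_hoechst", "hoechst_over_edu"))
    stop("unknown proliferation orientation: ", cfg$score$orientation)
  if (cfg$n_workers < 1L) stop("n_workers must be >= 1")
  invisible(cfg)
}

#' Read a run configuration from a JSON file
#'
#' Schema: `channels: {role: token}`, `wells: {id: treatment}`,
#' `control: label`, plus optional `correction`, `threshold`, `score`,
#' `n_workers` blocks mirroring [run_config()] arguments.
#'
#' @param path JSON file.
#' @param input_dir,output_dir directories (default: the config file's
#'   directory and `<input_dir>/results`).
#' @return a [run_config()].
#' @export
read_run_config <- function(path, input_dir = dirname(path),
                            output_dir = file.path(input_dir, "results")) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(js$channels) || is.null(js$wells) || is.null(js$control))
    stop("config must define channels, wells and control")
  corr <- do.call(correction_params,
                  as.list(js$correction %||% list()))
  run_config(input_dir = input_dir, output_dir = output_dir,
             channel_tokens = unlist(js$channels),
             layout = plate_layout(unlist(js$wells), js$control),
             correction = corr,
             threshold = as.list(js$threshold %||% list()),
             score = as.list(js$score %||% list()),
             n_workers = js$n_workers %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_as_list <- function(cfg) {
  list(input_dir = cfg$input_dir, output_dir = cfg$output_dir,
       channels = as.list(cfg$channel_tokens),
       wells = as.list(cfg$layout$assignments),
       control = cfg$layout$control_label,
       correction = cfg$correction[c("sigma_px", "enabled")],
       threshold = cfg$threshold, score = cfg$score,
       n_workers = cfg$n_workers)
}
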