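#' Pipeline run configuration
#'
#' Bundles every knob of an end-to-end run: input (a recording path or a
#' [sim_scene]), output path, mode, trail-rendering parameters and
#' preprocessing flags. Validation happens up front, before any computation,
#' and names the offending field.
#'
#' Modes: `"still"` (full-recording trail image), `"video"` (sliding-window
#' trail video), `"subtract_only"` (the minimal visualization: the
#' average-subtracted frames written out as a video), `"simulate"` (render a
#' synthetic recording plus its ground-truth CSV).
#'
#' @param output Output path (`.png` still; `.tif` movie for the other
#'   modes).
#' @param mode One of `"still"`, `"video"`, `"subtract_only"`, `"simulate"`.
#' @param input Input recording: multi-page TIFF path or image-sequence glob
#'   (required unless `mode = "simulate"`).
#' @param scene A [sim_scene] (required for `mode = "simulate"`).
#' @param fps Frame rate of the input (required when loading recordings).
#' @param window_s,fade_fraction,gain,offset,colormap,stride,global_time
#'   Trail parameters, see [trail_params()].
#' @param normalize,vignette,sigma_px,epsilon Preprocessing flags, see
#'   [preprocess_stack()].
#' @param target Brightness target, see [normalize_brightness()].
#' @param worm_length_px,max_speed_px_per_s Optional acquisition-check
#'   inputs, see [check_acquisition()].
#' @param log_level `"quiet"`, `"info"` or `"debug"`.
#' @return A validated `run_config`.
#' @export
run_config <- function(output, mode = c("still", "video", "subtract_only",
                                        "simulate"),
                       input = NULL, scene = NULL, fps = NULL,
                       window_s = 20, fade_fraction = 0.2, gain = 10,
                       offset = 0.05, colormap = "blue_red", stride = 1L,
                       global_time = FALSE,
                       normalize = TRUE, target = "auto", vignette = TRUE,
                       sigma_px = NULL, epsilon = 1e-3,
                       worm_length_px = NULL, max_speed_px_per_s = NULL,
                       log_level = c("info", "quiet", "debug")) {
  mode <- match.arg(mode)
  log_level <- match.arg(log_level)
  if (missing(output) || !is.character(output) || length(output) != 1L) {
    stop("field `output`: a single output path is required", call. = FALSE)
  }
  if (mode == "simulate") {
    if (!inherits(scene, "sim_scene")) {
      stop("field `scene`: mode \"simulate\" requires a sim_scene",
           call. = FALSE)
    }
  } else {
    if (is.null(input)) {
      stop(sprintf("field `input`: mode \"%s\" requires an input recording",
                   mode), call. = FALSE)
    }
    if (is.null(fps) || !is.numeric(fps) || fps <= 0) {
      stop("field `fps`: a positive frame rate is required to load recordings",
           call. = FALSE)
    }
  }
  tp <- tryCatch(
    trail_params(window_s = if (mode == "still") "full" else window_s,
                 fade_fraction = fade_fraction, gain = gain, offset = offset,
                 colormap = colormap, stride = stride,
                 global_time = global_time),
    error = function(e) stop(sprintf("field `trail_params`: %s",
                                     conditionMessage(e)), call. = FALSE))
  if (!is.null(sigma_px) && sigma_px <= 0) {
    stop("field `sigma_px`: must be positive", call. = FALSE)
  }
  if (epsilon <= 0) stop("field `epsilon`: must be positive", call. = FALSE)
  if (!is.null(worm_length_px) && worm_length_px <= 0) {
    stop("field `worm_length_px`: must be positive", call. = FALSE)
  }
  structure(list(
    output = output, mode = mode, input = input, scene = scene, fps = fps,
    params = tp, normalize = isTRUE(normalize), target = target,
    vignette = isTRUE(vignette), sigma_px = sigma_px, epsilon = epsilon,
    worm_length_px = worm_length_px,
    max_speed_px_per_s = max_speed_px_per_s, log_level = log_level),
    class = "run_config")
}

log_msg <- function(config, level, fmt, ...) {
  levels <- c(quiet = 0L, info = 1L, debug = 2L)
  if (levels[[config$log_level]] >= levels[[level]]) {
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
  }
}

config_as_list <- function(config) {
  tp <- config$params
  out <- list(
    output = config$output, mode = config$mode,
    input = if (is.null(config$input)) NULL else config$input,
    fps = config$fps,
    window_s = tp$window_s, fade_fraction = tp$fade_fraction,
    gain = tp$gain, offset = tp$offset, colormap = tp$colormap$name,
    colormap_points = apply(cbind(tp$colormap$u, tp$colormap$rgb), 1L,
                            function(r) paste(signif(r, 10), collapse = " ")),
    stride = tp$stride, global_time = tp$global_time,
    normalize = config$normalize,
    target = config$target, vignette = config$vignette,
    sigma_px = config$sigma_px, epsilon = config$epsilon,
    worm_length_px = config$worm_length_px,
    max_speed_px_per_s = config$max_speed_px_per_s,
    log_level = config$log_level)
  if (!is.null(config$scene)) {
    out$scene <- unclass(config$scene)
  }
  out[!vapply(out, is.null, logical(1L))]
}

#' Write the fully resolved parameter sidecar
#'
#' Every effective parameter (including defaults and the simulation seed) is
#' recorded next to the output as `<output>.params.yaml`, so a run can be
#' reproduced bit-identically from its artifacts alone.
#'
#' @param config A `run_config`.
#' @param path Sidecar path; default `<output>.params.yaml`.
#' @return Invisibly, the sidecar path.
#' @export
write_sidecar <- function(config, path = paste0(config$output,
                                                ".params.yaml")) {
  yaml::write_yaml(config_as_list(config), path)
  invisible(path)
}

#' Rebuild a run configuration from a sidecar file
#'
#' @param path Sidecar YAML path (or any YAML file of `run_config` fields).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$scene)) {
    vals$scene <- do.call(sim_scene, vals$scene[names(vals$scene) %in%
                                                  names(formals(sim_scene))])
  }
  vals$colormap_points <- NULL
  do.call(run_config, vals[names(vals) %in% names(formals(run_config))])
}

load_input <- function(config) {
  if (grepl("[*?]", config$input) || length(Sys.glob(config$input)) > 1L) {
    load_image_sequence(config$input, fps = config$fps)
  } else {
    load_video(config$input, fps = config$fps)
  }
}

# Write through a temporary file in the target directory so a failed stage
# never leaves a partial artifact at the output path.
atomic_write <- function(path, writer) {
  tmp <- tempfile(pattern = ".chronotrails_", tmpdir = dirname(path),
                  fileext = paste0(".", tools::file_ext(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  path
}

#' Execute a pipeline run
#'
#' Wires the stages end to end per mode: load (or simulate), brightness
#' normalization, optional vignetting correction, average subtraction,
#' rendering, and lossless output, with a fully resolved parameter sidecar.
#' Stage errors abort with a stage-named message and leave no partial file
#' at the output path.
#'
#' @param config A `run_config`.
#' @return Invisibly, a named list of written artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    log_msg(config, "info", "stage '%s' done in %.2f s", name,
            proc.time()[["elapsed"]] - t0)
    out
  }
  written <- list()

  if (config$mode == "simulate") {
    sim <- stage("simulate", simulate_scene(config$scene))
    written$video <- stage("write", atomic_write(config$output, function(p) {
      write_video(sim$stack, p, fps = sim$stack$fps)
    }))
    truth_path <- paste0(tools::file_path_sans_ext(config$output),
                         "_truth.csv")
    written$truth <- stage("write_truth", atomic_write(truth_path, function(p)
      write_ground_truth(sim$truth, p)))
    written$sidecar <- write_sidecar(config)
    return(invisible(written))
  }

  stack <- stage("load", load_input(config))
  if (!is.null(config$worm_length_px) &&
      !is.null(config$max_speed_px_per_s)) {
    warns <- check_acquisition(stack, config$worm_length_px,
                               config$max_speed_px_per_s)
    for (w in warns) log_msg(config, "info", "acquisition: %s", w)
  }
  pre <- stage("preprocess", preprocess_stack(
    stack, normalize = config$normalize, target = config$target,
    vignette = config$vignette, sigma_px = config$sigma_px,
    epsilon = config$epsilon))
  sub <- pre$subtracted

  if (config$mode == "subtract_only") {
    written$video <- stage("write", atomic_write(config$output, function(p) {
      write_video(sub, p, fps = sub$fps)
    }))
  } else if (config$mode == "still") {
    tf <- stage("render", render_still(sub, config$params))
    written$image <- stage("write", atomic_write(config$output, function(p)
      write_image(tf$image, p)))
  } else {  # video
    tfs <- stage("render", render_video(sub, config$params))
    written$video <- stage("write", atomic_write(config$output, function(p) {
      write_video(lapply(tfs, `[[`, "image"), p, fps = sub$fps)
    }))
  }
  written$sidecar <- write_sidecar(config)
  invisible(written)
}
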