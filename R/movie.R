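# Keyframed movie generation. A stage interpolates one parameter linearly
# over round(duration * fps) frames; rotation stages compose an equal
# per-frame delta rotation (angle / frame_count about a fixed axis) so the
# endpoint matches the closed-form single rotation. Frames are captured from
# the session after each parameter update, so two runs with identical
# inputs produce byte-identical PNG sequences.

#' Define a movie stage
#'
#' @param kind `"zoom"`, `"rotate"`, `"plane_move"` or `"mode_switch"`.
#' @param duration_s stage duration in seconds.
#' @param fps frames per second; `frame_count = round(duration_s * fps)`
#'   must be >= 1.
#' @param from,to start/end values for `zoom` (zoom factors) and
#'   `plane_move` (plane depths, world units). When `from` is `NULL` the
#'   stage starts from the session's current value.
#' @param axis,angle_deg rotation axis and total angle (`rotate` only).
#' @param clip_mode clip mode to switch to (`mode_switch` only; also applied
#'   before `plane_move` stages when given).
#' @return an object of class `vox_stage`.
#' @export
movie_stage <- function(kind = c("zoom", "rotate", "plane_move", "mode_switch"),
                        duration_s = 1, fps = 10, from = NULL, to = NULL,
                        axis = "y", angle_deg = 0, clip_mode = NULL) {
  kind <- match.arg(kind)
  if (!is.finite(duration_s) || duration_s <= 0)
    stop("duration_s must be > 0", call. = FALSE)
  if (!is.finite(fps) || fps <= 0) stop("fps must be > 0", call. = FALSE)
  frame_count <- round(duration_s * fps)
  if (frame_count < 1) stop("round(duration_s * fps) must be >= 1", call. = FALSE)
  structure(list(kind = kind, duration_s = duration_s, fps = fps,
                 frame_count = as.integer(frame_count), from = from, to = to,
                 axis = axis, angle_deg = angle_deg, clip_mode = clip_mode),
            class = "vox_stage")
}

#' Run one movie stage against a session
#'
#' For frame `k = 1..frame_count` the stage parameter is set to its linear
#' interpolation at `t = k / frame_count` (rotations: composition of k
#' per-frame deltas), then a frame is captured.
#'
#' @param session a [vox_session()] with a volume loaded.
#' @param stage a [movie_stage()].
#' @param width,height capture viewport in pixels.
#' @return list of exactly `frame_count` `vox_frame`s.
#' @export
run_stage <- function(session, stage, width = 128, height = 128) {
  stopifnot(inherits(session, "vox_session"), inherits(stage, "vox_stage"))
  if (is.null(session$volume))
    stop("no volume loaded; load one before running stages", call. = FALSE)
  n <- stage$frame_count
  frames <- vector("list", n)
  if (!is.null(stage$clip_mode))
    session$view$clip_mode <- stage$clip_mode
  if (stage$kind == "rotate") {
    delta <- rotation_matrix(stage$axis, stage$angle_deg / n)
    for (k in seq_len(n)) {
      session$view <- compose_rotation(session$view, delta)
      frames[[k]] <- session_capture(session, width, height)
    }
  } else {
    from <- switch(stage$kind,
                   zoom = if (is.null(stage$from)) session$view$zoom else stage$from,
                   plane_move = if (is.null(stage$from)) session$view$plane_depth
                                else stage$from,
                   mode_switch = 0)
    to <- switch(stage$kind, mode_switch = 0,
                 if (is.null(stage$to)) from else stage$to)
    for (k in seq_len(n)) {
      val <- from + (to - from) * k / n
      if (stage$kind == "zoom") session$view$zoom <- val
      if (stage$kind == "plane_move") session$view$plane_depth <- val
      frames[[k]] <- session_capture(session, width, height)
    }
  }
  frames
}

#' The packaged sample movie
#'
#' A replica of the scripted showcase movie, at 10 fps throughout:
#' 1. set documented render parameters and disable UI overlays;
#' 2. reset the view;
#' 3. 1 s zoom-in (10 frames), zoom 1 -> 1.5;
#' 4. 5 s rotation (50 frames), 180 degrees about y;
#' 5. sampling plane to the box edge, front clipping on, then a 2 s plane
#'    move (20 frames) to 10% of the view-axis extent behind the volume
#'    center;
#' 6. a second 5 s 180-degree y-rotation (50 frames) back to the start view,
#'    via per-frame delta-matrix composition;
#' 7. slice mode, 2 s plane fly-out (20 frames) toward the camera.
#'
#' @param session a [vox_session()] with a volume loaded.
#' @param width,height capture viewport in pixels.
#' @param out_dir when given, the PNG sequence is written there (the
#'   directory is removed again if any stage fails).
#' @param fps frames per second (10 as scripted).
#' @return list with `frames` (all frames, in order) and `stage_frames`
#'   (named per-stage frame counts).
#' @export
sample_movie <- function(session, width = 128, height = 128, out_dir = NULL,
                         fps = 10) {
  stopifnot(inherits(session, "vox_session"))
  if (is.null(session$volume)) stop("no volume loaded", call. = FALSE)
  nc <- session$volume$meta$num_channels
  session_set_render_params(session, list(
    channels = lapply(seq_len(nc), function(i)
      list(dark = 0.05, mid = 0.6, bright = 0.85, alpha = 0.9))))
  session_set_ui_params(session, list(plane_grid = FALSE,
                                      coordinate_readout = FALSE))
  session$view <- reset_view(session$volume$meta)

  ext <- 2 * view_axis_half_extent(session$volume$meta, session$view$rotation)
  stages <- list(
    zoom = movie_stage("zoom", 1, fps, from = 1, to = 1.5),
    rotate1 = movie_stage("rotate", 5, fps, axis = "y", angle_deg = 180),
    plane_move = movie_stage("plane_move", 2, fps, from = ext / 2,
                             to = -0.1 * ext, clip_mode = "front"),
    rotate2 = movie_stage("rotate", 5, fps, axis = "y", angle_deg = 180),
    slice_out = movie_stage("plane_move", 2, fps, to = 0.6 * ext,
                            clip_mode = "plane"))
  run_all <- function() {
    out <- list()
    for (nm in names(stages))
      out[[nm]] <- run_stage(session, stages[[nm]], width, height)
    out
  }
  if (is.null(out_dir)) {
    per_stage <- run_all()
  } else {
    per_stage <- tryCatch(run_all(), error = function(e) {
      unlink(out_dir, recursive = TRUE)
      stop(e)
    })
  }
  frames <- do.call(c, unname(per_stage))
  if (!is.null(out_dir)) write_movie(frames, out_dir, fps)
  list(frames = frames,
       stage_frames = vapply(per_stage, length, 1L))
}

#' Write frames as a numbered PNG sequence (optionally MP4)
#'
#' The PNG sequence (`frame_000001.png`, ...) is the bit-exact surface; MP4
#' muxing is best-effort and only attempted when an `ffmpeg` binary is on
#' the PATH.
#'
#' @param frames list of `vox_frame`s with identical dimensions.
#' @param path output directory for the sequence.
#' @param fps frames per second (MP4 only).
#' @param mp4 when `TRUE`, also mux an MP4 next to the sequence.
#' @return `path`, invisibly.
#' @export
write_movie <- function(frames, path, fps = 10, mp4 = FALSE) {
  if (length(frames) < 1) stop("need at least one frame", call. = FALSE)
  dims <- lapply(frames, function(f) dim(f$rgb))
  if (!all(vapply(dims, identical, TRUE, dims[[1]])))
    stop("frame dimensions differ; nothing written", call. = FALSE)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(frames))
    write_frame_png(frames[[k]], file.path(path, sprintf("frame_%06d.png", k)))
  if (mp4) {
    ffmpeg <- Sys.which("ffmpeg")
    if (!nzchar(ffmpeg)) {
      vx_log("warn", "ffmpeg not found; wrote PNG sequence only")
    } else {
      system2(ffmpeg, c("-y", "-loglevel", "error", "-framerate", fps,
                        "-i", file.path(path, "frame_%06d.png"),
                        "-pix_fmt", "yuv420p",
                        file.path(path, "movie.mp4")))
    }
  }
  invisible(path)
}
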