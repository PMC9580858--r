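# Session state: one volume + per-channel transfers + view + render settings.
# The HTTP endpoints, the movie engine and the CLI all drive a session; the
# server simply exposes one over HTTP. All setters validate fully before
# mutating, so an invalid call never changes state.

vox_invalid <- function(field, msg) {
  stop(structure(class = c("vox_invalid", "error", "condition"),
                 list(message = sprintf("invalid field '%s': %s", field, msg),
                      call = NULL, field = field)))
}

vox_conflict <- function(msg) {
  stop(structure(class = c("vox_conflict", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Create a rendering session
#'
#' @param fov_y,camera_distance,near,far camera defaults used for every
#'   capture (see [camera_model()]).
#' @return an environment of class `vox_session`.
#' @export
vox_session <- function(fov_y = 30, camera_distance = 2.5, near = 0.01,
                        far = 10) {
  s <- new.env(parent = emptyenv())
  s$volume <- NULL
  s$transfers <- list()
  s$view <- view_params()
  s$settings <- render_settings()
  s$camera <- list(fov_y = fov_y, camera_distance = camera_distance,
                   near = near, far = far)
  class(s) <- "vox_session"
  s
}

#' Install a volume into a session
#'
#' Resets transfers to per-channel defaults and the view to [reset_view()],
#' matching viewer semantics: a new volume replaces the old one.
#'
#' @param s a [vox_session()].
#' @param vol a `vox_volume`.
#' @return the session, invisibly.
#' @export
session_load_volume <- function(s, vol) {
  stopifnot(inherits(s, "vox_session"), inherits(vol, "vox_volume"))
  s$volume <- vol
  s$transfers <- default_transfers(vol$meta$num_channels)
  s$view <- reset_view(vol$meta)
  invisible(s)
}

session_camera <- function(s, width, height) {
  camera_model(fov_y = s$camera$fov_y, viewport = c(width, height),
               camera_distance = s$camera$camera_distance,
               near = s$camera$near, far = s$camera$far)
}

#' Capture a frame from the current session state
#'
#' @param s a [vox_session()].
#' @param width,height viewport size in pixels.
#' @return a `vox_frame`.
#' @export
session_capture <- function(s, width = 512, height = 512) {
  stopifnot(inherits(s, "vox_session"))
  if (is.null(s$volume)) vox_conflict("no volume loaded")
  render_frame(s$volume, s$transfers, s$view, session_camera(s, width, height),
               s$settings)
}

# --- JSON parameter documents --------------------------------------------

# canonical serialization: every GET and every test round-trip goes through
# this one function, so identical state always yields identical bytes
doc_json <- function(doc) {
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                null = "null"))
}

#' Read the render-parameter document
#'
#' One entry per channel (`dark`, `mid`, `bright`, `alpha`, `color`,
#' `visible`; `mid` is the effective, clamped value) plus global `settings`
#' (`background`, `step_scale`, `early_termination_alpha`).
#'
#' @param s a [vox_session()].
#' @return the document as a list.
#' @export
session_render_params <- function(s) {
  stopifnot(inherits(s, "vox_session"))
  list(channels = lapply(s$transfers, function(tr)
         list(dark = tr$dark, mid = tr$mid, bright = tr$bright,
              alpha = tr$alpha, color = tr$color, visible = tr$visible)),
       settings = list(background = s$settings$background,
                       step_scale = s$settings$step_scale,
                       early_termination_alpha = s$settings$early_termination_alpha))
}

num1 <- function(x, field, lo = -Inf, hi = Inf) {
  x <- suppressWarnings(as.numeric(x))
  if (length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    vox_invalid(field, sprintf("must be a number in [%s, %s]", lo, hi))
  x
}

#' Update render parameters from a (partial) document
#'
#' Absent fields are left unchanged; per-channel entries apply by position
#' (a `NULL` entry skips that channel). Out-of-range values raise a
#' validation error naming the field, and state is only mutated after the
#' whole document validates.
#'
#' @param s a [vox_session()].
#' @param doc a (partial) render-parameter document as a list.
#' @return the session, invisibly.
#' @export
session_set_render_params <- function(s, doc) {
  stopifnot(inherits(s, "vox_session"))
  if (is.null(s$volume)) vox_conflict("no volume loaded; PUT /loadImage first")
  transfers <- s$transfers
  if (!is.null(doc$channels)) {
    if (length(doc$channels) > length(transfers))
      vox_invalid("channels", sprintf("%d entries but volume has %d channels",
                                      length(doc$channels), length(transfers)))
    for (i in seq_along(doc$channels)) {
      ch <- doc$channels[[i]]
      if (is.null(ch)) next
      cur <- transfers[[i]]
      f <- function(name, default) if (is.null(ch[[name]])) default else ch[[name]]
      dark <- num1(f("dark", cur$dark), sprintf("channels[%d].dark", i - 1L), 0, 1)
      bright <- num1(f("bright", cur$bright), sprintf("channels[%d].bright", i - 1L), 0, 1)
      if (dark >= bright)
        vox_invalid(sprintf("channels[%d].dark", i - 1L), "dark must be < bright")
      mid <- num1(f("mid", cur$mid), sprintf("channels[%d].mid", i - 1L), 0, 1)
      alpha <- num1(f("alpha", cur$alpha), sprintf("channels[%d].alpha", i - 1L), 0, 1)
      color <- f("color", cur$color)
      color <- suppressWarnings(as.numeric(unlist(color)))
      if (length(color) != 3L || any(!is.finite(color)) || any(color < 0) ||
          any(color > 1))
        vox_invalid(sprintf("channels[%d].color", i - 1L),
                    "must be an RGB triple in [0, 1]")
      visible <- f("visible", cur$visible)
      if (!is.logical(visible) || length(visible) != 1L || is.na(visible))
        vox_invalid(sprintf("channels[%d].visible", i - 1L), "must be a boolean")
      transfers[[i]] <- channel_transfer(dark, mid, bright, alpha, color, visible)
    }
  }
  settings <- s$settings
  if (!is.null(doc$settings)) {
    st <- doc$settings
    bg <- if (is.null(st$background)) settings$background else
      suppressWarnings(as.numeric(unlist(st$background)))
    if (length(bg) != 3L || any(!is.finite(bg)) || any(bg < 0) || any(bg > 1))
      vox_invalid("settings.background", "must be an RGB triple in [0, 1]")
    ss <- if (is.null(st$step_scale)) settings$step_scale else
      num1(st$step_scale, "settings.step_scale", 1e-6, Inf)
    et <- if (is.null(st$early_termination_alpha))
      settings$early_termination_alpha else
      num1(st$early_termination_alpha, "settings.early_termination_alpha", 1e-12, 1)
    settings <- render_settings(bg, ss, et, settings$overlays)
  }
  s$transfers <- transfers
  s$settings <- settings
  invisible(s)
}

#' Read the view-parameter document
#'
#' `rotation` is the 3x3 world rotation as 9 reals, row-major.
#'
#' @param s a [vox_session()].
#' @return the document as a list.
#' @export
session_view_params <- function(s) {
  stopifnot(inherits(s, "vox_session"))
  v <- s$view
  list(rotation = as.vector(t(v$rotation)), zoom = v$zoom, pan = v$pan,
       plane_depth = v$plane_depth, clip_mode = v$clip_mode)
}

#' Update view parameters from a (partial) document
#'
#' Rotations are validated (orthonormal, det 1 within tolerance) and then
#' re-orthonormalized before storing.
#'
#' @param s a [vox_session()].
#' @param doc a (partial) view-parameter document as a list.
#' @return the session, invisibly.
#' @export
session_set_view_params <- function(s, doc) {
  stopifnot(inherits(s, "vox_session"))
  if (is.null(s$volume)) vox_conflict("no volume loaded; PUT /loadImage first")
  v <- s$view
  rotation <- v$rotation
  if (!is.null(doc$rotation)) {
    m <- suppressWarnings(as.numeric(unlist(doc$rotation)))
    if (length(m) != 9L || any(!is.finite(m)))
      vox_invalid("rotation", "must be 9 reals, row-major")
    m <- t(matrix(m, 3, 3))  # row-major wire order -> R matrix
    rotation <- tryCatch(check_rotation(m),
                         error = function(e) vox_invalid("rotation", conditionMessage(e)))
  }
  zoom <- if (is.null(doc$zoom)) v$zoom else num1(doc$zoom, "zoom", 1e-9, Inf)
  pan <- if (is.null(doc$pan)) v$pan else {
    p <- suppressWarnings(as.numeric(unlist(doc$pan)))
    if (length(p) != 2L || any(!is.finite(p)))
      vox_invalid("pan", "must be 2 reals")
    p
  }
  plane_depth <- if (is.null(doc$plane_depth)) v$plane_depth else
    num1(doc$plane_depth, "plane_depth")
  clip_mode <- if (is.null(doc$clip_mode)) v$clip_mode else {
    cm <- as.character(doc$clip_mode)
    if (!cm %in% c("off", "front", "plane"))
      vox_invalid("clip_mode", "must be one of off, front, plane")
    cm
  }
  s$view <- view_params(rotation, zoom, pan, plane_depth, clip_mode)
  invisible(s)
}

#' Read the UI overlay toggles
#' @param s a [vox_session()].
#' @return list with `plane_grid` and `coordinate_readout`.
#' @export
session_ui_params <- function(s) {
  stopifnot(inherits(s, "vox_session"))
  s$settings$overlays
}

#' Update UI overlay toggles
#'
#' Only `plane_grid` and `coordinate_readout` are recognized; any other
#' field raises a validation error naming it.
#'
#' @param s a [vox_session()].
#' @param doc list of boolean toggles.
#' @return the session, invisibly.
#' @export
session_set_ui_params <- function(s, doc) {
  stopifnot(inherits(s, "vox_session"))
  known <- c("plane_grid", "coordinate_readout")
  extra <- setdiff(names(doc), known)
  if (length(extra)) vox_invalid(extra[1], "unknown uiParams field")
  ov <- s$settings$overlays
  for (k in known) {
    if (is.null(doc[[k]])) next
    if (!is.logical(doc[[k]]) || length(doc[[k]]) != 1L || is.na(doc[[k]]))
      vox_invalid(k, "must be a boolean")
    ov[[k]] <- doc[[k]]
  }
  s$settings$overlays <- ov
  invisible(s)
}
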