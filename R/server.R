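# Local HTTP control API. Endpoints mirror the scripting surface:
#   POST /loadImage      raw channel bytes + JSON metadata header
#   GET/PUT /renderParams, /viewParams   JSON parameter documents
#   PUT /uiParams        overlay toggles
#   GET /captureImage    deterministic PNG of the current state
#   GET /ping            liveness probe; POST /shutdown  orderly stop
#
# The API is deliberately piecemeal: a client that only implements
# /loadImage and /captureImage gets a fully working default rendering.

DTYPE_SIZES <- c(uint8 = 1L, uint16 = 2L, float32 = 4L, float64 = 8L)

json_response <- function(status, body) {
  if (!is.character(body)) body <- doc_json(body)
  list(status = status,
       headers = list("Content-Type" = "application/json"),
       body = body)
}

error_response <- function(status, msg) {
  json_response(status, list(error = msg))
}

decode_payload <- function(bytes, dtype, n) {
  switch(dtype,
    uint8 = as.integer(bytes),
    uint16 = readBin(bytes, "integer", n = n, size = 2L, endian = "little",
                     signed = FALSE),
    float32 = readBin(bytes, "numeric", n = n, size = 4L, endian = "little"),
    float64 = readBin(bytes, "numeric", n = n, size = 8L, endian = "little"))
}

handle_load_image <- function(session, req) {
  meta_json <- req$HTTP_X_VOLUME_META
  if (is.null(meta_json) || !nzchar(meta_json))
    return(error_response(400L, "missing X-Volume-Meta header"))
  meta <- tryCatch(jsonlite::fromJSON(meta_json, simplifyVector = TRUE),
                   error = function(e) NULL)
  if (is.null(meta)) return(error_response(400L, "X-Volume-Meta is not valid JSON"))
  for (f in c("dims", "num_channels", "dtype"))
    if (is.null(meta[[f]]))
      return(error_response(400L, sprintf("metadata field '%s' is required", f)))
  dtype <- as.character(meta$dtype)
  if (!dtype %in% names(DTYPE_SIZES))
    return(error_response(400L, sprintf(
      "unsupported dtype '%s' (supported: %s)", dtype,
      paste(names(DTYPE_SIZES), collapse = ", "))))
  vmeta <- tryCatch(
    volume_metadata(meta$dims, meta$num_channels,
                    if (is.null(meta$physical_voxel_size)) c(1, 1, 1)
                    else meta$physical_voxel_size,
                    meta$channel_names),
    error = function(e) e)
  if (inherits(vmeta, "error"))
    return(error_response(400L, conditionMessage(vmeta)))
  n <- prod(vmeta$dims) * vmeta$num_channels
  expected <- n * DTYPE_SIZES[[dtype]]
  body <- req$rook.input$read()
  if (length(body) != expected)
    return(error_response(400L, sprintf(
      "payload is %d bytes but dims x channels x %s imply %d",
      length(body), dtype, expected)))
  vals <- decode_payload(body, dtype, n)
  # wire order channel-major (x fastest, then y, z, channel) -> (c, z, y, x)
  arr <- aperm(array(vals, dim = c(vmeta$dims, vmeta$num_channels)),
               c(4L, 3L, 2L, 1L))
  vol <- tryCatch(volume_from_array(arr, vmeta), error = function(e) e)
  if (inherits(vol, "error"))
    return(error_response(400L, conditionMessage(vol)))
  session_load_volume(session, vol)
  json_response(200L, list(channels = vmeta$num_channels, dims = vmeta$dims))
}

parse_query <- function(qs) {
  if (is.null(qs) || !nzchar(qs)) return(list())
  qs <- sub("^\\?", "", qs)
  kv <- strsplit(strsplit(qs, "&", fixed = TRUE)[[1]], "=", fixed = TRUE)
  stats::setNames(lapply(kv, function(x) httpuv::decodeURIComponent(x[2])),
                  vapply(kv, `[`, "", 1L))
}

handle_capture <- function(session, req) {
  if (is.null(session$volume))
    return(error_response(409L, "no volume loaded; POST /loadImage first"))
  q <- parse_query(req$QUERY_STRING)
  width <- if (is.null(q$width)) 512L else suppressWarnings(as.integer(q$width))
  height <- if (is.null(q$height)) 512L else suppressWarnings(as.integer(q$height))
  for (v in list(c("width", width), c("height", height))) {
    x <- suppressWarnings(as.integer(v[2]))
    if (is.na(x) || x < 1L || x > 4096L)
      return(error_response(400L, sprintf("%s must be in [1, 4096]", v[1])))
  }
  frame <- session_capture(session, width, height)
  list(status = 200L, headers = list("Content-Type" = "image/png"),
       body = write_frame_png(frame))
}

handle_params <- function(session, req, getter, setter) {
  if (req$REQUEST_METHOD == "GET")
    return(json_response(200L, getter(session)))
  if (req$REQUEST_METHOD != "PUT")
    return(error_response(405L, "use GET or PUT"))
  body <- rawToChar(req$rook.input$read())
  doc <- tryCatch(jsonlite::fromJSON(body, simplifyVector = FALSE),
                  error = function(e) NULL)
  if (is.null(doc)) return(error_response(400L, "request body is not valid JSON"))
  res <- tryCatch({ setter(session, doc); NULL },
                  vox_invalid = function(e) error_response(400L, conditionMessage(e)),
                  vox_conflict = function(e) error_response(409L, conditionMessage(e)))
  if (!is.null(res)) return(res)
  json_response(200L, getter(session))
}

route_request <- function(session, req, state) {
  path <- req$PATH_INFO
  method <- req$REQUEST_METHOD
  key <- paste(method, path)
  switch(key,
    "POST /loadImage" = handle_load_image(session, req),
    "GET /renderParams" = ,
    "PUT /renderParams" = handle_params(session, req, session_render_params,
                                        session_set_render_params),
    "GET /viewParams" = ,
    "PUT /viewParams" = handle_params(session, req, session_view_params,
                                      session_set_view_params),
    "GET /uiParams" = ,
    "PUT /uiParams" = handle_params(session, req, session_ui_params,
                                    session_set_ui_params),
    "GET /captureImage" = handle_capture(session, req),
    "GET /ping" = json_response(200L, list(status = "ok")),
    "POST /shutdown" = { state$stop <- TRUE; json_response(200L, list(status = "bye")) },
    error_response(404L, sprintf("no such endpoint: %s %s", method, path)))
}

#' Serve the control API over local HTTP
#'
#' Binds a localhost-only HTTP server exposing the session state. Blocks
#' until `POST /shutdown` (or interrupt) unless `blocking = FALSE`, in which
#' case the started server object is returned and the caller drives the
#' event loop with `httpuv::service()`.
#'
#' @param port TCP port (default 8307).
#' @param host bind address; localhost by default.
#' @param session a [vox_session()]; a fresh one by default.
#' @param blocking run the event loop until shutdown.
#' @param quiet suppress per-request logs.
#' @return invisibly, the session (blocking) or the httpuv server object.
#' @export
vx_serve <- function(port = 8307, host = "127.0.0.1", session = vox_session(),
                     blocking = TRUE, quiet = FALSE) {
  state <- new.env(parent = emptyenv())
  state$stop <- FALSE
  app <- list(call = function(req) {
    t0 <- proc.time()[["elapsed"]]
    resp <- tryCatch(route_request(session, req, state),
                     error = function(e) error_response(500L, conditionMessage(e)))
    if (!quiet)
      vx_log("info", "%s %s -> %d (%.1f ms)", req$REQUEST_METHOD,
             req$PATH_INFO, resp$status,
             (proc.time()[["elapsed"]] - t0) * 1000)
    resp
  })
  srv <- tryCatch(httpuv::startServer(host, port, app),
                  error = function(e)
                    stop(sprintf("cannot bind %s:%d (port busy?): %s",
                                 host, port, conditionMessage(e)),
                         call. = FALSE))
  vx_log("info", "serving on http://%s:%d", host, port)
  if (!blocking) return(invisible(srv))
  on.exit(httpuv::stopServer(srv))
  while (!state$stop) httpuv::service(250)
  httpuv::service(50)  # flush the shutdown response
  vx_log("info", "server stopped")
  invisible(session)
}
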