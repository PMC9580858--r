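# Thin HTTP scripting client. No rendering logic lives here: every method
# is a pass-through to the server endpoints, with payload encoding. The
# client can auto-start a local server subprocess when none is listening,
# mirroring the "viewer pops up when you show an image" workflow.

client_request <- function(base, method, path, body = NULL, headers = NULL) {
  h <- curl::new_handle()
  curl::handle_setopt(h, customrequest = method)
  if (!is.null(body)) {
    if (is.character(body)) body <- charToRaw(body)
    curl::handle_setopt(h, postfields = body, postfieldsize = length(body))
  }
  if (!is.null(headers)) curl::handle_setheaders(h, .list = headers)
  resp <- curl::curl_fetch_memory(paste0(base, path), handle = h)
  resp
}

client_json <- function(resp) {
  txt <- rawToChar(resp$content)
  if (resp$status_code >= 400)
    stop(sprintf("server returned %d: %s", resp$status_code, txt),
         call. = FALSE)
  jsonlite::fromJSON(txt, simplifyVector = FALSE)
}

server_alive <- function(base) {
  ok <- tryCatch(client_request(base, "GET", "/ping")$status_code == 200,
                 error = function(e) FALSE)
  isTRUE(ok)
}

#' Connect to (or start) a local rendering server
#'
#' Returns a client whose methods mirror the HTTP endpoints:
#' * `show(x, physical_voxel_size, channel_names)` — send a 3-D or 4-D array
#'   (dims x, y, z\[, channel\]); float arrays are quantized server-side.
#' * `get_render_params()` / `set_render_params(doc)` — `/renderParams`.
#' * `get_view_params()` / `set_view_params(doc)` — `/viewParams`.
#' * `set_ui_params(doc)` — `/uiParams` overlay toggles.
#' * `capture(width, height, path = NULL)` — PNG bytes (or write to `path`).
#' * `stop_server()` — orderly shutdown of an auto-started server.
#'
#' @param port server port (default 8307).
#' @param host server host.
#' @param auto_start when no server answers, start one in a background R
#'   process and wait for it.
#' @param startup_timeout seconds to wait for an auto-started server.
#' @return a list of client functions.
#' @export
vox_client <- function(port = 8307, host = "127.0.0.1", auto_start = TRUE,
                       startup_timeout = 30) {
  base <- sprintf("http://%s:%d", host, port)
  proc <- NULL
  if (!server_alive(base)) {
    if (!auto_start)
      stop(sprintf(paste0("no server is listening on %s; start one with ",
                          "voxcast::vx_serve(port = %d) or use ",
                          "vox_client(auto_start = TRUE)"), base, port),
           call. = FALSE)
    proc <- callr::r_bg(function(port, host)
      voxcast::vx_serve(port = port, host = host, quiet = TRUE),
      args = list(port = port, host = host), supervise = TRUE)
    deadline <- Sys.time() + startup_timeout
    while (!server_alive(base)) {
      if (!proc$is_alive() || Sys.time() > deadline) {
        err <- tryCatch(proc$read_all_error(), error = function(e) "")
        stop("failed to start a local server on ", base,
             if (nzchar(err)) paste0(": ", err), call. = FALSE)
      }
      Sys.sleep(0.1)
    }
  }

  show <- function(x, physical_voxel_size = c(1, 1, 1), channel_names = NULL) {
    d <- dim(x)
    if (is.null(d) || !length(d) %in% c(3L, 4L))
      stop("x must be a 3-D or 4-D array (x, y, z[, channel])", call. = FALSE)
    if (length(d) == 3L) d <- c(d, 1L)
    dim(x) <- d
    is_codes <- is.integer(x) && !anyNA(x) && min(x) >= 0L && max(x) <= 255L
    dtype <- if (is_codes) "uint8" else "float64"
    body <- if (is_codes) as.raw(as.vector(x)) else
      writeBin(as.numeric(as.vector(x)), raw(), size = 8L, endian = "little")
    meta <- list(dims = d[1:3], num_channels = d[4], dtype = dtype,
                 physical_voxel_size = physical_voxel_size,
                 channel_names = channel_names)
    hdr <- list("X-Volume-Meta" = doc_json(meta),
                "Content-Type" = "application/octet-stream")
    client_json(client_request(base, "POST", "/loadImage", body, hdr))
  }

  get_doc <- function(path) function()
    client_json(client_request(base, "GET", path))
  put_doc <- function(path) function(doc)
    client_json(client_request(base, "PUT", path, doc_json(doc),
                               list("Content-Type" = "application/json")))

  capture <- function(width = 512, height = 512, path = NULL) {
    resp <- client_request(base, "GET",
                           sprintf("/captureImage?width=%d&height=%d",
                                   as.integer(width), as.integer(height)))
    if (resp$status_code >= 400)
      stop(sprintf("server returned %d: %s", resp$status_code,
                   rawToChar(resp$content)), call. = FALSE)
    if (is.null(path)) return(resp$content)
    writeBin(resp$content, path)
    invisible(path)
  }

  stop_server <- function() {
    tryCatch(client_request(base, "POST", "/shutdown"), error = function(e) NULL)
    if (!is.null(proc)) {
      deadline <- Sys.time() + 5
      while (proc$is_alive() && Sys.time() < deadline) Sys.sleep(0.05)
      if (proc$is_alive()) proc$kill()
    }
    invisible(NULL)
  }

  list(base_url = base, process = proc, show = show,
       get_render_params = get_doc("/renderParams"),
       set_render_params = put_doc("/renderParams"),
       get_view_params = get_doc("/viewParams"),
       set_view_params = put_doc("/viewParams"),
       get_ui_params = get_doc("/uiParams"),
       set_ui_params = put_doc("/uiParams"),
       capture = capture, stop_server = stop_server)
}
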