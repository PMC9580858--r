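# Launch a control-API server in a background R process (the client and
# server cannot share one R event loop). The child inherits .libPaths() via
# callr, so it finds the same installed package under test.

start_test_server <- function(port = httpuv::randomPort()) {
  proc <- callr::r_bg(function(port)
    voxcast::vx_serve(port = port, quiet = TRUE),
    args = list(port = port), supervise = TRUE)
  base <- sprintf("http://127.0.0.1:%d", port)
  deadline <- Sys.time() + 30
  repeat {
    ok <- tryCatch(
      curl::curl_fetch_memory(paste0(base, "/ping"))$status_code == 200,
      error = function(e) FALSE)
    if (isTRUE(ok)) break
    if (!proc$is_alive() || Sys.time() > deadline)
      stop("test server failed to start: ",
           tryCatch(proc$read_all_error(), error = function(e) ""))
    Sys.sleep(0.1)
  }
  list(port = port, base = base, proc = proc,
       stop = function() {
         tryCatch(curl::curl_fetch_memory(paste0(base, "/shutdown"),
                  handle = curl::new_handle(customrequest = "POST")),
                  error = function(e) NULL)
         deadline <- Sys.time() + 5
         while (proc$is_alive() && Sys.time() < deadline) Sys.sleep(0.05)
         if (proc$is_alive()) proc$kill()
       })
}

http_get <- function(base, path) {
  curl::curl_fetch_memory(paste0(base, path))
}

http_send <- function(base, method, path, body, headers = NULL) {
  h <- curl::new_handle(customrequest = method)
  if (is.character(body)) body <- charToRaw(body)
  curl::handle_setopt(h, postfields = body, postfieldsize = length(body))
  if (!is.null(headers)) curl::handle_setheaders(h, .list = headers)
  curl::curl_fetch_memory(paste0(base, path), handle = h)
}

json_of <- function(resp) jsonlite::fromJSON(rawToChar(resp$content),
                                             simplifyVector = FALSE)
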