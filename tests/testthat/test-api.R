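# One server subprocess serves this whole file; tests are ordered so that
# pre-load conflict behavior is exercised before a volume is installed.

srv <- start_test_server()
withr::defer(srv$stop(), teardown_env())

meta_hdr <- function(dims, nc, dtype, pvs = c(1, 1, 1)) {
  list("X-Volume-Meta" = jsonlite::toJSON(
    list(dims = dims, num_channels = nc, dtype = dtype,
         physical_voxel_size = pvs), auto_unbox = TRUE, digits = NA),
    "Content-Type" = "application/octet-stream")
}

test_that("parameter writes and captures 409 before any volume is loaded", {
  r <- http_send(srv$base, "PUT", "/renderParams", '{"settings":{}}')
  expect_equal(r$status_code, 409L)
  r <- http_send(srv$base, "PUT", "/viewParams", '{"zoom": 2}')
  expect_equal(r$status_code, 409L)
  r <- http_get(srv$base, "/captureImage?width=32&height=32")
  expect_equal(r$status_code, 409L)
})

test_that("loadImage validates payloads atomically", {
  # truncated body: 400, session still has no volume
  r <- http_send(srv$base, "POST", "/loadImage", raw(10),
                 meta_hdr(c(4, 4, 4), 1, "uint8"))
  expect_equal(r$status_code, 400L)
  expect_match(json_of(r)$error, "64")
  expect_equal(http_get(srv$base, "/captureImage")$status_code, 409L)

  # unsupported dtype
  r <- http_send(srv$base, "POST", "/loadImage", raw(64),
                 meta_hdr(c(4, 4, 4), 1, "int32"))
  expect_equal(r$status_code, 400L)
  expect_match(json_of(r)$error, "dtype")

  # valid 2-channel 8^3 uint8 payload: 200 + echo
  set.seed(501)
  codes <- as.raw(sample(0:255, 1024, replace = TRUE))
  r <- http_send(srv$base, "POST", "/loadImage", codes,
                 meta_hdr(c(8, 8, 8), 2, "uint8"))
  expect_equal(r$status_code, 200L)
  echo <- json_of(r)
  expect_equal(echo$channels, 2L)
  expect_equal(unlist(echo$dims), c(8L, 8L, 8L))
})

test_that("renderParams round-trips with clamping of the effective mid", {
  g0 <- http_get(srv$base, "/renderParams")
  expect_equal(g0$status_code, 200L)
  doc <- json_of(g0)
  expect_length(doc$channels, 2)
  expect_equal(doc$channels[[1]]$mid, 0.5)
  expect_equal(unlist(doc$channels[[2]]$color), c(0, 1, 0))

  # PUT a partial document: only channel 0's mid; 0.9 clamps to 0.75
  r <- http_send(srv$base, "PUT", "/renderParams",
                 '{"channels": [{"mid": 0.9}]}')
  expect_equal(r$status_code, 200L)
  doc <- json_of(r)
  expect_equal(doc$channels[[1]]$mid, 0.75)
  expect_equal(doc$channels[[2]]$mid, 0.5)   # untouched
  expect_equal(doc$channels[[1]]$dark, 0)    # untouched

  # out-of-range value: 400 naming the field, state unchanged
  r <- http_send(srv$base, "PUT", "/renderParams",
                 '{"channels": [{"alpha": 1.5}]}')
  expect_equal(r$status_code, 400L)
  expect_match(json_of(r)$error, "alpha")
  expect_equal(json_of(http_get(srv$base, "/renderParams"))$channels[[1]]$alpha, 1)

  # set -> get -> set -> get is byte-identical
  put1 <- http_send(srv$base, "PUT", "/renderParams",
                    '{"channels":[{"dark":0.1,"mid":0.6,"bright":0.8,"alpha":0.7}],"settings":{"background":[0.1,0.2,0.3]}}')
  txt1 <- rawToChar(put1$content)
  put2 <- http_send(srv$base, "PUT", "/renderParams", txt1)
  expect_identical(rawToChar(put2$content), txt1)
  expect_identical(rawToChar(http_get(srv$base, "/renderParams")$content), txt1)
})

test_that("viewParams round-trips, orthonormalizes and validates rotations", {
  # two 180-degree y-rotation PUTs -> identity within 1e-9
  ry <- rotation_matrix("y", 180)
  put_rot <- function(R) http_send(srv$base, "PUT", "/viewParams",
    jsonlite::toJSON(list(rotation = as.vector(t(R))), digits = NA))
  expect_equal(put_rot(ry)$status_code, 200L)
  got <- json_of(http_get(srv$base, "/viewParams"))
  R1 <- t(matrix(unlist(got$rotation), 3, 3))
  expect_equal(put_rot(ry %*% R1)$status_code, 200L)
  got <- json_of(http_get(srv$base, "/viewParams"))
  expect_lt(max(abs(t(matrix(unlist(got$rotation), 3, 3)) - diag(3))), 1e-9)

  # clip mode echo
  r <- http_send(srv$base, "PUT", "/viewParams", '{"clip_mode": "plane"}')
  expect_equal(json_of(r)$clip_mode, "plane")

  # non-rotation matrix -> 400
  r <- http_send(srv$base, "PUT", "/viewParams",
                 '{"rotation": [2,0,0, 0,2,0, 0,0,2]}')
  expect_equal(r$status_code, 400L)
  expect_match(json_of(r)$error, "rotation")

  # restore defaults for the capture tests
  http_send(srv$base, "PUT", "/viewParams",
            '{"rotation":[1,0,0,0,1,0,0,0,1],"zoom":1,"pan":[0,0],"clip_mode":"off"}')
})

test_that("captureImage is deterministic and honors the session state", {
  c1 <- http_get(srv$base, "/captureImage?width=40&height=30")
  expect_equal(c1$status_code, 200L)
  expect_match(curl::parse_headers_list(c1$headers)[["content-type"]], "image/png")
  c2 <- http_get(srv$base, "/captureImage?width=40&height=30")
  expect_identical(c1$content, c2$content)
  img <- png::readPNG(c1$content)
  expect_equal(dim(img), c(30, 40, 3))
  expect_equal(http_get(srv$base, "/captureImage?width=0&height=10")$status_code,
               400L)
})

test_that("uiParams toggles overlays and rejects unknown fields", {
  r <- http_send(srv$base, "PUT", "/uiParams", '{"sparkles": true}')
  expect_equal(r$status_code, 400L)
  expect_match(json_of(r)$error, "sparkles")

  # defaults: overlays on
  doc <- json_of(http_get(srv$base, "/uiParams"))
  expect_true(doc$plane_grid)
  expect_true(doc$coordinate_readout)

  # overlays only draw with an active plane; enable front clipping
  http_send(srv$base, "PUT", "/viewParams",
            '{"clip_mode": "front", "plane_depth": 0}')
  on1 <- http_get(srv$base, "/captureImage?width=48&height=48")$content
  off <- http_send(srv$base, "PUT", "/uiParams",
                   '{"plane_grid": false, "coordinate_readout": false}')
  expect_equal(off$status_code, 200L)
  off1 <- http_get(srv$base, "/captureImage?width=48&height=48")$content
  off2 <- http_get(srv$base, "/captureImage?width=48&height=48")$content
  expect_false(identical(on1, off1))
  expect_identical(off1, off2)
  # idempotent PUT
  off3 <- http_send(srv$base, "PUT", "/uiParams", '{"plane_grid": false}')
  expect_equal(off3$status_code, 200L)
  expect_identical(off1, http_get(srv$base, "/captureImage?width=48&height=48")$content)
  http_send(srv$base, "PUT", "/viewParams", '{"clip_mode": "off"}')
})

test_that("float payloads are quantized exactly like the library call", {
  set.seed(502)
  dims <- c(6, 5, 4); nc <- 2
  vals <- runif(prod(dims) * nc) * 100 - 20
  body <- writeBin(vals, raw(), size = 8, endian = "little")
  r <- http_send(srv$base, "POST", "/loadImage", body,
                 meta_hdr(dims, nc, "float64"))
  expect_equal(r$status_code, 200L)
  # loadImage resets transfers and view but not global settings; pin the
  # background so the local route below sees identical state
  http_send(srv$base, "PUT", "/renderParams",
            '{"settings": {"background": [0, 0, 0]}}')
  server_png <- http_get(srv$base, "/captureImage?width=32&height=32")$content

  # local route: same array through quantize_volume + render_frame
  arr <- aperm(array(vals, dim = c(dims, nc)), c(4, 3, 2, 1))
  vol <- quantize_volume(arr, volume_metadata(dims, nc))
  s <- vox_session()
  session_load_volume(s, vol)
  local_png <- write_frame_png(session_capture(s, 32, 32))
  expect_identical(server_png, local_png)
})

test_that("the minimal piecemeal client works: loadImage then captureImage", {
  srv2 <- start_test_server()
  withr::defer(srv2$stop())
  vol <- make_synthetic_volume("blobs", dims = c(8, 8, 8), num_channels = 1,
                               seed = 4)
  body <- as.raw(as.vector(aperm(vol$codes, c(4, 3, 2, 1))))
  r <- http_send(srv2$base, "POST", "/loadImage", body,
                 meta_hdr(c(8, 8, 8), 1, "uint8"))
  expect_equal(r$status_code, 200L)
  cap <- http_get(srv2$base, "/captureImage?width=24&height=24")
  expect_equal(cap$status_code, 200L)
  img <- png::readPNG(cap$content)
  expect_equal(dim(img), c(24, 24, 3))
  expect_gt(max(img), 0)  # defaults render actual content
})

test_that("the R client mirrors the endpoints", {
  cl <- vox_client(port = srv$port, auto_start = FALSE)
  set.seed(503)
  x <- array(runif(8 * 8 * 8 * 2), dim = c(8, 8, 8, 2))
  echo <- cl$show(x, physical_voxel_size = c(1, 1, 2))
  expect_equal(echo$channels, 2L)
  cl$set_render_params(list(settings = list(background = c(0, 0, 0))))
  doc <- cl$get_render_params()
  expect_length(doc$channels, 2)
  cl$set_view_params(list(zoom = 1.5))
  expect_equal(cl$get_view_params()$zoom, 1.5)
  png_bytes <- cl$capture(20, 26)
  expect_equal(dim(png::readPNG(png_bytes)), c(26, 20, 3))

  # server-side codes match local quantization of the same float array
  arr <- aperm(x, c(4, 3, 2, 1))
  vol <- quantize_volume(arr, volume_metadata(c(8, 8, 8), 2, c(1, 1, 2)))
  s <- vox_session()
  session_load_volume(s, vol)
  s$view$zoom <- 1.5
  expect_identical(cl$capture(20, 26), write_frame_png(session_capture(s, 20, 26)))
})

test_that("a refused connection gives a startup hint when auto_start is off", {
  dead_port <- httpuv::randomPort()
  expect_error(vox_client(port = dead_port, auto_start = FALSE), "vx_serve")
})
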