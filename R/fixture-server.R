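# Local HTTP test server with range support, so the remote loading strategy
# is testable fully offline.  The server is a small Python script shipped in
# inst/http; it binds an ephemeral loopback port and reports it through a
# ready file.

#' Start a local range-capable HTTP server for a directory
#'
#' @param dir directory to serve.
#' @param ranges if `FALSE`, the server ignores `Range` headers and always
#'   sends full bodies (to exercise the capability-error path).
#' @param timeout_s how long to wait for the server to come up.
#' @return a handle with `$url(file)`, `$port` and `$stop()`.
#' @export
start_fixture_server <- function(dir, ranges = TRUE, timeout_s = 10) {
  script <- system.file("http", "range_server.py", package = "edflazy")
  stopifnot(nzchar(script), dir.exists(dir))
  ready <- tempfile("edflazy-server-")
  env <- if (ranges) character(0) else "NO_RANGES=1"
  system2("python", c(shQuote(script), shQuote(normalizePath(dir)), shQuote(ready)),
          wait = FALSE, env = env, stdout = FALSE, stderr = FALSE)
  deadline <- Sys.time() + timeout_s
  while (!file.exists(ready) || file.size(ready) == 0) {
    if (Sys.time() > deadline) {
      edf_error("edf_server_error", "fixture server failed to start")
    }
    Sys.sleep(0.05)
  }
  info <- scan(ready, what = integer(), quiet = TRUE)
  pid <- info[1]; port <- info[2]
  unlink(ready)
  handle <- list(
    port = port,
    url = function(file) sprintf("http://127.0.0.1:%d/%s", port, file),
    stop = function() {
      tools::pskill(pid)
      invisible(TRUE)
    }
  )
  class(handle) <- "edflazy_fixture_server"
  handle
}
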