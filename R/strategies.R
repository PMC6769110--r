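# Pluggable loading strategies: byte-range reads against some backing source.
#
# A strategy is a list with
#   read(offset, length) -> raw vector of exactly `length` bytes
#   size()               -> total byte count of the source
# read() is pure with respect to the file content and satisfies the
# concatenation property read(o,a) + read(o+a,b) == read(o,a+b).
# Offsets are 0-based (byte positions as in the format description).

new_loading_strategy <- function(read, size, description) {
  structure(list(read = read, size = size, description = description),
            class = "edf_loading_strategy")
}

#' @export
print.edf_loading_strategy <- function(x, ...) {
  cat("<loading strategy:", x$description, ">\n")
  invisible(x)
}

#' Read bytes through a loading strategy
#'
#' @param strategy an `edf_loading_strategy`.
#' @param offset 0-based byte offset.
#' @param length number of bytes.
#' @return raw vector of exactly `length` bytes.
#' @export
read_bytes <- function(strategy, offset, length) {
  stopifnot(inherits(strategy, "edf_loading_strategy"),
            offset >= 0, length >= 0)
  if (length == 0) return(raw(0))
  out <- strategy$read(offset, length)
  if (length(out) != length) {
    edf_error("edf_short_read_error",
              sprintf("strategy returned %d bytes for a %d byte read at offset %.0f",
                      length(out), length, offset))
  }
  out
}

#' Local-file loading strategy
#'
#' Reads byte slices of a file on disk via seek + read.
#'
#' @param path path to an existing file.
#' @return an `edf_loading_strategy`.
#' @export
local_file_strategy <- function(path) {
  if (!file.exists(path)) {
    edf_error("edf_missing_file_error", sprintf("no such file: %s", path))
  }
  path <- normalizePath(path)
  new_loading_strategy(
    read = function(offset, length) {
      con <- file(path, "rb")
      on.exit(close(con))
      seek(con, where = offset, origin = "start")
      readBin(con, "raw", n = length)
    },
    size = function() file.size(path),
    description = paste0("local:", path)
  )
}

parse_content_range_total <- function(hdrs) {
  cr <- hdrs[tolower(names(hdrs)) == "content-range"]
  if (length(cr) == 0) return(NA_real_)
  m <- regmatches(cr[[1]], regexec("bytes [0-9]+-[0-9]+/([0-9]+)", cr[[1]]))[[1]]
  if (length(m) == 2L) as.numeric(m[2]) else NA_real_
}

#' HTTP range-request loading strategy
#'
#' Issues one single-range request (`Range: bytes=o-(o+l-1)`) per read and
#' verifies the server answered with partial content of the requested length.
#' A server that ignores the range header and replies with the full body is
#' detected and reported, never silently buffered.
#'
#' @param url URL of the remote file on a range-capable server.
#' @return an `edf_loading_strategy`.
#' @export
http_range_strategy <- function(url) {
  total <- NA_real_
  fetch_range <- function(offset, length) {
    h <- curl::new_handle()
    curl::handle_setheaders(h, Range = sprintf("bytes=%.0f-%.0f",
                                               offset, offset + length - 1))
    res <- curl::curl_fetch_memory(url, h)
    if (res$status_code == 200L) {
      edf_error("edf_http_range_unsupported_error",
                sprintf("server at %s ignored the Range header (status 200, full body)",
                        url))
    }
    if (res$status_code != 206L) {
      edf_error("edf_http_error",
                sprintf("range request failed with status %d for %s",
                        res$status_code, url))
    }
    hdrs <- curl::parse_headers_list(res$headers)
    t <- parse_content_range_total(hdrs)
    if (!is.na(t)) total <<- t
    res$content
  }
  new_loading_strategy(
    read = function(offset, length) {
      out <- fetch_range(offset, length)
      if (length(out) != length) {
        edf_error("edf_short_read_error",
                  sprintf("server returned %d bytes for a %d byte range request",
                          length(out), length))
      }
      out
    },
    size = function() {
      if (is.na(total)) fetch_range(0, 1)  # Content-Range carries the total
      if (is.na(total)) {
        edf_error("edf_http_error",
                  sprintf("server at %s did not report a Content-Range total", url))
      }
      total
    },
    description = paste0("http:", url)
  )
}

#' In-memory loading strategy (useful for tests and small files)
#' @param bytes a raw vector.
#' @return an `edf_loading_strategy`.
#' @export
memory_strategy <- function(bytes) {
  stopifnot(is.raw(bytes))
  new_loading_strategy(
    read = function(offset, length) {
      if (offset + length > length(bytes)) {
        edf_error("edf_short_read_error", "read past end of buffer")
      }
      bytes[(offset + 1):(offset + length)]
    },
    size = function() length(bytes),
    description = sprintf("memory:%d bytes", length(bytes))
  )
}

#' Wrap a strategy, counting reads (instrumentation for cache/laziness tests)
#'
#' @param strategy an `edf_loading_strategy`.
#' @return an `edf_loading_strategy` with extra fields `n_reads()`,
#'   `bytes_read()` and `reset()`.
#' @export
counting_strategy <- function(strategy) {
  n <- 0L
  bytes <- 0
  log <- list()
  s <- new_loading_strategy(
    read = function(offset, length) {
      n <<- n + 1L
      bytes <<- bytes + length
      log[[length(log) + 1L]] <<- c(offset = offset, length = length)
      strategy$read(offset, length)
    },
    size = strategy$size,
    description = paste0("counting:", strategy$description)
  )
  s$n_reads <- function() n
  s$bytes_read <- function() bytes
  s$read_log <- function() log
  s$reset <- function() { n <<- 0L; bytes <<- 0; log <<- list() }
  s
}

#' Resolve a path or URL to a loading strategy
#' @param input local path or `http(s)://` URL.
#' @export
resolve_strategy <- function(input) {
  if (grepl("^https?://", input)) http_range_strategy(input) else local_file_strategy(input)
}
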