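# Header pseudonymization.
#
# Before a recording leaves the local machine its identifying header text is
# replaced with a generated pseudonym; the original <-> pseudonym mapping
# lives in a persistent key-value store that can be exported and
# re-imported.  Only the header changes -- all signal bytes are untouched.

.pseudonym_alphabet <- strsplit("ABCDEFGHJKMNPQRSTUVWXYZ23456789", "")[[1]]
.pseudonym_length <- 12L

#' Open (or create) a persistent pseudonym store
#'
#' The store is an injective mapping from original patient identification
#' text to generated pseudonyms, persisted as a CSV key-value file so it
#' survives process restarts.  Pseudonyms are 12-character strings over an
#' unambiguous uppercase+digit alphabet.
#'
#' @param path CSV backing file; created on first write.  `NULL` keeps the
#'   store in memory only.
#' @param seed optional RNG seed making pseudonym generation reproducible;
#'   the store keeps its own RNG stream and never disturbs the caller's.
#' @return an `edf_pseudonym_store` (mutable handle).
#' @export
pseudonym_store <- function(path = NULL, seed = NULL) {
  store <- new.env(parent = emptyenv())
  store$path <- path
  store$map <- character(0)        # named: original -> pseudonym
  store$created <- character(0)
  if (!is.null(path) && file.exists(path)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
    if (!all(c("original", "pseudonym") %in% names(df))) {
      edf_error("edf_store_error", "malformed pseudonym store file")
    }
    store$map <- stats::setNames(df$pseudonym, df$original)
    store$created <- if ("created_at" %in% names(df)) df$created_at else
      rep("", nrow(df))
  }
  withr::with_preserve_seed({
    set.seed(if (is.null(seed)) sample.int(.Machine$integer.max, 1) else seed)
    store$rng_state <- get(".Random.seed", globalenv())
  })
  class(store) <- "edf_pseudonym_store"
  store
}

#' @export
print.edf_pseudonym_store <- function(x, ...) {
  cat(sprintf("<pseudonym store: %d entr%s%s>\n", length(x$map),
              if (length(x$map) == 1) "y" else "ies",
              if (is.null(x$path)) ", in-memory" else paste0(", ", x$path)))
  invisible(x)
}

store_save <- function(store) {
  if (is.null(store$path)) return(invisible(store))
  export_mapping(store, store$path)
  invisible(store)
}

with_store_rng <- function(store, expr) {
  withr::with_preserve_seed({
    assign(".Random.seed", store$rng_state, globalenv())
    out <- expr
    store$rng_state <- get(".Random.seed", globalenv())
    out
  })
}

#' Look up or generate the pseudonym for an original identifier
#'
#' The same original always yields the same pseudonym within one store.
#' Generation retries on (unlikely) collisions a bounded number of times.
#'
#' @param store an `edf_pseudonym_store`.
#' @param original original identification text.
#' @export
get_pseudonym <- function(store, original) {
  original <- as.character(original)
  hit <- store$map[original]
  if (!is.na(hit)) return(unname(hit))
  p <- with_store_rng(store, {
    for (i in 1:100) {
      cand <- paste(sample(.pseudonym_alphabet, .pseudonym_length, replace = TRUE),
                    collapse = "")
      if (!cand %in% store$map) break
      cand <- NA_character_
    }
    cand
  })
  if (is.na(p)) {
    edf_error("edf_pseudonym_collision_error",
              "could not generate a collision-free pseudonym")
  }
  store$map[original] <- p
  store$created[length(store$map)] <- format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                             tz = "UTC")
  store_save(store)
  p
}

#' Pseudonymize a recording header
#'
#' Replaces the whole patient identification field by the stored pseudonym
#' (generating one on first sight) and, by default, scrubs free text from
#' the recording identification field.  All other fields keep their exact
#' byte representation.
#'
#' @param rec an `edf_recording_header`.
#' @param store an `edf_pseudonym_store`.
#' @param scrub_recording also blank the recording identification field.
#' @return a modified copy of `rec`.
#' @export
pseudonymize <- function(rec, store, scrub_recording = TRUE) {
  out <- edf_set_field(rec, "patient_id", get_pseudonym(store, rec$patient_id))
  if (scrub_recording) out <- edf_set_field(out, "recording_id", "")
  out
}

#' Pseudonymize an EDF file
#'
#' Copies `input` to `output`, rewriting only the header: the patient field
#' (and optionally the recording field).  Every other byte -- including all
#' signal data -- is copied verbatim.  With `enabled = FALSE` the copy is
#' byte-identical (the default protection can be switched off, giving the
#' sender full control).
#'
#' @param input,output EDF file paths.
#' @param store an `edf_pseudonym_store`.
#' @param enabled if `FALSE`, plain byte copy.
#' @param scrub_recording also blank the recording identification field.
#' @return `output`, invisibly.
#' @export
pseudonymize_file <- function(input, output, store, enabled = TRUE,
                              scrub_recording = TRUE) {
  if (!enabled) {
    file.copy(input, output, overwrite = TRUE)
    return(invisible(output))
  }
  x <- open_edf(input)
  rec2 <- pseudonymize(x$rec, store, scrub_recording = scrub_recording)
  hdr <- write_headers(rec2, x$sigs)
  n <- file.size(input)
  src <- file(input, "rb"); on.exit(close(src), add = TRUE)
  dst <- file(output, "wb"); on.exit(close(dst), add = TRUE)
  writeBin(hdr, dst)
  seek(src, where = length(hdr), origin = "start")
  left <- n - length(hdr)
  while (left > 0) {
    chunk <- readBin(src, "raw", n = min(left, 8388608))
    writeBin(chunk, dst)
    left <- left - length(chunk)
  }
  invisible(output)
}

#' Export the pseudonym mapping
#'
#' Written as a two-column-plus-timestamp table (`original`, `pseudonym`,
#' `created_at`) in CSV.  The same layout is accepted by
#' [import_mapping()], e.g. to re-pseudonymize remotely stored files.
#'
#' @param store an `edf_pseudonym_store`.
#' @param path output file.
#' @export
export_mapping <- function(store, path) {
  df <- data.frame(original = if (is.null(names(store$map))) character(0) else
                     names(store$map),
                   pseudonym = unname(store$map),
                   created_at = store$created[seq_along(store$map)],
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Import a pseudonym mapping, merging into a store
#'
#' Merges the file's pairs into `store` (a fresh in-memory store by
#' default).  A pair contradicting an existing entry -- same original with
#' a different pseudonym, or the reverse -- is a conflict error and aborts
#' the import with the store unchanged.
#'
#' @param path CSV mapping file with columns `original`, `pseudonym`.
#' @param store target store.
#' @return the store, invisibly.
#' @export
import_mapping <- function(path, store = pseudonym_store()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("original", "pseudonym") %in% names(df))) {
    edf_error("edf_store_error", "malformed mapping file: need original, pseudonym")
  }
  if (anyDuplicated(df$original) || anyDuplicated(df$pseudonym)) {
    edf_error("edf_mapping_conflict_error", "mapping file is not injective")
  }
  for (i in seq_len(nrow(df))) {
    o <- df$original[i]; p <- df$pseudonym[i]
    cur <- store$map[o]
    if (!is.na(cur) && cur != p) {
      edf_error("edf_mapping_conflict_error",
                sprintf("conflicting pseudonym for %s", dQuote(o)))
    }
    if (is.na(cur) && p %in% store$map) {
      edf_error("edf_mapping_conflict_error",
                sprintf("pseudonym %s already maps to another original", dQuote(p)))
    }
  }
  for (i in seq_len(nrow(df))) {
    o <- df$original[i]
    if (is.na(store$map[o])) {
      store$map[o] <- df$pseudonym[i]
      store$created[length(store$map)] <-
        if ("created_at" %in% names(df)) df$created_at[i] else ""
    }
  }
  store_save(store)
  invisible(store)
}
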