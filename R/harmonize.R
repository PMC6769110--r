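# Channel-label harmonization.
#
# EDF+ defines standard signal label texts, but compliance in the wild is
# low: the same electrode derivation appears as "C4-A1", "EEGC4-A1",
# "EEG C4-A1", and vendors invent local names ("LEGBEINLI" for the left
# anterior tibialis EMG).  Harmonization maps such variants to one standard
# text via a curated table; unknown labels pass through flagged, never
# guessed.

.modality_prefix_re <- "^(EEG|EMG|EOG|ECG)[ :_.-]*"

#' Normalize a raw channel label into its lookup key
#'
#' Uppercases, trims, collapses internal whitespace, and strips a leading
#' modality token (EEG/EMG/EOG/ECG) with any separators -- so "C4-A1",
#' "EEGC4-A1" and "EEG C4-A1" share the key "C4-A1".  A label that is only
#' a modality token is kept as-is.
#'
#' @param raw character vector of labels.
#' @return character vector of normalized keys.
#' @export
normalize_key <- function(raw) {
  x <- toupper(trimws(raw))
  x <- gsub("[[:space:]]+", " ", x)
  stripped <- sub(.modality_prefix_re, "", x)
  ifelse(nzchar(stripped), stripped, x)
}

#' Load a harmonization table from CSV
#'
#' Expects columns `variant`, `standard`, `category` (and optionally `note`);
#' UTF-8 with a header row.  Variants are normalized with [normalize_key()];
#' every standard label is additionally entered as its own key, so standards
#' are fixed points.  Two rows whose variants normalize to the same key but
#' name different standards are rejected.
#'
#' @param path CSV file; default is the bundled seed table (the well-known
#'   printed equivalences plus standard self-entries -- a starting point,
#'   not the full curated list).
#' @return an `edf_harmonization_table` (data frame keyed by normalized
#'   variant).
#' @export
load_harmonization_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "harmonization_seed.csv", package = "edflazy")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("variant", "standard", "category")
  if (!all(need %in% names(df))) {
    edf_error("edf_table_error",
              sprintf("harmonization table must have columns %s",
                      paste(need, collapse = ", ")))
  }
  if (anyNA(df$variant) || anyNA(df$standard) || any(!nzchar(df$variant))) {
    edf_error("edf_table_error", "malformed row: empty variant or standard")
  }
  if (!"note" %in% names(df)) df$note <- ""
  # self-entries make every standard label a fixed point
  self <- unique(df[, c("standard", "category")])
  self <- data.frame(variant = self$standard, standard = self$standard,
                     category = self$category, note = "standard self-entry",
                     stringsAsFactors = FALSE)
  df <- rbind(df[, c("variant", "standard", "category", "note")], self)
  df$key <- normalize_key(df$variant)
  conflict <- tapply(df$standard, df$key, function(s) length(unique(s)) > 1L)
  if (any(conflict)) {
    edf_error("edf_table_conflict_error",
              sprintf("conflicting entries for key(s): %s",
                      paste(names(conflict)[conflict], collapse = ", ")))
  }
  df <- df[!duplicated(df$key), c("key", "standard", "category", "note")]
  rownames(df) <- NULL
  class(df) <- c("edf_harmonization_table", "data.frame")
  df
}

#' Save a harmonization table to CSV (canonical serialization)
#' @param table an `edf_harmonization_table`.
#' @param path output CSV path.
#' @export
save_harmonization_table <- function(table, path) {
  out <- data.frame(variant = table$key, standard = table$standard,
                    category = table$category, note = table$note,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Harmonize channel labels against a table
#'
#' Looks each label up by its normalized key; matched labels are replaced by
#' the standard text, unmatched labels are returned unchanged with
#' `matched = FALSE` and category `"unknown"`.
#'
#' @param raw character vector of raw labels.
#' @param table an `edf_harmonization_table` (default: bundled seed table).
#' @return data frame with columns `raw`, `standard`, `matched`, `category`.
#' @export
harmonize <- function(raw, table = load_harmonization_table()) {
  key <- normalize_key(raw)
  i <- match(key, table$key)
  data.frame(
    raw = as.character(raw),
    standard = ifelse(is.na(i), as.character(raw), table$standard[i]),
    matched = !is.na(i),
    category = ifelse(is.na(i), "unknown", table$category[i]),
    stringsAsFactors = FALSE
  )
}
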