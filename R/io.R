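#' Write a twin-pair table to delimited text with a ground-truth sidecar
#'
#' The table is written as comma-separated text with the header
#' `family_id, zygosity, sex1, sex2, age, <trait>_1, <trait>_2, ...`; any
#' generating parameters stored in `attr(pairs, "truth")` are echoed into a
#' JSON sidecar next to the CSV so simulated cohorts remain self-describing.
#'
#' @param pairs A twin-pair data frame (one row per pair).
#' @param path Output CSV path; the sidecar replaces the extension by
#'   `.json`.
#' @return `path`, invisibly.
#' @export
write_twin_pairs <- function(pairs, path) {
  utils::write.csv(pairs, path, row.names = FALSE, quote = FALSE)
  truth <- attr(pairs, "truth")
  if (!is.null(truth)) {
    sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
    jsonlite::write_json(truth, sidecar, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a twin-pair table written by [write_twin_pairs()]
#'
#' @param path CSV path; a `.json` sidecar with generating parameters is
#'   restored into `attr(, "truth")` when present.
#' @return A twin-pair data frame.
#' @export
read_twin_pairs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  if (file.exists(sidecar))
    attr(d, "truth") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  d
}

#' Trait columns of a pair table, with validation
#' @noRd
pair_trait <- function(pairs, trait) {
  cols <- paste0(trait, c("_1", "_2"))
  if (!all(cols %in% names(pairs)))
    stop("trait '", trait, "' not found: expected columns ",
         paste(cols, collapse = ", "), call. = FALSE)
  list(t1 = pairs[[cols[1]]], t2 = pairs[[cols[2]]])
}

#' Pool zygosity labels into MZ / DZ groups
#' @noRd
zyg_group <- function(zygosity) {
  ifelse(zygosity == "MZ", "MZ",
         ifelse(zygosity %in% c("DZ", "DZss", "DZos"), "DZ", NA_character_))
}
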