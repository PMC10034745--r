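state_csv_columns <- c(
  protein = "Protein", sequence = "Sequence", start = "Start", end = "End",
  state = "State", exposure = "Exposure", uptake = "Uptake"
)

#' Read a state-data CSV of deuterium uptake
#'
#' Reads the tabular per-peptide, per-exposure uptake export produced by HDX
#' processing software (columns `Protein`, `Sequence`, `Start`, `End`,
#' `State`, `Exposure`, `Uptake`, optionally `Uptake SD` and `Replicate`).
#' Exposures are converted to seconds; parsing is locale-independent (`.`
#' decimal mark). Rows whose exposure or uptake cells fail to parse are
#' dropped with a per-row diagnostic warning rather than aborting the read.
#'
#' @param path CSV file path.
#' @param exposure_units `"s"` (canonical) or `"min"` (common in vendor
#'   exports; converted to seconds).
#' @return A tibble with lower-case columns `protein`, `sequence`, `start`,
#'   `end`, `state`, `exposure` (s), `uptake` (Da), and `replicate` /
#'   `uptake_sd` when present.
#' @export
read_state_csv <- function(path, exposure_units = c("s", "min")) {
  exposure_units <- match.arg(exposure_units)
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    locale = readr::locale(decimal_mark = "."),
    progress = FALSE
  )
  missing <- setdiff(unname(state_csv_columns), names(raw))
  if (length(missing) > 0L) {
    abort(paste0("Missing required column(s): ", paste(missing, collapse = ", ")))
  }
  out <- tibble::tibble(
    protein = raw$Protein,
    sequence = toupper(raw$Sequence),
    start = suppressWarnings(as.integer(raw$Start)),
    end = suppressWarnings(as.integer(raw$End)),
    state = raw$State,
    exposure = suppressWarnings(as.numeric(raw$Exposure)),
    uptake = suppressWarnings(as.numeric(raw$Uptake))
  )
  if ("Replicate" %in% names(raw)) {
    out$replicate <- suppressWarnings(as.integer(raw$Replicate))
  }
  if ("Uptake SD" %in% names(raw)) {
    out$uptake_sd <- suppressWarnings(as.numeric(raw$`Uptake SD`))
  }
  bad <- which(is.na(out$exposure) | is.na(out$uptake) | is.na(out$start) |
    is.na(out$end) | is.na(out$sequence))
  if (length(bad) > 0L) {
    warn(sprintf(
      "Dropped %d malformed row(s): %s",
      length(bad),
      paste(utils::head(bad, 10), collapse = ", ")
    ))
    out <- out[-bad, ]
  }
  if (exposure_units == "min") out$exposure <- out$exposure * 60
  out
}

#' @rdname read_state_csv
#' @param data Tibble in the schema returned by `read_state_csv()`.
#' @export
write_state_csv <- function(data, path) {
  stopifnot(is.data.frame(data))
  need <- names(state_csv_columns)
  missing <- setdiff(need, names(data))
  if (length(missing) > 0L) {
    abort(paste0("Missing required column(s): ", paste(missing, collapse = ", ")))
  }
  out <- tibble::tibble(
    Protein = data$protein, Sequence = data$sequence,
    Start = data$start, End = data$end, State = data$state,
    Exposure = data$exposure, Uptake = data$uptake
  )
  if ("replicate" %in% names(data)) out$Replicate <- data$replicate
  if ("uptake_sd" %in% names(data)) out$`Uptake SD` <- data$uptake_sd
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read peptide lists
#'
#' `read_peptide_csv()` reads a `sequence,start,end` CSV;
#' `read_fasta_sequences()` reads protein or peptide sequences from a plain
#' FASTA file.
#'
#' @param path File path.
#' @return A tibble (`name`, `sequence`, and for the CSV reader `start`,
#'   `end`).
#' @export
read_peptide_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      sequence = readr::col_character(),
      start = readr::col_integer(),
      end = readr::col_integer(),
      .default = readr::col_character()
    ),
    progress = FALSE
  )
  if (!all(c("sequence", "start", "end") %in% names(df))) {
    abort("Peptide CSV needs columns sequence, start, end.")
  }
  if (!"name" %in% names(df)) df$name <- df$sequence
  dplyr::select(df, "name", "sequence", "start", "end")
}

#' @rdname read_peptide_csv
#' @export
read_fasta_sequences <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  headers <- grepl("^>", lines)
  if (!any(headers)) abort("Not a FASTA file (no '>' headers).")
  idx <- cumsum(headers)
  names_ <- sub("^>\\s*", "", lines[headers])
  seqs <- vapply(
    seq_along(names_),
    function(i) paste(toupper(lines[idx == i & !headers]), collapse = ""),
    character(1)
  )
  tibble::tibble(name = vapply(strsplit(names_, "\\s+"), `[[`, character(1), 1),
                 sequence = seqs)
}
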