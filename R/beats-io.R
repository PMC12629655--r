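#' Assemble a beat-annotated recording
#'
#' Bundles the three pieces of one recording — the per-beat table, the rhythm
#' episodes, and the recording metadata — into a validated `af_recording`
#' object, the unit every downstream step consumes.
#'
#' @param beats Data frame with columns `time_s` (seconds from recording
#'   start, strictly increasing), `rr_ms` (interval terminating on that beat,
#'   ms; `NA` allowed for the first beat only) and `label`
#'   (`"N"`, `"PAC"` or `"ARTIFACT"`).
#' @param episodes Data frame with columns `rhythm` (only `"AF"` supported),
#'   `onset_s`, `offset_s`; may have zero rows. Episodes must be sorted,
#'   non-overlapping, and each at least 30 s long (the AF definition floor:
#'   irregular RR without P waves sustained for >= 30 s).
#' @param meta Named list with `recording_id`, `patient_id`, `recording_date`
#'   (a `Date` or parseable string), `age` (years), `sex` (`"M"`, `"F"` or
#'   `"unknown"`) and `duration_s`.
#' @return An `af_recording`: list with tibbles `beats`, `episodes` and list
#'   `meta`.
#' @export
af_recording <- function(beats, episodes = NULL, meta) {
  beats <- tibble::as_tibble(beats)
  required <- c("time_s", "rr_ms", "label")
  missing_cols <- setdiff(required, names(beats))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Beat table is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ), class = "afonset_format_error")
  }
  beats <- beats[required]
  beats$time_s <- as.double(beats$time_s)
  beats$rr_ms <- as.double(beats$rr_ms)
  beats$label <- as.character(beats$label)

  bad_label <- which(!beats$label %in% c("N", "PAC", "ARTIFACT"))
  if (length(bad_label) > 0) {
    abort(sprintf(
      "Unparseable beat label %s at row %d.",
      beats$label[bad_label[1]], bad_label[1]
    ), class = "afonset_format_error")
  }
  n <- nrow(beats)
  if (n > 0) {
    dt <- diff(beats$time_s)
    if (any(dt <= 0)) {
      first_bad <- which(dt <= 0)[1] + 1L
      abort(sprintf(
        "Beat times must be strictly increasing; first violation at row %d.",
        first_bad
      ), class = "afonset_validation_error")
    }
    rr <- beats$rr_ms[-1]
    if (anyNA(rr)) {
      abort("`rr_ms` may be NA for the first beat only.",
        class = "afonset_validation_error"
      )
    }
    if (any(rr <= 0)) {
      abort("RR intervals must be positive.", class = "afonset_validation_error")
    }
    mismatch <- abs(rr / 1000 - dt) > 1e-3
    if (any(mismatch)) {
      abort(sprintf(
        "rr_ms inconsistent with beat-time difference (> 1 ms) at row %d.",
        which(mismatch)[1] + 1L
      ), class = "afonset_validation_error")
    }
  }

  if (is.null(episodes) || nrow(as.data.frame(episodes)) == 0) {
    episodes <- tibble::tibble(
      rhythm = character(), onset_s = double(), offset_s = double()
    )
  } else {
    episodes <- tibble::as_tibble(episodes)[, c("rhythm", "onset_s", "offset_s")]
    episodes$onset_s <- as.double(episodes$onset_s)
    episodes$offset_s <- as.double(episodes$offset_s)
    if (any(episodes$rhythm != "AF")) {
      abort("Only rhythm code 'AF' is supported.",
        class = "afonset_validation_error"
      )
    }
    if (any(episodes$offset_s <= episodes$onset_s)) {
      abort("Episode offset must exceed onset.",
        class = "afonset_validation_error"
      )
    }
    episodes <- dplyr::arrange(episodes, .data$onset_s)
    dur <- episodes$offset_s - episodes$onset_s
    if (any(dur < 30)) {
      abort(sprintf(
        "AF episode of %.1f s is below the 30-s definition floor.",
        min(dur)
      ), class = "afonset_validation_error")
    }
    if (nrow(episodes) > 1 &&
      any(episodes$onset_s[-1] < episodes$offset_s[-nrow(episodes)])) {
      abort("AF episodes must not overlap.", class = "afonset_validation_error")
    }
  }

  meta_req <- c(
    "recording_id", "patient_id", "recording_date", "age", "sex", "duration_s"
  )
  missing_meta <- setdiff(meta_req, names(meta))
  if (length(missing_meta) > 0) {
    abort(paste0(
      "Metadata missing field(s): ", paste(missing_meta, collapse = ", ")
    ), class = "afonset_format_error")
  }
  meta <- meta[meta_req]
  meta$recording_date <- as.Date(meta$recording_date)
  meta$age <- as.double(meta$age)
  meta$duration_s <- as.double(meta$duration_s)
  if (!meta$sex %in% c("M", "F", "unknown")) {
    abort("`sex` must be 'M', 'F' or 'unknown'.",
      class = "afonset_validation_error"
    )
  }
  if (meta$duration_s <= 0) {
    abort("`duration_s` must be positive.", class = "afonset_validation_error")
  }
  if (meta$age < 0) {
    abort("`age` must be non-negative.", class = "afonset_validation_error")
  }

  structure(
    list(beats = beats, episodes = episodes, meta = meta),
    class = "af_recording"
  )
}

#' @export
print.af_recording <- function(x, ...) {
  cat(sprintf(
    "<af_recording %s> patient %s, %.1f h, %d beats, %d AF episode(s)\n",
    x$meta$recording_id, x$meta$patient_id, x$meta$duration_s / 3600,
    nrow(x$beats), nrow(x$episodes)
  ))
  invisible(x)
}

#' Read a beat-annotation file
#'
#' Parses the plain-text beat dialect: a CSV with header `time_s,rr_ms,label`,
#' one row per beat, followed by optional rhythm lines
#' `#EPISODE,AF,<onset_s>,<offset_s>`. Metadata is read from the sidecar JSON
#' (`<stem>.json`) next to the file.
#'
#' @param path Path to the beat CSV.
#' @return A validated [af_recording()].
#' @export
read_beats <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "afonset_format_error")
  }
  lines <- readLines(path, warn = FALSE)
  is_episode <- startsWith(lines, "#EPISODE")
  body <- lines[!is_episode & !startsWith(lines, "#")]
  if (length(body) < 1 || trimws(body[1]) != "time_s,rr_ms,label") {
    abort("Missing or malformed header `time_s,rr_ms,label`.",
      class = "afonset_format_error"
    )
  }
  beats <- readr::read_csv(
    I(paste(body, collapse = "\n")),
    col_types = readr::cols(
      time_s = readr::col_double(),
      rr_ms = readr::col_double(),
      label = readr::col_character()
    ),
    progress = FALSE
  )

  ep_lines <- lines[is_episode]
  episodes <- NULL
  if (length(ep_lines) > 0) {
    parts <- strsplit(ep_lines, ",", fixed = TRUE)
    if (any(lengths(parts) != 4)) {
      abort("Malformed #EPISODE line.", class = "afonset_format_error")
    }
    episodes <- tibble::tibble(
      rhythm = vapply(parts, `[`, "", 2),
      onset_s = as.double(vapply(parts, `[`, "", 3)),
      offset_s = as.double(vapply(parts, `[`, "", 4))
    )
  }

  meta_path <- paste0(tools::file_path_sans_ext(path), ".json")
  if (!file.exists(meta_path)) {
    abort(sprintf("Metadata sidecar not found: %s", meta_path),
      class = "afonset_format_error"
    )
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)

  af_recording(beats, episodes, meta)
}

#' Write a recording in the beat-annotation dialect
#'
#' Inverse of [read_beats()]: writes the beat CSV (with `#EPISODE` lines
#' appended) and the metadata sidecar JSON. `read_beats(write_beats(x, p))`
#' reproduces `x` field for field.
#'
#' @param rec An [af_recording()].
#' @param path Output CSV path; the sidecar is written to `<stem>.json`.
#' @return `path`, invisibly.
#' @export
write_beats <- function(rec, path) {
  stopifnot(inherits(rec, "af_recording"))
  b <- rec$beats
  rr_chr <- ifelse(is.na(b$rr_ms), "", format_num(b$rr_ms))
  lines <- c(
    "time_s,rr_ms,label",
    paste(format_num(b$time_s), rr_chr, b$label, sep = ",")
  )
  if (nrow(rec$episodes) > 0) {
    lines <- c(lines, sprintf(
      "#EPISODE,%s,%s,%s",
      rec$episodes$rhythm,
      format_num(rec$episodes$onset_s),
      format_num(rec$episodes$offset_s)
    ))
  }
  writeLines(lines, path)
  meta <- rec$meta
  meta$recording_date <- format(meta$recording_date)
  jsonlite::write_json(
    meta, paste0(tools::file_path_sans_ext(path), ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

# full-precision, locale-stable number formatting for the text dialect
format_num <- function(x) {
  out <- formatC(x, format = "fg", digits = 15)
  gsub(" ", "", out, fixed = TRUE)
}
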