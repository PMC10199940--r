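# EEG record container and plain-text cohort IO.
#
# Native on-disk format: "#"-prefixed header lines (format tag, fs, group,
# eye condition, subject id, channel names) followed by a whitespace-delimited
# samples x channels numeric table at 6 significant digits.

new_eeg_record <- function(subject_id, group, channel_names, signal, fs,
                           eye_condition = NULL) {
  check_group(group)
  channel_names <- as.character(channel_names)
  if (length(channel_names) == 0) stop_eeg("empty channel list")
  if (anyDuplicated(channel_names)) {
    stop_eeg("duplicate channel names: ",
             paste(unique(channel_names[duplicated(channel_names)]),
                   collapse = ", "))
  }
  bad <- setdiff(channel_names, .EEG_CHANNELS)
  if (length(bad) > 0) {
    stop_eeg("unknown channel names: ", paste(bad, collapse = ", "))
  }
  signal <- as.matrix(signal)
  if (nrow(signal) != length(channel_names)) {
    stop_eeg(
      "channel count mismatch: ", nrow(signal), " signal rows vs ",
      length(channel_names), " channel names"
    )
  }
  if (!is.numeric(signal) || anyNA(signal)) {
    stop_eeg("signal must be numeric with no missing values")
  }
  eye <- .GROUP_EYE[[group]]
  if (!is.null(eye_condition) && !identical(eye_condition, eye)) {
    stop_eeg("group ", group, " implies eye_condition '", eye, "'")
  }
  rownames(signal) <- channel_names
  structure(
    list(
      subject_id = as.character(subject_id), group = group,
      eye_condition = eye, channel_names = channel_names,
      signal = signal, fs = fs
    ),
    class = "eeg_record"
  )
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(
    "<eeg_record>", x$subject_id, " group", x$group,
    paste0("(eyes ", x$eye_condition, ");"),
    nrow(x$signal), "channels x", ncol(x$signal), "samples @", x$fs, "Hz\n"
  )
  invisible(x)
}

#' Tidy view of an EEG record
#'
#' @param x An `eeg_record`.
#' @param ... Unused.
#' @return A tibble with one row per (channel, time) sample: `subject_id`,
#'   `group`, `eye_condition`, `channel`, `time` (seconds), `value`.
#' @importFrom tibble as_tibble
#' @method as_tibble eeg_record
#' @export
as_tibble.eeg_record <- function(x, ...) {
  n <- ncol(x$signal)
  tibble::tibble(
    subject_id = x$subject_id,
    group = x$group,
    eye_condition = x$eye_condition,
    channel = rep(x$channel_names, each = n),
    time = rep((seq_len(n) - 1) / x$fs, times = length(x$channel_names)),
    value = as.vector(t(x$signal))
  )
}

#' Write an EEG record to a plain-text file
#'
#' Emits a commented header (sampling rate, group, eye condition, subject id,
#' channel names) followed by a samples-by-channels numeric table at 6
#' significant digits; [read_eeg_record()] inverts it.
#'
#' @param record An `eeg_record`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_eeg_record <- function(record, path) {
  stopifnot(inherits(record, "eeg_record"))
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop_eeg("cannot open '", path, "' for writing: ", conditionMessage(e))
  })
  on.exit(close(con))
  writeLines(c(
    "# eeg-record v1",
    paste("# fs", format(record$fs)),
    paste("# group", record$group),
    paste("# eye_condition", record$eye_condition),
    paste("# subject_id", record$subject_id),
    paste("# channels", paste(record$channel_names, collapse = " "))
  ), con)
  body <- apply(
    t(record$signal), 1,
    function(row) paste(sprintf("%.6g", row), collapse = " ")
  )
  writeLines(body, con)
  invisible(path)
}

header_field <- function(lines, key, path) {
  pat <- paste0("^# ", key, " ")
  hit <- grep(pat, lines, value = TRUE)
  if (length(hit) != 1) {
    stop_eeg("file '", path, "': expected exactly one '# ", key, "' header")
  }
  sub(pat, "", hit)
}

#' Read an EEG record from a plain-text file
#'
#' @param path File written by [write_eeg_record()] (or following the same
#'   format: `#`-prefixed header declaring `fs` and channel names, then a
#'   samples x channels numeric table).
#' @return An `eeg_record`.
#' @export
read_eeg_record <- function(path) {
  if (!file.exists(path)) stop_eeg("file not found: ", path)
  lines <- readLines(path)
  head_idx <- grep("^#", lines)
  header <- lines[head_idx]
  body <- lines[setdiff(seq_along(lines), head_idx)]
  body <- body[nzchar(trimws(body))]
  fs <- as.numeric(header_field(header, "fs", path))
  if (is.na(fs)) stop_eeg("file '", path, "': non-numeric fs header")
  channels <- strsplit(header_field(header, "channels", path), "\\s+")[[1]]
  group <- header_field(header, "group", path)
  subject_id <- header_field(header, "subject_id", path)
  if (length(body) == 0) stop_eeg("file '", path, "': no data rows")
  cells <- strsplit(trimws(body), "\\s+")
  ncol_seen <- lengths(cells)
  if (any(ncol_seen != length(channels))) {
    stop_eeg(
      "file '", path, "': ", sum(ncol_seen != length(channels)),
      " rows with column count != ", length(channels), " declared channels"
    )
  }
  values <- suppressWarnings(as.numeric(unlist(cells)))
  if (anyNA(values)) stop_eeg("file '", path, "': non-numeric cell")
  # unlist() concatenates row by row, so filling column-major gives a
  # channels x samples matrix directly.
  signal <- matrix(values, nrow = length(channels))
  new_eeg_record(
    subject_id = subject_id, group = group, channel_names = channels,
    signal = signal, fs = fs
  )
}

#' Write a cohort as a directory tree
#'
#' Lays records out as `root/<group>/<subject_id>.txt`, the layout
#' [load_cohort()] reads back.
#'
#' @param records List of `eeg_record` objects.
#' @param root Output directory (created if needed).
#' @return `root`, invisibly.
#' @export
write_cohort <- function(records, root) {
  stopifnot(length(records) > 0)
  for (rec in records) {
    dir <- file.path(root, rec$group)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_eeg_record(rec, file.path(dir, paste0(rec$subject_id, ".txt")))
  }
  invisible(root)
}

#' Load a cohort directory
#'
#' Reads every record under `root/{A,B,C,D}/*.txt`, assigns groups by
#' directory, and validates that all records share one channel set.
#'
#' @param root Cohort root directory.
#' @return A list with `records` (list of `eeg_record`) and `index`, a tibble
#'   with one row per record (`subject_id`, `group`, `eye_condition`, `file`).
#' @export
load_cohort <- function(root) {
  if (!dir.exists(root)) stop_eeg("cohort root not found: ", root)
  records <- list()
  files <- character()
  for (g in .EEG_GROUPS) {
    gdir <- file.path(root, g)
    if (!dir.exists(gdir)) next
    for (f in sort(list.files(gdir, pattern = "\\.txt$", full.names = TRUE))) {
      rec <- tryCatch(read_eeg_record(f), error = function(e) {
        stop_eeg("malformed record '", f, "': ", conditionMessage(e))
      })
      if (!identical(rec$group, g)) {
        stop_eeg("record '", f, "' declares group ", rec$group,
                 " but sits in directory ", g)
      }
      records[[length(records) + 1L]] <- rec
      files <- c(files, f)
    }
  }
  if (length(records) > 1) {
    ref <- records[[1]]$channel_names
    for (i in seq_along(records)) {
      if (!identical(records[[i]]$channel_names, ref)) {
        stop_eeg(
          "record '", files[i], "' channel set differs from the cohort's"
        )
      }
    }
  }
  index <- tibble::tibble(
    subject_id = vapply(records, `[[`, "", "subject_id"),
    group = vapply(records, `[[`, "", "group"),
    eye_condition = vapply(records, `[[`, "", "eye_condition"),
    file = files
  )
  list(records = records, index = index)
}
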