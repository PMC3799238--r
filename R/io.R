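# On-disk formats: CSV spike/event tables, CSV or 16-bit EDF LFP traces,
# JSON + CSV reports. Comma separator, "." decimal, UTF-8, mandatory header.

#' Read sorted spike trains from CSV
#'
#' Expects a delimited-text file with header `unit_id,channel_id,time_s`.
#' Times within each unit are sorted; exact duplicates are collapsed with a
#' warning and counted.
#'
#' @param path file path.
#' @param span optional recording interval `[start, end]` in seconds;
#'   inferred as `[0, max time]` when absent.
#' @return A named list of [spike_train] objects, one per distinct unit.
#' @export
read_spike_trains <- function(path, span = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("unit_id", "channel_id", "time_s"))
    if (!col %in% names(df))
      stop_fmt("spike file %s: missing required column '%s'", path, col)
  if (!nrow(df)) return(structure(list(), names = character()))
  if (any(df$time_s < 0)) stop_fmt("spike file %s: negative times", path)
  if (is.null(span)) span <- c(0, max(df$time_s))
  out <- lapply(split(df, df$unit_id), function(d) {
    spike_train(d$time_s, span = span, unit_id = d$unit_id[1],
                channel_id = d$channel_id[1])
  })
  out[order(names(out))]
}

#' Write spike trains to CSV
#'
#' @param trains a list of [spike_train] objects.
#' @param path output file path.
#' @export
write_spike_trains <- function(trains, path) {
  rows <- lapply(trains, function(tr) {
    if (!length(tr$times)) return(NULL)
    data.frame(unit_id = tr$unit_id, channel_id = tr$channel_id,
               time_s = sprintf("%.6f", tr$times))
  })
  df <- do.call(rbind, c(rows, list(data.frame(unit_id = character(),
                                               channel_id = character(),
                                               time_s = character()))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an event set from CSV
#'
#' Header: `channel_id,peak_time_s,onset_s,offset_s,peak_amplitude_uv`.
#'
#' @param path file path.
#' @return An [event_set] with source `"imported"`.
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("channel_id", "peak_time_s", "onset_s", "offset_s", "peak_amplitude_uv")
  for (col in need)
    if (!col %in% names(df)) stop_fmt("event file %s: missing column '%s'", path, col)
  event_set(peak_time = df$peak_time_s, onset = df$onset_s, offset = df$offset_s,
            peak_amplitude = df$peak_amplitude_uv, channel_id = df$channel_id,
            source = "imported")
}

#' Write an event set to CSV
#' @param events an [event_set].
#' @param path output file path.
#' @export
write_events <- function(events, path) {
  df <- data.frame(channel_id = events$channel_id,
                   peak_time_s = sprintf("%.6f", events$peak_time),
                   onset_s = sprintf("%.6f", events$onset),
                   offset_s = sprintf("%.6f", events$offset),
                   peak_amplitude_uv = sprintf("%.6f", events$peak_amplitude))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an LFP trace
#'
#' Dispatches on extension: `.edf` for standard 16-bit EDF with physical
#' scaling, anything else is treated as delimited text whose first line is
#' `fs_hz=<rate>` followed by one sample (microvolts) per line.
#'
#' @param path file path.
#' @param channel channel label to extract (EDF only; the text format holds
#'   a single channel and `channel` just names it).
#' @return An [lfp_signal].
#' @export
read_lfp <- function(path, channel = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "edf") return(read_edf(path, channel))
  if (!ext %in% c("csv", "txt", "dat"))
    stop_fmt("unknown LFP file extension '.%s' (expect .edf or .csv/.txt)", ext)
  lines <- readLines(path)
  if (!length(lines) || !grepl("^fs_hz=", lines[1]))
    stop_fmt("LFP text file %s: first line must be 'fs_hz=<rate>'", path)
  fs <- as.numeric(sub("^fs_hz=", "", lines[1]))
  if (!is.finite(fs) || fs <= 0) stop_fmt("LFP text file %s: bad sampling rate", path)
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop_fmt("LFP text file %s: empty sample section", path)
  lfp_signal(as.numeric(body), fs,
             channel_id = if (is.null(channel)) "ch1" else channel)
}

#' Write an LFP trace
#'
#' `.edf` paths get a 16-bit EDF file (one channel, physical scaling chosen
#' from the data range); other paths get the `fs_hz=` text format.
#'
#' @param lfp an [lfp_signal].
#' @param path output file path.
#' @export
write_lfp <- function(lfp, path) {
  if (tolower(tools::file_ext(path)) == "edf") return(write_edf(lfp, path))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("fs_hz=%.10g", lfp$fs), con)
  writeLines(sprintf("%.6f", lfp$samples), con)
  invisible(path)
}

# --- minimal EDF (16-bit) support -----------------------------------------
# Fixed-layout ASCII header of 256 bytes plus 256 per signal; data records of
# little-endian int16 with linear digital->physical scaling. The writer emits
# a single-channel file with one data record holding the whole trace.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

write_edf <- function(lfp, path) {
  n <- length(lfp$samples)
  pmin <- min(lfp$samples); pmax <- max(lfp$samples)
  if (pmax <= pmin) { pmin <- pmin - 1; pmax <- pmax + 1 }  # constant trace
  dmin <- -32768; dmax <- 32767
  dig <- as.integer(pmin(pmax(
    round((lfp$samples - pmin) / (pmax - pmin) * (dmax - dmin) + dmin),
    dmin), dmax))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad("synthetic", 80),
    edf_pad("iedflow", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 + 256, 8),
    edf_pad("", 44),
    edf_pad(1, 8),                              # n data records
    edf_pad(format(n / lfp$fs, digits = 8), 8), # record duration (s)
    edf_pad(1, 4),                              # n signals
    edf_pad(lfp$channel_id, 16),
    edf_pad("", 80),                            # transducer
    edf_pad("uV", 8),
    edf_pad(format(pmin, digits = 8), 8),
    edf_pad(format(pmax, digits = 8), 8),
    edf_pad(dmin, 8), edf_pad(dmax, 8),
    edf_pad("", 80),                            # prefiltering
    edf_pad(n, 8),                              # samples per record
    edf_pad("", 32))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  writeBin(dig, con, size = 2L, endian = "little")
  invisible(path)
}

read_edf <- function(path, channel = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(rawToChar(readBin(con, "raw", w)))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- fld(16); fld(80); fld(8)
  pmins <- as.numeric(fld(8)); pmaxs <- as.numeric(fld(8))
  dmins <- as.numeric(fld(8)); dmaxs <- as.numeric(fld(8))
  fld(80)
  nrs <- as.integer(fld(8)); fld(32)
  if (is.null(channel)) {
    idx <- 1L
  } else {
    idx <- match(channel, labels)
    if (is.na(idx))
      stop_fmt("channel '%s' not in EDF file %s (available: %s)",
               channel, path, paste(labels, collapse = ", "))
  }
  chunks <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      v <- readBin(con, "integer", nrs[s], size = 2L, signed = TRUE,
                   endian = "little")
      if (s == idx) chunks[[r]] <- v
    }
  }
  dig <- unlist(chunks)
  phys <- (dig - dmins[idx]) * (pmaxs[idx] - pmins[idx]) /
    (dmaxs[idx] - dmins[idx]) + pmins[idx]
  fs <- nrs[idx] / rec_dur
  lfp_signal(phys, fs, channel_id = labels[idx])
}

# quantization step of the EDF encoding used by write_edf
edf_quantum <- function(samples) {
  pmin <- min(samples); pmax <- max(samples)
  if (pmax <= pmin) return(2 / 65535)
  (pmax - pmin) / 65535
}

#' Write a consolidated analysis report
#'
#' Tabular components (data frames) are written as CSV files next to the
#' JSON summary; everything scalar/nested goes into the JSON. Re-reading
#' reproduces values to six decimals.
#'
#' @param results a named list; data frame elements become `<name>.csv`,
#'   the rest is serialised to `report.json`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) stop_fmt("cannot create report directory %s", dir)
  paths <- character()
  scalars <- list()
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.data.frame(x)) {
      p <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(format_numeric_df(x), p, row.names = FALSE, quote = FALSE)
      paths <- c(paths, p)
    } else {
      scalars[[nm]] <- x
    }
  }
  p <- file.path(dir, "report.json")
  jsonlite::write_json(scalars, p, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(paths, p))
}

format_numeric_df <- function(df) {
  for (j in seq_along(df))
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- sprintf("%.6f", df[[j]])
  df
}
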