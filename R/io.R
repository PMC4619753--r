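#' Probe geometry for an fNIRS recording
#'
#' Describes the optode layout: source and detector positions, the measurement
#' list mapping each data row to a (source, detector, wavelength) triple, the
#' wavelengths in nm, and the per-channel source-detector separation in cm.
#' Rows of the intensity matrix that measure the same source-detector pair at
#' different wavelengths belong to one *measurement channel*.
#'
#' @param source_pos Numeric matrix, sources x 3, positions in cm.
#' @param detector_pos Numeric matrix, detectors x 3, positions in cm.
#' @param meas_list Integer matrix, rows x 3: source index, detector index,
#'   wavelength index (all 1-based, as stored in .nirs files).
#' @param wavelengths Numeric vector of wavelengths in nm.
#' @param separations Optional per-row source-detector distance in cm;
#'   computed from the positions when omitted.
#' @return A `probe_geometry` object.
#' @export
probe_geometry <- function(source_pos, detector_pos, meas_list, wavelengths,
                           separations = NULL) {
  source_pos <- as.matrix(source_pos)
  detector_pos <- as.matrix(detector_pos)
  meas_list <- as.matrix(meas_list)
  if (ncol(meas_list) < 3L) stop("meas_list needs columns (source, detector, wavelength)")
  meas_list <- meas_list[, 1:3, drop = FALSE]
  colnames(meas_list) <- c("source", "detector", "wavelength")
  if (any(meas_list[, 1] < 1 | meas_list[, 1] > nrow(source_pos)))
    stop("measurement list references a nonexistent source")
  if (any(meas_list[, 2] < 1 | meas_list[, 2] > nrow(detector_pos)))
    stop("measurement list references a nonexistent detector")
  if (any(meas_list[, 3] < 1 | meas_list[, 3] > length(wavelengths)))
    stop("measurement list references a nonexistent wavelength")
  if (is.null(separations)) {
    separations <- sqrt(rowSums((source_pos[meas_list[, 1], , drop = FALSE] -
                                 detector_pos[meas_list[, 2], , drop = FALSE])^2))
  }
  if (any(separations <= 0)) stop("source-detector separations must be > 0")
  structure(list(source_pos = source_pos, detector_pos = detector_pos,
                 meas_list = meas_list, wavelengths = as.numeric(wavelengths),
                 separations = as.numeric(separations)),
            class = "probe_geometry")
}

# Group measurement-list rows into measurement channels: rows sharing a
# source-detector pair across wavelengths. Returns a list with one integer
# vector of row indices per channel, ordered by wavelength index.
measurement_channels <- function(probe) {
  key <- paste(probe$meas_list[, 1], probe$meas_list[, 2], sep = "-")
  idx <- split(seq_len(nrow(probe$meas_list)), factor(key, levels = unique(key)))
  lapply(idx, function(i) i[order(probe$meas_list[i, 3])])
}

#' Raw fNIRS recording
#'
#' Raw optical intensity in the canonical channels x time orientation plus
#' the time axis and probe geometry.
#'
#' @param intensity Numeric matrix, measurement rows x time points.
#' @param time Strictly increasing time vector in seconds, one entry per column.
#' @param probe A [probe_geometry()].
#' @param subject_id Label for the recording.
#' @return A `raw_recording` object with a derived `sampling_rate` (Hz).
#' @export
raw_recording <- function(intensity, time, probe, subject_id = "subject") {
  intensity <- as.matrix(intensity)
  time <- as.numeric(time)
  if (ncol(intensity) != length(time))
    stop("time length (", length(time), ") does not match intensity columns (",
         ncol(intensity), ")")
  if (nrow(intensity) != nrow(probe$meas_list))
    stop("intensity rows (", nrow(intensity), ") do not match measurement list (",
         nrow(probe$meas_list), ")")
  dt <- diff(time)
  if (any(dt <= 0)) stop("time vector not increasing")
  if (length(dt) > 1 && (max(dt) - min(dt)) / mean(dt) > 1e-6)
    stop("time vector is not uniformly sampled (relative tolerance 1e-6)")
  structure(list(intensity = intensity, time = time,
                 sampling_rate = 1 / mean(dt), probe = probe,
                 subject_id = subject_id),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("fNIRS raw recording '%s': %d measurement rows x %d samples @ %.4g Hz (%.1f s)\n",
              x$subject_id, nrow(x$intensity), ncol(x$intensity),
              x$sampling_rate, diff(range(x$time))))
  cat(sprintf("  %d sources, %d detectors, wavelengths %s nm\n",
              nrow(x$probe$source_pos), nrow(x$probe$detector_pos),
              paste(x$probe$wavelengths, collapse = "/")))
  invisible(x)
}

.probe_to_sd <- function(probe) {
  ml <- cbind(probe$meas_list[, 1], probe$meas_list[, 2], 1, probe$meas_list[, 3])
  list(SrcPos = probe$source_pos, DetPos = probe$detector_pos,
       Lambda = probe$wavelengths, MeasList = ml,
       nSrcs = nrow(probe$source_pos), nDets = nrow(probe$detector_pos),
       Separations = probe$separations)
}

.sd_to_probe <- function(sd) {
  for (f in c("SrcPos", "DetPos", "Lambda", "MeasList"))
    if (is.null(sd[[f]])) stop("missing variable in SD struct: ", f)
  ml <- as.matrix(sd$MeasList)
  wl_col <- if (ncol(ml) >= 4L) 4L else 3L
  probe_geometry(sd$SrcPos, sd$DetPos,
                 cbind(ml[, 1], ml[, 2], ml[, wl_col]),
                 as.numeric(sd$Lambda),
                 separations = if (!is.null(sd$Separations)) as.numeric(sd$Separations))
}

#' Read a .nirs recording
#'
#' Reads a MATLAB-container .nirs file with variables `d` (raw intensity),
#' `t` (time in seconds) and `SD` (probe structure). The on-disk orientation
#' of `d` (time x measurements, the common convention, or the transpose) is
#' auto-detected by matching one dimension to `length(t)`; a square matrix
#' requires the explicit `orientation` argument.
#'
#' @param path File path.
#' @param subject_id Label; defaults to the file name without extension.
#' @param orientation One of "auto", "time_x_channels", "channels_x_time".
#' @return A [raw_recording()] in channels x time orientation.
#' @export
read_nirs <- function(path, subject_id = NULL,
                      orientation = c("auto", "time_x_channels", "channels_x_time")) {
  orientation <- match.arg(orientation)
  vars <- read_mat5(path)
  for (v in c("d", "t", "SD"))
    if (is.null(vars[[v]])) stop("not a valid .nirs file, missing variable: ", v)
  d <- vars$d
  tv <- as.numeric(vars$t)
  nt <- length(tv)
  if (orientation == "auto") {
    if (nrow(d) == nt && ncol(d) == nt && nrow(d) != 1L)
      stop("square intensity matrix: orientation ambiguous, pass orientation=")
    if (ncol(d) == nt) {
      # already channels x time
    } else if (nrow(d) == nt) {
      d <- t(d)
    } else stop("neither dimension of d (", nrow(d), "x", ncol(d),
                ") matches length(t) = ", nt)
  } else if (orientation == "time_x_channels") {
    d <- t(d)
  }
  probe <- .sd_to_probe(vars$SD)
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  raw_recording(d, tv, probe, subject_id)
}

#' Write a .nirs recording
#'
#' Stores the recording in the conventional on-disk layout: `d` as
#' time x measurements, `t` as a time vector, `SD` as a probe struct.
#'
#' @param rec A [raw_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nirs <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  write_mat5(list(d = t(rec$intensity), t = rec$time,
                  SD = .probe_to_sd(rec$probe)), path)
}

# Default stand-in geometry for formats that carry no probe description:
# one source-detector pair per measurement channel, laid out along a line
# with the given separation.
default_probe <- function(n_channels, wavelengths, separation_cm = 3) {
  src <- cbind(separation_cm * (seq_len(n_channels) - 1), 0, 0)
  det <- cbind(separation_cm * (seq_len(n_channels) - 1) + separation_cm, 0, 0)
  ml <- do.call(rbind, lapply(seq_along(wavelengths), function(w)
    cbind(seq_len(n_channels), seq_len(n_channels), w)))
  probe_geometry(src, det, ml, wavelengths)
}

#' Read a Hitachi-style CSV export
#'
#' Reads the documented minimal dialect for ETG-style CSV exports: a header
#' section of `key,value[,value...]` lines which must include
#' `Sampling Period[s]`, an optional `Wavelength[nm]` line, then a line
#' reading `Data`, an optional column-label row, and a rectangular numeric
#' block with one column per measurement row (channel-major across
#' wavelengths). Vendor exports vary; this dialect is a documented stand-in
#' with a configurable separator.
#'
#' @param path File path.
#' @param sep Field separator (default ",").
#' @param separation_cm Assumed source-detector separation for the synthesized
#'   probe geometry (the CSV carries none).
#' @param subject_id Label; defaults to the file name.
#' @return A [raw_recording()].
#' @export
read_hitachi_csv <- function(path, sep = ",", separation_cm = 3,
                             subject_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  data_at <- which(tolower(trimws(lines)) %in% c("data", "data:"))
  if (length(data_at) == 0L)
    stop("no 'Data' marker line found; not in the supported CSV dialect")
  data_at <- data_at[1L]
  header <- list()
  for (ln in lines[seq_len(data_at - 1L)]) {
    parts <- strsplit(ln, sep, fixed = TRUE)[[1L]]
    if (length(parts) >= 2L)
      header[[trimws(parts[1L])]] <- trimws(parts[-1L])
  }
  sp <- header[["Sampling Period[s]"]]
  if (is.null(sp)) stop("missing 'Sampling Period[s]' header line")
  sp <- as.numeric(sp[1L])
  if (!is.finite(sp) || sp <= 0) stop("invalid sampling period: ", sp)
  wavelengths <- if (!is.null(header[["Wavelength[nm]"]]))
    as.numeric(header[["Wavelength[nm]"]]) else c(695, 830)

  if (data_at >= length(lines)) stop("no samples in data block")
  body <- lines[(data_at + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) stop("no samples in data block")
  first_cells <- strsplit(body[1L], sep, fixed = TRUE)[[1L]]
  # a column-label row is entirely non-numeric; a stray bad cell in an
  # otherwise numeric row must be reported as an error below instead
  has_labels <- all(is.na(suppressWarnings(as.numeric(first_cells))))
  if (has_labels) body <- body[-1L]
  if (length(body) == 0L) stop("no samples in data block")
  rows <- strsplit(body, sep, fixed = TRUE)
  ncols <- length(rows[[1L]])
  vals <- matrix(NA_real_, length(rows), ncols)
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) != ncols)
      stop("ragged data block at row ", i, ": expected ", ncols, " columns")
    v <- suppressWarnings(as.numeric(rows[[i]]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1L]
      stop("non-numeric cell in data block at row ", i, ", column ", j)
    }
    vals[i, ] <- v
  }
  n_wl <- length(wavelengths)
  if (ncols %% n_wl != 0L)
    stop("column count (", ncols, ") is not a multiple of the wavelength count (",
         n_wl, ")")
  n_channels <- ncols %/% n_wl
  # columns are channel-major: ch1-wl1, ch1-wl2, ch2-wl1, ...; reorder to the
  # .nirs convention of wavelength-major measurement rows
  chan_of_col <- rep(seq_len(n_channels), each = n_wl)
  wl_of_col <- rep(seq_len(n_wl), times = n_channels)
  ord <- order(wl_of_col, chan_of_col)
  intensity <- t(vals[, ord, drop = FALSE])
  probe <- default_probe(n_channels, wavelengths, separation_cm)
  tv <- (seq_len(nrow(vals)) - 1L) * sp
  if (is.null(subject_id)) subject_id <- sub("\\.[^.]*$", "", basename(path))
  raw_recording(intensity, tv, probe, subject_id)
}

#' Convert a Hitachi-style CSV to .nirs
#'
#' @param in_path CSV input (see [read_hitachi_csv()]).
#' @param out_path .nirs output.
#' @param ... Passed to [read_hitachi_csv()].
#' @return `out_path`, invisibly.
#' @export
convert_csv_to_nirs <- function(in_path, out_path, ...) {
  write_nirs(read_hitachi_csv(in_path, ...), out_path)
  invisible(out_path)
}

#' Processed recording ("proc" record)
#'
#' Bundles a raw recording with its optical-density matrix, concentration
#' series, probe, and an append-only processing history.
#'
#' @param raw A [raw_recording()].
#' @param od Optical-density matrix (channels x time) or NULL.
#' @param conc A [conc_series()] or NULL when concentrations have not been
#'   computed yet.
#' @param history Data frame with columns `step`, `params`, `timestamp`.
#' @return A `proc_record` object.
#' @export
proc_record <- function(raw, od = NULL, conc = NULL, history = NULL) {
  stopifnot(inherits(raw, "raw_recording"))
  if (!is.null(od)) {
    od <- as.matrix(od)
    stopifnot(all(dim(od) == dim(raw$intensity)))
  }
  if (!is.null(conc)) {
    stopifnot(inherits(conc, "conc_series"))
    if (ncol(conc$hbo) != ncol(raw$intensity))
      stop("concentration series and raw recording disagree on time axis")
  }
  if (is.null(history))
    history <- data.frame(step = character(0), params = character(0),
                          timestamp = character(0))
  structure(list(raw = raw, od = od, conc = conc, probe = raw$probe,
                 history = history),
            class = "proc_record")
}

#' @export
print.proc_record <- function(x, ...) {
  cat(sprintf("proc record '%s': %d measurement rows, %d samples\n",
              x$raw$subject_id, nrow(x$raw$intensity), ncol(x$raw$intensity)))
  cat(sprintf("  OD: %s; concentrations: %s; history: %d step(s)\n",
              if (is.null(x$od)) "missing" else "present",
              if (is.null(x$conc)) "missing" else "present",
              nrow(x$history)))
  invisible(x)
}

# Append one step to a proc record's history.
add_history <- function(rec, step, params = "") {
  rec$history <- rbind(rec$history, data.frame(
    step = step, params = params,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  rec
}

#' Write / read a .proc record
#'
#' The on-disk layout mirrors the four-field MATLAB convention: `RawData`
#' (struct with `d` time x measurements and `t`), `OD` (time x measurements),
#' `Conc` (struct with `HbO`, `HbR`, `HbT`, each time x channels), `SD`
#' (probe struct), plus a `History` struct of string cells. Missing OD or
#' concentrations are stored as empty arrays and flagged on read.
#'
#' @param rec A [proc_record()].
#' @param path File path.
#' @return `write_proc` returns `path` invisibly; `read_proc` returns the
#'   [proc_record()].
#' @export
write_proc <- function(rec, path) {
  stopifnot(inherits(rec, "proc_record"))
  empty <- matrix(numeric(0), 0L, 0L)
  conc_field <- if (is.null(rec$conc)) {
    list(HbO = empty, HbR = empty, HbT = empty, time = empty)
  } else {
    list(HbO = t(rec$conc$hbo), HbR = t(rec$conc$hbr), HbT = t(rec$conc$hbt),
         time = rec$conc$time)
  }
  vars <- list(
    RawData = list(d = t(rec$raw$intensity), t = rec$raw$time,
                   subject = rec$raw$subject_id),
    OD = if (is.null(rec$od)) empty else t(rec$od),
    Conc = conc_field,
    SD = .probe_to_sd(rec$probe),
    History = list(step = as.list(rec$history$step),
                   params = as.list(rec$history$params),
                   timestamp = as.list(rec$history$timestamp)))
  write_mat5(vars, path)
}

#' @rdname write_proc
#' @export
read_proc <- function(path) {
  vars <- read_mat5(path)
  for (v in c("RawData", "OD", "Conc", "SD"))
    if (is.null(vars[[v]])) stop("not a valid .proc file, missing field: ", v)
  probe <- .sd_to_probe(vars$SD)
  raw <- raw_recording(t(vars$RawData$d), as.numeric(vars$RawData$t), probe,
                       subject_id = if (!is.null(vars$RawData$subject))
                         vars$RawData$subject else "subject")
  od <- if (length(vars$OD) == 0L) NULL else t(vars$OD)
  conc <- if (length(vars$Conc$HbO) == 0L) {
    NULL
  } else {
    conc_series(hbo = t(vars$Conc$HbO), hbr = t(vars$Conc$HbR),
                time = as.numeric(vars$Conc$time))
  }
  history <- if (!is.null(vars$History) && length(vars$History$step) > 0L) {
    data.frame(step = unlist(vars$History$step, use.names = FALSE),
               params = unlist(vars$History$params, use.names = FALSE),
               timestamp = unlist(vars$History$timestamp, use.names = FALSE))
  } else NULL
  rec <- proc_record(raw, od = od, conc = conc, history = history)
  if (is.null(conc)) message("proc record read: concentration missing")
  rec
}
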