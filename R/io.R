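# ---- delimited (CSV) recordings --------------------------------------------

# pad/truncate an ascii field to exactly n bytes
edf_field <- function(x, n) {
  s <- substr(as.character(x), 1, n)
  formatC(s, width = -n, flag = " ")
}

#' Read and write multichannel recordings
#'
#' Two on-disk formats are supported: a plain delimited matrix (CSV, channels
#' as columns with electrode-label header, samples as rows, amplitudes in uV)
#' and 16-bit EDF (European Data Format; one file per subject, physical units
#' uV). On reading, channel labels are normalized (case-insensitive, a
#' reference suffix such as `-Av` is stripped) and the channels are reordered
#' to the standard montage; files with missing or extra channels raise an
#' error naming them. EDF amplitudes are quantized to 16 bits, so a
#' write/read round trip agrees to within one quantization step.
#'
#' @param path File path; format is chosen by extension (`.edf` vs anything
#'   else) unless `format` is given.
#' @param format `"auto"`, `"edf"` or `"csv"`.
#' @param fs Sampling rate in Hz, required for CSV input (EDF carries it in
#'   the header).
#' @param subject_id,group Metadata attached on read (CSV carries none).
#' @return `read_recording()` returns an `eeg_recording`.
#' @export
read_recording <- function(path, format = c("auto", "edf", "csv"), fs = 250,
                           subject_id = sub("\\.[^.]*$", "", basename(path)),
                           group = "unknown") {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (format == "csv") {
    tab <- utils::read.csv(path, check.names = FALSE)
    data <- t(as.matrix(tab))
    labels <- normalize_channel_labels(rownames(data))
  } else {
    r <- read_edf_raw(path)
    data <- r$data
    labels <- normalize_channel_labels(r$labels)
    fs <- r$fs
  }
  ref <- montage_1020()
  missing <- setdiff(ref, labels)
  extra <- setdiff(labels, ref)
  if (length(missing) || length(extra))
    stop("channel mismatch; missing: ",
         if (length(missing)) paste(missing, collapse = ", ") else "none",
         "; extra: ",
         if (length(extra)) paste(extra, collapse = ", ") else "none")
  rownames(data) <- labels
  data <- data[ref, , drop = FALSE]
  cfg <- recording_config(n_channels = length(ref), channel_labels = ref,
                          fs = fs, duration = ncol(data) / fs)
  structure(list(data = data, config = cfg, subject_id = subject_id,
                 group = group),
            class = "eeg_recording")
}

#' @rdname read_recording
#' @param recording An `eeg_recording` to write.
#' @export
write_recording <- function(recording, path, format = c("auto", "edf",
                                                        "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (format == "csv") {
    tab <- as.data.frame(t(recording$data))
    names(tab) <- recording$config$channel_labels
    utils::write.csv(tab, path, row.names = FALSE)
  } else {
    write_edf_raw(recording$data, recording$config$fs, path,
                  patient = recording$subject_id)
  }
  invisible(path)
}

# Minimal EDF writer: 16-bit, physical units uV, a single data record holding
# the whole signal (record duration = n / fs seconds).
write_edf_raw <- function(data, fs, path, patient = "X") {
  ns <- nrow(data)
  n <- ncol(data)
  pmin <- apply(data, 1, min); pmax <- apply(data, 1, max)
  flat <- pmax - pmin == 0
  pmax[flat] <- pmax[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8), edf_field(patient, 80), edf_field("qeegnl", 80),
    edf_field("01.01.26", 8), edf_field("00.00.00", 8),
    edf_field(256 * (1 + ns), 8), edf_field("", 44),
    edf_field(1, 8), edf_field(format(n / fs, digits = 7), 8),
    edf_field(ns, 4))
  sig <- paste0(
    paste(vapply(rownames(data), edf_field, "", n = 16), collapse = ""),
    paste(rep(edf_field("", 80), ns), collapse = ""),
    paste(rep(edf_field("uV", 8), ns), collapse = ""),
    paste(vapply(pmin, function(x) edf_field(format(x, digits = 7), 8), ""),
          collapse = ""),
    paste(vapply(pmax, function(x) edf_field(format(x, digits = 7), 8), ""),
          collapse = ""),
    paste(rep(edf_field(dmin, 8), ns), collapse = ""),
    paste(rep(edf_field(dmax, 8), ns), collapse = ""),
    paste(rep(edf_field("", 80), ns), collapse = ""),
    paste(rep(edf_field(n, 8), ns), collapse = ""),
    paste(rep(edf_field("", 32), ns), collapse = ""))
  writeChar(paste0(hdr, sig), con, eos = NULL)
  for (ch in seq_len(ns)) {
    dig <- round((data[ch, ] - pmin[ch]) / (pmax[ch] - pmin[ch]) *
                   (dmax - dmin) + dmin)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

# Minimal EDF reader for the layout written above (any record count).
read_edf_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  vapply(seq_len(ns), function(i) rd(80), "")  # transducer
  vapply(seq_len(ns), function(i) rd(8), "")   # phys dim
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(80), "")  # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(32), "")  # reserved
  chunks <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    rec <- lapply(seq_len(ns), function(ch) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2, signed = TRUE,
                     endian = "little")
      (dig - dmin[ch]) / (dmax[ch] - dmin[ch]) * (pmax[ch] - pmin[ch]) +
        pmin[ch]
    })
    chunks[[r]] <- rec
  }
  data <- do.call(rbind, lapply(seq_len(ns), function(ch)
    unlist(lapply(chunks, `[[`, ch))))
  rownames(data) <- labels
  list(data = data, labels = labels, fs = spr[1] / rec_dur)
}

# ---- feature tables ---------------------------------------------------------

#' Read and write feature tables
#'
#' Feature tables are UTF-8 CSV with a header row: `subject_id`, `group`,
#' then the 57 feature columns (`RE_C1` ... `LZC_C19`). [write_arff()] exports
#' the same table in ARFF for interoperability with Weka-style tools.
#'
#' @param features A feature table.
#' @param path File path.
#' @export
write_feature_table <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' @rdname write_feature_table
#' @param relation ARFF relation name.
#' @export
write_arff <- function(features, path, relation = "qeegnl_features") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@relation ", relation), con)
  for (nm in names(features)) {
    if (is.numeric(features[[nm]])) {
      writeLines(paste0("@attribute ", nm, " numeric"), con)
    } else {
      lev <- unique(features[[nm]])
      writeLines(paste0("@attribute ", nm, " {",
                        paste(lev, collapse = ","), "}"), con)
    }
  }
  writeLines("@data", con)
  utils::write.table(features, con, sep = ",", col.names = FALSE,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
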