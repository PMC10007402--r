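# File readers and writers: delimited feature tables, delimited multichannel
# EEG time series, and a minimal reader for continuous 16-bit EDF recordings.

#' Write a feature table to a tab-separated file
#'
#' One row per commercial viewing: identifier columns (`participant`,
#' `product`, `viewing`, optionally `label`) followed by the named feature
#' columns, with a header row.
#'
#' @param ft data frame (e.g. from [feature_table()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  utils::write.table(ft, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path input path.
#' @return a data frame.
#' @export
read_feature_table <- function(path) {
  ft <- utils::read.delim(path, check.names = FALSE)
  if (nrow(ft) == 0L) stop("empty feature table: ", path)
  ft
}

# split a feature table into the numeric feature matrix (features x samples)
# and the label vector named by `label_col`
feature_matrix_from_table <- function(ft, label_col = "label") {
  if (!label_col %in% names(ft))
    stop("feature table has no '", label_col, "' column")
  id_cols <- intersect(c("participant", "product", "viewing", label_col), names(ft))
  feat <- as.matrix(ft[, setdiff(names(ft), id_cols), drop = FALSE])
  if (!is.numeric(feat)) stop("non-numeric feature columns in table")
  labels <- as.integer(ft[[label_col]])
  if (anyNA(labels) || min(labels) < 1L)
    stop("labels must be positive integers (1-based classes)")
  list(x = t(feat), labels = labels)
}

#' Write an EEG trial as a delimited time-series file
#'
#' Tab-separated, one header row of channel names, one row per sample. A
#' `# rate=<Hz> participant=<i> product=<i> viewing=<i>` comment line
#' precedes the header.
#'
#' @param trial an [eeg_trial()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eeg_tsv <- function(trial, path) {
  stopifnot(inherits(trial, "eeg_trial"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate=%g participant=%d product=%d viewing=%d",
                     trial$rate, trial$participant_id, trial$product_id,
                     trial$viewing_id), con)
  utils::write.table(t(trial$data), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = trial$channel_names)
  invisible(path)
}

#' Read an EEG trial from a delimited time-series file
#'
#' Accepts the format of [write_eeg_tsv()]: an optional `#`-prefixed
#' metadata line (`rate`, `participant`, `product`, `viewing` as
#' `key=value`), then a channel-name header row, then one row per sample.
#'
#' @param path input path.
#' @param rate fallback sampling rate when no metadata line is present.
#' @return an [eeg_trial()].
#' @export
read_eeg_tsv <- function(path, rate = 500) {
  first <- readLines(path, n = 1L)
  meta <- list(rate = rate, participant = 1L, product = 1L, viewing = 1L)
  skip <- 0L
  if (startsWith(first, "#")) {
    skip <- 1L
    for (kv in strsplit(trimws(sub("^#", "", first)), "\\s+")[[1]]) {
      parts <- strsplit(kv, "=", fixed = TRUE)[[1]]
      if (length(parts) == 2L) meta[[parts[1]]] <- as.numeric(parts[2])
    }
  }
  d <- utils::read.delim(path, skip = skip, check.names = FALSE)
  eeg_trial(t(as.matrix(d)), rate = meta$rate,
            channel_names = colnames(d),
            participant_id = meta$participant, product_id = meta$product,
            viewing_id = meta$viewing)
}

#' Read a continuous EDF recording
#'
#' Minimal reader for the European Data Format: parses the 256-byte global
#' header and per-signal headers, decodes the 16-bit little-endian data
#' records, and rescales each signal from digital to physical units with its
#' stored calibration. Annotation channels (`EDF Annotations`) are dropped.
#' Discontinuous (EDF+D) files are not supported.
#'
#' @param path EDF file path.
#' @param participant_id,product_id,viewing_id identifiers to attach.
#' @return an [eeg_trial()] when the montage channels are present, otherwise
#'   a plain list with `data`, `rate`, `channel_names`.
#' @export
read_edf <- function(path, participant_id = 1L, product_id = 1L, viewing_id = 1L) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd_str <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  version <- rd_str(8)
  if (!identical(version, "0")) stop("not an EDF file (version field '", version, "')")
  rd_str(80); rd_str(80); rd_str(8); rd_str(8)   # patient, recording, date, time
  header_bytes <- as.integer(rd_str(8))
  reserved <- rd_str(44)
  if (grepl("EDF\\+D", reserved)) stop("discontinuous EDF+D files are not supported")
  n_records <- as.integer(rd_str(8))
  record_dur <- as.numeric(rd_str(8))
  ns <- as.integer(rd_str(4))
  if (is.na(ns) || ns < 1) stop("corrupt EDF header")

  fld <- function(w) vapply(seq_len(ns), function(i) rd_str(w), character(1))
  labels <- fld(16)
  fld(80); fld(8)                                 # transducer, physical dim
  phys_min <- as.numeric(fld(8)); phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8)); dig_max <- as.numeric(fld(8))
  fld(80)                                         # prefiltering
  samples_per_rec <- as.integer(fld(8))
  fld(32)                                         # reserved
  seek(con, header_bytes)

  keep <- labels != "EDF Annotations"
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_min - gain * dig_min
  total <- samples_per_rec * n_records
  data <- lapply(seq_len(ns), function(i) if (keep[i]) numeric(total[i]) else NULL)
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      v <- readBin(con, "integer", n = samples_per_rec[i], size = 2,
                   signed = TRUE, endian = "little")
      if (keep[i])
        data[[i]][((r - 1) * samples_per_rec[i] + 1):(r * samples_per_rec[i])] <-
          gain[i] * v + offset[i]
    }
  }
  kept <- which(keep)
  rate <- samples_per_rec[kept] / record_dur
  if (length(unique(rate)) != 1L)
    stop("mixed sampling rates across EDF signals are not supported")
  mat <- do.call(rbind, data[kept])
  # EDF labels often carry a type prefix such as "EEG Fp1"
  ch <- sub("^EEG ", "", labels[kept])
  if (all(eeg_channel_names() %in% ch))
    eeg_trial(mat, rate = rate[1], channel_names = ch,
              participant_id = participant_id, product_id = product_id,
              viewing_id = viewing_id)
  else
    list(data = mat, rate = rate[1], channel_names = ch)
}

#' Write a numeric matrix as a delimited file (debug helper)
#'
#' Used to dump adjacency/Laplacian/prior matrices or solver traces for
#' inspection.
#'
#' @param m numeric matrix or vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(as.matrix(m), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
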