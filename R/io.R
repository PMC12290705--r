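# File I/O: the project trial container (R-native serialization of an
# explicit list layout), a minimal EDF reader, mono WAV read/write, and
# YAML/JSON configuration.

#' Write a trial container
#'
#' Serializes a list of trials to disk. Each trial holds `X` (channels x
#' samples), `audio`, `onset_index`, optionally `truth` (`S`, `A`, `agr_db`),
#' with top-level `fs` and `channel_names`.
#'
#' @param trials list of [trial_epoch()] objects (or plain lists with the
#'   same fields).
#' @param path output file path.
#' @param fs sampling rate (Hz); taken from the first trial when `NULL`.
#' @param channel_names optional channel labels.
#' @param truths optional list of `sim_truth` objects, one per trial.
#' @return `path`, invisibly.
#' @export
write_trial_container <- function(trials, path, fs = NULL,
                                  channel_names = NULL, truths = NULL) {
  stopifnot(length(trials) >= 1)
  if (is.null(fs)) fs <- trials[[1]]$fs
  if (is.null(channel_names))
    channel_names <- sprintf("ch%02d", seq_len(nrow(trials[[1]]$X)))
  obj <- list(
    format = "pcdenoise-trial-container",
    version = 1L,
    fs = fs,
    channel_names = channel_names,
    trials = lapply(seq_along(trials), function(i) {
      tr <- trials[[i]]
      out <- list(X = tr$X, audio = tr$audio,
                  onset_index = tr$onset_index)
      if (!is.null(truths)) {
        tt <- truths[[i]]
        out$truth <- list(S = rbind(tt$S_neural, tt$s_artifact),
                          A = tt$A_mix, agr_db = tt$agr_db)
      }
      out
    })
  )
  saveRDS(obj, path)
  invisible(path)
}

#' Read a trial container
#'
#' @param path file written by [write_trial_container()].
#' @return list with `fs`, `channel_names`, `trials` (each a
#'   [trial_epoch()] with optional `truth` attached as an attribute).
#' @export
read_trial_container <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "pcdenoise-trial-container"))
    stop("not a pcdenoise trial container: ", path)
  trials <- lapply(obj$trials, function(tr) {
    te <- trial_epoch(tr$X, tr$audio, tr$onset_index, fs = obj$fs)
    if (!is.null(tr$truth)) attr(te, "truth") <- tr$truth
    te
  })
  list(fs = obj$fs, channel_names = obj$channel_names, trials = trials)
}

#' Read a recording from EDF or a trial container
#'
#' EDF files must have a single common sampling rate across channels;
#' resampling is out of scope and mixed-rate files are rejected with the
#' offending channels named.
#'
#' @param path an EDF file or a trial container.
#' @return a [recording()] (EDF) or the result of [read_trial_container()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.edf$", path, ignore.case = TRUE)) return(read_edf(path))
  read_trial_container(path)
}

#' Minimal EDF reader
#'
#' Parses the European Data Format header and 16-bit sample records and
#' applies the per-channel physical scaling. Annotation channels are
#' dropped.
#'
#' @param path EDF file.
#' @return a [recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_str <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  version <- hdr_str(8)
  if (version != "0") stop("not an EDF file (version field '", version, "')")
  hdr_str(80); hdr_str(80); hdr_str(8); hdr_str(8)   # ids, date, time
  hdr_str(8)                                          # header bytes
  hdr_str(44)                                         # reserved
  n_rec <- as.integer(hdr_str(8))
  rec_dur <- as.numeric(hdr_str(8))
  ns <- as.integer(hdr_str(4))
  field <- function(w) vapply(seq_len(ns), function(i) hdr_str(w), "")
  labels <- field(16)
  field(80)                                           # transducer
  field(8)                                            # physical dimension
  phys_min <- as.numeric(field(8))
  phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8))
  dig_max <- as.numeric(field(8))
  field(80)                                           # prefiltering
  spr <- as.integer(field(8))                         # samples per record
  field(32)                                           # reserved
  keep <- !grepl("annotation", labels, ignore.case = TRUE)
  fs_all <- spr / rec_dur
  if (length(unique(fs_all[keep])) > 1) {
    stop("inconsistent sampling rates across channels: ",
         paste(sprintf("%s=%g Hz", labels[keep], fs_all[keep]),
               collapse = ", "))
  }
  data <- vector("list", ns)
  for (i in seq_len(ns)) data[[i]] <- numeric(n_rec * spr[i])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[i], size = 2, endian = "little")
      data[[i]][(r - 1) * spr[i] + seq_len(spr[i])] <- raw
    }
  }
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_min - gain * dig_min
  X <- do.call(rbind, lapply(which(keep), function(i) {
    data[[i]] * gain[i] + offset[i]
  }))
  recording(X, fs = unique(fs_all[keep]), channel_names = labels[keep])
}

#' Read a mono WAV file
#'
#' Supports 16-bit PCM and 32-bit IEEE float; multichannel files are
#' averaged to mono.
#'
#' @param path WAV file.
#' @return list with `wave` (float in `[-1, 1]` for PCM) and `fs`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (rawToChar(readBin(con, "raw", 4)) != "RIFF") stop("not a RIFF file")
  readBin(con, "integer", 1, 4, endian = "little")
  if (rawToChar(readBin(con, "raw", 4)) != "WAVE") stop("not a WAV file")
  fmt <- NULL; wave <- NULL
  repeat {
    id_raw <- readBin(con, "raw", 4)
    if (length(id_raw) < 4) break
    id <- rawToChar(id_raw)
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, 2, endian = "little"),
        n_channels = readBin(con, "integer", 1, 2, endian = "little"),
        fs = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate = readBin(con, "integer", 1, 4, endian = "little"),
        block_align = readBin(con, "integer", 1, 2, endian = "little"),
        bits = readBin(con, "integer", 1, 2, endian = "little")
      )
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (id == "data") {
      stopifnot(!is.null(fmt))
      n <- size / (fmt$bits / 8)
      wave <- if (fmt$audio_format == 3 && fmt$bits == 32) {
        readBin(con, "double", n, size = 4, endian = "little")
      } else if (fmt$audio_format == 1 && fmt$bits == 16) {
        readBin(con, "integer", n, size = 2, endian = "little") / 32768
      } else {
        stop("unsupported WAV encoding (format ", fmt$audio_format,
             ", ", fmt$bits, " bit)")
      }
      break
    } else {
      readBin(con, "raw", size)
    }
  }
  if (is.null(wave)) stop("no data chunk in WAV file")
  if (fmt$n_channels > 1) {
    wave <- colMeans(matrix(wave, nrow = fmt$n_channels))
  }
  list(wave = wave, fs = fmt$fs)
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param wave waveform; rescaled to the PCM range by its maximum absolute
#'   value when it exceeds 1.
#' @param fs sampling rate (Hz).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, fs, path) {
  m <- max(abs(wave), 1)
  pcm <- as.integer(round(pmin(pmax(wave / m, -1), 32767 / 32768) * 32768))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_size, con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")        # PCM
  writeBin(1L, con, size = 2, endian = "little")        # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a YAML or JSON session configuration
#'
#' @param path configuration file (`.yml`/`.yaml`/`.json`).
#' @return named list of configuration values.
#' @export
read_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}
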