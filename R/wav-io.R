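#' Write a mono waveform to a RIFF WAV file
#'
#' Writes 16-bit PCM (default) or IEEE float32 mono WAV.  16-bit samples are
#' clipped to \[-1, 1\] and scaled by 32767.
#'
#' @param recording An [audio_recording()] object, or a numeric waveform.
#' @param path Output file path.
#' @param sample_rate Sample rate in Hz; taken from the recording if omitted.
#' @param format `"pcm16"` or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(recording, path, sample_rate = NULL, format = c("pcm16", "float32")) {
  format <- match.arg(format)
  if (inherits(recording, "audio_recording")) {
    samples <- recording$samples
    if (is.null(sample_rate)) sample_rate <- recording$sample_rate
  } else {
    samples <- as.numeric(recording)
    if (is.null(sample_rate)) stop("sample_rate required for a bare waveform")
  }
  n <- length(samples)
  con <- file(path, "wb")
  on.exit(close(con))
  bits <- if (format == "pcm16") 16L else 32L
  bytes_per <- bits %/% 8L
  data_size <- n * bytes_per
  audio_format <- if (format == "pcm16") 1L else 3L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(audio_format, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (format == "pcm16") {
    x <- pmax(-1, pmin(1, samples))
    writeBin(as.integer(round(x * 32767)), con, size = 2, endian = "little")
  } else {
    writeBin(samples, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a mono RIFF WAV file
#'
#' Supports 16-bit PCM and IEEE float32 mono files (the formats
#' [write_wav()] emits).  PCM samples are rescaled to \[-1, 1\].
#'
#' @param path WAV file path.
#' @return A list with `samples` and `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, integer(), size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stop_callscore("not a RIFF/WAVE file", "callscore_bad_wav")
  }
  audio_format <- NA_integer_; n_channels <- NA_integer_
  sample_rate <- NA_integer_; bits <- NA_integer_
  samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      audio_format <- readBin(con, integer(), size = 2, endian = "little")
      n_channels <- readBin(con, integer(), size = 2, endian = "little")
      sample_rate <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      extra <- size - 16L
      if (extra > 0L) readBin(con, raw(), n = extra)
    } else if (identical(id, "data")) {
      if (audio_format == 1L && bits == 16L) {
        samples <- readBin(con, integer(), n = size %/% 2L, size = 2,
                           signed = TRUE, endian = "little") / 32767
      } else if (audio_format == 3L && bits == 32L) {
        samples <- readBin(con, numeric(), n = size %/% 4L, size = 4,
                           endian = "little")
      } else {
        stop_callscore("unsupported WAV encoding", "callscore_bad_wav")
      }
      break
    } else {
      readBin(con, raw(), n = size + size %% 2L)
    }
  }
  if (is.null(samples)) stop_callscore("no data chunk found", "callscore_bad_wav")
  if (n_channels != 1L) stop_callscore("only mono WAV supported", "callscore_bad_wav")
  list(samples = samples, sample_rate = sample_rate)
}

#' Write region-of-interest annotations
#'
#' One line per ROI: `start_s<TAB>end_s<TAB>class_id`, compatible with
#' common audio-annotation tab formats.
#'
#' @param recording An [audio_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_roi <- function(recording, path) {
  rois <- recording$rois
  df <- data.frame(start_s = vapply(rois, `[`, numeric(1), 1L),
                   end_s = vapply(rois, `[`, numeric(1), 2L),
                   class_id = recording$class_label)
  if (length(rois) == 0L) df <- df[0, ]
  write.table(df, path, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Read region-of-interest annotations written by [write_roi()]
#'
#' @param path Annotation file path.
#' @return A data frame with columns `start_s`, `end_s`, `class_id`.
#' @export
read_roi <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      class_id = integer(0)))
  }
  df <- read.table(path, sep = "\t", col.names = c("start_s", "end_s", "class_id"))
  df
}

#' Write a synthetic dataset to disk
#'
#' Writes one WAV and one ROI annotation file per recording plus a manifest
#' CSV (`path,class_id,duration_s`).
#'
#' @param dataset A list of [audio_recording()] objects.
#' @param dir Output directory (created if absent).
#' @param format WAV sample format, see [write_wav()].
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir, format = "pcm16") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(dataset), function(i) {
    rec <- dataset[[i]]
    base <- sprintf("rec%04d", i)
    write_wav(rec, file.path(dir, paste0(base, ".wav")), format = format)
    write_roi(rec, file.path(dir, paste0(base, ".roi.txt")))
    data.frame(path = paste0(base, ".wav"), class_id = rec$class_label,
               duration_s = length(rec$samples) / rec$sample_rate)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir Dataset directory containing `manifest.csv`.
#' @return A list of [audio_recording()] objects.
#' @export
read_dataset <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  lapply(seq_len(nrow(manifest)), function(i) {
    wav <- read_wav(file.path(dir, manifest$path[i]))
    roi_path <- file.path(dir, sub("\\.wav$", ".roi.txt", manifest$path[i]))
    rois <- if (file.exists(roi_path)) {
      df <- read_roi(roi_path)
      lapply(seq_len(nrow(df)), function(j) c(df$start_s[j], df$end_s[j]))
    } else list()
    audio_recording(wav$samples, wav$sample_rate,
                    class_label = manifest$class_id[i], rois = rois)
  })
}
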