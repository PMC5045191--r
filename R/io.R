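# Plain-text persistence and optional external-data adapters.

#' Persist and reload patch ensembles
#'
#' Ensembles are written as a CSV data matrix plus a JSON metadata sidecar
#' (`<path>.meta.json`) carrying geometry, whitening tag and provenance.
#'
#' @param ensemble a [patch_ensemble].
#' @param path CSV file path.
#' @export
write_ensemble <- function(ensemble, path) {
  utils::write.table(ensemble_data(ensemble), path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(geometry = ensemble_geometry(ensemble),
               whitened = ensemble$whitened,
               provenance = serialize_provenance(ensemble$provenance))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

# Reduce arbitrary provenance entries to JSON-representable values: functions
# and big objects become summaries, classed lists are unclassed recursively.
serialize_provenance <- function(p) {
  simplify <- function(x) {
    if (is.function(x)) return("<function>")
    if (is.matrix(x)) return(sprintf("<matrix %d x %d>", nrow(x), ncol(x)))
    if (is.list(x)) return(lapply(unclass(x), simplify))
    attributes(x) <- attributes(x)["names"]
    x
  }
  lapply(p, simplify)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  X <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(X) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  patch_ensemble(X, meta$geometry, whitened = meta$whitened,
                 provenance = as.list(meta$provenance))
}

#' Persist and reload network states
#'
#' Weights are written as CSVs (`<stem>_W.csv`, `<stem>_V.csv`,
#' `<stem>_ymean.csv`).
#'
#' @param state a [network_state()].
#' @param stem file path stem.
#' @export
write_network_state <- function(state, stem) {
  utils::write.table(state$W, paste0(stem, "_W.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(state$V, paste0(stem, "_V.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(matrix(state$y_mean, nrow = 1), paste0(stem, "_ymean.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(stem)
}

#' @rdname write_network_state
#' @export
read_network_state <- function(stem) {
  W <- as.matrix(utils::read.table(paste0(stem, "_W.csv"), sep = ","))
  V <- as.matrix(utils::read.table(paste0(stem, "_V.csv"), sep = ","))
  ym <- as.numeric(utils::read.table(paste0(stem, "_ymean.csv"), sep = ","))
  dimnames(W) <- NULL; dimnames(V) <- NULL
  network_state(W, V, ym)
}

#' Spike trains as two-column CSV
#'
#' Columns `neuron` (id) and `time_ms`; one file may hold several trains.
#'
#' @param trains named list of [spike_train()]s.
#' @param path CSV path.
#' @export
write_spike_trains <- function(trains, path) {
  df <- do.call(rbind, lapply(names(trains), function(nm) {
    if (length(trains[[nm]]$times) == 0) return(NULL)
    data.frame(neuron = nm, time_ms = trains[[nm]]$times)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_trains
#' @param duration common train duration, ms.
#' @export
read_spike_trains <- function(path, duration) {
  df <- utils::read.csv(path)
  lapply(split(df$time_ms, df$neuron), function(t) spike_train(sort(t), duration))
}

#' Read an image stack from PNG/TIFF files (optional adapter)
#'
#' Reads grayscale images (color is averaged to luminance) into a list of
#' matrices, e.g. to feed [sample_patches()] with an external natural-image
#' corpus. Requires the `png`/`tiff` packages.
#'
#' @param paths character vector of image file paths.
#' @export
read_image_stack <- function(paths) {
  lapply(paths, function(p) {
    ext <- tolower(tools::file_ext(p))
    im <- if (ext == "png") {
      if (!requireNamespace("png", quietly = TRUE)) {
        nlh_stop("reading PNG requires the 'png' package", "nlhebb_input_error")
      }
      png::readPNG(p)
    } else if (ext %in% c("tif", "tiff")) {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        nlh_stop("reading TIFF requires the 'tiff' package", "nlhebb_input_error")
      }
      tiff::readTIFF(p)
    } else {
      nlh_stop(paste0("unsupported image format: ", ext), "nlhebb_input_error")
    }
    if (length(dim(im)) == 3) im <- apply(im[, , 1:min(3, dim(im)[3]), drop = FALSE], c(1, 2), mean)
    im
  })
}

#' Minimal PCM WAV reader (optional adapter)
#'
#' Reads mono or multi-channel 8/16/32-bit integer PCM WAV files (channels
#' averaged), returning a waveform with a `sample_rate` attribute for
#' [spectrogram_segments()].
#'
#' @param path WAV file path.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) nlh_stop("not a RIFF/WAV file", "nlhebb_input_error")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE")) {
    nlh_stop("not a WAVE file", "nlhebb_input_error")
  }
  fmt <- NULL; data <- NULL
  while (is.null(data)) {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) nlh_stop("truncated WAV file", "nlhebb_input_error")
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        channels = as.integer(raw[3]) + 256L * as.integer(raw[4]),
        sample_rate = sum(as.integer(raw[5:8]) * 256^(0:3)),
        bits = as.integer(raw[15]) + 256L * as.integer(raw[16]))
    } else if (id == "data") {
      if (is.null(fmt)) nlh_stop("WAV data chunk before fmt", "nlhebb_input_error")
      bytes <- fmt$bits / 8
      n <- sz / bytes
      data <- if (fmt$bits == 8) {
        readBin(con, "integer", n, 1, signed = FALSE) / 127.5 - 1
      } else {
        readBin(con, "integer", n, bytes, signed = TRUE, endian = "little") /
          2^(fmt$bits - 1)
      }
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
  }
  if (fmt$channels > 1) {
    data <- colMeans(matrix(data, fmt$channels))
  }
  structure(data, sample_rate = fmt$sample_rate)
}
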