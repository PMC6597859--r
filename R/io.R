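#' Read a mono audio signal from a WAV file
#'
#' Minimal RIFF/WAVE reader covering integer PCM (8/16/24/32 bit) and IEEE
#' float (32/64 bit) encodings. Stereo or multichannel files are averaged to
#' mono with a warning. Samples are returned on a [-1, 1] scale.
#'
#' @param path Path to a `.wav` file.
#' @return List with `samples` (numeric vector) and `fs` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE")) stop("not a WAVE file")
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        n_channels = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        fs = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate = readBin(con, "integer", 1, 4, endian = "little"),
        block_align = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        bits = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE))
      extra <- sz - 16L
      if (extra > 0) invisible(readBin(con, "raw", extra))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (sz %% 2L == 1L) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2L))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV: missing fmt or data chunk")
  bytes <- fmt$bits %/% 8L
  n <- length(data_raw) %/% bytes
  x <- if (fmt$audio_format == 3L) {
    readBin(data_raw, "double", n, size = bytes, endian = "little")
  } else if (fmt$audio_format == 1L) {
    if (fmt$bits == 8L) {
      (as.numeric(readBin(data_raw, "integer", n, 1, signed = FALSE)) - 128) / 128
    } else if (fmt$bits == 24L) {
      m <- matrix(as.integer(data_raw), nrow = 3)
      v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
      v[v >= 2^23] <- v[v >= 2^23] - 2^24
      v / 2^23
    } else {
      readBin(data_raw, "integer", n, size = bytes, endian = "little") /
        2^(fmt$bits - 1L)
    }
  } else stop("unsupported WAV encoding (format tag ", fmt$audio_format, ")")
  if (fmt$n_channels > 1L) {
    warning("averaging ", fmt$n_channels, " channels to mono")
    x <- rowMeans(matrix(x, ncol = fmt$n_channels, byrow = TRUE))
  }
  list(samples = as.numeric(x), fs = fmt$fs)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write / read an envelope as delimited text with a JSON sidecar
#'
#' One value per line; a `<path>.json` sidecar records the sampling rate and
#' provenance. Round-trips at full double precision.
#'
#' @param env An [envelope()].
#' @param path Output file path.
#' @param source Free-text provenance string stored in the sidecar.
#' @return `path`, invisibly (`read_envelope` returns the [envelope()]).
#' @export
write_envelope <- function(env, path, source = "abtrf") {
  writeLines(formatC(as.numeric(env), format = "g", digits = 17), path)
  jsonlite::write_json(list(fs = sample_rate(env), source = source,
                            n = length(env)),
                       sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_envelope
#' @export
read_envelope <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path))
  envelope(as.numeric(readLines(path)), meta$fs, nonnegative = FALSE)
}

#' Write / read a stimulus representation as TSV with a JSON sidecar
#' @param rep A [stim_rep()].
#' @param path Output file path.
#' @return `path`, invisibly (`read_stim_rep` returns the [stim_rep()]).
#' @export
write_stim_rep <- function(rep, path) {
  utils::write.table(format(unclass(rep), digits = 17, trim = TRUE,
                            scientific = TRUE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(list(fs = sample_rate(rep), labels = colnames(rep)),
                       sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_stim_rep
#' @export
read_stim_rep <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(m) <- NULL
  stim_rep(m, meta$fs, meta$labels)
}

#' Write / read a TRF model as text with a JSON sidecar
#'
#' The weight tensor is stored as a lags x (features * channels) TSV at full
#' double precision; the sidecar records the lag window, sampling rate,
#' lambda, labels and intercept, so the round-trip reproduces the model to
#' text precision (better than 1e-12 relative).
#'
#' @param model A `trf_model`.
#' @param path Output file path.
#' @return `path`, invisibly (`read_trf` returns the `trf_model`).
#' @export
write_trf <- function(model, path) {
  d <- dim(model$weights)
  flat <- matrix(model$weights, d[1], d[2] * d[3])
  utils::write.table(format(flat, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(list(tmin = model$window$tmin, tmax = model$window$tmax,
                            fs = model$fs, lambda = model$lambda,
                            feature_labels = model$feature_labels,
                            channel_labels = model$channel_labels,
                            intercept = model$intercept, dims = d),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trf
#' @export
read_trf <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  flat <- as.matrix(utils::read.table(path, sep = "\t"))
  d <- as.integer(meta$dims)
  win <- lag_window(meta$tmin, meta$tmax, meta$fs)
  wmat <- rbind(matrix(as.numeric(flat), d[1] * d[2], d[3]),
                as.numeric(meta$intercept))
  make_trf(wmat, win, meta$lambda, as.character(meta$feature_labels),
           as.character(meta$channel_labels))
}

#' Default run configuration
#'
#' All tunables of the end-to-end pipeline in one serialisable list. The
#' defaults reproduce the package's reference conditions: 8 amplitude bins
#' of 8 dB, lag window -100 to 400 ms, 7 selected channels, 100 permutation
#' repetitions.
#'
#' @param ... Overrides of the default fields.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(...) {
  cfg <- list(
    preset = "sim-ambbn",       # sim-ambbn | sim-speech
    n_subjects = 10,
    n_trials = 20, trial_seconds = 60, fs = 128, n_channels = 32,
    snr_db = 0, latency_shift = 11, onset_pathway = FALSE,
    width_db = 8, n_bins = 8, spl_floor_db = -80,
    tmin = -100, tmax = 400,
    lambda_grid = default_lambda_grid(),
    n_channels_select = 7,
    models = c("env", "spl", "onset", "ab", "ab_plus_onset"),
    null_reps = 100,
    highpass_hz = 1, var_lo = 0.5, var_hi = 2, neighbor_k = 2,
    seed = 1, out_dir = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Save / load a run configuration as YAML
#' @param config A [run_config()].
#' @param path File path.
#' @return `path` invisibly; `read_run_config` returns the [run_config()].
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}
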