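# External interfaces: delimited tables for trajectories/states/events/
# features, float64 binary arrays with JSON sidecars for neural recordings,
# PCM WAV audio, and whole-study serialization with exact round-tripping.

# Tab-separated tables with full double precision (%.17g round-trips IEEE
# doubles exactly through text).
write_table_exact <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_table_exact <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write / read a wrist trajectory as a delimited table
#'
#' Columns: frame, x, y, confidence; frame rate and wrist side in a header
#' comment are not used -- supply them on read.
#' @param traj a [wrist_trajectory()].
#' @param path file path.
#' @export
write_trajectory <- function(traj, path) {
  write_table_exact(data.frame(frame = seq_along(traj$x), x = traj$x,
                               y = traj$y, confidence = traj$confidence),
                    path)
}

#' @rdname write_trajectory
#' @param frame_rate,wrist_side metadata to attach on read.
#' @export
read_trajectory <- function(path, frame_rate = 30,
                            wrist_side = "contralateral") {
  d <- read_table_exact(path)
  wrist_trajectory(d$x, d$y, d$confidence, frame_rate, wrist_side)
}

#' Write / read a state sequence as a delimited table
#' @param states a [state_sequence()].
#' @param path file path.
#' @export
write_states <- function(states, path) {
  df <- data.frame(frame = seq_along(states$labels), label = states$labels)
  if (!is.null(states$posterior)) df$posterior <- states$posterior
  write_table_exact(df, path)
}

#' @rdname write_states
#' @param source provenance flag for the reloaded object.
#' @export
read_states <- function(path, source = "fitted") {
  d <- read_table_exact(path)
  state_sequence(d$label, posterior = d$posterior, source = source)
}

#' Write / read a neural recording as float64 binary + JSON sidecar
#'
#' Voltages are stored column-major (sample-fastest) as little-endian
#' float64 in `<path>.bin`; rate, channel metadata, hemisphere, bad-channel
#' flags and the zeroed-sample mask go to `<path>.json`.
#' @param rec a [neural_recording()].
#' @param path base path (without extension).
#' @export
write_recording <- function(rec, path) {
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(t(rec$voltages)), con, size = 8, endian = "little")
  meta <- list(sample_rate = rec$sample_rate, n_channels = nrow(rec$voltages),
               n_samples = ncol(rec$voltages),
               channel_names = rec$channel_names,
               positions = unname(apply(rec$positions, 1, as.numeric,
                                        simplify = FALSE)),
               group = rec$group, hemisphere = rec$hemisphere,
               is_motor = rec$is_motor, bad_channels = rec$bad_channels,
               zeroed_idx = which(rec$zeroed_mask))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = meta$n_channels * meta$n_samples, size = 8,
               endian = "little")
  V <- matrix(v, nrow = meta$n_channels, byrow = TRUE)
  pos <- if (is.matrix(meta$positions)) meta$positions
         else if (is.list(meta$positions))
           do.call(rbind, lapply(meta$positions, as.numeric))
         else matrix(as.numeric(meta$positions), 1)
  rec <- neural_recording(V, meta$sample_rate, meta$channel_names, pos,
                          meta$group, meta$hemisphere, meta$is_motor)
  rec$bad_channels <- as.logical(meta$bad_channels)
  if (length(meta$zeroed_idx) > 0)
    rec$zeroed_mask[as.integer(meta$zeroed_idx)] <- TRUE
  rec
}

#' Write / read mono 16-bit PCM WAV audio
#'
#' Interoperability export; note 16-bit quantization is lossy. Study
#' serialization stores audio losslessly as float64 instead.
#' @param audio an [audio_track()].
#' @param path file path.
#' @export
write_wav <- function(audio, path) {
  samples <- as.integer(round(pmin(pmax(audio$samples, -1), 1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  nbytes <- 2L * length(samples)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + nbytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(audio$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(audio$sample_rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(nbytes, con, size = 4, endian = "little")
  writeBin(samples, con, size = 2, endian = "little")
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readChar(con, 4)                                        # RIFF
  readBin(con, "integer", size = 4, endian = "little")
  readChar(con, 8)                                        # WAVEfmt
  fmt_size <- readBin(con, "integer", size = 4, endian = "little")
  fmt <- readBin(con, "integer", size = 2, endian = "little")
  readBin(con, "integer", size = 2, endian = "little")    # channels
  rate <- readBin(con, "integer", size = 4, endian = "little")
  readBin(con, "integer", size = 4, endian = "little")
  readBin(con, "integer", size = 2, endian = "little")
  readBin(con, "integer", size = 2, endian = "little")
  if (fmt != 1) stop("only PCM WAV supported")
  readChar(con, 4)                                        # data
  nbytes <- readBin(con, "integer", size = 4, endian = "little")
  s <- readBin(con, "integer", n = nbytes / 2, size = 2, endian = "little")
  audio_track(s / 32767, rate)
}

#' Write / read an atlas as a delimited table
#'
#' Columns: region, x, y, z (mm).
#' @param atlas an [atlas_regions()].
#' @param path file path.
#' @export
write_atlas <- function(atlas, path) {
  rows <- lapply(names(atlas$regions), function(r) {
    p <- atlas$regions[[r]]
    data.frame(region = r, x = p[, 1], y = p[, 2], z = p[, 3])
  })
  write_table_exact(do.call(rbind, rows), path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  d <- read_table_exact(path)
  atlas_regions(lapply(split(d, factor(d$region, unique(d$region))),
                       function(g) as.matrix(g[, c("x", "y", "z")])))
}

# Lossless float64 audio container used by study serialization.
write_audio_bin <- function(audio, path) {
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(audio$samples, con, size = 8, endian = "little")
  jsonlite::write_json(list(sample_rate = audio$sample_rate,
                            n = length(audio$samples)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
}

read_audio_bin <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  audio_track(readBin(con, "double", n = meta$n, size = 8,
                      endian = "little"), meta$sample_rate)
}

#' Serialize / reload a synthetic study
#'
#' Writes every component (trajectories, state labels, recordings, audio,
#' atlas, ground truth, config) under a directory using exact text or
#' float64 binary formats, so a reloaded study is identical.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created).
#' @export
save_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- study$config
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  write_atlas(study$atlas, file.path(dir, "atlas.tsv"))
  for (s in seq_along(study$subjects)) {
    sub <- study$subjects[[s]]
    sd <- file.path(dir, sprintf("subject%02d", s))
    dir.create(sd, showWarnings = FALSE)
    jsonlite::write_json(sub$layout, file.path(sd, "layout.json"),
                         auto_unbox = TRUE, digits = NA)
    gt <- sub$ground_truth
    write_table_exact(gt$features, file.path(sd, "features.tsv"))
    write_table_exact(as.data.frame(gt$deltas), file.path(sd, "deltas.tsv"))
    for (di in seq_along(sub$days)) {
      day <- sub$days[[di]]
      dd <- file.path(sd, sprintf("day%02d", di))
      dir.create(dd, showWarnings = FALSE)
      write_trajectory(day$traj$contra, file.path(dd, "contra.tsv"))
      write_trajectory(day$traj$ipsi, file.path(dd, "ipsi.tsv"))
      write_states(day$traj$contra_states, file.path(dd, "contra_states.tsv"))
      write_states(day$traj$ipsi_states, file.path(dd, "ipsi_states.tsv"))
      write_table_exact(day$events, file.path(dd, "events.tsv"))
      write_recording(day$recording, file.path(dd, "recording"))
      write_audio_bin(day$audio, file.path(dd, "audio"))
    }
  }
  invisible(dir)
}

#' @rdname save_study
#' @export
load_study <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  cfg$true_betas <- as.list(cfg$true_betas)
  config <- do.call(synthetic_config, cfg[names(cfg) %in%
                                            names(formals(synthetic_config))])
  atlas <- read_atlas(file.path(dir, "atlas.tsv"))
  sdirs <- sort(list.files(dir, pattern = "^subject", full.names = TRUE))
  subjects <- lapply(sdirs, function(sd) {
    layout <- jsonlite::read_json(file.path(sd, "layout.json"),
                                  simplifyVector = TRUE)
    layout$positions <- matrix(layout$positions,
                               ncol = 3)
    features <- read_table_exact(file.path(sd, "features.tsv"))
    deltas <- as.matrix(read_table_exact(file.path(sd, "deltas.tsv")))
    ddirs <- sort(list.files(sd, pattern = "^day", full.names = TRUE))
    days <- lapply(ddirs, function(dd) {
      list(traj = list(
             contra = read_trajectory(file.path(dd, "contra.tsv"),
                                      config$frame_rate, "contralateral"),
             ipsi = read_trajectory(file.path(dd, "ipsi.tsv"),
                                    config$frame_rate, "ipsilateral"),
             contra_states = read_states(file.path(dd, "contra_states.tsv"),
                                         "ground-truth"),
             ipsi_states = read_states(file.path(dd, "ipsi_states.tsv"),
                                       "ground-truth")),
           events = read_table_exact(file.path(dd, "events.tsv")),
           recording = read_recording(file.path(dd, "recording")),
           audio = read_audio_bin(file.path(dd, "audio")))
    })
    list(days = days, layout = layout,
         ground_truth = list(features = features, deltas = deltas,
                             true_betas = config$true_betas,
                             beta0 = config$beta0))
  })
  structure(list(config = config, atlas = atlas, subjects = subjects),
            class = "synthetic_study")
}
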