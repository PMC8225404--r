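# End-to-end orchestration: simulate -> segment -> detect-events ->
# preprocess -> spectral -> project -> group-stats -> features -> regress.
# A single master seed deterministically derives every stage seed, and all
# written outputs carry the configuration hash and seed.

# 32-bit FNV-1a hash of a serialized object, reported as hex.
config_hash <- function(obj) {
  raw <- serialize(obj, NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(raw)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

derive_seed <- function(master, stage_index) {
  as.integer((as.numeric(master) * 48271 + stage_index * 7919) %% (2^31 - 1))
}

#' Pipeline configuration
#'
#' Bundles the synthetic-study configuration with stage parameters. All
#' defaults are the analysis defaults used throughout: 0.5 s onset windows,
#' duration limits [0.5, 4] s, confidence 0.4, quadratic R^2 0.6, 200
#' events/day, 1-200 Hz band, 500 Hz, 2 cm FWHM, density threshold 3, 2000
#' bootstrap replicates, LFB/HFB bands, 200 splits.
#'
#' @param synth a [synthetic_config()].
#' @param seed master seed; stage seeds are derived from it.
#' @param max_dwell HSMM dwell truncation (frames).
#' @param hsmm_max_iter EM iteration cap.
#' @param per_day_cap maximum events kept per day.
#' @param n_boot bootstrap replicates for group masking.
#' @param n_splits regression train/test splits.
#' @param decim spectrogram time decimation.
#' @param stages character vector of stages to run, in pipeline order.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synthetic_config(), seed = 1,
                            max_dwell = 150, hsmm_max_iter = 15,
                            per_day_cap = 200, n_boot = 2000,
                            n_splits = 200, decim = 20L,
                            stages = c("simulate", "segment", "detect-events",
                                       "preprocess", "spectral", "project",
                                       "group-stats", "features", "regress")) {
  structure(list(synth = synth, seed = seed, max_dwell = max_dwell,
                 hsmm_max_iter = hsmm_max_iter, per_day_cap = per_day_cap,
                 n_boot = n_boot, n_splits = n_splits, decim = decim,
                 stages = stages),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Executes the configured stages in order and returns all intermediate and
#' final products. If `out_dir` is given, delimited result tables are
#' written there, each preceded by a comment line carrying the
#' configuration hash and master seed. Stage failures halt with the stage
#' name and cause.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return named list of stage outputs.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- config_hash(unclass(config))
  run_stage <- function(name, expr) {
    if (!(name %in% config$stages)) return(NULL)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  out <- list(config_hash = hash, seed = config$seed)
  synth <- config$synth
  synth$seed <- derive_seed(config$seed, 1)
  study <- run_stage("simulate", generate_study(synth))
  out$study <- study
  if (is.null(study)) return(out)
  nsub <- length(study$subjects)
  # --- segment + detect-events + features (behavioral path) ---------------
  states <- list(); events <- list(); feats <- list()
  for (s in seq_len(nsub)) {
    states[[s]] <- list(); events[[s]] <- list(); feats[[s]] <- list()
    for (di in seq_along(study$subjects[[s]]$days)) {
      day <- study$subjects[[s]]$days[[di]]
      st <- run_stage("segment", {
        par <- fit_arhsmm(day$traj$contra,
                          init_seed = derive_seed(config$seed, 10 + s),
                          max_iter = config$hsmm_max_iter,
                          max_dwell = config$max_dwell)
        decode_states(par, day$traj$contra)
      })
      if (is.null(st)) st <- day$traj$contra_states
      states[[s]][[di]] <- st
      ev <- run_stage("detect-events",
        find_events(st, day$traj$contra, day = study$config$days[di],
                    day_start_time = study$config$day_start_time,
                    per_day_cap = config$per_day_cap))
      events[[s]][[di]] <- ev
      if (!is.null(ev)) {
        feats[[s]][[di]] <- run_stage("features",
          feature_table(ev, day$traj$contra, day$traj$ipsi, st,
                        day$traj$ipsi_states, audio = day$audio))
      }
    }
  }
  out$states <- states
  out$events <- events
  # --- preprocess + spectral ----------------------------------------------
  recs <- list(); powers <- list(); spectra <- list()
  for (s in seq_len(nsub)) {
    recs[[s]] <- list(); powers[[s]] <- list(); spectra[[s]] <- list()
    for (di in seq_along(study$subjects[[s]]$days)) {
      day <- study$subjects[[s]]$days[[di]]
      rec <- run_stage("preprocess", preprocess_recording(day$recording))
      if (is.null(rec)) rec <- day$recording
      recs[[s]][[di]] <- rec
      sp <- run_stage("spectral", {
        ev <- events[[s]][[di]]
        kept <- ev[ev$kept, , drop = FALSE]
        segs <- extract_segments(rec, kept)
        if (length(segs) >= 2) segs <- reject_bad_segments(segs, rec$bad_channels)
        bp <- band_power_table(segs, bad = rec$bad_channels,
                               decim = config$decim)
        planes <- lapply(segs, function(sg) {
          lapply(which(!rec$bad_channels), function(ch) {
            spg <- morlet_power(sg, ch, decim = config$decim)
            baseline_subtract(spg)
          })
        })
        list(band_powers = bp, planes = planes,
             grid = if (length(segs) > 0)
               morlet_power(segs[[1]], 1, decim = config$decim)[c("freqs", "times")]
             else NULL)
      })
      powers[[s]][[di]] <- sp$band_powers
      spectra[[s]][[di]] <- sp
    }
  }
  out$recordings <- recs
  # --- project + group-stats ----------------------------------------------
  gs <- run_stage("group-stats", {
    proj <- run_stage("project", {
      lapply(seq_len(nsub), function(s) {
        lay <- study$subjects[[s]]$layout
        bad <- recs[[s]][[1]]$bad_channels
        pos <- mirror_electrodes(lay$positions[!bad, , drop = FALSE],
                                 lay$hemisphere)
        compute_weights(pos, study$atlas)
      })
    })
    out$weights <- proj
    regions <- Reduce(intersect, lapply(proj, function(w) w$retained))
    grid <- NULL
    region_planes <- lapply(regions, function(r) {
      lapply(seq_len(nsub), function(s) {
        planes_days <- list()
        for (di in seq_along(spectra[[s]])) {
          sp <- spectra[[s]][[di]]
          if (is.null(sp$grid)) next
          grid <<- sp$grid
          for (pl in sp$planes) {
            prj <- project_power(lapply(pl, function(x) x$power), proj[[s]])
            planes_days[[length(planes_days) + 1]] <- prj[[r]]
          }
        }
        planes_days
      })
    })
    names(region_planes) <- regions
    per_region <- lapply(region_planes, aggregate_spectrograms)
    masked <- lapply(seq_along(per_region), function(i)
      bootstrap_baseline_mask(per_region[[i]], grid$times,
                              n_boot = config$n_boot,
                              seed = derive_seed(config$seed, 50 + i),
                              event_planes = region_planes[[i]]))
    names(masked) <- regions
    bp_all <- do.call(rbind, lapply(seq_len(nsub), function(s) {
      do.call(rbind, lapply(seq_along(powers[[s]]), function(di) {
        d <- powers[[s]][[di]]
        if (is.null(d) || nrow(d) == 0) return(NULL)
        d$subject <- s
        d$day <- study$config$days[di]
        d
      }))
    }))
    kw <- NULL
    if (!is.null(bp_all)) {
      long <- rbind(data.frame(band = "LFB", value = bp_all$LFB,
                               subject = bp_all$subject, day = bp_all$day),
                    data.frame(band = "HFB", value = bp_all$HFB,
                               subject = bp_all$subject, day = bp_all$day))
      kw <- list(by_subject = if (nsub > 1)
                   kruskal_wallis_bands(long, "subject") else NULL,
                 by_day = kruskal_wallis_bands(long, "day"))
    }
    list(group = per_region, masked = masked, kruskal = kw)
  })
  out$group_stats <- gs
  # --- regress -------------------------------------------------------------
  out$features <- feats
  out$regression <- run_stage("regress", {
    res <- list()
    for (s in seq_len(nsub)) {
      ft <- do.call(rbind, feats[[s]])
      bp <- do.call(rbind, lapply(seq_along(powers[[s]]), function(di) {
        d <- powers[[s]][[di]]
        if (is.null(d) || nrow(d) == 0) return(NULL)
        # event ids are per-day; offset to be unique within subject
        d$event_id <- d$event_id + (di - 1) * 100000
        d
      }))
      ids <- unique(bp$event_id)
      ftk <- do.call(rbind, lapply(seq_along(feats[[s]]), function(di) {
        f <- feats[[s]][[di]]
        if (is.null(f) || nrow(f) == 0) return(NULL)
        f$event_id <- f$event_id + (di - 1) * 100000
        f
      }))
      ftk <- ftk[ftk$event_id %in% ids, , drop = FALSE]
      bp <- bp[bp$event_id %in% ftk$event_id, , drop = FALSE]
      res[[s]] <- run_splits(bp, ftk, n_splits = config$n_splits,
                             seed = derive_seed(config$seed, 90 + s))
    }
    res
  })
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir, hash, config$seed)
  out
}

# Delimited tables with a provenance comment line.
write_pipeline_outputs <- function(out, out_dir, hash, seed) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- sprintf("# config_hash=%s seed=%d", hash, seed)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    con <- file(path, "w")
    writeLines(stamp, con)
    close(con)
    suppressWarnings(
      utils::write.table(format(df, digits = 17), path, sep = "\t",
                         quote = FALSE, row.names = FALSE, append = TRUE))
  }
  if (!is.null(out$events)) {
    ev <- do.call(rbind, lapply(seq_along(out$events), function(s) {
      d <- do.call(rbind, out$events[[s]])
      if (!is.null(d) && nrow(d) > 0) d$subject <- s
      d
    }))
    if (!is.null(ev)) emit(ev, "events.tsv")
  }
  if (!is.null(out$features)) {
    ft <- do.call(rbind, lapply(seq_along(out$features), function(s) {
      d <- do.call(rbind, out$features[[s]])
      if (!is.null(d) && nrow(d) > 0) d$subject <- s
      d
    }))
    if (!is.null(ft)) emit(ft, "features.tsv")
  }
  if (!is.null(out$regression)) {
    for (s in seq_along(out$regression)) {
      r <- out$regression[[s]]
      if (is.null(r)) next
      emit(r$full_r2, sprintf("full_r2_subject%02d.tsv", s))
      emit(r$delta_r2, sprintf("delta_r2_subject%02d.tsv", s))
      emit(r$retention, sprintf("retention_subject%02d.tsv", s))
      emit(r$coefficients, sprintf("coefficients_subject%02d.tsv", s))
    }
  }
  invisible(out_dir)
}
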