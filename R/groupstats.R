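# Group-level aggregation of event spectrograms, bootstrap baseline null
# with Benjamini-Hochberg FDR masking, and rank-based across-group tests.

#' Aggregate per-event spectrograms to the group level
#'
#' Median over events within each subject (bin-wise), then mean across
#' subjects. Subjects lacking the region are skipped with a warning.
#'
#' @param per_subject list (one element per subject) of lists of
#'   frequency x time matrices (one per event), all identically shaped.
#' @return group-level matrix.
#' @export
aggregate_spectrograms <- function(per_subject) {
  meds <- list()
  for (s in seq_along(per_subject)) {
    evs <- per_subject[[s]]
    if (is.null(evs) || length(evs) == 0) {
      warning("subject ", s, " has no events for this region; skipped")
      next
    }
    arr <- array(unlist(evs), dim = c(dim(evs[[1]]), length(evs)))
    meds[[length(meds) + 1]] <- apply(arr, c(1, 2), stats::median)
  }
  if (length(meds) == 0) stop("no subjects with events")
  Reduce(`+`, meds) / length(meds)
}

#' Mask a group spectrogram by a bootstrap baseline null with FDR correction
#'
#' For each frequency, a null distribution of `n_boot` bootstrap draws is
#' built by resampling that frequency's baseline time-point values (each
#' draw the mean of `block` resampled values; the default `block = 1`
#' makes the null the distribution of baseline bin values itself, which is
#' what calibrates the two-sided test against single-bin noise). Each
#' time-frequency bin gets a two-sided p-value
#' 2 * min(P(null >= obs), P(null <= obs)) with a +1/(n+1) continuity
#' correction; Benjamini-Hochberg correction is applied across all bins of
#' the plane and bins with corrected p > alpha are set to 0.
#'
#' @param power frequency x time matrix (dB relative to baseline).
#' @param times time grid (s).
#' @param baseline baseline window (s).
#' @param n_boot bootstrap replicates (>= 100).
#' @param alpha FDR level.
#' @param seed RNG seed.
#' @param block number of resampled baseline values averaged per replicate
#'   (group-level null only).
#' @param event_planes optional per-subject lists of per-event
#'   frequency x time matrices (the planes that were aggregated into
#'   `power`). When supplied, each bootstrap replicate redraws one random
#'   baseline time point per event and reapplies the full aggregation
#'   (median over events, mean over subjects), so the null has the same
#'   sampling distribution as an aggregated bin. This is the calibrated
#'   default for group masking; the group-level null (resampling the
#'   aggregated baseline bins directly) is too discrete to calibrate many
#'   comparisons and is kept only for single-plane use.
#' @return list with `masked` matrix, `p` raw and `p_adj` corrected p-value
#'   matrices.
#' @export
bootstrap_baseline_mask <- function(power, times, baseline = c(-1.5, -1),
                                    n_boot = 2000, alpha = 0.05, seed = 1,
                                    block = 1, event_planes = NULL) {
  if (n_boot < 100) stop("n_boot must be at least 100")
  bsel <- times >= baseline[1] & times <= baseline[2]
  if (!any(bsel)) stop("baseline window not present in time grid")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  nf <- nrow(power)
  nt <- ncol(power)
  p <- matrix(1, nf, nt)
  for (f in seq_len(nf)) {
    if (all(power[f, ] == 0)) next                     # degenerate null
    null_means <- if (!is.null(event_planes)) {
      # event-level: redraw a baseline time point per event, re-aggregate
      per_subj <- lapply(event_planes, function(evs) {
        evs <- Filter(Negate(is.null), evs)
        if (length(evs) == 0) return(NULL)
        E <- t(vapply(evs, function(m) m[f, bsel], numeric(sum(bsel))))
        idx <- matrix(sample.int(ncol(E), n_boot * nrow(E), replace = TRUE),
                      n_boot, nrow(E))
        vals <- matrix(E[cbind(rep(seq_len(nrow(E)), each = n_boot),
                               as.vector(idx))], n_boot, nrow(E))
        apply(vals, 1, stats::median)
      })
      per_subj <- Filter(Negate(is.null), per_subj)
      Reduce(`+`, per_subj) / length(per_subj)
    } else {
      base <- power[f, bsel]
      if (block == 1) {
        sample(base, n_boot, replace = TRUE)
      } else {
        rowMeans(matrix(sample(base, n_boot * block, replace = TRUE),
                        n_boot, block))
      }
    }
    obs <- power[f, ]
    ge <- (vapply(obs, function(o) sum(null_means >= o), 1) + 1) / (n_boot + 1)
    le <- (vapply(obs, function(o) sum(null_means <= o), 1) + 1) / (n_boot + 1)
    p[f, ] <- pmin(1, 2 * pmin(ge, le))
  }
  p_adj <- matrix(stats::p.adjust(p, method = "BH"), nf, nt)
  masked <- power
  masked[p_adj > alpha] <- 0
  list(masked = masked, p = p, p_adj = p_adj)
}

#' Kruskal-Wallis tests of band power across groups
#'
#' Thin wrapper over the standard rank-based one-way test, run separately
#' per band.
#'
#' @param band_powers data.frame with columns `band`, `value` and the
#'   grouping column.
#' @param grouping name of the grouping column ("subject" or "day").
#' @return data.frame with band, H statistic, degrees of freedom and p.
#' @export
kruskal_wallis_bands <- function(band_powers, grouping = "subject") {
  stopifnot(grouping %in% names(band_powers))
  out <- lapply(unique(band_powers$band), function(b) {
    d <- band_powers[band_powers$band == b, ]
    g <- factor(d[[grouping]])
    if (nlevels(g) < 2) stop("need at least 2 groups")
    if (length(unique(d$value)) == 1)
      return(data.frame(band = b, H = 0, df = nlevels(g) - 1, p = 1))
    kt <- stats::kruskal.test(d$value, g)
    data.frame(band = b, H = unname(kt$statistic),
               df = unname(kt$parameter), p = kt$p.value)
  })
  do.call(rbind, out)
}
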