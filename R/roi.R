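# Electrode-to-atlas-region projection via 3D Gaussian weights.
#
# Each electrode contributes to a region with unnormalized weight
# sum_p exp(-d(e, p)^2 / (2 sigma^2)) over the region's points, with
# sigma = FWHM / (2 sqrt(2 ln 2)) and FWHM defaulting to 20 mm. Summing
# weights over electrodes gives the region's electrode density; regions with
# group-mean density > 3 are retained and their weights normalized across
# electrodes to sum to 1.

#' Mirror right-hemisphere electrode positions into the left hemisphere
#'
#' @param positions n x 3 matrix of electrode positions (mm).
#' @param hemisphere "left" or "right".
#' @return positions with x negated for right-hemisphere subjects.
#' @export
mirror_electrodes <- function(positions, hemisphere) {
  positions <- as.matrix(positions)
  if (hemisphere == "right") positions[, 1] <- -positions[, 1]
  positions
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Gaussian electrode-to-region projection weights
#'
#' @param positions n x 3 matrix of (mirrored) electrode positions in mm;
#'   bad channels should be excluded beforehand.
#' @param atlas an [atlas_regions()] object.
#' @param fwhm Gaussian full width at half maximum in mm (default 20).
#' @param density_threshold minimum electrode density to retain a region.
#' @param densities optional precomputed per-region densities (e.g. averaged
#'   across subjects) used for retention instead of this subject's own.
#' @return object of class `projection_weights` with per-region normalized
#'   electrode weights, raw densities and the retained-region list.
#' @export
compute_weights <- function(positions, atlas, fwhm = 20,
                            density_threshold = 3, densities = NULL) {
  stopifnot(inherits(atlas, "atlas_regions"))
  positions <- as.matrix(positions)
  if (nrow(positions) == 0) stop("no electrode positions")
  sigma <- fwhm_to_sigma(fwhm)
  raw <- vapply(atlas$regions, function(pts) {
    w <- numeric(nrow(positions))
    for (e in seq_len(nrow(positions))) {
      d2 <- rowSums(sweep(pts, 2, positions[e, ])^2)
      w[e] <- sum(exp(-d2 / (2 * sigma^2)))
    }
    w
  }, numeric(nrow(positions)))
  raw <- matrix(raw, nrow = nrow(positions),
                dimnames = list(NULL, names(atlas$regions)))
  dens <- colSums(raw)
  ret_dens <- if (is.null(densities)) dens else densities[names(atlas$regions)]
  retained <- names(atlas$regions)[ret_dens > density_threshold]
  weights <- raw[, retained, drop = FALSE]
  weights <- sweep(weights, 2, pmax(colSums(weights), .Machine$double.eps), "/")
  structure(list(weights = weights, density = dens, retained = retained,
                 sigma = sigma, fwhm = fwhm),
            class = "projection_weights")
}

#' @export
print.projection_weights <- function(x, ...) {
  cat(sprintf("<projection_weights: %d electrodes, %d/%d regions retained, sigma %.4f mm>\n",
              nrow(x$weights), length(x$retained), length(x$density), x$sigma))
  invisible(x)
}

#' Project electrode-level power onto retained regions
#'
#' Linear weighted average: region value = sum_e w_e * power_e. `power` may
#' be a vector (one value per electrode, e.g. a band power) or a matrix/list
#' of identically shaped planes per electrode.
#'
#' @param power numeric vector of per-electrode values, or a list of
#'   per-electrode matrices (e.g. spectrogram power planes).
#' @param weights a `projection_weights` object.
#' @return named vector (or list of matrices) per retained region.
#' @export
project_power <- function(power, weights) {
  stopifnot(inherits(weights, "projection_weights"))
  W <- weights$weights
  if (is.list(power)) {
    if (length(power) != nrow(W))
      stop("one power plane per electrode required")
    out <- lapply(weights$retained, function(r) {
      acc <- power[[1]] * 0
      for (e in seq_len(nrow(W))) acc <- acc + W[e, r] * power[[e]]
      acc
    })
    names(out) <- weights$retained
    return(out)
  }
  power <- as.numeric(power)
  if (length(power) != nrow(W))
    stop("power must have one value per electrode in the weight matrix")
  stats::setNames(as.numeric(crossprod(W, power)), colnames(W))
}
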