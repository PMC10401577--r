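# Torsion time series, distributions, hydrogen-bond-motif flip detection,
# and NPT cell averaging from MD trajectories.

#' Unwrap a periodic angle series
#'
#' Chooses the minimal angular step between consecutive frames so the
#' unwrapped series has no jump larger than 180 degrees. Steps larger than
#' 90 degrees of true motion are counted as under-sampled.
#'
#' @param wrapped angle series in degrees.
#' @return list with \code{unwrapped} and \code{n_undersampled}.
#' @export
unwrap_angles <- function(wrapped) {
  steps <- wrap_angle(diff(wrapped))
  list(unwrapped = wrapped[1] + c(0, cumsum(steps)),
       n_undersampled = sum(abs(steps) > 90))
}

#' Torsion time series from trajectory frames
#'
#' Applies \code{\link{measure_torsion}} frame by frame for each torsion
#' spec (frames carry their own cells, so minimum images track cell
#' fluctuations) and builds wrapped and continuous-unwrapped views.
#'
#' @param frames list of frames (\code{\link{read_xyz_frames}} format:
#'   \code{cell}, \code{elements}, \code{cart}, optional \code{time}).
#' @param specs list of \code{\link{torsion_spec}}s (or 4-vectors).
#' @param times optional time axis in ps; defaults to per-frame \code{time}
#'   records (converted from fs) or the frame index.
#' @param molecules optional molecular partition forwarded to the per-frame
#'   \code{\link{crystal}} (skips bond inference when supplied).
#' @return object of class \code{torsion_trajectory}: \code{times} (ps),
#'   \code{wrapped} and \code{unwrapped} (frames x torsions matrices,
#'   degrees), \code{specs}, \code{n_undersampled}.
#' @export
torsion_timeseries <- function(frames, specs, times = NULL, molecules = NULL) {
  specs <- lapply(specs, as_torsion_spec)
  nf <- length(frames)
  if (nf < 1) stop("no frames supplied")
  wrapped <- matrix(NA_real_, nf, length(specs))
  for (i in seq_len(nf)) {
    fr <- frames[[i]]
    maxid <- max(unlist(specs))
    if (nrow(fr$cart) < maxid) stop("frame ", i, " is missing atoms for the torsion specs")
    cr <- crystal(fr$cell, fr$elements, cart_to_frac(fr$cart, fr$cell),
                  molecules = if (is.null(molecules))
                    list(seq_len(nrow(fr$cart))) else molecules)
    for (j in seq_along(specs)) {
      wrapped[i, j] <- measure_torsion(cr, specs[[j]])
    }
  }
  if (is.null(times)) {
    ft <- vapply(frames, function(f) if (is.null(f$time)) NA_real_ else f$time,
                 numeric(1))
    times <- if (anyNA(ft)) seq_len(nf) else ft / 1000  # fs -> ps
  }
  un <- apply(wrapped, 2, function(col) unwrap_angles(col)$unwrapped)
  nu <- sum(apply(wrapped, 2, function(col) unwrap_angles(col)$n_undersampled))
  structure(list(times = times, wrapped = wrapped,
                 unwrapped = matrix(un, nf), specs = specs,
                 n_undersampled = nu),
            class = "torsion_trajectory")
}

#' @export
print.torsion_trajectory <- function(x, ...) {
  cat(sprintf("torsion_trajectory: %d frames x %d torsion(s), %.3f .. %.3f ps\n",
              nrow(x$wrapped), ncol(x$wrapped), min(x$times), max(x$times)))
  invisible(x)
}

#' Normalized dihedral-angle distribution
#'
#' Histogram over (-180, 180] normalized so the integrated area
#' (sum of height x bin width) is exactly 100.
#'
#' @param series angle series in degrees (any wrapping).
#' @param bin_width bin width in degrees; must divide 360.
#' @return data.frame with \code{angle} (bin centers) and \code{density}
#'   (per degree, area-normalized to 100).
#' @export
torsion_distribution <- function(series, bin_width = 5) {
  series <- as.numeric(series)
  if (length(series) == 0) stop("empty angle series")
  if (abs(360 / bin_width - round(360 / bin_width)) > 1e-9) {
    stop("bin width must divide 360")
  }
  nb <- round(360 / bin_width)
  w <- wrap_angle(series)
  idx <- ceiling((w + 180) / bin_width)
  idx[idx < 1] <- 1; idx[idx > nb] <- nb
  counts <- tabulate(idx, nbins = nb)
  density <- 100 * counts / (sum(counts) * bin_width)
  data.frame(angle = -180 + (seq_len(nb) - 0.5) * bin_width,
             density = density)
}

in_basin <- function(angle, basin) {
  angle > basin[1] & angle <= basin[2]
}

basin_labels <- function(wrapped, basins) {
  lab <- rep(NA_character_, length(wrapped))
  for (nm in names(basins)) {
    lab[in_basin(wrapped, basins[[nm]])] <- nm
  }
  lab
}

#' Default torsion basins for thiol hydrogen-bond motifs
#'
#' SH...S-like: (30, 150]; SH...O-like: (-150, -30]; everything else
#' (including the +/-180 region) is the metastable remainder.
#' @return named list of angle intervals in degrees.
#' @export
default_basins <- function() {
  list("SH...S" = c(30, 150), "SH...O" = c(-150, -30))
}

#' Detect hydrogen-bond-motif flips in torsion series
#'
#' A committed-basin automaton: the torsion keeps its current basin label
#' until it has resided in a different basin continuously for at least
#' \code{dwell} ps, at which point one flip is recorded (at the entry time
#' into the new basin). Time outside all basins (e.g. the +/-180 metastable
#' region) interrupts a pending commitment but never commits. Excursions
#' shorter than the dwell are ignored; an out-and-back excursion counts as
#' two flips only when both residences meet the dwell.
#'
#' @param traj a \code{\link{torsion_timeseries}} result, or a numeric
#'   matrix of wrapped angles (frames x torsions) with a \code{times}
#'   argument.
#' @param basins named list of disjoint angle intervals (degrees); default
#'   \code{\link{default_basins}}.
#' @param dwell minimum residence in ps to commit a flip (default 0.5).
#' @param times time axis in ps when \code{traj} is a plain matrix.
#' @return data.frame of flip events: \code{torsion}, \code{time} (ps),
#'   \code{from}, \code{to}, \code{dwell_confirmed} (ps).
#' @export
detect_flips <- function(traj, basins = default_basins(), dwell = 0.5,
                         times = NULL) {
  if (inherits(traj, "torsion_trajectory")) {
    times <- traj$times
    wrapped <- traj$wrapped
  } else {
    wrapped <- as.matrix(traj)
    if (is.null(times)) stop("times required for a plain angle matrix")
  }
  stopifnot(dwell > 0)
  nms <- names(basins)
  for (i in seq_along(basins)) {
    for (j in seq_along(basins)) {
      if (i < j && basins[[i]][1] < basins[[j]][2] &&
          basins[[j]][1] < basins[[i]][2]) {
        stop("basins overlap: ", nms[i], " and ", nms[j])
      }
    }
  }
  events <- data.frame(torsion = integer(0), time = numeric(0),
                       from = character(0), to = character(0),
                       dwell_confirmed = numeric(0))
  for (j in seq_len(ncol(wrapped))) {
    lab <- basin_labels(wrapped[, j], basins)
    committed <- lab[!is.na(lab)][1]
    if (is.na(committed) || is.null(committed)) next
    pending <- NA_character_
    entry <- NA_real_
    for (i in seq_along(lab)) {
      cur <- lab[i]
      if (is.na(cur) || cur == committed) {
        pending <- NA_character_  # metastable or home basin resets the clock
        next
      }
      if (is.na(pending) || cur != pending) {
        pending <- cur
        entry <- times[i]
      }
      if (times[i] - entry >= dwell) {
        events <- rbind(events, data.frame(
          torsion = j, time = entry, from = committed, to = cur,
          dwell_confirmed = times[i] - entry))
        committed <- cur
        pending <- NA_character_
      }
    }
  }
  events
}

#' Fraction of time per basin per torsion
#'
#' @inheritParams detect_flips
#' @return matrix (torsions x basins) of occupancies in [0, 1]; rows sum to
#'   at most 1, the remainder being metastable/unassigned time.
#' @export
motif_occupancy <- function(traj, basins = default_basins()) {
  wrapped <- if (inherits(traj, "torsion_trajectory")) traj$wrapped
             else as.matrix(traj)
  out <- matrix(0, ncol(wrapped), length(basins),
                dimnames = list(NULL, names(basins)))
  for (j in seq_len(ncol(wrapped))) {
    lab <- basin_labels(wrapped[, j], basins)
    out[j, ] <- table(factor(lab, levels = names(basins))) / length(lab)
  }
  out
}

#' Average NPT cell parameters over frames
#'
#' @param frames list of frames with \code{cell} matrices.
#' @return data.frame with one row per parameter (a, b, c, alpha, beta,
#'   gamma): \code{mean} and \code{sd}.
#' @export
average_cell <- function(frames) {
  if (length(frames) < 1) stop("no frames")
  pars <- t(vapply(frames, function(f) cell_parameters(f$cell), numeric(6)))
  data.frame(parameter = c("a", "b", "c", "alpha", "beta", "gamma"),
             mean = colMeans(pars),
             sd = if (nrow(pars) > 1) apply(pars, 2, stats::sd) else rep(0, 6))
}
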