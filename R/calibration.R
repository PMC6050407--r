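#' Assemble a bead calibration set
#'
#' Calibration beads carry known numbers of fluorophores per bead; acquiring
#' them on the instrument yields, for each bead peak, a cloud of observed
#' intensities. The log-log regression of intensity on fluorophore count is
#' the standard curve that converts cell fluorescence to absolute receptor
#' numbers.
#'
#' @param known Strictly increasing vector (length >= 2) of fluorophores per
#'   bead for each peak.
#' @param intensities List (same length) of observed intensity vectors, one
#'   per peak, each non-empty.
#' @return A `bead_calibration_set`.
#' @export
bead_calibration_set <- function(known, intensities) {
  known <- as.numeric(known)
  if (length(known) < 2) stop("need at least 2 bead peaks", call. = FALSE)
  if (any(diff(known) <= 0)) {
    stop("known fluorophores-per-bead values must be strictly increasing",
         call. = FALSE)
  }
  if (!is.list(intensities) || length(intensities) != length(known)) {
    stop("`intensities` must be a list with one vector per peak", call. = FALSE)
  }
  if (any(vapply(intensities, length, integer(1)) < 1)) {
    stop("every peak needs at least one observed intensity", call. = FALSE)
  }
  structure(list(known = known, intensities = lapply(intensities, as.numeric)),
            class = "bead_calibration_set")
}

#' Read a bead calibration set from CSV
#'
#' Expects columns `known_fluorophores` and `intensity`, one row per bead
#' event.
#'
#' @param path CSV path.
#' @return A [bead_calibration_set()].
#' @export
read_beads_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (!all(c("known_fluorophores", "intensity") %in% names(df))) {
    stop("bead CSV needs columns known_fluorophores, intensity", call. = FALSE)
  }
  known <- sort(unique(df$known_fluorophores))
  bead_calibration_set(known, lapply(known, function(k)
    df$intensity[df$known_fluorophores == k]))
}

#' Write a bead calibration set to CSV
#' @param beads A [bead_calibration_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_beads_csv <- function(beads, path) {
  stopifnot(inherits(beads, "bead_calibration_set"))
  df <- data.frame(
    known_fluorophores = rep(beads$known, lengths(beads$intensities)),
    intensity = format_full(unlist(beads$intensities)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fit the bead standard curve
#'
#' Ordinary least squares of log10(median intensity) on log10(fluorophores
#' per bead), one point per peak. The median is used as the per-peak summary
#' for robustness to outlier bead events.
#'
#' @param beads A [bead_calibration_set()].
#' @param receptors_per_fluorophore Stoichiometry factor carried onto the
#'   curve: receptors per fluorophore, combining fluorophore:antibody and
#'   antibody:receptor ratios (default 1, i.e. 1:1:1 for PE conjugates).
#' @return A `calibration_curve` with fields `slope`, `intercept`,
#'   `r_squared`, `receptors_per_fluorophore`.
#' @export
fit_bead_curve <- function(beads, receptors_per_fluorophore = 1) {
  stopifnot(inherits(beads, "bead_calibration_set"))
  if (receptors_per_fluorophore <= 0) {
    stop("receptors_per_fluorophore must be strictly positive", call. = FALSE)
  }
  med <- vapply(beads$intensities, stats::median, numeric(1))
  if (any(med <= 0)) {
    stop("cannot fit calibration: peak(s) ",
         paste(which(med <= 0), collapse = ", "),
         " have non-positive median intensity", call. = FALSE)
  }
  x <- log10(beads$known)
  y <- log10(med)
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- unname(fit$coefficients[2])
  intercept <- unname(fit$coefficients[1])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  if (!is.finite(slope) || slope <= 0) {
    stop("calibration fit produced a non-positive slope; check bead peaks",
         call. = FALSE)
  }
  structure(list(slope = slope, intercept = intercept,
                 r_squared = max(0, min(1, r2)),
                 receptors_per_fluorophore = receptors_per_fluorophore),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(paste0("<calibration_curve> log10(I) = %.4f + %.4f * log10(F)",
                     "  (R^2 = %.4f, receptors/fluorophore = %g)\n"),
              x$intercept, x$slope, x$r_squared, x$receptors_per_fluorophore))
  invisible(x)
}

#' Convert cell fluorescence to receptors per cell
#'
#' Inverts the bead standard curve:
#' `receptors = receptors_per_fluorophore * 10^((log10(I) - intercept) / slope)`
#' for positive intensities. Events with `I <= 0` (possible after instrument
#' baseline subtraction) are assigned 0 receptors rather than dropped, so
#' composition counts are conserved; their number is reported for downstream
#' log-domain exclusion tallies.
#'
#' @param events An [event_table()].
#' @param channel Channel to calibrate.
#' @param curve A [fit_bead_curve()] result.
#' @return Numeric vector of receptors/cell with attribute
#'   `n_excluded_nonpositive`.
#' @export
calibrate <- function(events, channel, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  intensity <- channel_values(events, channel)
  calibrate_intensity(intensity, curve)
}

#' @rdname calibrate
#' @param intensity Raw intensity vector (alternative entry point).
#' @export
calibrate_intensity <- function(intensity, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  pos <- intensity > 0
  receptors <- numeric(length(intensity))
  receptors[pos] <- curve$receptors_per_fluorophore *
    10^((log10(intensity[pos]) - curve$intercept) / curve$slope)
  attr(receptors, "n_excluded_nonpositive") <- sum(!pos)
  receptors
}
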