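# Modified Beer-Lambert law: the 2x2 linear map between dual-wavelength
# optical-density changes and (HbO, HbR) concentration changes.

#' Extinction-coefficient table for dual-wavelength MBLL
#'
#' Holds the molar extinction coefficients of HbO and HbR at the two
#' wavelengths and the total corrected photon path length
#' d = DPF x source-detector distance. Defaults are for a 760/850 nm
#' system: EC(HbO,760) = 1486.5865, EC(HbR,760) = 3843.707,
#' EC(HbO,850) = 2526.391, EC(HbR,850) = 1798.643 cm^-1/(mol L^-1),
#' d = 18 cm (DPF 6 x 3 cm).
#'
#' @param ec 2x2 matrix, rows = wavelengths (lambda1, lambda2),
#'   columns = chromophores (HbO, HbR).
#' @param d Total corrected photon path length, cm.
#' @param wavelengths Numeric length-2, nm (metadata only).
#' @return An `extinction_table`.
#' @export
extinction_table <- function(ec = matrix(c(1486.5865, 3843.707,
                                           2526.391, 1798.643),
                                         nrow = 2, byrow = TRUE,
                                         dimnames = list(c("l1", "l2"),
                                                         c("HbO", "HbR"))),
                             d = 18, wavelengths = c(760, 850)) {
  stopifnot(is.matrix(ec), all(dim(ec) == 2), d > 0)
  det_ec <- ec[1, 1] * ec[2, 2] - ec[1, 2] * ec[2, 1]
  if (abs(det_ec) < 1e-12 * max(abs(ec))^2) {
    stop("extinction coefficient matrix is singular; MBLL system unsolvable",
         call. = FALSE)
  }
  structure(list(ec = ec, d = d, wavelengths = wavelengths, det = det_ec),
            class = "extinction_table")
}

#' Convert optical density changes to hemoglobin concentration changes
#'
#' Solves, sample by sample, the MBLL system
#' `dOD_lambda = d * (EC_lambda^HbO dHbO + EC_lambda^HbR dHbR)` for the two
#' chromophores by the 2x2 cofactor formulas, and reports concentrations in
#' umol/L (a fixed 1e6 scaling of mol/L, given dimensionless dOD and d in cm
#' with EC in cm^-1/(mol L^-1)).
#'
#' @param od An `optical_recording` (see [synth_subject()] / [read_optical_csv()]).
#' @param table An [extinction_table()].
#' @return A `hemo_recording` with `hbo`, `hbr` (channels x timepoints,
#'   umol/L), `sample_rate`, `channel_ids`, `schedule`.
#' @export
mbll_convert <- function(od, table = extinction_table()) {
  stopifnot(inherits(od, "optical_recording"))
  bad <- which(!is.finite(od$od), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "non-finite optical density at channel %d, timepoint %d (wavelength %d)%s",
      bad[1, 1], bad[1, 2], bad[1, 3],
      if (nrow(bad) > 1) sprintf(" and %d more", nrow(bad) - 1) else ""),
      call. = FALSE)
  }
  ec <- table$ec; d <- table$d; det_ec <- table$det
  od1 <- od$od[, , 1, drop = TRUE]  # lambda1 (760 nm)
  od2 <- od$od[, , 2, drop = TRUE]
  # cofactor solution of d * ec %*% c(hbo, hbr) = c(od1, od2), scaled to umol/L
  hbo <- 1e6 * (ec[2, 2] * od1 - ec[1, 2] * od2) / (d * det_ec)
  hbr <- 1e6 * (ec[1, 1] * od2 - ec[2, 1] * od1) / (d * det_ec)
  structure(list(sample_rate = od$sample_rate,
                 hbo = rbind(hbo), hbr = rbind(hbr),
                 channel_ids = od$channel_ids,
                 schedule = od$schedule,
                 ground_truth = od$ground_truth),
            class = "hemo_recording")
}

#' Map hemoglobin concentration changes to optical density changes
#'
#' Exact algebraic inverse of [mbll_convert()]:
#' `dOD_lambda = d * (EC_lambda^HbO dHbO + EC_lambda^HbR dHbR)` with
#' concentrations converted from umol/L to mol/L. Used by the synthetic
#' generator and by round-trip tests.
#'
#' @param hemo A `hemo_recording` (umol/L).
#' @param table An [extinction_table()].
#' @return An `optical_recording`.
#' @export
mbll_forward <- function(hemo, table = extinction_table()) {
  stopifnot(inherits(hemo, "hemo_recording"))
  ec <- table$ec; d <- table$d
  co <- hemo$hbo * 1e-6; cr <- hemo$hbr * 1e-6
  od <- array(0, dim = c(nrow(co), ncol(co), 2))
  od[, , 1] <- d * (ec[1, 1] * co + ec[1, 2] * cr)
  od[, , 2] <- d * (ec[2, 1] * co + ec[2, 2] * cr)
  structure(list(sample_rate = hemo$sample_rate,
                 wavelengths = table$wavelengths,
                 od = od,
                 channel_ids = hemo$channel_ids,
                 schedule = hemo$schedule,
                 ground_truth = hemo$ground_truth),
            class = "optical_recording")
}
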