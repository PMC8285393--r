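# Plate-screening and pharmacology formulas. Control statistics use the
# sample standard deviation (n - 1 denominator) throughout, and the
# control terms of the normalization formulas are per-plate control
# means.

#' Construct a plate-data object
#'
#' @param well well identifiers (character).
#' @param role one of `"negative_control"`, `"positive_control"`,
#'   `"test"` per well.
#' @param signal raw luminescence per well; must be finite.
#' @param plate_id plate label.
#' @return data.table of class `plate_data` with columns `plate_id`,
#'   `well`, `role`, `signal`.
#' @export
plate_data <- function(well, role, signal, plate_id = "plate1") {
  stopifnot(length(well) == length(role), length(role) == length(signal))
  role <- as.character(role)
  if (!all(role %in% c("negative_control", "positive_control", "test"))) {
    stop("unknown well role", call. = FALSE)
  }
  if (!all(is.finite(signal))) stop("non-finite signal", call. = FALSE)
  if (!any(role == "negative_control") || !any(role == "positive_control")) {
    stop("plate needs at least one well of each control role", call. = FALSE)
  }
  p <- data.table::data.table(plate_id = plate_id, well = as.character(well),
                              role = role, signal = as.numeric(signal))
  data.table::setattr(p, "class", c("plate_data", class(p)))
  p[]
}

#' Read plate data from CSV
#'
#' Expected columns: `plate_id, well, row, col, role, signal` (`row` and
#' `col` optional).
#'
#' @param path CSV path.
#' @return A [plate_data()] object.
#' @export
read_plate_csv <- function(path) {
  tab <- data.table::fread(path)
  required <- c("plate_id", "well", "role", "signal")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("plate file ", path, " lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  plate_data(tab$well, tab$role, tab$signal, plate_id = tab$plate_id[1])
}

control_means <- function(plate) {
  list(neg = mean(plate$signal[plate$role == "negative_control"]),
       pos = mean(plate$signal[plate$role == "positive_control"]))
}

#' Percent activation of each well
#'
#' Normalizes raw luminescence to the per-plate control means:
#' `% Activation = 100 * (signal - neg_mean) / (pos_mean - neg_mean)`,
#' so the negative-control mean maps to 0 and the positive-control mean
#' to 100. Affine-invariant: shifting or positively scaling all raw
#' signals leaves the result unchanged.
#'
#' @param plate a [plate_data()] object.
#' @return data.table with columns `well`, `role`,
#'   `percent_activation` (all wells, controls included).
#' @export
percent_activation <- function(plate) {
  cm <- control_means(plate)
  if (cm$pos == cm$neg) {
    stop("degenerate controls: positive and negative control means are equal",
         call. = FALSE)
  }
  data.table::data.table(
    well = plate$well, role = plate$role,
    percent_activation = 100 * (plate$signal - cm$neg) / (cm$pos - cm$neg)
  )
}

#' Statistical threshold of activity for hit calling
#'
#' `mean(test activations) + 3 * sd(negative-control activations)`,
#' with the sample SD. A compound whose percent activation exceeds the
#' threshold is a screening hit.
#'
#' @param test_activations percent-activation values of all test wells.
#' @param negative_control_activations percent-activation values of
#'   negative controls (>= 2 values).
#' @return Threshold on the percent-activation scale.
#' @export
hit_threshold <- function(test_activations, negative_control_activations) {
  stopifnot(length(negative_control_activations) >= 2)
  mean(test_activations) + 3 * stats::sd(negative_control_activations)
}

#' Plate quality control: Z'-factor, S/B, S/N, percent CV
#'
#' `z_prime = 1 - 3 * (sd_pos + sd_neg) / |mean_pos - mean_neg|`;
#' values above 0.5 indicate a reliable assay window, so `qc_flag` is
#' raised when `z_prime <= 0.5`. Signal-to-background is the ratio of
#' control means, signal-to-noise the control-mean difference over the
#' negative-control SD, and percent CV is `100 * sd / mean` per control
#' role.
#'
#' @param plate a [plate_data()] object with >= 2 wells per control role.
#' @return list with `z_prime`, `s_b`, `s_n`, `cv_pos`, `cv_neg`,
#'   `qc_flag`.
#' @export
plate_qc <- function(plate) {
  pos <- plate$signal[plate$role == "positive_control"]
  neg <- plate$signal[plate$role == "negative_control"]
  stopifnot(length(pos) >= 2, length(neg) >= 2)
  mu_p <- mean(pos); mu_n <- mean(neg)
  sd_p <- stats::sd(pos); sd_n <- stats::sd(neg)
  if (mu_p == mu_n) stop("degenerate controls: equal means", call. = FALSE)
  z <- z_prime_factor(mu_p, sd_p, mu_n, sd_n)
  list(
    z_prime = z,
    s_b = if (mu_n != 0) mu_p / mu_n else stop("signal/background undefined: zero negative mean", call. = FALSE),
    s_n = (mu_p - mu_n) / sd_n,
    cv_pos = 100 * sd_p / mu_p,
    cv_neg = 100 * sd_n / mu_n,
    qc_flag = z <= 0.5
  )
}

#' Z'-factor from control summary statistics
#'
#' @param mean_pos,sd_pos,mean_neg,sd_neg control means and sample SDs.
#' @return `1 - 3 * (sd_pos + sd_neg) / abs(mean_pos - mean_neg)`; at
#'   most 1, and exactly 1 only when both control SDs are 0.
#' @export
z_prime_factor <- function(mean_pos, sd_pos, mean_neg, sd_neg) {
  if (mean_pos == mean_neg) stop("degenerate controls: equal means", call. = FALSE)
  1 - 3 * (sd_pos + sd_neg) / abs(mean_pos - mean_neg)
}

#' Percent viability from cytotoxicity controls
#'
#' `100 * (test - low_mean) / (high_mean - low_mean)`: the
#' high-signal (untreated cells) control mean maps to 100 and the
#' low-signal (fully toxic) control mean to 0.
#'
#' @param test_signal test-well signal(s).
#' @param low_mean,high_mean control means.
#' @return Percent viability (vectorized over `test_signal`).
#' @export
percent_viability <- function(test_signal, low_mean, high_mean) {
  if (high_mean == low_mean) {
    stop("degenerate controls: equal high and low means", call. = FALSE)
  }
  100 * (test_signal - low_mean) / (high_mean - low_mean)
}

#' Reporter signal normalized to lysate protein
#'
#' @param rlu relative luminescence units.
#' @param protein_ug total protein in the lysate, micrograms (> 0).
#' @return RLU per microgram protein.
#' @export
rlu_per_ug <- function(rlu, protein_ug) {
  if (any(protein_ug <= 0)) stop("protein_ug must be positive", call. = FALSE)
  rlu / protein_ug
}

#' Apparent permeability (Papp)
#'
#' `Papp = (dQ/dt) / (A * C0)` in cm/s. Inputs must already be in
#' consistent units (amount per second, cm^2, amount per cm^3); no unit
#' inference is performed.
#'
#' @param dq_dt translocated amount per unit time (amount/s).
#' @param area transwell area in cm^2 (> 0).
#' @param c0 initial donor concentration (amount/cm^3, > 0).
#' @return Papp in cm/s (vectorized).
#' @export
apparent_permeability <- function(dq_dt, area, c0) {
  if (any(area <= 0)) stop("area must be positive", call. = FALSE)
  if (any(c0 <= 0)) stop("c0 must be positive", call. = FALSE)
  if (any(dq_dt < 0)) stop("dq_dt must be nonnegative", call. = FALSE)
  dq_dt / (area * c0)
}

#' Efflux ratio
#'
#' `ER = Papp(B->A) / Papp(A->B)`, the basolateral-to-apical over
#' apical-to-basolateral permeability ratio; values well above 1
#' indicate active efflux.
#'
#' @param papp_ba,papp_ab apparent permeabilities (same units).
#' @return Efflux ratio.
#' @export
efflux_ratio <- function(papp_ba, papp_ab) {
  if (any(papp_ab <= 0)) stop("papp_ab must be positive", call. = FALSE)
  papp_ba / papp_ab
}
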