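#' Detection-model parameters for the synthetic study
#'
#' The synthetic generator draws a Bernoulli "label produced" outcome per
#' lesion per scan from a logistic model in log-dose, optionally penalised
#' above a high-dose knee (some reconstruction methods destabilise detection
#' at high dose as well as low). Label geometry and colour are governed by
#' dose-dependent size and intensity scale curves, an isotropic in-plane
#' centroid offset, and small per-scan jitter so repeated acquisitions are
#' similar but not identical.
#'
#' `detection` is a named list `params$detection[[lesion_id]][[reconstruction]]`
#' with elements `intercept`, `slope` (logit scale, log-dose covariate) and
#' optionally `deg_knee_mGy`, `deg_rate` for the high-dose degradation term:
#' logit p = intercept + slope * log(dose) - deg_rate * max(0, dose - deg_knee).
#'
#' @param detection nested list of logistic parameters (see Details).
#' @param size_floor,size_sat_mGy the rendered blob radius is
#'   `max_diameter/2 * (size_floor + (1 - size_floor) * min(1, dose/size_sat))`,
#'   i.e. it grows with dose and saturates at the full lesion radius.
#' @param intensity_lo,intensity_hi,intensity_sat_mGy target label intensity
#'   (inverted-grayscale scale, 0-1) ramps from `intensity_lo` to
#'   `intensity_hi`, saturating at `intensity_sat_mGy`.
#' @param offset_scale_mm per-axis SD of the isotropic in-plane centroid
#'   offset, in mm.
#' @param size_jitter_sd,intensity_jitter_sd relative (size) and absolute
#'   (intensity) per-scan jitter SDs.
#' @return an object of class `detection_params`.
#' @export
detection_params <- function(detection,
                             size_floor = 0.4, size_sat_mGy = 5,
                             intensity_lo = 0.35, intensity_hi = 0.65,
                             intensity_sat_mGy = 5,
                             offset_scale_mm = 2,
                             size_jitter_sd = 0.05,
                             intensity_jitter_sd = 0.02) {
  stopifnot(is.list(detection), length(detection) > 0,
            size_floor >= 0, size_floor <= 1, size_sat_mGy > 0,
            intensity_lo >= 0, intensity_hi <= 1,
            intensity_lo <= intensity_hi,
            offset_scale_mm >= 0)
  structure(list(detection = detection,
                 size_floor = size_floor, size_sat_mGy = size_sat_mGy,
                 intensity_lo = intensity_lo, intensity_hi = intensity_hi,
                 intensity_sat_mGy = intensity_sat_mGy,
                 offset_scale_mm = offset_scale_mm,
                 size_jitter_sd = size_jitter_sd,
                 intensity_jitter_sd = intensity_jitter_sd),
            class = "detection_params")
}

#' Default detection-model parameters
#'
#' Calibrated so that, under the default design, the expected number of
#' labels per lesion and reconstruction reproduces the qualitative behaviour
#' of a dose/reconstruction consistency experiment: a large MCA aneurysm
#' labelled at every dose except the lowest (and, with FBP, the two lowest),
#' an ACoA aneurysm with unstable labelling at low dose and — with FBP — a
#' degradation above ~14 mGy, and a small BA aneurysm labelled only
#' sporadically with IR and never with FBP.
#'
#' @return a `detection_params` object.
#' @export
default_detection_params <- function() {
  detection_params(detection = list(
    MCA = list(IR  = list(intercept = 4.10, slope = 11),
               FBP = list(intercept = -3.91, slope = 11)),
    ACoA = list(IR  = list(intercept = -2.26, slope = 2.5),
                FBP = list(intercept = -3.27, slope = 2.2,
                           deg_knee_mGy = 13, deg_rate = 0.3)),
    BA = list(IR  = list(intercept = -3.00, slope = 0),
              FBP = list(intercept = -8.00, slope = 0))
  ))
}

#' Probability that a lesion receives a label
#'
#' Logistic in log-dose with an optional high-dose degradation term:
#' `plogis(intercept + slope * log(d) - deg_rate * pmax(0, d - deg_knee))`.
#' Without the degradation term the probability is non-decreasing in dose
#' whenever `slope >= 0`.
#'
#' @param dose_mGy CTDIvol in mGy (> 0); vectorised.
#' @param reconstruction reconstruction method name.
#' @param lesion_id lesion identifier.
#' @param params a `detection_params` object.
#' @return probabilities in `[0, 1]`.
#' @export
label_probability <- function(dose_mGy, reconstruction, lesion_id, params) {
  stopifnot(inherits(params, "detection_params"))
  if (any(dose_mGy <= 0)) stop("dose_mGy must be > 0")
  pl <- params$detection[[lesion_id]]
  if (is.null(pl)) stop("unknown lesion_id: ", lesion_id)
  pr <- pl[[reconstruction]]
  if (is.null(pr)) stop("unknown reconstruction '", reconstruction,
                        "' for lesion ", lesion_id)
  eta <- pr$intercept + pr$slope * log(dose_mGy)
  if (!is.null(pr$deg_knee_mGy)) {
    eta <- eta - (pr$deg_rate %||% 0) * pmax(0, dose_mGy - pr$deg_knee_mGy)
  }
  plogis(eta)
}

size_scale <- function(dose_mGy, params) {
  params$size_floor +
    (1 - params$size_floor) * pmin(1, dose_mGy / params$size_sat_mGy)
}

intensity_scale <- function(dose_mGy, params) {
  params$intensity_lo + (params$intensity_hi - params$intensity_lo) *
    pmin(1, dose_mGy / params$intensity_sat_mGy)
}
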