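#' Factors needed for body-weight SUV conversion
#'
#' Everything required to convert a PET activity-concentration map (Bq/ml)
#' into body-weight standardised uptake values: injected dose, tracer
#' half-life, injection and acquisition times, and patient weight.  Times
#' are seconds on a common clock (seconds since midnight of the acquisition
#' date); an acquisition time earlier than the injection time is assumed to
#' have crossed midnight once and is advanced by 24 h.
#'
#' @param injected_dose injected activity at injection time, Bq (> 0).
#' @param half_life radionuclide half-life, seconds (> 0). FDG: 6586.2 s.
#' @param injection_time injection (radiopharmaceutical start) time, seconds.
#' @param acquisition_time scan acquisition start time, seconds.
#' @param patient_weight patient weight, kg (> 0).
#' @param decay_reference where the stored activity is decay-corrected to;
#'   `"START"` (scan acquisition start, the vendor default) is the only
#'   reference under which the single-exponential injection-to-acquisition
#'   correction below is exact.
#' @return object of class `suv_factors`.
#' @export
suv_factors <- function(injected_dose, half_life, injection_time,
                        acquisition_time, patient_weight,
                        decay_reference = "START") {
  if (!is.numeric(injected_dose) || injected_dose <= 0)
    stop("injected_dose must be > 0 Bq", call. = FALSE)
  if (!is.numeric(half_life) || half_life <= 0)
    stop("half_life must be > 0 s", call. = FALSE)
  if (!is.numeric(patient_weight) || patient_weight <= 0)
    stop("patient_weight must be > 0 kg", call. = FALSE)
  if (acquisition_time < injection_time) {
    # once-only midnight wrap; anything still negative is a data error
    acquisition_time <- acquisition_time + 86400
    if (acquisition_time < injection_time)
      stop("acquisition_time precedes injection_time by more than 24 h",
           call. = FALSE)
  }
  structure(list(injected_dose = as.numeric(injected_dose),
                 half_life = as.numeric(half_life),
                 injection_time = as.numeric(injection_time),
                 acquisition_time = as.numeric(acquisition_time),
                 patient_weight = as.numeric(patient_weight),
                 decay_reference = decay_reference),
            class = "suv_factors")
}

#' @export
print.suv_factors <- function(x, ...) {
  cat(sprintf(
    "<suv_factors> dose %.3g Bq, T1/2 %.1f s, weight %.1f kg, dt %.0f s\n",
    x$injected_dose, x$half_life, x$patient_weight, decay_interval(x)))
  invisible(x)
}

#' Injection-to-acquisition decay interval in seconds
#' @param factors an `suv_factors` object.
#' @export
decay_interval <- function(factors) {
  factors$acquisition_time - factors$injection_time
}

# dose remaining at acquisition start, Bq
decayed_dose <- function(factors) {
  dt <- decay_interval(factors)
  if (dt < 0) stop("negative decay interval", call. = FALSE)
  factors$injected_dose * 2 ^ (-dt / factors$half_life)
}

#' Convert an activity-concentration volume to body-weight SUV
#'
#' `SUV_bw(v) = C(v) / (D * 2^(-dt/T) / (1000 * W))` with `C` in Bq/ml, `D`
#' the injected dose in Bq decayed over `dt = acquisition - injection`
#' seconds with half-life `T`, and `W` the patient weight in kg (`1000 * W`
#' grams; under the 1 g/ml tissue-density convention SUV is dimensionless).
#'
#' @param pet `volume_image` with units `"BQML"`.
#' @param factors an [suv_factors] object.
#' @return `volume_image` with units `"SUV_BW"`.
#' @seealso [suv_to_activity()] for the exact inverse.
#' @export
to_suv_map <- function(pet, factors) {
  stopifnot(inherits(factors, "suv_factors"))
  if (!is_volume_image(pet) || pet$units != "BQML")
    stop("unit error: to_suv_map expects a BQML volume", call. = FALSE)
  denom <- decayed_dose(factors) / (1000 * factors$patient_weight)
  volume_image(pet$data / denom, spacing = pet$spacing, origin = pet$origin,
               units = "SUV_BW")
}

#' Convert a body-weight SUV volume back to activity concentration
#'
#' Exact inverse of [to_suv_map()] for the same factors; used by the phantom
#' generator to write PET series whose SUV conversion recovers the planted
#' uptake values.
#'
#' @param suv `volume_image` with units `"SUV_BW"`.
#' @param factors an [suv_factors] object.
#' @return `volume_image` with units `"BQML"`.
#' @export
suv_to_activity <- function(suv, factors) {
  stopifnot(inherits(factors, "suv_factors"))
  if (!is_volume_image(suv) || suv$units != "SUV_BW")
    stop("unit error: suv_to_activity expects an SUV_BW volume", call. = FALSE)
  denom <- decayed_dose(factors) / (1000 * factors$patient_weight)
  volume_image(suv$data * denom, spacing = suv$spacing, origin = suv$origin,
               units = "BQML")
}
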