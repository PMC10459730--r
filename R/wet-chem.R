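#' Convert spectrophotometric absorbances to pigment concentrations
#'
#' Reference chemistry for 96% ethanol extracts: absorbances at 665, 649
#' and 470 nm map to chlorophyll a, chlorophyll b, total chlorophylls and
#' total carotenoids (mg/L) via the Lichtenthaler-type equations
#' \deqn{Chla = 13.95 A_{665} - 6.88 A_{649}}
#' \deqn{Chlb = 24.96 A_{649} - 7.32 A_{665}}
#' \deqn{Chls = Chla + Chlb}
#' \deqn{Cars = (1000 A_{470} - 2.05\,Chla - 114.8\,Chlb) / 245}
#' The carotenoid numerator is taken whole over 245 (the standard form).
#'
#' @param A665,A649,A470 non-negative absorbances; vectors are converted
#'   elementwise. Replicate measurements should be averaged at the
#'   absorbance level before calling (see [average_absorbances()]).
#' @return data.frame with columns `Chla`, `Chlb`, `Chls`, `Cars` (mg/L).
#'   Negative outputs are allowed but raise a warning: they indicate
#'   physically implausible input.
#' @export
pigments_from_absorbance <- function(A665, A649, A470) {
  stopifnot(length(A665) == length(A649), length(A649) == length(A470))
  if (any(!is.finite(c(A665, A649, A470))) ||
      any(c(A665, A649, A470) < 0)) {
    stop("absorbances must be finite and non-negative")
  }
  chla <- 13.95 * A665 - 6.88 * A649
  chlb <- 24.96 * A649 - 7.32 * A665
  chls <- chla + chlb
  cars <- (1000 * A470 - 2.05 * chla - 114.8 * chlb) / 245
  out <- data.frame(Chla = chla, Chlb = chlb, Chls = chls, Cars = cars)
  if (any(out < 0)) {
    warning("negative pigment concentration: physically implausible absorbances")
  }
  out
}

#' Average replicate absorbance triplets
#'
#' Triplicate spectrophotometer readings are reduced by an unweighted mean
#' per wavelength before conversion to concentrations.
#'
#' @param df data.frame with columns `sample_id`, `A665`, `A649`, `A470`,
#'   one row per replicate.
#' @return data.frame with one row per `sample_id` and mean absorbances.
#' @export
average_absorbances <- function(df) {
  stopifnot(all(c("sample_id", "A665", "A649", "A470") %in% names(df)))
  agg <- stats::aggregate(df[c("A665", "A649", "A470")],
                          by = list(sample_id = df$sample_id), FUN = mean)
  agg[order(agg$sample_id), , drop = FALSE]
}
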