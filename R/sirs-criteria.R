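#' Count systemic inflammation (SIRS) criteria met
#'
#' Counts how many of the four systemic-inflammation criteria a record
#' meets, using the min/max summaries of the first 24 h:
#' \itemize{
#'   \item temperature: \code{Temp.Max} > 38 or \code{Temp.Min} < 36 degC;
#'   \item heart rate: \code{HeartRate.Max} > 90 beats/min;
#'   \item respiration: \code{RR.Max} > 20 breaths/min or \code{PaCO2} <
#'     32 mmHg;
#'   \item white cells: \code{WBC.Max} > 12 or \code{WBC.Min} < 4
#'     (10^3 cells/mm^3), or \code{Immature.Neutrophils} > 10 (percent).
#' }
#' All inequalities are strict; a missing field simply contributes no
#' count, so the result is defined for incomplete records. Study inclusion
#' requires at least two criteria.
#'
#' @param record a data frame (one or more rows) carrying some of the
#'   fields above; absent columns are treated as missing.
#' @return integer vector of criteria counts, 0-4.
#' @examples
#' count_sirs_criteria(data.frame(Temp.Max = 39, HeartRate.Max = 100,
#'                                RR.Max = 22, WBC.Max = 13))  # 4
#' @export
count_sirs_criteria <- function(record) {
  record <- as.data.frame(record)
  n <- nrow(record)
  col <- function(nm) {
    if (nm %in% names(record)) as.numeric(record[[nm]]) else rep(NA_real_, n)
  }
  gt <- function(x, thr) !is.na(x) & x > thr
  lt <- function(x, thr) !is.na(x) & x < thr
  temp <- gt(col("Temp.Max"), 38) | lt(col("Temp.Min"), 36)
  hr <- gt(col("HeartRate.Max"), 90)
  resp <- gt(col("RR.Max"), 20) | lt(col("PaCO2"), 32)
  wbc <- gt(col("WBC.Max"), 12) | lt(col("WBC.Min"), 4) |
    gt(col("Immature.Neutrophils"), 10)
  as.integer(temp) + as.integer(hr) + as.integer(resp) + as.integer(wbc)
}
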