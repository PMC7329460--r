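#' Total nitrogen content from yield and protein concentration
#'
#' `NC = GY x PC / 6.25`, evaluated unit-consistently: GY in t/ha is
#' converted to kg/ha and PC from percent to a fraction, so that
#' `NC [kg N/ha] = 1.6 * GY [t/ha] * PC [%]`. The constant 6.25 is the
#' standard protein-to-nitrogen conversion factor.
#'
#' @param gy grain yield in t/ha (non-negative, vectorised).
#' @param pc protein concentration in percent of grain mass (0-100).
#' @return Nitrogen content in kg N/ha.
#' @examples
#' compute_nc(7.44, 11.49)  # 136.77 kg N/ha
#' @export
compute_nc <- function(gy, pc) {
  if (any(gy < 0, na.rm = TRUE)) stop_domain("negative grain yield")
  if (any(pc < 0 | pc > 100, na.rm = TRUE))
    stop_domain("protein concentration outside [0, 100] %")
  (gy * 1000) * (pc / 100) / 6.25
}

#' Descriptive statistics for a trait column
#'
#' @param records data frame of trait records.
#' @param trait name of the numeric column to summarise.
#' @return One-row data frame: `n`, `mean`, `sd` (sample, n-1 denominator),
#'   `min`, `max`.
#' @export
descriptive_stats <- function(records, trait) {
  if (!trait %in% names(records)) stop_domain("no column '", trait, "'")
  x <- records[[trait]]
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop_domain("no non-missing records for '", trait, "'")
  data.frame(trait = trait, n = length(x), mean = mean(x),
             sd = if (length(x) > 1L) stats::sd(x) else 0,
             min = min(x), max = max(x))
}
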