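#' Unit conversion factors to micrograms per litre
#'
#' All concentrations are held internally in ug/L; native units are retained
#' on the analyte record so reports can be rendered back on the original
#' scale. Conversion is a fixed power-of-ten scaling, so normalising twice
#' is the same as normalising once.
#'
#' @param unit Character vector of units, each one of `"ug/L"`, `"ng/L"`,
#'   `"mg/L"`.
#' @return Numeric multiplier taking a value in `unit` to ug/L.
#' @examples
#' unit_to_ugL_factor(c("ng/L", "mg/L"))  # 0.001, 1000
#' @export
unit_to_ugL_factor <- function(unit) {
  factors <- c("ug/L" = 1, "ng/L" = 1e-3, "mg/L" = 1e3)
  bad <- setdiff(unique(unit), names(factors))
  if (length(bad) > 0) {
    stop("unknown concentration unit(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(factors[unit])
}

#' Convert a concentration to ug/L
#'
#' @param value Numeric concentration in `unit`.
#' @param unit Unit the value is expressed in (see [unit_to_ugL_factor()]).
#' @return Value in ug/L.
#' @export
to_ugL <- function(value, unit) {
  value * unit_to_ugL_factor(unit)
}

#' Convert a ug/L concentration to micromolar
#'
#' Puts water concentrations on the same molar scale as ToxCast activity
#' concentrations at cutoff (ACC, reported in uM):
#' ug/L divided by g/mol gives umol/L.
#'
#' @param conc_ugL Concentration in ug/L.
#' @param molecular_weight Molecular weight in g/mol; must be positive.
#' @return Concentration in micromolar (umol/L).
#' @examples
#' to_molar(100, 100)   # 1 uM
#' @export
to_molar <- function(conc_ugL, molecular_weight) {
  if (any(!is.na(molecular_weight) & molecular_weight <= 0)) {
    stop("molecular_weight must be positive", call. = FALSE)
  }
  conc_ugL / molecular_weight
}
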