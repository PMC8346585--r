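#' Unit conversion table
#'
#' All unit conversions used across the pipeline, centralized so the
#' fmol-per-cell to umol-per-litre chain is audited in one place and never
#' inlined as magic numbers.
#'
#' @format named numeric vector:
#' \describe{
#'   \item{fmol_per_umol}{1e9 fmol in one umol}
#'   \item{pg_per_fmol_C}{12e-3 pg carbon per fmol (molar mass 12 g mol^-1)}
#'   \item{seconds_per_day}{86400}
#'   \item{umol_cm2_per_mmol_m2}{0.1; areal-flux unit rendering}
#'   \item{l_per_ml}{1e-3}
#'   \item{mol_per_pmol}{1e-12}
#' }
#' @export
unit_conversions <- c(
  fmol_per_umol       = 1e9,
  pg_per_fmol_C       = 12e-3,
  seconds_per_day     = 86400,
  umol_cm2_per_mmol_m2 = 0.1,
  l_per_ml            = 1e-3,
  mol_per_pmol        = 1e-12
)

#' Natural abundance of 15N, atom percent
#'
#' Default used by the synthetic generator and examples only; real analyses
#' take the reference from the unincubated control bottle.
#' @export
NAT_ABUNDANCE_15N <- 0.3663

#' Natural abundance of 13C, atom percent
#' @export
NAT_ABUNDANCE_13C <- 1.07
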