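# Physical constants and geometry defaults (SI unless noted).

.kB <- 1.380649e-23 # J/K

# Idealized beta-geometry (nm): residue rise along the strand, inter-strand
# (hydrogen-bond) spacing within a sheet, inter-sheet stacking distance.
.beta_rise <- 0.35
.beta_strand_spacing <- 0.48
.beta_sheet_spacing <- 0.53

#' Van der Waals radii used by the coarse structure builder
#'
#' Bondi radii (nm) for the heavy-atom elements of the coarse backbone+Cbeta
#' representation. Hydrogens are not modeled; their parent heavy atoms carry
#' the plain Bondi radius.
#'
#' @return Named numeric vector of radii in nm.
#' @export
#' @examples
#' silk_vdw_radii()
silk_vdw_radii <- function() {
  c(C = 0.170, N = 0.155, O = 0.152, S = 0.180)
}

# unit helpers
.pN_per_N <- 1e12
.nm_per_m <- 1e9
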