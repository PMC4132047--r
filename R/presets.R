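# Named parameter presets for the two sliding environments the model is
# used to compare: the amorphous-crystalline interface studied here, and
# sliding within the entangled amorphous phase (prior work). The amorphous
# preset is a synthetic calibration chosen to reproduce the reported
# order-of-magnitude viscosity of that environment (1e4 Ns/m^2, about two
# orders above the interface value); it is not a fit to data.

#' Bond-model presets
#'
#' @param which `"interface"` (amorphous-crystalline sliding, this
#'   pipeline's target) or `"amorphous"` (sliding within the amorphous
#'   phase; synthetic calibration to the published order of magnitude).
#' @return A [bond_params()] object.
#' @export
#' @examples
#' viscous_limit(bond_preset("amorphous")) / viscous_limit(bond_preset())
bond_preset <- function(which = c("interface", "amorphous")) {
  which <- match.arg(which)
  switch(which,
         interface = bond_params(ma = 1.32, U_bond = 8.4, m = 2,
                                 xi0 = 1e-12, temperature = 300),
         amorphous = bond_params(ma = 1.32, U_bond = 10.45, m = 2,
                                 xi0 = 1e-12, temperature = 300))
}
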