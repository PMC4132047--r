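# shared fixtures, built once per session

.fx <- new.env(parent = emptyenv())

# reduced composite: 2 units of 3x3 hexa-alanine, 3 bundles of 4 short chains
small_spec <- function() {
  builder_spec(n_units = 2, strands_per_sheet = 3, sheets_per_unit = 3,
               polyala_length = 6, n_bundles = 3, chains_per_bundle = 4,
               amorphous_sequence = "GPGGYGPGSQGP")
}

small_composite <- function() {
  if (is.null(.fx$comp)) .fx$comp <- assemble_composite(small_spec())
  .fx$comp
}

full_composite <- function() {
  if (is.null(.fx$full)) .fx$full <- assemble_composite(builder_spec())
  .fx$full
}

# study-condition ground truth used across emulator tests
study_truth <- function() {
  ground_truth(bond = bond_params(), n_contact = 68, n_total = 1344)
}

n_residues <- function(s) nrow(dplyr::distinct(s[, c("chain_id", "residue_index")]))
n_chains <- function(s) length(unique(s$chain_id))

# 1D uniaxial-stress driver for material-point tests: finds the lateral
# strain that keeps the transverse stresses zero
uni_step <- function(state, dexx, card) {
  f <- function(dl) plastic_update(c(dexx, dl, dl, 0), state, card)$stress[2]
  dl <- uniroot(f, c(-abs(dexx) * 2, abs(dexx) * 2), tol = 1e-16)$root
  plastic_update(c(dexx, dl, dl, 0), state, card)
}
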