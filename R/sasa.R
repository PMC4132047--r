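# Solvent-accessible surface areas (Shrake-Rupley) and the
# amorphous-crystalline contact area used to normalize friction forces.

#' Shrake-Rupley solvent-accessible surface area
#'
#' Samples each atom's expanded sphere (radius + probe) with a deterministic
#' golden-spiral point set and counts points not occluded by any neighbor.
#' Results are bit-reproducible for a fixed `n_points` (no randomness).
#'
#' @param s A `silk_structure` (or any data frame with x, y, z, vdw_radius
#'   in nm).
#' @param probe Solvent probe radius in nm (0.14 nm, the standard water
#'   probe).
#' @param n_points Sphere sample points per atom (>= 32).
#' @return An object of class `silk_sasa`: list with `per_atom` (tibble:
#'   atom index, area nm^2), `total_area`, `probe_radius`, `n_sphere_points`.
#' @export
#' @examples
#' one <- tibble::tibble(x = 0, y = 0, z = 0, vdw_radius = 0.17)
#' sh <- shrake_rupley(one, probe = 0.14, n_points = 960)
#' sh$total_area / (4 * pi * 0.31^2) # ~1
shrake_rupley <- function(s, probe = 0.14, n_points = 960) {
  if (n_points < 32) stop("n_points must be >= 32", call. = FALSE)
  if (probe < 0) stop("probe radius must be >= 0", call. = FALSE)
  if (nrow(s) == 0) {
    return(structure(list(per_atom = tibble::tibble(atom_index = integer(),
                                                    area = numeric()),
                          total_area = 0, probe_radius = probe,
                          n_sphere_points = n_points), class = "silk_sasa"))
  }
  xyz <- as.matrix(s[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates", call. = FALSE)
  if (any(s$vdw_radius <= 0)) stop("vdw_radius must be > 0", call. = FALSE)
  area <- sasa_shrake_rupley_cpp(xyz, s$vdw_radius, probe, as.integer(n_points))
  structure(list(per_atom = tibble::tibble(atom_index = seq_len(nrow(s)),
                                           area = as.numeric(area)),
                 total_area = sum(area), probe_radius = probe,
                 n_sphere_points = n_points),
            class = "silk_sasa")
}

#' Amorphous-crystalline contact area and contacting residues
#'
#' The contact (resistance) area is computed by inclusion-exclusion of
#' solvent-accessible areas: A = (SASA_a + SASA_b - SASA_combined) / 2.
#' A residue is counted as "in contact" when its buried area (isolated
#' minus in-complex SASA summed over its atoms) exceeds `threshold`.
#'
#' @param a,b Two `silk_structure` objects sharing a coordinate frame
#'   (typically the amorphous and crystalline phases of a composite).
#' @param probe Probe radius, nm.
#' @param n_points Sphere sample points per atom.
#' @param threshold Buried-area threshold (nm^2) for counting a residue as
#'   contacting.
#' @return An object of class `silk_contact`: `area_contact` (nm^2),
#'   `n_contact` (residues over both bodies), `n_contact_a`, `n_contact_b`,
#'   and `per_residue` (tibble with body, chain_id, residue_index, phase,
#'   buried area).
#' @export
#' @examples
#' comp <- assemble_composite(builder_spec(n_units = 1, n_bundles = 1,
#'                                         sheets_per_unit = 2,
#'                                         strands_per_sheet = 2))
#' ct <- contact_area(structure_phase(comp, "amorphous"),
#'                    structure_phase(comp, "crystalline"), n_points = 240)
#' ct$area_contact >= 0
contact_area <- function(a, b, probe = 0.14, n_points = 960, threshold = 0.01) {
  empty <- function() {
    structure(list(area_contact = 0, n_contact = 0L, n_contact_a = 0L,
                   n_contact_b = 0L,
                   per_residue = tibble::tibble(body = character(),
                                                chain_id = character(),
                                                residue_index = integer(),
                                                phase = character(),
                                                buried = numeric())),
              class = "silk_contact")
  }
  if (is.null(a) || is.null(b) || nrow(a) == 0 || nrow(b) == 0) return(empty())
  sa <- shrake_rupley(a, probe, n_points)
  sb <- shrake_rupley(b, probe, n_points)
  comb <- dplyr::bind_rows(a, b)
  sc <- shrake_rupley(comb, probe, n_points)
  A <- (sa$total_area + sb$total_area - sc$total_area) / 2

  iso <- c(sa$per_atom$area, sb$per_atom$area)
  buried_atom <- iso - sc$per_atom$area
  per <- comb
  per$body <- rep(c("a", "b"), c(nrow(a), nrow(b)))
  per$buried <- buried_atom
  per_res <- per |>
    dplyr::group_by(.data$body, .data$chain_id, .data$residue_index,
                    .data$phase) |>
    dplyr::summarise(buried = sum(.data$buried), .groups = "drop")
  in_ct <- per_res$buried > threshold
  structure(list(area_contact = max(A, 0),
                 n_contact = sum(in_ct),
                 n_contact_a = sum(in_ct & per_res$body == "a"),
                 n_contact_b = sum(in_ct & per_res$body == "b"),
                 per_residue = per_res),
            class = "silk_contact")
}

#' @export
print.silk_contact <- function(x, ...) {
  cat(sprintf("silk contact: A = %.2f nm^2, %d contacting residues (%d + %d)\n",
              x$area_contact, x$n_contact, x$n_contact_a, x$n_contact_b))
  invisible(x)
}

#' @export
tidy.silk_contact <- function(x, ...) x$per_residue
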