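# Idealized composite builder: polyalanine beta-stack crystal units plus
# extended glycine-rich amorphous chains, coarse heavy-atom representation
# (N, CA, C, O + CB). Coordinates in nm; the pulling axis is y.

.aa3 <- c(A = "ALA", G = "GLY", P = "PRO", Y = "TYR", S = "SER", Q = "GLN",
          C = "CYS", D = "ASP", E = "GLU", F = "PHE", H = "HIS", I = "ILE",
          K = "LYS", L = "LEU", M = "MET", N = "ASN", R = "ARG", T = "THR",
          V = "VAL", W = "TRP")

#' Specification for the silk composite builder
#'
#' Defaults reproduce the composite studied here: two crystalline units of
#' five beta-sheets by five strands of octa-alanine, 3 nm apart, with seven
#' bundles of eight fully extended 24-residue glycine-rich chains placed
#' between and around them.
#'
#' @param n_units Number of crystalline units.
#' @param strands_per_sheet Beta-strands per sheet.
#' @param sheets_per_unit Stacked sheets per crystalline unit.
#' @param polyala_length Residues per crystalline strand.
#' @param n_bundles Number of amorphous bundles.
#' @param chains_per_bundle Chains per amorphous bundle.
#' @param amorphous_sequence One-letter sequence of each amorphous chain.
#' @param unit_gap Surface-to-surface gap between crystalline units, nm.
#' @return A validated `silk_builder_spec` list.
#' @export
#' @examples
#' spec <- builder_spec()
#' spec$n_bundles
builder_spec <- function(n_units = 2, strands_per_sheet = 5, sheets_per_unit = 5,
                         polyala_length = 8, n_bundles = 7, chains_per_bundle = 8,
                         amorphous_sequence = "GPGGYGPGSQGPSGPGGYGPGGPG",
                         unit_gap = 3) {
  counts <- c(n_units = n_units, strands_per_sheet = strands_per_sheet,
              sheets_per_unit = sheets_per_unit, polyala_length = polyala_length,
              chains_per_bundle = chains_per_bundle)
  bad <- counts < 1 | counts != round(counts)
  if (any(bad)) {
    stop("builder counts must be positive integers; invalid: ",
         paste(names(counts)[bad], collapse = ", "), call. = FALSE)
  }
  if (n_bundles < 0 || n_bundles != round(n_bundles)) {
    stop("n_bundles must be a non-negative integer", call. = FALSE)
  }
  if (unit_gap < 0) stop("unit_gap must be >= 0", call. = FALSE)
  if (n_bundles > 0 && (!nzchar(amorphous_sequence) ||
                        !all(strsplit(amorphous_sequence, "")[[1]] %in% names(.aa3)))) {
    stop("amorphous_sequence must be a non-empty one-letter amino-acid string",
         call. = FALSE)
  }
  structure(list(n_units = n_units, strands_per_sheet = strands_per_sheet,
                 sheets_per_unit = sheets_per_unit, polyala_length = polyala_length,
                 n_bundles = n_bundles, chains_per_bundle = chains_per_bundle,
                 amorphous_sequence = amorphous_sequence, unit_gap = unit_gap),
            class = "silk_builder_spec")
}

# one fully extended chain along +/- y; coarse backbone + CB (except glycine)
.chain_atoms <- function(sequence, chain_id, phase, origin = c(0, 0, 0),
                         direction = 1) {
  aa <- strsplit(sequence, "")[[1]]
  nres <- length(aa)
  radii <- silk_vdw_radii()
  rows <- vector("list", nres)
  for (i in seq_len(nres)) {
    yc <- origin[2] + direction * (i - 1) * .beta_rise
    pleat <- if (i %% 2 == 1) 1 else -1
    at <- list(
      c("N", "N", origin[1] - 0.05, yc - direction * 0.12, origin[3]),
      c("CA", "C", origin[1], yc, origin[3]),
      c("C", "C", origin[1] + 0.05, yc + direction * 0.12, origin[3]),
      c("O", "O", origin[1] + 0.17, yc + direction * 0.12, origin[3])
    )
    if (aa[i] != "G") {
      at <- c(at, list(c("CB", "C", origin[1], yc, origin[3] + pleat * 0.153)))
    }
    m <- do.call(rbind, at)
    rows[[i]] <- tibble::tibble(
      atom = m[, 1], element = m[, 2],
      x = as.numeric(m[, 3]), y = as.numeric(m[, 4]), z = as.numeric(m[, 5]),
      vdw_radius = unname(radii[m[, 2]]),
      residue_index = i, residue_name = unname(.aa3[aa[i]]),
      chain_id = chain_id, phase = phase
    )
  }
  dplyr::bind_rows(rows)
}

.as_structure <- function(atoms, box = NULL) {
  if (is.null(box)) {
    box <- c(diff(range(atoms$x)), diff(range(atoms$y)), diff(range(atoms$z))) + 2
  }
  structure(atoms, class = c("silk_structure", class(tibble::tibble())),
            box = box)
}

.shift <- function(s, dx = 0, dy = 0, dz = 0) {
  s$x <- s$x + dx
  s$y <- s$y + dy
  s$z <- s$z + dz
  s
}

#' Build one crystalline beta-stack unit
#'
#' Strands run along y (the pulling axis) with alternating direction
#' (antiparallel sheets); strands are spaced 0.48 nm within a sheet and
#' sheets stacked 0.53 nm apart along z.
#'
#' @param spec A [builder_spec()].
#' @param id_offset Integer offset for chain numbering.
#' @return A `silk_structure` tibble of atoms tagged `phase = "crystalline"`.
#' @export
#' @examples
#' u <- build_crystal_unit(builder_spec())
#' length(unique(u$chain_id)) # 25 chains
build_crystal_unit <- function(spec, id_offset = 0) {
  stopifnot(inherits(spec, "silk_builder_spec"))
  seqc <- strrep("A", spec$polyala_length)
  chains <- list()
  idx <- 0
  for (h in seq_len(spec$sheets_per_unit) - 1) {
    for (s in seq_len(spec$strands_per_sheet) - 1) {
      idx <- idx + 1
      dir <- if (s %% 2 == 0) 1 else -1
      orig <- c(s * .beta_strand_spacing,
                if (dir == 1) 0 else (spec$polyala_length - 1) * .beta_rise,
                h * .beta_sheet_spacing)
      chains[[idx]] <- .chain_atoms(seqc, sprintf("C%03d", idx + id_offset),
                                    "crystalline", orig, dir)
    }
  }
  .as_structure(dplyr::bind_rows(chains))
}

#' Build one bundle of fully extended amorphous chains
#'
#' Chains are laid out in parallel on a square cross-section grid (0.55 nm
#' spacing, center position left empty) and run along +y.
#'
#' @param spec A [builder_spec()].
#' @param anchor xyz position (nm) of the bundle origin (first residue plane).
#' @param id_offset Integer offset for chain numbering.
#' @return A `silk_structure` tibble tagged `phase = "amorphous"`.
#' @export
#' @examples
#' b <- build_amorphous_bundle(builder_spec())
#' length(unique(b$chain_id)) # 8 chains
build_amorphous_bundle <- function(spec, anchor = c(0, 0, 0), id_offset = 0) {
  stopifnot(inherits(spec, "silk_builder_spec"))
  if (!nzchar(spec$amorphous_sequence)) stop("amorphous_sequence is empty")
  n <- spec$chains_per_bundle
  k <- ceiling(sqrt(n + 1))
  g <- expand.grid(ix = seq_len(k) - (k + 1) / 2, iz = seq_len(k) - (k + 1) / 2)
  g <- g[order(g$ix^2 + g$iz^2), ]
  g <- g[-1, , drop = FALSE] # drop the center slot
  g <- g[seq_len(n), , drop = FALSE]
  chains <- lapply(seq_len(n), function(i) {
    .chain_atoms(spec$amorphous_sequence, sprintf("A%03d", i + id_offset),
                 "amorphous",
                 anchor + c(g$ix[i] * 0.55, 0, g$iz[i] * 0.55), 1)
  })
  .as_structure(dplyr::bind_rows(chains))
}

# minimum inter-atom distance between two atom sets, bounding-box prefiltered
.min_cross_dist <- function(a, b, cutoff = 1.0) {
  bb <- function(s) c(range(s$x), range(s$y), range(s$z))
  ba <- bb(a); bbx <- bb(b)
  sel_a <- a$x > bbx[1] - cutoff & a$x < bbx[2] + cutoff &
    a$y > bbx[3] - cutoff & a$y < bbx[4] + cutoff &
    a$z > bbx[5] - cutoff & a$z < bbx[6] + cutoff
  sel_b <- b$x > ba[1] - cutoff & b$x < ba[2] + cutoff &
    b$y > ba[3] - cutoff & b$y < ba[4] + cutoff &
    b$z > ba[5] - cutoff & b$z < ba[6] + cutoff
  if (!any(sel_a) || !any(sel_b)) return(Inf)
  A <- as.matrix(a[sel_a, c("x", "y", "z")])
  B <- as.matrix(b[sel_b, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(max(min(d2), 0))
}

#' Assemble the full crystalline/amorphous composite
#'
#' Crystalline units are separated by `unit_gap` along z (their stacking
#' axis); amorphous bundles are placed between and around them with 0.35 nm
#' clearance, their upper termini aligned with the crystal top so that
#' sliding them upward keeps full contact over
#' (bundle length - crystal length) before detachment begins. The layout is
#' deterministic: identical specs give bit-identical structures.
#'
#' @param spec A [builder_spec()].
#' @param clearance Placement clearance between bundle and crystal atom
#'   centers, nm.
#' @return A `silk_structure` tibble of the whole composite.
#' @export
#' @examples
#' comp <- assemble_composite(builder_spec())
#' table(substr(unique(comp$chain_id), 1, 1)) # 50 C + 56 A chains
assemble_composite <- function(spec, clearance = 0.35) {
  stopifnot(inherits(spec, "silk_builder_spec"))
  units <- list()
  n_chain <- spec$strands_per_sheet * spec$sheets_per_unit
  for (uidx in seq_len(spec$n_units)) {
    u <- build_crystal_unit(spec, id_offset = (uidx - 1) * n_chain)
    u <- .shift(u, dx = -mean(range(u$x)), dz = -mean(range(u$z)))
    units[[uidx]] <- u
  }
  # stack units along z with the prescribed surface-to-surface gap
  zext <- diff(range(units[[1]]$z))
  pitch <- zext + spec$unit_gap
  z0 <- -(spec$n_units - 1) * pitch / 2
  units <- lapply(seq_along(units), function(i) {
    .shift(units[[i]], dz = z0 + (i - 1) * pitch)
  })
  cryst <- .as_structure(dplyr::bind_rows(units))

  if (spec$n_bundles == 0) return(cryst)

  proto <- build_amorphous_bundle(spec)
  bxw <- diff(range(proto$x)) / 2
  bzw <- diff(range(proto$z)) / 2
  ytop_c <- max(cryst$y)
  lb <- diff(range(proto$y))
  xlo <- min(cryst$x); xhi <- max(cryst$x)
  zlo <- min(cryst$z); zhi <- max(cryst$z)
  # placement slots: one central (between units), then a ring around the
  # assembly; extra bundles go to an outer ring
  ring <- list(c(-1.0, zhi + clearance + bzw), c(1.0, zhi + clearance + bzw),
               c(-1.0, zlo - clearance - bzw), c(1.0, zlo - clearance - bzw),
               c(xhi + clearance + bxw, 0), c(xlo - clearance - bxw, 0))
  slots <- c(list(c(0, 0)), ring,
             lapply(ring, function(p) p * 1.9 + sign(p) * 1.2))
  if (spec$n_bundles > length(slots)) {
    stop("too many bundles for the deterministic layout (max ",
         length(slots), ")", call. = FALSE)
  }
  bundles <- lapply(seq_len(spec$n_bundles), function(i) {
    p <- slots[[i]]
    build_amorphous_bundle(spec,
                           anchor = c(p[1], ytop_c - lb + 0.12, p[2]),
                           id_offset = (i - 1) * spec$chains_per_bundle)
  })
  amor <- .as_structure(dplyr::bind_rows(bundles))

  dmin <- .min_cross_dist(amor, cryst)
  for (i in seq_along(bundles)) {
    for (j in seq_along(bundles)) {
      if (j > i) dmin <- min(dmin, .min_cross_dist(bundles[[i]], bundles[[j]]))
    }
  }
  if (dmin < 0.2) {
    stop(sprintf("placement clash: minimum inter-body distance %.3f nm < 0.2 nm",
                 dmin), call. = FALSE)
  }
  .as_structure(dplyr::bind_rows(cryst, amor))
}

#' Split a structure by phase
#'
#' @param s A `silk_structure`.
#' @param phase `"crystalline"` or `"amorphous"`.
#' @return The `silk_structure` subset.
#' @export
structure_phase <- function(s, phase = c("crystalline", "amorphous")) {
  phase <- match.arg(phase)
  .as_structure(dplyr::filter(s, .data$phase == !!phase), box = attr(s, "box"))
}

#' Write a structure as PDB
#'
#' Coordinates are converted from nm to Angstrom; the chain identity and
#' phase tag are encoded in the 4-character segment id (`C###` crystalline,
#' `A###` amorphous), with the one-letter chain column cycled for viewers.
#'
#' @param s A `silk_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  if (is.null(s) || nrow(s) == 0) stop("cannot write an empty structure")
  chains <- unique(s$chain_id)
  chain_letter <- setNames(rep(LETTERS, length.out = length(chains)), chains)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(s[, c("x", "y", "z")])) * 10),
    resno = s$residue_index,
    resid = s$residue_name,
    eleno = seq_len(nrow(s)),
    elety = s$atom,
    chain = unname(chain_letter[s$chain_id]),
    segid = s$chain_id,
    elesy = s$element,
    o = rep(1, nrow(s)), b = rep(0, nrow(s))
  )
  # stamp the segment id (cols 73-76); bio3d's writer leaves it blank
  lines <- readLines(path, warn = FALSE)
  rec <- grep("^(ATOM|HETATM)", lines)
  seg4 <- sprintf("%-4s", s$chain_id)
  for (i in seq_along(rec)) {
    l <- lines[rec[i]]
    if (nchar(l) < 76) l <- sprintf("%-76s", l)
    substr(l, 73, 76) <- seg4[i]
    lines[rec[i]] <- l
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a structure written by [write_pdb()]
#'
#' @param path PDB file path.
#' @return A `silk_structure` tibble (coordinates in nm).
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  at <- grep("^(ATOM|HETATM)", lines)
  for (ln in at) {
    l <- lines[ln]
    if (nchar(l) < 54 ||
        anyNA(suppressWarnings(as.numeric(c(substr(l, 31, 38), substr(l, 39, 46),
                                            substr(l, 47, 54)))))) {
      stop(sprintf("malformed PDB record at line %d of %s", ln, path),
           call. = FALSE)
    }
  }
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  seg <- trimws(a$segid)
  ph <- dplyr::case_when(substr(seg, 1, 1) == "C" ~ "crystalline",
                         substr(seg, 1, 1) == "A" ~ "amorphous",
                         TRUE ~ NA_character_)
  if (anyNA(ph)) {
    stop("PDB lacks the phase-tagged segment ids this package writes",
         call. = FALSE)
  }
  radii <- silk_vdw_radii()
  el <- ifelse(nzchar(trimws(a$elesy)), trimws(a$elesy),
               substr(trimws(a$elety), 1, 1))
  tib <- tibble::tibble(
    atom = trimws(a$elety), element = el,
    x = a$x / 10, y = a$y / 10, z = a$z / 10,
    vdw_radius = unname(radii[el]),
    residue_index = a$resno, residue_name = trimws(a$resid),
    chain_id = seg, phase = ph
  )
  if (anyNA(tib$vdw_radius)) stop("unknown element in PDB; no vdW radius")
  .as_structure(tib)
}
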