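# Voxel-grid solvent-excluded volume. The solvent-excluded (SES) region is
# the complement of the space reachable by a spherical probe: a probe centre
# is allowed anywhere farther than (r_vdw + r_probe) from every atom, and the
# excluded region is everything not within r_probe of an allowed centre —
# i.e. the morphological closing of the van der Waals region by the probe
# ball. On the grid: mark voxels within (r_i + probe) of any atom (the
# dilated set D), dilate D's complement by the probe ball, and keep the
# voxels the dilated complement does not reach.

# Bondi van der Waals radii (Angstrom) for the elements found in protein and
# nucleic-acid structures.
.VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                P = 1.80, SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85,
                I = 1.98, FE = 2.00, ZN = 1.39, MG = 1.73, "NA" = 2.27,
                K = 2.75, CA = 2.31, MN = 2.00)

#' Solvent-excluded volume of a set of atoms on a voxel grid
#'
#' Estimates the volume enclosed by the solvent-excluded surface of a set of
#' spheres (atoms with van der Waals radii) rolled by a spherical probe.
#' Voxels within `r_vdw + probe_radius` of any atom are marked, then voxels
#' reachable by a probe from outside (within `probe_radius` of the marked
#' region's complement) are removed; the remaining voxel count times the
#' voxel volume is the SES volume. The estimate converges (from above, for
#' the default centre-sampling rule) as `grid_spacing` decreases.
#'
#' @param xyz numeric matrix (n x 3) of atom coordinates, Angstrom.
#' @param elements character vector of element symbols (length n), looked up
#'   in the Bondi radius table; unknown elements are an error naming them.
#' @param radii optional explicit van der Waals radii (Angstrom), overriding
#'   the element lookup.
#' @param probe_radius solvent probe radius, Angstrom (default 1.4, water).
#' @param grid_spacing voxel edge length, Angstrom (default 0.5).
#' @return volume in Angstrom^3.
#' @examples
#' # an isolated carbon atom: SES volume is its own vdW sphere
#' ses_volume(matrix(0, 1, 3), "C", grid_spacing = 0.3)
#' @export
ses_volume <- function(xyz, elements = NULL, radii = NULL,
                       probe_radius = 1.4, grid_spacing = 0.5) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L || nrow(xyz) < 1L || anyNA(xyz)) {
    stop_field("xyz", "must be an n x 3 matrix of finite coordinates")
  }
  check_positive(probe_radius, "probe_radius")
  check_positive(grid_spacing, "grid_spacing")
  if (is.null(radii)) {
    if (is.null(elements)) stop_field("elements", "supply `elements` or `radii`")
    el <- toupper(trimws(elements))
    unknown <- setdiff(unique(el), names(.VDW_RADII))
    if (length(unknown)) {
      stop(sprintf("no van der Waals radius for element(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    radii <- unname(.VDW_RADII[el])
  }
  check_positive(radii, "radii")
  if (length(radii) != nrow(xyz)) stop_field("radii", "length must match rows of xyz")

  s <- grid_spacing
  pad <- max(radii) + 2 * probe_radius + 3 * s
  gx <- seq(min(xyz[, 1]) - pad, max(xyz[, 1]) + pad, by = s)
  gy <- seq(min(xyz[, 2]) - pad, max(xyz[, 2]) + pad, by = s)
  gz <- seq(min(xyz[, 3]) - pad, max(xyz[, 3]) + pad, by = s)
  dims <- c(length(gx), length(gy), length(gz))

  # exact signed clearance to the enlarged atom balls:
  # dE(x) = min_i( |x - a_i| - (r_i + probe) ), computed per atom on local
  # sub-blocks out to a margin that covers every voxel whose sign or shell
  # membership the atom could decide
  dE <- array(Inf, dims)
  margin <- probe_radius + 2 * s * sqrt(3)
  for (i in seq_len(nrow(xyz))) {
    r <- radii[i] + probe_radius
    reach <- r + margin
    ix <- which(abs(gx - xyz[i, 1]) <= reach)
    iy <- which(abs(gy - xyz[i, 2]) <= reach)
    iz <- which(abs(gz - xyz[i, 3]) <= reach)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (gx[ix] - xyz[i, 1])^2
    dy2 <- (gy[iy] - xyz[i, 2])^2
    dz2 <- (gz[iz] - xyz[i, 3])^2
    dist <- sqrt(outer(outer(dx2, dy2, `+`), dz2, `+`)) - r
    dE[ix, iy, iz] <- pmin(dE[ix, iy, iz], dist)
  }

  # probe sources: thin shell of allowed voxels just outside the enlarged
  # region; each carries its exact clearance, so the ball B(z, dE(z)) is
  # known solvent-accessible. A voxel x is solvent-excluded iff
  # min_z (|x - z| - dE(z)) > probe, which for the spherical boundary
  # patches of the enlarged region is exact up to O(spacing^2).
  shell <- which(dE > 0 & dE <= s * sqrt(3))
  inside <- dE <= 0
  m <- array(Inf, dims)
  if (length(shell)) {
    reach_vox <- ceiling((probe_radius + s * sqrt(3)) / s)
    steps <- -reach_vox:reach_vox
    offd <- sqrt(outer(outer(steps^2, steps^2, `+`), steps^2, `+`)) * s
    arr_ind <- arrayInd(shell, dims)
    for (k in seq_along(shell)) {
      ctr <- arr_ind[k, ]
      xs <- (ctr[1] + steps); ys <- (ctr[2] + steps); zs <- (ctr[3] + steps)
      okx <- xs >= 1 & xs <= dims[1]
      oky <- ys >= 1 & ys <= dims[2]
      okz <- zs >= 1 & zs <= dims[3]
      val <- offd[okx, oky, okz, drop = FALSE] - dE[shell[k]]
      blk <- m[xs[okx], ys[oky], zs[okz], drop = FALSE]
      m[xs[okx], ys[oky], zs[okz]] <- pmin(blk, val)
    }
  }
  # fractional (smoothed-interface) quadrature: m - probe is an accurate
  # signed distance to the SES surface near the boundary, so weighting each
  # voxel by a one-voxel-wide linear ramp removes lattice-alignment bias
  # (voxels with positive clearance are themselves solvent-accessible and at
  # least one probe radius away from the surface: weight 0)
  d <- m - probe_radius
  w <- array(0, dims)
  w[inside] <- pmin(pmax(d[inside] / s + 0.5, 0), 1)
  sum(w) * s^3
}

#' Protein specific volume from a crystal structure
#'
#' Derives the specific volume (ml/g) of a structure as its solvent-excluded
#' volume divided by the mass of the atoms actually present in the model —
#' residues missing from the coordinates contribute no volume and therefore
#' no mass. This is the route by which the 0.67 ml/g conversion constant used
#' in [volume_to_mw()] is obtained from structures of the relevant protein
#' families.
#'
#' @param pdb path to a PDB file, or a `bio3d` `pdb` object. Hydrogens are
#'   typically absent from crystal structures; the heavy-atom Bondi radii
#'   absorb them implicitly.
#' @param chain optional chain identifier(s) to restrict to.
#' @param probe_radius solvent probe radius, Angstrom (default 1.4).
#' @param grid_spacing voxel edge, Angstrom (default 0.5).
#' @return list with `specific_volume_ml_g`, `ses_volume_A3`, `mass_da`,
#'   `n_atoms`.
#' @export
specific_volume_from_structure <- function(pdb, chain = NULL,
                                           probe_radius = 1.4,
                                           grid_spacing = 0.5) {
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb)
  at <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  at <- at[at$resid != "HOH", , drop = FALSE]
  if (!is.null(chain)) at <- at[at$chain %in% chain, , drop = FALSE]
  if (!nrow(at)) stop_field("pdb", "no atoms after filtering")
  el <- toupper(trimws(at$elesy))
  el[el == "" | is.na(el)] <- toupper(substr(trimws(at$elety[el == "" | is.na(el)]), 1, 1))
  xyz <- cbind(at$x, at$y, at$z)
  v <- ses_volume(xyz, elements = el, probe_radius = probe_radius,
                  grid_spacing = grid_spacing)
  mass <- sum(.tv_atomic_mass(el))
  # Angstrom^3 -> cm^3 is 1e-24; Da -> g is 1/N_A
  sv <- (v * 1e-24) / (mass / .AVOGADRO)
  list(specific_volume_ml_g = sv, ses_volume_A3 = v, mass_da = mass,
       n_atoms = nrow(at))
}

# standard atomic weights (Da) for the elements in the radius table
.ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                  P = 30.974, SE = 78.971, F = 18.998, CL = 35.45,
                  BR = 79.904, I = 126.904, FE = 55.845, ZN = 65.38,
                  MG = 24.305, "NA" = 22.990, K = 39.098, CA = 40.078,
                  MN = 54.938)

.tv_atomic_mass <- function(elements) {
  el <- toupper(trimws(elements))
  unknown <- setdiff(unique(el), names(.ATOMIC_MASS))
  if (length(unknown)) {
    stop(sprintf("no atomic mass for element(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  unname(.ATOMIC_MASS[el])
}
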