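#' Elliptic-cylinder volume of an AFM particle
#'
#' AFM peaks of deposited protein complexes are modelled as elliptic
#' cylinders: \eqn{V = \pi h r_{long} r_{orth}}, with the radii equal to half
#' of the measured widths at half-height. (A spherical-segment model
#' under-estimates and a rectangular box over-estimates the volumes of
#' globular protein complexes relative to their expected molecular weights;
#' the elliptic cylinder is the geometry that matches.)
#'
#' @param h peak height, nm (> 0).
#' @param w_long width at half-height along the long axis, nm (> 0).
#' @param w_orth width at half-height along the orthogonal axis, nm (> 0).
#' @return volume in nm^3. Symmetric in `w_long`/`w_orth`.
#' @examples
#' elliptic_cylinder_volume(1, 2, 2)  # pi
#' @export
elliptic_cylinder_volume <- function(h, w_long, w_orth) {
  check_positive(h, "h"); check_positive(w_long, "w_long"); check_positive(w_orth, "w_orth")
  pi * h * (w_long / 2) * (w_orth / 2)
}

#' Cylindrical-segment volume of an adjacent DNA stretch
#'
#' DNA lying on the substrate next to a bound complex is modelled as a
#' cylindrical segment with volume \eqn{V = (2/3)\, h_{DNA}\, w_{DNA}^2},
#' from its measured height and width at half-height.
#'
#' @param h_dna DNA height, nm (> 0 allowed to be arbitrarily small).
#' @param w_dna DNA width at half-height, nm (> 0).
#' @return volume in nm^3.
#' @examples
#' dna_segment_volume(1.5, 1)  # 1
#' @export
dna_segment_volume <- function(h_dna, w_dna) {
  check_nonneg(h_dna, "h_dna"); check_positive(w_dna, "w_dna")
  (2 / 3) * h_dna * w_dna^2
}

#' Net protein volume of measured AFM peaks
#'
#' Computes the gross elliptic-cylinder volume of each peak and, for
#' DNA-bound peaks, subtracts the cylindrical-segment volume of the adjacent
#' DNA so that only protein volume remains. A negative net volume indicates a
#' measurement problem; such rows are flagged (`flagged = TRUE`) rather than
#' silently clamped, and are excluded downstream by default.
#'
#' @param peaks `data.frame` with columns `peak_id`, `h_nm`, `w_long_nm`,
#'   `w_orth_nm`, `dna_bound` (logical) and, for DNA-bound rows, `h_dna_nm`
#'   and `w_dna_nm`.
#' @return the input with added columns `gross_volume_nm3`, `dna_volume_nm3`,
#'   `net_volume_nm3` and `flagged`.
#' @seealso [afm_mass_table()] for the full volume-to-mass chain.
#' @export
net_protein_volume <- function(peaks) {
  req <- c("peak_id", "h_nm", "w_long_nm", "w_orth_nm", "dna_bound")
  miss <- setdiff(req, names(peaks))
  if (length(miss)) stop_field("peaks", paste("missing column(s):", paste(miss, collapse = ", ")))
  bound <- as.logical(peaks$dna_bound)
  if (any(bound)) {
    if (!all(c("h_dna_nm", "w_dna_nm") %in% names(peaks)) ||
        anyNA(peaks$h_dna_nm[bound]) || anyNA(peaks$w_dna_nm[bound]) ||
        any(peaks$h_dna_nm[bound] <= 0) || any(peaks$w_dna_nm[bound] <= 0)) {
      stop_field("peaks", "DNA-bound peaks require positive h_dna_nm and w_dna_nm")
    }
  }
  gross <- elliptic_cylinder_volume(peaks$h_nm, peaks$w_long_nm, peaks$w_orth_nm)
  dna <- rep(0, nrow(peaks))
  if (any(bound)) dna[bound] <- dna_segment_volume(peaks$h_dna_nm[bound], peaks$w_dna_nm[bound])
  net <- gross - dna
  peaks$gross_volume_nm3 <- gross
  peaks$dna_volume_nm3 <- dna
  peaks$net_volume_nm3 <- net
  peaks$flagged <- net < 0
  peaks
}

# Avogadro constant, exact SI value (Da per gram)
.AVOGADRO <- 6.02214076e23

#' Convert particle volume to molecular weight via a protein specific volume
#'
#' \eqn{M = V \times 10^{-21} / \bar v \times N_A} with \eqn{V} in nm^3 and
#' the specific volume \eqn{\bar v} in ml/g. The default 0.67 ml/g is the
#' protein specific volume derived from the solvent-excluded volumes of
#' crystal structures of the relevant protein families (see
#' [specific_volume_from_structure()] for the derivation on any structure).
#'
#' @param volume_nm3 volume(s), nm^3, >= 0.
#' @param specific_volume specific volume, ml/g (> 0); default 0.67.
#' @return molecular weight(s) in Da. Exact inverse of [mw_to_volume()].
#' @examples
#' volume_to_mw(67)  # 60221.4 Da at 0.67 ml/g
#' @export
volume_to_mw <- function(volume_nm3, specific_volume = 0.67) {
  check_nonneg(volume_nm3, "volume_nm3")
  check_positive(specific_volume, "specific_volume")
  volume_nm3 * 1e-21 / specific_volume * .AVOGADRO
}

#' @rdname volume_to_mw
#' @param mass_da molecular weight(s), Da, >= 0.
#' @export
mw_to_volume <- function(mass_da, specific_volume = 0.67) {
  check_nonneg(mass_da, "mass_da")
  check_positive(specific_volume, "specific_volume")
  mass_da / .AVOGADRO * specific_volume * 1e21
}

#' Reference mass ladder for dimer-multiple complexes
#'
#' Builds the expected molecular weights of homodimers and higher-order
#' dimer-of-dimer complexes from monomer masses. With the default E. coli
#' monomer masses (Cra 37,999 Da; FruK 33,756 Da) the ladder contains the two
#' homodimers — the (dimer)1 tier, whose similar masses make them hard to
#' distinguish — the (dimer)2 heterocomplex Cra2:FruK2, and the (dimer)3
#' complex Cra2:FruK2:Cra2 (a FruK dimer bridging two Cra dimers, the
#' composition deduced from the requirement that DNA-bound complexes contain
#' Cra and that single-protein samples contain only homodimers).
#'
#' @param monomers named numeric vector of monomer masses in Da; exactly two
#'   species, the first DNA-binding (default `c(Cra = 37999, FruK = 33756)`).
#' @return object of class `"reference_ladder"`: a `data.frame` with columns
#'   `label`, `tier` (1, 2 or 3 = number of homodimers), `composition` and
#'   `mass_da`, sorted by mass.
#' @examples
#' reference_ladder()
#' @export
reference_ladder <- function(monomers = c(Cra = 37999, FruK = 33756)) {
  check_positive(monomers, "monomers")
  if (length(monomers) != 2L || is.null(names(monomers))) {
    stop_field("monomers", "must be a named vector of two monomer masses")
  }
  a <- names(monomers)[1]; b <- names(monomers)[2]
  ladder <- data.frame(
    label = c(paste0(a, " homodimer"), paste0(b, " homodimer"),
              paste0(a, "2:", b, "2"), paste0(a, "2:", b, "2:", a, "2")),
    tier = c(1L, 1L, 2L, 3L),
    composition = c(paste0("2x", a), paste0("2x", b),
                    paste0("2x", a, " + 2x", b),
                    paste0("4x", a, " + 2x", b)),
    mass_da = c(2 * monomers[[1]], 2 * monomers[[2]],
                2 * monomers[[1]] + 2 * monomers[[2]],
                4 * monomers[[1]] + 2 * monomers[[2]]),
    stringsAsFactors = FALSE)
  ladder <- ladder[order(ladder$mass_da), ]
  rownames(ladder) <- NULL
  structure(ladder, class = c("reference_ladder", "data.frame"))
}

#' @export
print.reference_ladder <- function(x, ...) {
  cat("Reference mass ladder (Da):\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Full AFM volume-to-mass chain
#'
#' Runs [net_protein_volume()] and [volume_to_mw()] over a table of measured
#' peaks, producing one mass estimate per peak. Rows with negative net volume
#' are flagged and, by default, dropped from the returned table.
#'
#' @inheritParams net_protein_volume
#' @inheritParams volume_to_mw
#' @param drop_flagged drop rows whose net volume is negative (default TRUE).
#' @return `data.frame` with `peak_id`, `gross_volume_nm3`, `dna_volume_nm3`,
#'   `net_volume_nm3`, `mass_da`, `specific_volume`, `flagged`.
#' @examples
#' peaks <- simulate_afm_peaks(n = 5, noise_frac = 0, seed = 1)$peaks
#' afm_mass_table(peaks)
#' @export
afm_mass_table <- function(peaks, specific_volume = 0.67, drop_flagged = TRUE) {
  v <- net_protein_volume(peaks)
  out <- data.frame(peak_id = v$peak_id,
                    gross_volume_nm3 = v$gross_volume_nm3,
                    dna_volume_nm3 = v$dna_volume_nm3,
                    net_volume_nm3 = v$net_volume_nm3,
                    mass_da = ifelse(v$flagged, NA_real_,
                                     volume_to_mw(pmax(v$net_volume_nm3, 0), specific_volume)),
                    specific_volume = specific_volume,
                    flagged = v$flagged,
                    stringsAsFactors = FALSE)
  if (drop_flagged) out <- out[!out$flagged, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Average (isotope-abundance-weighted) residue masses, Da, plus one water for
# the free termini of an unmodified chain.
.RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.WATER_MASS <- 18.01528

#' Average molecular weight of a protein sequence
#'
#' Average isotopic mass of an unmodified polypeptide chain (residue masses
#' plus one water). Accepts a character string of one-letter codes or a FASTA
#' file path (read with bio3d).
#'
#' @param x amino-acid sequence (one-letter codes) or path to a FASTA file.
#' @return named numeric vector of masses in Da (one per sequence).
#' @examples
#' protein_mass("ACDEFGHIKLMNPQRSTVWY")
#' @export
protein_mass <- function(x) {
  seqs <- if (length(x) == 1L && file.exists(x)) {
    fa <- bio3d::read.fasta(x)
    ali <- fa$ali
    out <- apply(ali, 1L, function(r) paste(r[r != "-"], collapse = ""))
    stats::setNames(as.character(out), rownames(ali))
  } else {
    stats::setNames(as.character(x), names(x) %||% seq_along(x))
  }
  vapply(seqs, function(s) {
    aa <- strsplit(toupper(s), "")[[1]]
    aa <- aa[aa != "*"]
    unknown <- setdiff(unique(aa), names(.RESIDUE_MASS))
    if (length(unknown)) {
      stop_field("x", paste("unknown residue(s):", paste(unknown, collapse = ", ")))
    }
    sum(.RESIDUE_MASS[aa]) + .WATER_MASS
  }, numeric(1))
}
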