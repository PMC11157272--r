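test_that("elliptic-cylinder volume matches closed forms and is symmetric", {
  expect_equal(elliptic_cylinder_volume(1, 2, 2), pi)
  expect_equal(elliptic_cylinder_volume(2.5, 8, 6), 30 * pi)
  expect_equal(elliptic_cylinder_volume(1.3, 4.2, 7.7),
               elliptic_cylinder_volume(1.3, 7.7, 4.2))
  expect_error(elliptic_cylinder_volume(-1, 2, 2), "h")
})

test_that("DNA cylindrical-segment volume matches the printed form", {
  expect_equal(dna_segment_volume(1.5, 1), 1.0)
  expect_equal(dna_segment_volume(0.5, 6), 12.0)
  expect_equal(dna_segment_volume(0, 6), 0)  # degenerate height limit
  expect_error(dna_segment_volume(1, 0), "w_dna")
})

test_that("volume operations are homogeneous of degree 3 in lengths", {
  s <- 1.7
  expect_equal(elliptic_cylinder_volume(s * 2, s * 3, s * 4),
               s^3 * elliptic_cylinder_volume(2, 3, 4))
  expect_equal(dna_segment_volume(s * 0.5, s * 6),
               s^3 * dna_segment_volume(0.5, 6))
})

test_that("net protein volume subtracts adjacent DNA and flags negatives", {
  peaks <- data.frame(
    peak_id = c("free", "bound", "bad"),
    h_nm = c(2.5, 2.5, 0.2), w_long_nm = c(8, 8, 1), w_orth_nm = c(6, 6, 1),
    dna_bound = c(FALSE, TRUE, TRUE),
    h_dna_nm = c(NA, 0.5, 2), w_dna_nm = c(NA, 6, 6))
  v <- net_protein_volume(peaks)
  expect_equal(v$net_volume_nm3[1], 30 * pi)
  expect_equal(v$dna_volume_nm3[1], 0)
  expect_equal(v$net_volume_nm3[2], 30 * pi - 12)
  expect_true(v$flagged[3])   # DNA volume exceeds the gross peak volume
  masses <- afm_mass_table(peaks)
  expect_false("bad" %in% masses$peak_id)  # flagged rows excluded by default
  # DNA-bound peak without DNA measurements is a validation error
  bad <- peaks; bad$h_dna_nm[2] <- NA
  expect_error(net_protein_volume(bad), "h_dna")
})

test_that("volume-to-mass conversion matches the unit analysis and inverts", {
  # 67 nm^3 at 0.67 ml/g is 1e-19 g, i.e. Avogadro x 1e-19 Da
  expect_equal(volume_to_mw(67), 6.02214076e23 * 1e-19, tolerance = 1e-12)
  expect_equal(volume_to_mw(0), 0)
  for (v in c(1, 50, 500)) {
    expect_equal(mw_to_volume(volume_to_mw(v)), v, tolerance = 1e-12)
  }
  # linear in volume, inverse-linear in specific volume
  expect_equal(volume_to_mw(134), 2 * volume_to_mw(67))
  expect_equal(volume_to_mw(67, 0.335), 2 * volume_to_mw(67, 0.67))
})

test_that("the reference ladder holds the expected dimer-multiple masses", {
  lad <- reference_ladder()
  expect_equal(lad$mass_da[lad$label == "Cra homodimer"], 75998)
  expect_equal(lad$mass_da[lad$label == "FruK homodimer"], 67512)
  expect_equal(lad$mass_da[lad$tier == 2], 143510)
  expect_equal(lad$mass_da[lad$tier == 3], 219508)
  # every entry is a positive integer combination of the monomer masses
  combos <- outer(0:4 * 37999, 0:4 * 33756, `+`)
  expect_true(all(lad$mass_da %in% combos))
  expect_true(all(diff(lad$mass_da) > 0))
})

test_that("protein sequence masses agree with an external average-mass oracle", {
  # reference values computed with Biopython SeqUtils.molecular_weight
  expect_equal(unname(protein_mass("ACDEFGHIKLMNPQRSTVWY")), 2395.7134,
               tolerance = 1e-4)
  expect_equal(unname(protein_mass("MKTAYIAKQRQISFVK")), 1912.3025,
               tolerance = 1e-4)
  expect_error(protein_mass("ACDEFZ"), "Z")
})
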