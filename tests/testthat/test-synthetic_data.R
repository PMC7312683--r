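# The generator itself: determinism, helical arithmetic, probe semantics,
# defect mutants.

test_that("generation is deterministic and validates input", {
  f1 <- tempfile(fileext = ".pdb"); f2 <- tempfile(fileext = ".pdb")
  write_pdb(generate_fiber_duplex("B", "ATGCAT", structure_id = "x")$model, f1)
  write_pdb(generate_fiber_duplex("B", "ATGCAT", structure_id = "x")$model, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(generate_fiber_duplex("B", "AT"), "length >= 3")
  expect_error(generate_fiber_duplex("B", "ATXGA"), "invalid sequence")
})

test_that("helical rise arithmetic holds on generated coordinates", {
  g <- generate_fiber_duplex("B", "ATGCATGCAT", structure_id = "rise")
  # reference point per pair: C1' midpoint; pairs are stacked at the B rise
  mids <- vapply(0:9, function(i) {
    p <- g$ledger$pairs[g$ledger$pairs$pair_index == i, ]
    a1 <- groovescan:::.residue_atoms(g$model, paste0("A:", p$res1, ":."))
    a2 <- groovescan:::.residue_atoms(g$model, paste0("B:", p$res2, ":."))
    (a1$z[a1$atom == "C1'"] + a2$z[a2$atom == "C1'"]) / 2
  }, numeric(1))
  expect_equal(mids[10] - mids[1], 9 * 3.38, tolerance = 1e-6)
})

test_that("probe planting enforces exact distances, margins and ledger
          expectations", {
  g <- generate_fiber_duplex("B", "ATGCATGCAT", structure_id = "pp")
  plan <- data.frame(aa = c("PHE", "LYS", "ASN"),
                     nuc_chain = "A", nuc_seq = c(5, 5, 6),
                     groove = c("minor", "minor", "major"),
                     distance = c(5.9, 6.1, 4.0), stringsAsFactors = FALSE)
  pl <- plant_probe_residues(g$model, plan)
  expect_equal(pl$probes$expected_contact, c(TRUE, FALSE, FALSE))
  refs <- groovescan:::.reference_atom_table(pl$model)
  for (i in seq_len(nrow(pl$probes))) {
    pr <- pl$probes[i, ]
    probe_xyz <- groovescan:::.coords(
      groovescan:::.residue_atoms(pl$model,
                                  paste0(pr$probe_chain, ":", pr$probe_seq, ":.")))
    d_all <- vapply(seq_len(nrow(refs)), function(k)
      min(groovescan:::cross_dist(probe_xyz,
                                  matrix(as.numeric(refs[k, c("x", "y", "z")]), 1))),
      numeric(1))
    tgt_k <- which(refs$chain == pr$target_chain &
                     refs$res_seq == pr$target_seq & refs$groove == pr$groove)
    expect_equal(d_all[tgt_k], pr$distance, tolerance = 1e-6)
    expect_true(all(d_all[-tgt_k] >= pr$distance + 0.5 - 1e-9))
  }
  expect_error(
    plant_probe_residues(g$model, data.frame(
      aa = "GLY", nuc_chain = "A", nuc_seq = 5, groove = "minor",
      distance = 0.3, stringsAsFactors = FALSE)),
    "unsatisfiable")
})

test_that("perturbation is seeded-reproducible and guards backbone bonds", {
  g <- generate_fiber_duplex("B", "ATGCATGCAT", structure_id = "pt")
  a <- perturb_groove(g, steps = 4, displacement = 1, seed = 7,
                      jitter_sd = 0.05)
  b <- perturb_groove(g, steps = 4, displacement = 1, seed = 7,
                      jitter_sd = 0.05)
  expect_identical(a$model$atoms, b$model$atoms)
  c_ <- perturb_groove(g, steps = 4, displacement = 1, seed = 8,
                       jitter_sd = 0.05)
  expect_false(identical(a$model$atoms, c_$model$atoms))
  expect_error(perturb_groove(g, steps = 4, displacement = -6), "bond guard")
  expect_error(perturb_groove(g, steps = 99, displacement = 0), "out of range")
})

test_that("defect mutants fail for exactly their planted reason", {
  g <- generate_fiber_duplex("B", "ATGCATGCAT", structure_id = "dm")
  expect_true(validate_dna_chain(g$model, "A")$pass)
  m1 <- make_defect_mutant(g$model, "missing-atom", "A", 4, atom = "P")
  v1 <- validate_dna_chain(m1, "A")
  expect_false(v1$pass)
  expect_equal(nrow(v1$reasons), 1)
  expect_match(v1$reasons$reason, "missing heavy atom: P")
  m2 <- make_defect_mutant(g$model, "nonstandard-residue", "A", 4)
  v2 <- validate_dna_chain(m2, "A")
  expect_equal(nrow(v2$reasons), 1)
  expect_match(v2$reasons$reason, "non-standard")
  m3 <- make_defect_mutant(g$model, "broken-pair", "A", 4)
  expect_equal(nrow(detect_base_pairs(m3)), 9)
  expect_error(make_defect_mutant(g$model, "missing-atom", "A", 99), "not found")
})

test_that("amino-acid templates carry complete heavy-atom inventories", {
  expected_n <- c(ALA = 5, GLY = 4, ARG = 11, TRP = 14, PRO = 7)
  for (aa in names(expected_n))
    expect_equal(nrow(build_amino_acid(aa)), unname(expected_n[aa]))
  # all bonded atoms at plausible distances from their parent
  for (aa in c("LYS", "TYR", "HIS", "ILE")) {
    t <- build_amino_acid(aa)
    xyz <- as.matrix(t[, c("x", "y", "z")])
    d <- groovescan:::cross_dist(xyz, xyz)
    diag(d) <- Inf
    expect_true(all(apply(d, 1, min) > 1.1 & apply(d, 1, min) < 1.9))
  }
  expect_error(build_amino_acid("XYZ"), "unknown amino acid")
})
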