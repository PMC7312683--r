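# Reference atoms, the nearest-reference-atom 6.0 A rule, step assignment
# and dataset assembly / pruning.

test_that("reference atom map matches the per-base definitions", {
  expect_equal(unname(reference_atoms("dA")), c("N3", "N6"))
  expect_equal(unname(reference_atoms("dG")), c("N3", "O6"))
  expect_equal(unname(reference_atoms("dT")), c("O2", "O4"))
  expect_equal(unname(reference_atoms("dC")), c("O2", "N4"))
  expect_error(reference_atoms("BRU"), "non-standard")
})

planted_fixture <- function() {
  key <- "planted_fixture"
  if (is.null(.fixture_cache[[key]])) {
    g <- generate_fiber_duplex("B", "ATGCATGCAT", structure_id = "pf")
    plan <- data.frame(
      aa = c("ARG", "LEU", "SER", "LYS"),
      nuc_chain = "A", nuc_seq = c(4, 5, 6, 5),
      groove = c("minor", "minor", "minor", "major"),
      distance = c(5.0, 5.5, 6.5, 4.0), stringsAsFactors = FALSE)
    pl <- plant_probe_residues(g$model, plan)
    .fixture_cache[[key]] <- list(model = pl$model, probes = pl$probes,
                                  ledger = g$ledger)
  }
  .fixture_cache[[key]]
}

test_that("contact rule: strict cutoff and minor-nearest requirement", {
  fx <- planted_fixture()
  dups <- fixture_duplexes_of(fx$model)
  ct <- find_groove_contacts(fx$model, dups)
  # ARG at 5.0 and LEU at 5.5 contact; SER at 6.5 (outside) and LYS
  # (nearest atom is a major-groove reference) do not
  expect_setequal(ct$residue_type, c("ARG", "LEU"))
  expect_equal(ct$distance[ct$residue_type == "ARG"], 5.0, tolerance = 1e-6)
  expect_equal(ct$nuc_seq[ct$residue_type == "ARG"], 4)
  expect_equal(ct$distance[ct$residue_type == "LEU"], 5.5, tolerance = 1e-6)
  # distances are invariant under rigid motion of the whole structure
  mt <- transform_model(fx$model)
  ct2 <- find_groove_contacts(mt, fixture_duplexes_of(mt))
  expect_equal(ct2$distance[order(ct2$residue_type)],
               ct$distance[order(ct$residue_type)], tolerance = 1e-6)
})

test_that("step assignment picks the closer adjacent nucleotide and
          breaks ties toward 5'", {
  fx <- planted_fixture()
  dups <- fixture_duplexes_of(fx$model)
  ct <- find_groove_contacts(fx$model, dups)
  for (i in seq_len(nrow(ct))) {
    st <- assign_dinucleotide_step(ct[i, ], dups, fx$model)
    p <- ct$pair_index[i]
    expect_true(st$step_index %in% c(p - 1, p))
    # verify against directly computed neighbour distances
    dup <- dups[[ct$duplex[i]]]
    dist_to <- function(q) {
      row <- dup$pairs[dup$pairs$pair_index == q, ]
      key <- if (ct$strand[i] == 1) row$key_i else row$key_j
      base <- if (ct$strand[i] == 1) row$base_i else row$base_j
      ra <- groovescan:::.residue_atoms(fx$model, key)
      ref <- ra[ra$atom == reference_atoms(base)["minor"], ]
      min(groovescan:::.res_min_dists(
        fx$model, ct$residue_key[i],
        matrix(c(ref$x, ref$y, ref$z), 1)))
    }
    cand <- intersect(c(p - 1, p + 1), 0:(dup$n - 1))
    nearer <- cand[which.min(vapply(cand, dist_to, numeric(1)))]
    expect_equal(st$step_index, min(p, nearer))
  }
})

test_that("an exact neighbour tie selects the 5' nucleotide", {
  # probe at x = 10.2 is the position of A:3 itself, exactly equidistant
  # from the minor reference atoms of its neighbours A:2 and A:4
  toy <- toy_duplex_fixture(probe_xs = 3 * 3.4)
  ct <- data.frame(structure_id = "toy", chain = "P", residue_type = "GLY",
                   residue_seq = 1, residue_key = "P:1:.",
                   nuc_chain = "A", nuc_seq = 3, nuc_key = "A:3:.",
                   groove = "minor", distance = 1, duplex = 1,
                   pair_index = 2, strand = 1, stringsAsFactors = FALSE)
  st <- assign_dinucleotide_step(ct, toy$dups, toy$model)
  expect_equal(st$step_index, 1)
})

test_that("dataset assembly: uniqueness, blacklist, shared steps, width log", {
  fx <- planted_fixture()
  dups <- fixture_duplexes_of(fx$model)
  ct <- find_groove_contacts(fx$model, dups)
  tab <- build_dataset(ct, dups, fx$model)
  expect_s3_class(tab, "DatasetTable")
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$category == categorize_width(tab$width)))

  bl_key <- ct$residue_key[ct$residue_type == "ARG"]
  tab2 <- build_dataset(ct, dups, fx$model, blacklist = bl_key)
  expect_equal(nrow(tab2), 1)
  expect_match(attr(tab2, "log")$reason, "blacklisted", all = FALSE)

  # two residues contacting the same step produce two records sharing the
  # step reference (toy geometry: both nearest A:3, both 5'-side leaning)
  toy <- toy_duplex_fixture(probe_xs = c(9.8, 9.5))
  ct2 <- find_groove_contacts(toy$model, toy$dups)
  expect_equal(nrow(ct2), 2)
  expect_true(all(ct2$nuc_seq == 3))
  t2 <- build_dataset(ct2, toy$dups, toy$model)
  expect_equal(nrow(t2), 2)
  expect_equal(length(unique(t2$step_index)), 1)
  expect_equal(length(unique(t2$residue_key)), 2)

  # a contact whose step width is undefined is dropped with a reason
  g3 <- generate_fiber_duplex("B", "ATGCA", structure_id = "short")
  pl3 <- plant_probe_residues(g3$model, data.frame(
    aa = "ALA", nuc_chain = "A", nuc_seq = 1, groove = "minor",
    distance = 5.0, stringsAsFactors = FALSE))
  d3 <- fixture_duplexes_of(pl3$model)
  ct3 <- find_groove_contacts(pl3$model, d3)
  expect_equal(nrow(ct3), 1)
  t3 <- build_dataset(ct3, d3, pl3$model)
  expect_equal(nrow(t3), 0)
  expect_match(attr(t3, "log")$reason, "undefined width", all = FALSE)
})

test_that("family pruning removes annotated records, is idempotent and the
          empty set is the identity", {
  fx <- planted_fixture()
  dups <- fixture_duplexes_of(fx$model)
  tab <- build_dataset(find_groove_contacts(fx$model, dups), dups, fx$model)
  ann <- data.frame(structure_id = "pf", chain = "P",
                    residue_seq = tab$residue_seq[tab$residue_type == "ARG"],
                    family = "PF00505", stringsAsFactors = FALSE)
  p1 <- ds_prune(tab, ann)
  expect_equal(nrow(p1), nrow(tab) - 1)
  expect_false("ARG" %in% p1$residue_type)
  expect_equal(attr(p1, "label"), "DS2")
  p2 <- ds_prune(p1, ann)
  expect_equal(as.data.frame(p2), as.data.frame(p1))
  id <- ds_prune(tab, ann, excluded_families = character(0))
  expect_equal(as.data.frame(id), as.data.frame(tab), ignore_attr = TRUE)
  expect_equal(nrow(ds_prune(tab, ann, excluded_families = "PF99999")),
               nrow(tab))
  expect_error(ds_prune(tab, data.frame(a = 1)), "columns")
})
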