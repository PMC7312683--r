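# Backbone dihedrals, the phi/psi classifier, hydrogen-bond / vdW
# detection and Kabsch superposition.

test_that("constructed peptides return their target dihedrals", {
  for (tgt in list(c(-60, -45), c(-120, 130), c(-75, 150))) {
    pep <- build_peptide_with_dihedrals(rep("ALA", 5), rep(tgt[1], 5),
                                        rep(tgt[2], 5))
    dh <- compute_backbone_dihedrals(pep, "Q")
    expect_equal(dh$phi[2:5], rep(tgt[1], 4), tolerance = 1e-3)
    expect_equal(dh$psi[1:4], rep(tgt[2], 4), tolerance = 1e-3)
    expect_true(is.na(dh$phi[1]) && is.na(dh$psi[5]))
  }
  single <- build_peptide_with_dihedrals("GLY", -60, -45)
  dh1 <- compute_backbone_dihedrals(single, "Q")
  expect_true(all(is.na(dh1$phi)) && all(is.na(dh1$psi)))
})

test_that("phi/psi regions classify canonical conformations", {
  cases <- list(list(c(-60, -45), "alpha-helix"),
                list(c(-74, 10), "3-10-helix"),
                list(c(-120, 130), "beta-strand"),
                list(c(-75, 150), "polyproline-II"))
  for (cs in cases) {
    pep <- build_peptide_with_dihedrals(rep("ALA", 5), rep(cs[[1]][1], 5),
                                        rep(cs[[1]][2], 5))
    ss <- assign_secondary_structure(pep, "Q")
    expect_equal(ss$ss[3], cs[[2]])
    expect_equal(ss$ss[1], "unassigned")   # terminus
  }
  # every phi/psi point receives exactly one well-defined label
  pep <- build_peptide_with_dihedrals(rep("GLY", 5), rep(-60, 5), rep(-45, 5))
  base <- compute_backbone_dihedrals(pep, "Q")
  for (phi in seq(-175, 175, 50)) for (psi in seq(-175, 175, 50)) {
    d <- base; d$phi[3] <- phi; d$psi[3] <- psi
    lab <- assign_secondary_structure(pep, "Q", dihedrals = d)$ss[3]
    expect_length(lab, 1)
    expect_true(lab %in% c("alpha-helix", "3-10-helix", "beta-strand",
                           "polyproline-II", "turn", "bend", "others"))
  }
})

hb_fixture <- function(aa, anchor_atom, target_atom_key, offset_dist) {
  # place a residue so that anchor_atom sits at offset_dist from the chosen
  # DNA atom, approaching from outside along +radial
  g <- fixture_duplex("B", "ATGCATGCAT")
  m <- g$model
  sel <- m$atoms$chain == target_atom_key[1] &
    m$atoms$res_seq == as.integer(target_atom_key[2]) &
    m$atoms$atom == target_atom_key[3]
  tgt <- c(m$atoms$x[sel], m$atoms$y[sel], m$atoms$z[sel])
  u <- c(tgt[1], tgt[2], 0); u <- u / sqrt(sum(u^2))
  tmpl <- build_amino_acid(aa)
  anchor <- as.numeric(tmpl[tmpl$atom == anchor_atom, c("x", "y", "z")])
  ctr <- colMeans(as.matrix(tmpl[, c("x", "y", "z")]))
  R <- groovescan:::rotation_between(ctr - anchor, u)
  xyz <- t(apply(as.matrix(tmpl[, c("x", "y", "z")]), 1,
                 function(v) tgt + offset_dist * u + as.vector(R %*% (v - anchor))))
  tmpl$x <- xyz[, 1]; tmpl$y <- xyz[, 2]; tmpl$z <- xyz[, 3]
  tmpl$chain <- "Z"; tmpl$res_name <- aa; tmpl$res_seq <- 1; tmpl$ins <- ""
  tmpl$occupancy <- 1; tmpl$altloc <- ""; tmpl$hetatm <- FALSE
  m$atoms <- rbind(m$atoms, tmpl[, colnames(m$atoms)])
  m
}

test_that("hydrogen bonds: distance/angle criteria and target classes", {
  m <- hb_fixture("SER", "OG", c("A", 5, "OP1"), 2.9)
  hb <- detect_hbonds(m, protein_keys = "Z:1:.")
  ser <- hb[hb$protein_atom == "OG" & hb$dna_atom == "OP1", ]
  expect_gte(nrow(ser), 1)
  expect_equal(ser$dna_target[1], "phosphate")
  expect_equal(ser$protein_side[1], "side-chain")
  expect_equal(ser$distance[1], 2.9, tolerance = 1e-6)

  far <- hb_fixture("SER", "OG", c("A", 5, "OP1"), 3.8)
  hb2 <- detect_hbonds(far, protein_keys = "Z:1:.")
  expect_equal(nrow(hb2[hb2$dna_atom == "OP1" & hb2$protein_atom == "OG", ]), 0)

  m3 <- hb_fixture("GLY", "N", c("A", 2, "O2"), 3.0)   # thymine O2
  hb3 <- detect_hbonds(m3, protein_keys = "Z:1:.")
  bb <- hb3[hb3$protein_atom == "N" & hb3$dna_atom == "O2", ]
  expect_gte(nrow(bb), 1)
  expect_equal(bb$protein_side[1], "backbone")
  expect_equal(bb$dna_target[1], "base")

  # rigid-motion invariance of the bond count
  mt <- transform_model(m)
  expect_equal(nrow(detect_hbonds(mt, protein_keys = "Z:1:.")), nrow(hb))
})

test_that("vdW contacts respect the cutoff and exclude H-bonded pairs", {
  m <- hb_fixture("ALA", "CB", c("A", 6, "O2"), 3.7)
  vdw <- classify_vdw_contacts(m, protein_keys = "Z:1:.")
  cb <- vdw[vdw$protein_atom == "CB" & vdw$dna_atom == "O2", ]
  expect_equal(nrow(cb), 1)
  expect_equal(cb$dna_target, "base")

  far <- hb_fixture("ALA", "CB", c("A", 6, "O2"), 4.5)
  vdw2 <- classify_vdw_contacts(far, protein_keys = "Z:1:.")
  expect_equal(nrow(vdw2[vdw2$protein_atom == "CB" & vdw2$dna_atom == "O2", ]),
               0)

  mh <- hb_fixture("SER", "OG", c("A", 5, "OP1"), 2.9)
  hb <- detect_hbonds(mh, protein_keys = "Z:1:.")
  vdw3 <- classify_vdw_contacts(mh, hbonds = hb, protein_keys = "Z:1:.")
  expect_equal(nrow(vdw3[vdw3$protein_atom == "OG" &
                           vdw3$dna_atom == "OP1", ]), 0)
})

test_that("Kabsch superposition: exactness, invariances and oracle", {
  set.seed(31)
  A <- matrix(rnorm(15, sd = 4), ncol = 3)
  ident <- kabsch_superpose(A, A)
  expect_equal(ident$rmsd, 0, tolerance = 1e-12)
  expect_equal(ident$rotation, diag(3), tolerance = 1e-9)

  R <- groovescan:::rotation_about_axis(c(1, 2, -1), 71)
  B <- A %*% t(R); B <- sweep(B, 2, c(3, -8, 2), "+")
  fit <- kabsch_superpose(A, B)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_equal(crossprod(fit$rotation), diag(3), tolerance = 1e-9)
  expect_equal(A %*% t(fit$rotation) + rep(1, 5) %o% fit$translation, B,
               tolerance = 1e-8)

  # rmsd invariant under pre-rotation of either set
  pre <- groovescan:::rotation_about_axis(c(0, 1, 1), 33)
  C <- B; C[4, ] <- C[4, ] + c(1.1, -0.4, 0.7)
  expect_equal(kabsch_superpose(A %*% t(pre), C)$rmsd,
               kabsch_superpose(A, C)$rmsd, tolerance = 1e-9)

  # agreement with a brute-force rigid-motion search
  for (i in 1:3) {
    X <- matrix(rnorm(12, sd = 3), ncol = 3)
    Y <- matrix(rnorm(12, sd = 3), ncol = 3)
    expect_equal(kabsch_superpose(X, Y)$rmsd, oracle_min_rmsd(X, Y),
                 tolerance = 1e-4)
  }
  # 4 identical points with one displaced by 2 A: optimal rmsd matches the
  # brute-force value (close to, and no worse than, 2/sqrt(4))
  P <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10))
  Q <- P; Q[4, ] <- Q[4, ] + c(0, 0, 2)
  k <- kabsch_superpose(P, Q)$rmsd
  expect_equal(k, oracle_min_rmsd(P, Q), tolerance = 1e-4)
  expect_lte(k, 1.0 + 1e-9)
  expect_gt(k, 0.8)

  expect_error(kabsch_superpose(A[1:2, ], B[1:2, ]), "3 matched points")
  L <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(kabsch_superpose(L, L), "collinear")
})

test_that("representative step minimizes total pairwise RMSD with low-index
          ties", {
  base <- matrix(rnorm(24, sd = 3), ncol = 3)
  rot <- function(ang) base %*% t(groovescan:::rotation_about_axis(c(1, 1, 0),
                                                                   ang))
  expect_equal(representative_step(list(base)), 1L)
  expect_equal(representative_step(list(base, rot(40), base)), 1L)
  # two similar steps and an outlier: a similar one is representative
  s1 <- base; s2 <- base + matrix(rnorm(24, 0, 0.05), ncol = 3)
  out <- base + matrix(rnorm(24, 0, 3), ncol = 3)
  idx <- representative_step(list(out, s1, s2))
  expect_true(idx %in% c(2L, 3L))
  # verified against exhaustive pairwise sums
  steps <- list(out, s1, s2)
  sums <- vapply(1:3, function(i)
    sum(vapply(setdiff(1:3, i), function(j)
      kabsch_superpose(steps[[i]], steps[[j]])$rmsd, numeric(1))),
    numeric(1))
  expect_equal(idx, which.min(sums))
  expect_error(representative_step(list()), "empty")
})
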