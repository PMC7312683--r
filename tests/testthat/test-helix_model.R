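# Base pairing, duplex assembly, groove widths and sugar puckers.

test_that("pairing recovers the planted ledger and rejects separated strands", {
  g <- fixture_duplex("B", "ATGCATGCAT")
  bp <- detect_base_pairs(g$model)
  expect_equal(nrow(bp), 10)
  norm_pair <- function(c1, r1, c2, r2) {
    a <- paste(c1, r1); b <- paste(c2, r2)
    ifelse(a < b, paste(a, b), paste(b, a))
  }
  got <- norm_pair(bp$chain_i, bp$res_i, bp$chain_j, bp$res_j)
  want <- norm_pair(g$ledger$pairs$chain1, g$ledger$pairs$res1,
                    g$ledger$pairs$chain2, g$ledger$pairs$res2)
  expect_setequal(got, want)

  far <- g$model
  selB <- far$atoms$chain == "B"
  far$atoms$x[selB] <- far$atoms$x[selB] + 100
  expect_equal(nrow(detect_base_pairs(far)), 0)

  flipped <- make_defect_mutant(g$model, "broken-pair", "A", 5)
  expect_equal(nrow(detect_base_pairs(flipped)), 9)
})

test_that("duplex assembly respects adjacency and the minimum length", {
  g <- fixture_duplex("B", "ATGCATGCAT")
  bp <- detect_base_pairs(g$model)
  d <- build_duplexes(bp, g$model)
  expect_length(d, 1)
  expect_equal(d[[1]]$n, 10)
  expect_equal(d[[1]]$sequence, "ATGCATGCAT")
  # remove the middle pair -> two duplexes of 5 and 4
  resA <- ifelse(bp$chain_i == "A", bp$res_i, bp$res_j)
  mid <- bp[resA != 6, ]
  d2 <- build_duplexes(mid, g$model)
  expect_equal(sort(vapply(d2, `[[`, 0L, "n")), c(4L, 5L))
  # two isolated pairs are below the minimum length
  iso <- bp[resA %in% c(2, 7), ]
  expect_length(build_duplexes(iso, g$model), 0)
})

test_that("groove widths match the ideal-form anchors and end rules", {
  gA <- fixture_duplex("A", "GCGCGCATGCGC")
  dA <- fixture_duplexes_of(gA$model)[[1]]
  wA <- duplex_widths(dA, gA$model)
  central <- as.character(floor((dA$n - 2) / 2))
  expect_equal(unname(wA[central]), 18.5, tolerance = 0.01)

  gB <- fixture_duplex("B", "ATGCATGCAT")
  dB <- fixture_duplexes_of(gB$model)[[1]]
  wB <- duplex_widths(dB, gB$model)
  centB <- unname(wB[as.character(floor((dB$n - 2) / 2))])
  expect_gt(centB, 11); expect_lt(centB, 17)     # standard category

  # terminal steps undefined
  expect_true(is.na(wB["0"]))
  expect_true(is.na(wB[as.character(dB$n - 2)]))
  expect_match(attr(compute_minor_groove_width(dB, gB$model, 0), "reason"),
               "end")
  # a 3-bp duplex has no defined widths
  g3 <- generate_fiber_duplex("B", "ATG", structure_id = "tiny")
  d3 <- fixture_duplexes_of(g3$model)[[1]]
  expect_true(all(is.na(duplex_widths(d3, g3$model))))
  # missing phosphate in the window -> NA with reason
  gm <- make_defect_mutant(gB$model, "missing-atom", "A", 6, atom = "P")
  dm <- fixture_duplexes_of(gm)[[1]]
  wm <- compute_minor_groove_width(dm, gm, 4)
  expect_true(is.na(wm))
  expect_match(attr(wm, "reason"), "missing phosphate")
})

test_that("widths are rigid-motion invariant and respond monotonically to
          radial phosphate displacement", {
  g <- fixture_duplex("B", "ATGCATGCAT")
  d <- fixture_duplexes_of(g$model)[[1]]
  w0 <- duplex_widths(d, g$model)
  mt <- transform_model(g$model)
  dt <- fixture_duplexes_of(mt)[[1]]
  expect_equal(duplex_widths(dt, mt), w0, tolerance = 1e-6)

  widths <- vapply(c(0, -1, -2), function(disp) {
    gp <- if (disp == 0) g else perturb_groove(g, steps = 4,
                                               displacement = disp)
    dp <- fixture_duplexes_of(gp$model)[[1]]
    as.numeric(compute_minor_groove_width(dp, gp$model, 4))
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  # zero displacement leaves the model bit-identical
  same <- perturb_groove(g, steps = 4, displacement = 0)
  expect_identical(same$model$atoms, g$model$atoms)
})

test_that("sugar puckers land in the canonical bins and planar rings are
          flagged", {
  gA <- fixture_duplex("A", "GCGCGCATGCGC")
  pkA <- compute_sugar_pucker(gA$model, key = "A:5:.")
  expect_equal(pkA$label, "C3'-endo")
  expect_true(pkA$phase >= 0 && pkA$phase < 36)

  gB <- fixture_duplex("B", "ATGCATGCAT")
  pkB <- compute_sugar_pucker(gB$model, key = "A:5:.")
  expect_equal(pkB$label, "C2'-endo")
  expect_true(pkB$phase >= 144 && pkB$phase < 180)

  flat <- data.frame(atom = c("C1'", "C2'", "C3'", "C4'", "O4'"),
                     element = "C",
                     x = c(0, 1.4, 2.2, 1.4, 0.1),
                     y = c(0, 0.4, 1.6, 2.8, 2.2), z = 0)
  pkF <- compute_sugar_pucker(atoms = flat)
  expect_lt(pkF$amplitude, 5)
  expect_equal(pkF$label, "other")
  expect_equal(pkF$note, "near-planar")
  # missing ring atom errors with its name
  expect_error(compute_sugar_pucker(atoms = flat[-2, ]), "C2'")
})

test_that("pucker phase agrees with the independent pseudorotation oracle", {
  set.seed(7)
  for (i in 1:100) {
    ring <- groovescan:::.sugar_ring_local(runif(1, 0, 360), runif(1, 25, 45))
    ring <- ring + matrix(rnorm(15, 0, 0.03), ncol = 3)
    R <- groovescan:::rotation_about_axis(rnorm(3), runif(1, 0, 360))
    ring <- ring %*% t(R)
    atoms <- data.frame(atom = rownames(ring), element = "C",
                        x = ring[, 1], y = ring[, 2], z = ring[, 3])
    got <- compute_sugar_pucker(atoms = atoms)$phase
    expect_equal(got, oracle_pucker_phase(atoms), tolerance = 1e-6)
  }
})

test_that("groove-width tables round-trip and report unmatched rows", {
  g <- fixture_duplex("B", "ATGCATGCAT")
  d <- fixture_duplexes_of(g$model)[[1]]
  w <- duplex_widths(d, g$model)
  w <- w[!is.na(w)]
  f <- tempfile(fileext = ".tsv")
  write_groove_widths(w, f)
  w2 <- import_groove_widths(f, d)
  expect_equal(as.numeric(w2), as.numeric(w))
  expect_length(attr(w2, "unmatched"), 0)
  # an extra step row is reported unmatched
  write_groove_widths(c(w, "99" = 12.0), f)
  w3 <- import_groove_widths(f, d)
  expect_equal(attr(w3, "unmatched"), 99L)
  # empty table -> empty map
  writeLines("step_index\twidth", f)
  expect_length(import_groove_widths(f), 0)
})
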