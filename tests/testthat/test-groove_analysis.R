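# Width categories, interface segmentation, hexamer windows, GC content and
# sequence preferences.

test_that("width categorization applies inclusive boundaries and partitions
          the positive axis", {
  expect_equal(categorize_width(10.2), "narrow")
  expect_equal(categorize_width(11.0), "narrow")
  expect_equal(categorize_width(14.0), "standard")
  expect_equal(categorize_width(17.0), "wide")
  expect_equal(categorize_width(25.0), "wide")
  expect_error(categorize_width(NA_real_), "undefined")
  expect_error(categorize_width(-1), "positive")
  set.seed(11)
  w <- exp(runif(500, -2, 4))
  labs <- categorize_width(w)
  expect_true(all(labs %in% c("narrow", "standard", "wide")))
  expect_true(all((w <= 11) == (labs == "narrow")))
  expect_true(all((w >= 17) == (labs == "wide")))
})

test_that("interface segmentation bridges gaps of two and splits at three", {
  s1 <- build_interfaces(c(2, 3, 6))
  expect_length(s1, 1)
  expect_equal(s1[[1]]$steps, 2:6)
  s2 <- build_interfaces(c(2, 3, 7))
  expect_length(s2, 2)
  expect_equal(s2[[1]]$steps, 2:3)
  expect_equal(s2[[2]]$steps, 7)
  expect_length(build_interfaces(integer(0)), 0)
  # properties: segments disjoint, union covers the input set
  set.seed(3)
  for (r in 1:25) {
    st <- sort(sample(0:40, sample(1:20, 1)))
    segs <- build_interfaces(st)
    all_steps <- unlist(lapply(segs, `[[`, "steps"))
    expect_equal(anyDuplicated(all_steps), 0)
    expect_true(all(st %in% all_steps))
  }
})

test_that("hexamer windows: count L-5, central-step width, residue union", {
  g <- fixture_duplex("B", "ATGCATGCAT")
  dup <- fixture_duplexes_of(g$model)[[1]]
  w <- duplex_widths(dup, g$model)
  # segment spanning steps 1..7 covers 8 nucleotides -> 3 windows
  seg <- build_interfaces(1:7)[[1]]
  hw <- sliding_hexamers(seg, dup, w,
                         step_residues = list("1" = "PHE:a", "5" = "GLY:b"))
  expect_equal(nrow(hw), 3)
  expect_equal(hw$width, unname(w[as.character(3:5)]))
  # window starting at 1 contains steps 1..5: both residues
  expect_equal(hw$residues[1], "GLY:b,PHE:a")
  # window starting at 3 contains steps 3..7: only GLY
  expect_equal(hw$residues[3], "GLY:b")
  # six-nucleotide segment -> exactly one window
  seg2 <- build_interfaces(2:6)[[1]]
  expect_equal(nrow(sliding_hexamers(seg2, dup, w)), 1)
  # shorter segments produce no windows
  seg3 <- build_interfaces(2:4)[[1]]
  expect_equal(nrow(sliding_hexamers(seg3, dup, w)), 0)
  # window count property over random segments
  for (start in 0:3) for (end in start:(dup$n - 2)) {
    seg <- list(start = start, end = end)
    L <- end - start + 2
    hw <- sliding_hexamers(structure(seg, class = "InterfaceSegment"), dup, w)
    expect_equal(nrow(hw) + length(attr(hw, "skipped")), max(0, L - 5))
  }
})

test_that("undefined central widths are skipped with a log entry", {
  g <- fixture_duplex("B", "ATGCATGCAT")
  dup <- fixture_duplexes_of(g$model)[[1]]
  w <- duplex_widths(dup, g$model)
  seg <- build_interfaces(0:6)[[1]]         # window at 0 has central step 2
  w2 <- w; w2["2"] <- NA
  hw <- sliding_hexamers(seg, dup, w2)
  expect_equal(attr(hw, "skipped"), 0)
  expect_false(0 %in% hw$nuc_start)
})

test_that("GC content is a sixth-integer fraction of strand-1 G/C", {
  expect_equal(gc_content("ATATAT"), 0)
  expect_equal(gc_content("GCGCGC"), 1)
  expect_equal(gc_content("ATGCAT"), 1 / 3)
  expect_error(gc_content("ATGC"), "6 nucleotides")
  set.seed(5)
  for (i in 1:30) {
    s <- paste(sample(c("A", "C", "G", "T"), 6, TRUE), collapse = "")
    expect_true(gc_content(s) %in% ((0:6)/6))
  }
})

test_that("width-by-GC tables route windows to every contacting amino acid", {
  win <- data.frame(nuc_start = c(0, 1, 2), sequence = c("ATATAT", "GCGCGC",
                                                         "ATGCAT"),
                    gc_content = c(0, 1, 1 / 3), width = c(18, 12, 15),
                    residues = c("PHE:a,GLY:b", "", "PHE:c"),
                    stringsAsFactors = FALSE)
  out <- width_by_gc(win)
  expect_equal(nrow(out$pooled), 3)
  expect_setequal(out$pooled$gc_level, c(0, 6, 2))
  phe <- out$per_aa[out$per_aa$amino_acid == "PHE", ]
  expect_setequal(phe$width, c(18, 15))
  gly <- out$per_aa[out$per_aa$amino_acid == "GLY", ]
  expect_equal(gly$width, 18)
  empty <- width_by_gc(win[0, ])
  expect_equal(nrow(empty$pooled), 0)
  expect_equal(nrow(empty$per_aa), 0)
})

test_that("sequence preferences pool complements and normalize per residue", {
  expect_equal(groovescan:::step_class(c("AA", "TT", "AT", "TA", "CC", "AG")),
               c("ApA/TpT", "ApA/TpT", "ApT", "TpA", "CpC/GpG", "ApG/CpT"))
  tab <- data.frame(residue_type = c(rep("LEU", 5), rep("ASP", 4)),
                    step_sequence = c(rep("AA", 3), rep("GC", 2),
                                      rep("CC", 2), rep("GG", 2)),
                    stringsAsFactors = FALSE)
  sp <- sequence_preferences(tab)
  leu <- sp[sp$amino_acid == "LEU", ]
  expect_equal(leu$frequency[leu$class == "ApA/TpT"], 0.6)
  expect_equal(leu$frequency[leu$class == "GpC"], 0.4)
  asp <- sp[sp$amino_acid == "ASP", ]
  expect_equal(asp$frequency[asp$class == "CpC/GpG"], 1.0)
  expect_equal(sum(leu$frequency), 1)
  expect_equal(nrow(sequence_preferences(tab[0, ])), 0)
})
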