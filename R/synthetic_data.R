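# Fully ledgered synthetic protein-DNA complexes: fiber-model duplexes,
# groove perturbations, planted amino-acid probes, peptides with prescribed
# backbone dihedrals, and single-defect mutants.  Every planted feature is
# recorded in a ground-truth ledger so downstream detectors can be scored
# exactly.

# Solve for a bridging atom X with |X-A| = a and |X-B| = b, in the plane
# spanned by A, B and ref.  Falls back to the collinear point (bond to B
# stretched) when the separation exceeds a + b.
.place_two_bond <- function(A, B, a, b, ref) {
  d <- vnorm(B - A)
  u <- unitv(B - A)
  if (d >= a + b || d <= abs(a - b) + 1e-9) return(A + a * u)
  m <- (a^2 - b^2 + d^2) / (2 * d)
  h <- sqrt(max(0, a^2 - m^2))
  vperp <- (ref - A) - sum((ref - A) * u) * u
  w <- if (vnorm(vperp) < 1e-6) {
    p <- cross3(u, c(0, 0, 1))
    if (vnorm(p) < 1e-6) p <- cross3(u, c(0, 1, 0))
    unitv(p)
  } else unitv(vperp)
  A + m * u + h * w
}

.atom_row <- function(name, xyz) {
  data.frame(atom = name, element = .guess_element(name),
             x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
}

# Build one nucleotide's atom table.  `p_own` / `p_next` may be virtual
# (used for orientation only); `emit_p` controls the 5'-phosphate group.
.build_nucleotide <- function(base, base_xyz, c1_world, n_world,
                              p_own, p_next, emit_p, form) {
  fp <- FIBER_FORMS[[form]]
  ring <- .sugar_ring_local(fp$pucker_phase, fp$pucker_tau)
  sug <- .orient_sugar(ring, c1_world, n_world, p_own, p_next)
  c4 <- sug["C4'", ]; c3 <- sug["C3'", ]
  c5 <- c4 + 1.51 * unitv(p_own - c4)
  o5 <- .place_two_bond(c5, p_own, 1.44, 1.59, c4)
  o3 <- .place_two_bond(c3, p_next, 1.42, 1.59, c4)
  rows <- list()
  if (emit_p) {
    d5 <- unitv(o5 - p_own)
    d3 <- unitv(o3 - p_own)   # approximate direction of the O3' bridge
    nn <- cross3(d5, d3)
    if (vnorm(nn) < 1e-6) nn <- cross3(d5, c(0, 0, 1))
    nn <- unitv(nn)
    bis <- -unitv(d5 + d3)
    op1 <- p_own + 1.48 * unitv(cos(0.6) * bis + sin(0.6) * nn)
    op2 <- p_own + 1.48 * unitv(cos(0.6) * bis - sin(0.6) * nn)
    rows <- c(rows, list(.atom_row("P", p_own), .atom_row("OP1", op1),
                         .atom_row("OP2", op2)))
  }
  rows <- c(rows, list(
    .atom_row("O5'", o5), .atom_row("C5'", c5), .atom_row("C4'", c4),
    .atom_row("O4'", sug["O4'", ]), .atom_row("C3'", c3),
    .atom_row("O3'", o3), .atom_row("C2'", sug["C2'", ]),
    .atom_row("C1'", c1_world)))
  for (nm in BASE_ATOMS[[base]]) {
    if (nm == "C1'") next
    rows <- c(rows, list(.atom_row(nm, base_xyz[nm, ])))
  }
  do.call(rbind, rows)
}

#' Generate an ideal fiber-model DNA duplex
#'
#' Builds an all-heavy-atom A- or B-form double helix from the packaged
#' repeating-unit geometry: planar Watson-Crick pairs propagated with the
#' form's twist/rise, calibrated phosphate cylindrical placement, and sugars
#' with the form's canonical pucker (C3'-endo for A, C2'-endo for B).  The
#' helix axis is the z axis.  Deterministic for a given specification.
#'
#' @param form "A" or "B".
#' @param sequence strand-1 sequence, 5'->3', over A/C/G/T; length >= 3.
#' @param structure_id label for the emitted model.
#' @param chain1,chain2 chain identifiers for the two strands.
#' @return list with `model` (a `StructureModel`, metadata marked as an
#'   idealized X-ray-like entry) and `ledger` (planted base pairs, sequence,
#'   form, residue numbering map).
#' @export
generate_fiber_duplex <- function(form = c("B", "A"), sequence,
                                  structure_id = "synthetic",
                                  chain1 = "A", chain2 = "B") {
  form <- match.arg(form)
  sequence <- toupper(sequence)
  bases <- strsplit(sequence, "")[[1]]
  if (length(bases) < 3) stop("sequence must have length >= 3")
  if (!all(bases %in% c("A", "C", "G", "T")))
    stop("invalid sequence characters: ",
         paste(unique(bases[!bases %in% c("A", "C", "G", "T")]), collapse = ""))
  fp <- FIBER_FORMS[[form]]
  n <- length(bases)
  shift <- c(0, fp$disp_y, 0)

  # embedded pair templates
  emb1 <- vector("list", n); emb2 <- vector("list", n)
  for (i in seq_len(n)) {
    tpl <- .pair_template(paste0("d", bases[i]))
    R <- rot_z((i - 1) * fp$twist)
    zoff <- c(0, 0, (i - 1) * fp$rise)
    emb1[[i]] <- sweep(tpl$s1, 2, shift, "+") %*% t(R)
    emb2[[i]] <- sweep(tpl$s2, 2, shift, "+") %*% t(R)
    emb1[[i]] <- sweep(emb1[[i]], 2, zoff, "+")
    emb2[[i]] <- sweep(emb2[[i]], 2, zoff, "+")
    rownames(emb1[[i]]) <- rownames(tpl$s1)
    rownames(emb2[[i]]) <- rownames(tpl$s2)
  }

  res_frames <- list()
  add_res <- function(chain, res_seq, base, df) {
    df$chain <- chain; df$res_name <- base; df$res_seq <- res_seq
    df$ins <- ""; df$occupancy <- 1; df$altloc <- ""; df$hetatm <- FALSE
    res_frames[[length(res_frames) + 1]] <<- df
  }

  # strand 1, pairs 0..n-1, residues 1..n
  for (i in seq_len(n)) {
    b1 <- paste0("d", bases[i])
    pi0 <- i - 1
    p_own <- .p_position(form, pi0, 1)
    p_next <- .p_position(form, pi0 + 1, 1)
    df <- .build_nucleotide(b1, emb1[[i]], emb1[[i]]["C1'", ],
                            emb1[[i]][GLYCOSIDIC_N[b1], ],
                            p_own, p_next, emit_p = (i > 1), form)
    add_res(chain1, i, b1, df)
  }
  # strand 2, file order 5'->3' = pairs n-1 .. 0, residues 1..n
  for (k in seq_len(n)) {
    j <- n - k                       # pair index
    b2 <- paste0("d", DNA_COMPLEMENT[bases[j + 1]])
    p_own <- .p_position(form, j, 2)
    p_next <- .p_position(form, j - 1, 2)
    df <- .build_nucleotide(b2, emb2[[j + 1]], emb2[[j + 1]]["C1'", ],
                            emb2[[j + 1]][GLYCOSIDIC_N[b2], ],
                            p_own, p_next, emit_p = (k > 1), form)
    add_res(chain2, k, b2, df)
  }

  atoms <- do.call(rbind, res_frames)
  atoms <- atoms[, c("chain", "res_name", "res_seq", "ins", "atom", "element",
                     "x", "y", "z", "occupancy", "altloc", "hetatm")]
  model <- new_structure_model(atoms, structure_id,
                               metadata = list(method = "X-RAY DIFFRACTION",
                                               resolution = 1.5,
                                               synthetic = TRUE))
  pairs <- data.frame(pair_index = 0:(n - 1),
                      chain1 = chain1, res1 = 1:n,
                      base1 = paste0("d", bases),
                      chain2 = chain2, res2 = n:1,
                      base2 = paste0("d", DNA_COMPLEMENT[bases]),
                      stringsAsFactors = FALSE)
  ledger <- list(kind = "fiber_duplex", form = form, sequence = sequence,
                 pairs = pairs, chain1 = chain1, chain2 = chain2)
  list(model = model, ledger = ledger)
}

# ---------------------------------------------------------------------------

#' Build a full heavy-atom amino-acid residue template
#'
#' Idealized internal geometry; used to plant probe residues.
#' @param aa three-letter amino-acid code.
#' @return data.frame(atom, element, x, y, z).
#' @export
build_amino_acid <- function(aa) {
  if (!aa %in% AMINO_ACIDS) stop("unknown amino acid: ", aa)
  pos <- list(N = c(0, 0, 0), CA = c(1.458, 0, 0))
  pos$C <- pos$CA + 1.525 * c(cos(deg2rad(69)), sin(deg2rad(69)), 0)
  pos$O <- place_atom(pos$N, pos$CA, pos$C, 1.231, 120.5, -45)
  if (aa != "GLY")
    pos$CB <- place_atom(pos$C, pos$N, pos$CA, 1.53, 110.5, -122)
  zm <- SIDECHAIN_ZMATRIX[[aa]]
  if (!is.null(zm)) {
    for (row in zm) {
      nm <- row[1]
      pos[[nm]] <- place_atom(pos[[row[4]]], pos[[row[3]]], pos[[row[2]]],
                              as.numeric(row[5]), as.numeric(row[6]),
                              as.numeric(row[7]))
    }
  }
  do.call(rbind, lapply(names(pos), function(nm) .atom_row(nm, pos[[nm]])))
}

# Reference-atom table for all standard nucleotides of a model.
.reference_atom_table <- function(model) {
  res <- residue_table(model)
  res <- res[res$kind == "dna", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(res))) {
    r <- res[i, ]
    ref <- REFERENCE_ATOM_MAP[[r$res_name]]
    ra <- .residue_atoms(model, r$key)
    for (g in c("minor", "major")) {
      sel <- ra[ra$atom == ref[[g]], , drop = FALSE]
      if (nrow(sel) == 1)
        out[[length(out) + 1]] <- data.frame(
          chain = r$chain, res_seq = r$res_seq, ins = r$ins, key = r$key,
          base = r$res_name, groove = g, atom = ref[[g]],
          x = sel$x, y = sel$y, z = sel$z, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Plant amino-acid probe residues at controlled distances
#'
#' Each probe is a complete heavy-atom residue placed so that its nearest
#' heavy atom sits exactly at the requested distance from the requested
#' groove reference atom, at least 0.5 Angstrom closer to it than to every
#' other reference atom in the structure, and without steric clash
#' (< 2 Angstrom) with existing atoms.  A deterministic direction scan plus a
#' 1D root solve enforces the exact distance; an unsatisfiable placement is
#' an error naming the probe.
#'
#' @param model a `StructureModel` containing DNA.
#' @param plan data.frame with columns `aa`, `nuc_chain`, `nuc_seq`,
#'   `groove` ("minor"/"major"), `distance` (Angstrom).
#' @param chain chain id for the planted probes.
#' @param cutoff contact cutoff used to fill the expected-contact column.
#' @return list with `model` (probes appended) and `probes` (ledger
#'   data.frame with the expected contact outcome per probe).
#' @export
plant_probe_residues <- function(model, plan, chain = "P", cutoff = 6.0) {
  refs <- .reference_atom_table(model)
  if (is.null(refs) || nrow(refs) == 0) stop("model contains no standard nucleotides")
  dirs <- fibonacci_sphere(700)
  existing <- .coords(.heavy(model$atoms))
  next_seq <- 1
  if (any(model$atoms$chain == chain))
    next_seq <- max(model$atoms$res_seq[model$atoms$chain == chain]) + 1
  ledger <- list(); new_atoms <- list()

  for (p in seq_len(nrow(plan))) {
    row <- plan[p, ]
    tgt <- refs[refs$chain == row$nuc_chain & refs$res_seq == row$nuc_seq &
                  refs$groove == row$groove, , drop = FALSE]
    if (nrow(tgt) != 1)
      stop("probe ", p, ": no ", row$groove, " reference atom on ",
           row$nuc_chain, ":", row$nuc_seq)
    ref_xyz <- c(tgt$x, tgt$y, tgt$z)
    others <- refs[!(refs$key == tgt$key & refs$groove == row$groove), ,
                   drop = FALSE]
    other_xyz <- as.matrix(others[, c("x", "y", "z")])
    tmpl <- build_amino_acid(row$aa)
    tc <- .coords(tmpl)
    bb <- colMeans(tc[tmpl$atom %in% c("N", "CA", "C", "O"), , drop = FALSE])
    tip_i <- which.max(sqrt(rowSums(sweep(tc, 2, bb)^2)))
    tip <- tc[tip_i, ]
    axis <- bb - tip
    if (vnorm(axis) < 1e-6) axis <- c(0, 0, 1)
    d <- row$distance
    placed <- NULL
    for (k in seq_len(nrow(dirs))) {
      u <- dirs[k, ]
      R <- rotation_between(axis, u)
      local_shift <- t(apply(tc, 1, function(v) as.vector(R %*% (v - tip))))
      g <- function(s) min(sqrt(rowSums(sweep(local_shift, 2,
                                              -(d + s) * u)^2))) - d
      lo <- -5; hi <- 15
      if (g(lo) > 0 || g(hi) < 0) next
      s_star <- stats::uniroot(g, c(lo, hi), tol = 1e-10)$root
      probe_xyz <- sweep(local_shift, 2, ref_xyz + (d + s_star) * u, "+")
      d_tgt <- min(sqrt(rowSums(sweep(probe_xyz, 2, ref_xyz)^2)))
      if (abs(d_tgt - d) > 1e-6) next
      if (nrow(other_xyz) > 0 && min(cross_dist(probe_xyz, other_xyz)) < d + 0.5)
        next
      # clash: nearest existing heavy atom (reference atom itself is at d)
      if (min(cross_dist(probe_xyz, existing)) < min(2.0, d - 1e-9)) next
      placed <- probe_xyz
      break
    }
    if (is.null(placed))
      stop("unsatisfiable placement for probe ", p, " (", row$aa, " at ",
           d, " A from ", row$groove, " atom of ", row$nuc_chain, ":",
           row$nuc_seq, ")")
    df <- tmpl
    df$x <- placed[, 1]; df$y <- placed[, 2]; df$z <- placed[, 3]
    df$chain <- chain; df$res_name <- row$aa; df$res_seq <- next_seq
    df$ins <- ""; df$occupancy <- 1; df$altloc <- ""; df$hetatm <- FALSE
    new_atoms[[length(new_atoms) + 1]] <-
      df[, c("chain", "res_name", "res_seq", "ins", "atom", "element",
             "x", "y", "z", "occupancy", "altloc", "hetatm")]
    existing <- rbind(existing, placed)
    ledger[[length(ledger) + 1]] <- data.frame(
      probe_chain = chain, probe_seq = next_seq, aa = row$aa,
      target_chain = row$nuc_chain, target_seq = row$nuc_seq,
      groove = row$groove, distance = d,
      expected_contact = (row$groove == "minor" && d < cutoff),
      stringsAsFactors = FALSE)
    next_seq <- next_seq + 1
  }
  model$atoms <- rbind(model$atoms, do.call(rbind, new_atoms))
  rownames(model$atoms) <- NULL
  list(model = model, probes = do.call(rbind, ledger))
}

# ---------------------------------------------------------------------------

#' Perturb the minor-groove phosphates of selected steps
#'
#' Displaces the phosphate groups entering the width window of the selected
#' steps radially (positive = outward, widening), optionally with seeded
#' Gaussian jitter, and re-derives the O5'/O3' bridge atoms.  A bond guard
#' rejects displacements that break backbone connectivity.  Assumes the
#' generator frame (helix axis = z).
#'
#' @param bundle list(model, ledger) from [generate_fiber_duplex()].
#' @param steps integer vector of step indices (0-based).
#' @param displacement radial displacement in Angstrom.
#' @param seed integer seed for the jitter (only used when jitter_sd > 0).
#' @param jitter_sd standard deviation of isotropic Gaussian jitter.
#' @return the bundle with perturbed model and a `perturbations` ledger entry.
#' @export
perturb_groove <- function(bundle, steps, displacement, seed = 1,
                           jitter_sd = 0) {
  model <- bundle$model; ledger <- bundle$ledger
  pairs <- ledger$pairs
  n <- nrow(pairs)
  targets <- list()
  for (s in steps) {
    if (s < 0 || s > n - 2) stop("step index out of range: ", s)
    for (pi in intersect(c(s + 1, s + 2), 1:(n - 1)))
      targets[[length(targets) + 1]] <- c(ledger$chain1, pairs$res1[pi + 1])
    for (pj in intersect(c(s - 1, s), 0:(n - 2)))
      targets[[length(targets) + 1]] <- c(ledger$chain2, pairs$res2[pj + 1])
  }
  targets <- unique(targets)
  a <- model$atoms
  key_all <- .residue_key(a$chain, a$res_seq, a$ins)
  if (jitter_sd > 0) set.seed(seed)

  for (t in targets) {
    ch <- t[1]; rs <- as.integer(t[2])
    sel <- a$chain == ch & a$res_seq == rs
    if (!any(sel & a$atom == "P")) next   # 5'-terminal residue: nothing to move
    pi_ <- which(sel & a$atom == "P")
    P_old <- c(a$x[pi_], a$y[pi_], a$z[pi_])
    rdir <- c(P_old[1], P_old[2], 0)
    rdir <- unitv(rdir)
    delta <- displacement * rdir
    if (jitter_sd > 0) delta <- delta + stats::rnorm(3, 0, jitter_sd)
    P_new <- P_old + delta
    for (nm in c("P", "OP1", "OP2")) {
      idx <- which(sel & a$atom == nm)
      if (length(idx)) {
        a$x[idx] <- a$x[idx] + delta[1]
        a$y[idx] <- a$y[idx] + delta[2]
        a$z[idx] <- a$z[idx] + delta[3]
      }
    }
    getxyz <- function(idx) c(a$x[idx], a$y[idx], a$z[idx])
    # re-derive the O5' bridge of this residue
    i_c5 <- which(sel & a$atom == "C5'"); i_c4 <- which(sel & a$atom == "C4'")
    i_o5 <- which(sel & a$atom == "O5'")
    if (length(i_c5) && length(i_o5)) {
      dPC5 <- vnorm(getxyz(i_c5) - P_new)
      if (dPC5 > 4.5 || dPC5 < 1.6)
        stop("bond guard violated: P-C5' separation ", round(dPC5, 2),
             " A on ", ch, ":", rs)
      o5 <- .place_two_bond(getxyz(i_c5), P_new, 1.44, 1.59, getxyz(i_c4))
      a$x[i_o5] <- o5[1]; a$y[i_o5] <- o5[2]; a$z[i_o5] <- o5[3]
    }
    # re-derive the O3' bridge of the 5'-neighbour residue (bonded to this P)
    prev <- which(a$chain == ch & a$res_seq == rs - 1 & a$atom == "C3'")
    if (length(prev)) {
      psel <- a$chain == ch & a$res_seq == rs - 1
      i_o3 <- which(psel & a$atom == "O3'")
      i_c4p <- which(psel & a$atom == "C4'")
      dPC3 <- vnorm(getxyz(prev) - P_new)
      if (dPC3 > 4.8 || dPC3 < 1.6)
        stop("bond guard violated: O3'-P bridge separation ", round(dPC3, 2),
             " A on ", ch, ":", rs)
      o3 <- .place_two_bond(getxyz(prev), P_new, 1.42, 1.59, getxyz(i_c4p))
      a$x[i_o3] <- o3[1]; a$y[i_o3] <- o3[2]; a$z[i_o3] <- o3[3]
    }
  }
  model$atoms <- a
  ledger$perturbations <- rbind(
    ledger$perturbations,
    data.frame(steps = paste(steps, collapse = ","),
               displacement = displacement, jitter_sd = jitter_sd,
               seed = seed, stringsAsFactors = FALSE))
  list(model = model, ledger = ledger)
}

# ---------------------------------------------------------------------------

#' Build a peptide chain with prescribed backbone dihedrals
#'
#' Backbone constructed from ideal bond lengths/angles (NeRF chaining) so the
#' target phi/psi values are achieved exactly; omega fixed at 180 degrees.
#'
#' @param sequence character vector of three-letter residue codes.
#' @param phi,psi numeric vectors of target dihedrals in degrees (phi[1] and
#'   psi[length] only orient terminal atoms).
#' @param chain chain identifier.
#' @param structure_id model label.
#' @return a `StructureModel` containing the peptide.
#' @export
build_peptide_with_dihedrals <- function(sequence, phi, psi, chain = "Q",
                                         structure_id = "peptide") {
  n <- length(sequence)
  stopifnot(length(phi) == n, length(psi) == n)
  if (!all(sequence %in% AMINO_ACIDS)) stop("unknown residue in sequence")
  N <- list(); CA <- list(); C <- list()
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(1.458, 0, 0)
  C[[1]] <- CA[[1]] + 1.525 * c(cos(deg2rad(69)), sin(deg2rad(69)), 0)
  for (i in seq_len(n)[-1]) {
    N[[i]] <- place_atom(N[[i - 1]], CA[[i - 1]], C[[i - 1]], 1.329, 116.6,
                         psi[i - 1])
    CA[[i]] <- place_atom(CA[[i - 1]], C[[i - 1]], N[[i]], 1.458, 121.7, 180)
    C[[i]] <- place_atom(C[[i - 1]], N[[i]], CA[[i]], 1.525, 111.0, phi[i])
  }
  rows <- list()
  for (i in seq_len(n)) {
    O <- place_atom(N[[i]], CA[[i]], C[[i]], 1.231, 120.8, psi[i] + 180)
    res <- rbind(.atom_row("N", N[[i]]), .atom_row("CA", CA[[i]]),
                 .atom_row("C", C[[i]]), .atom_row("O", O))
    if (sequence[i] != "GLY") {
      CB <- place_atom(C[[i]], N[[i]], CA[[i]], 1.53, 110.5, -122)
      res <- rbind(res, .atom_row("CB", CB))
    }
    res$chain <- chain; res$res_name <- sequence[i]; res$res_seq <- i
    res$ins <- ""; res$occupancy <- 1; res$altloc <- ""; res$hetatm <- FALSE
    rows[[i]] <- res
  }
  atoms <- do.call(rbind, rows)
  atoms <- atoms[, c("chain", "res_name", "res_seq", "ins", "atom", "element",
                     "x", "y", "z", "occupancy", "altloc", "hetatm")]
  new_structure_model(atoms, structure_id,
                      metadata = list(method = "X-RAY DIFFRACTION",
                                      resolution = 1.5, synthetic = TRUE))
}

#' Introduce a single documented defect into a model
#'
#' @param model a `StructureModel`.
#' @param defect "missing-atom", "nonstandard-residue" or "broken-pair".
#' @param chain,res_seq residue address of the defect target.
#' @param atom atom name (for "missing-atom").
#' @param new_name replacement residue name (for "nonstandard-residue").
#' @param translation displacement vector (for "broken-pair"; default 20 A
#'   along x, enough to break any pairing criterion).
#' @return the mutated model.
#' @export
make_defect_mutant <- function(model, defect = c("missing-atom",
                                                 "nonstandard-residue",
                                                 "broken-pair"),
                               chain, res_seq, atom = "P",
                               new_name = "BRU", translation = c(20, 0, 0)) {
  defect <- match.arg(defect)
  a <- model$atoms
  sel <- a$chain == chain & a$res_seq == res_seq
  if (!any(sel)) stop("defect target not found: ", chain, ":", res_seq)
  if (defect == "missing-atom") {
    hit <- sel & a$atom == atom
    if (!any(hit)) stop("atom ", atom, " not present on ", chain, ":", res_seq)
    a <- a[!hit, , drop = FALSE]
  } else if (defect == "nonstandard-residue") {
    a$res_name[sel] <- new_name
  } else {
    a$x[sel] <- a$x[sel] + translation[1]
    a$y[sel] <- a$y[sel] + translation[2]
    a$z[sel] <- a$z[sel] + translation[3]
  }
  model$atoms <- a
  rownames(model$atoms) <- NULL
  model
}
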