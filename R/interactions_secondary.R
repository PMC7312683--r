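# Backbone dihedrals, a phi/psi-region secondary-structure classifier,
# geometric hydrogen-bond and van der Waals contact detection against DNA,
# Kabsch superposition and representative-step selection.

#' Backbone phi/psi dihedrals of a protein chain
#'
#' Standard definitions from consecutive N/CA/C atoms; undefined (NA) at
#' chain termini, at chain breaks (peptide C-N distance > 2 Angstrom) and
#' where backbone atoms are missing.
#'
#' @param model a `StructureModel`.
#' @param chain_id protein chain identifier.
#' @return data.frame(chain, res_seq, res_name, key, phi, psi).
#' @export
compute_backbone_dihedrals <- function(model, chain_id) {
  res <- residue_table(model)
  res <- res[res$chain == chain_id & res$kind == "protein", , drop = FALSE]
  n <- nrow(res)
  if (n == 0) stop("no protein residues on chain ", chain_id)
  bb <- lapply(res$key, function(k) {
    ra <- .residue_atoms(model, k)
    g <- function(nm) {
      s <- ra[ra$atom == nm, , drop = FALSE]
      if (nrow(s) != 1) return(NULL)
      c(s$x, s$y, s$z)
    }
    list(N = g("N"), CA = g("CA"), C = g("C"))
  })
  linked <- function(i, j) {         # peptide bond i -> j
    !is.null(bb[[i]]$C) && !is.null(bb[[j]]$N) &&
      vnorm(bb[[i]]$C - bb[[j]]$N) < 2.0
  }
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    b <- bb[[i]]
    if (is.null(b$N) || is.null(b$CA) || is.null(b$C)) next
    if (i > 1 && linked(i - 1, i))
      phi[i] <- torsion_angle(bb[[i - 1]]$C, b$N, b$CA, b$C)
    if (i < n && linked(i, i + 1))
      psi[i] <- torsion_angle(b$N, b$CA, b$C, bb[[i + 1]]$N)
  }
  data.frame(chain = chain_id, res_seq = res$res_seq, res_name = res$res_name,
             key = res$key, phi = phi, psi = psi, stringsAsFactors = FALSE)
}

.in_range <- function(x, lo, hi) !is.na(x) & x >= lo & x <= hi

#' Assign secondary structure from phi/psi regions and chain curvature
#'
#' Region classifier (precedence order resolves overlaps): alpha-helix
#' (phi in [-100,-30], psi in [-80,-5]); 3-10 helix (phi in [-100,-30],
#' psi in (-5,45]); polyproline-II (phi in [-90,-55], psi in [120,180]);
#' beta-strand (phi in [-170,-70], psi in [90,180] or [-180,-170]); then
#' bend (C-alpha virtual angle over 5 residues > 70 degrees) and turn
#' (45-70 degrees); everything else "others"; missing dihedrals ->
#' "unassigned".
#'
#' @param model a `StructureModel`.
#' @param chain_id protein chain identifier.
#' @param dihedrals optional precomputed table from
#'   [compute_backbone_dihedrals()].
#' @return the dihedral table with a `ss` column appended.
#' @export
assign_secondary_structure <- function(model, chain_id, dihedrals = NULL) {
  if (is.null(dihedrals)) dihedrals <- compute_backbone_dihedrals(model, chain_id)
  phi <- dihedrals$phi; psi <- dihedrals$psi
  n <- nrow(dihedrals)
  ca <- lapply(dihedrals$key, function(k) {
    ra <- .residue_atoms(model, k)
    s <- ra[ra$atom == "CA", , drop = FALSE]
    if (nrow(s) != 1) return(NULL)
    c(s$x, s$y, s$z)
  })
  virt <- rep(NA_real_, n)
  for (i in 3:max(3, n - 2)) {
    if (n < 5 || i > n - 2) break
    a <- ca[[i - 2]]; b <- ca[[i]]; c_ <- ca[[i + 2]]
    if (is.null(a) || is.null(b) || is.null(c_)) next
    virt[i] <- 180 - angle3(a, b, c_)   # deviation from straight
  }
  ss <- character(n)
  for (i in seq_len(n)) {
    if (is.na(phi[i]) || is.na(psi[i])) { ss[i] <- "unassigned"; next }
    if (.in_range(phi[i], -100, -30) && .in_range(psi[i], -80, -5))
      ss[i] <- "alpha-helix"
    else if (.in_range(phi[i], -100, -30) && !is.na(psi[i]) &&
             psi[i] > -5 && psi[i] <= 45)
      ss[i] <- "3-10-helix"
    else if (.in_range(phi[i], -90, -55) && .in_range(psi[i], 120, 180))
      ss[i] <- "polyproline-II"
    else if (.in_range(phi[i], -170, -70) &&
             (.in_range(psi[i], 90, 180) || .in_range(psi[i], -180, -170)))
      ss[i] <- "beta-strand"
    else if (!is.na(virt[i]) && virt[i] > 70)
      ss[i] <- "bend"
    else if (!is.na(virt[i]) && virt[i] > 45)
      ss[i] <- "turn"
    else ss[i] <- "others"
  }
  dihedrals$ss <- ss
  dihedrals
}

# ---------------------------------------------------------------------------

.dna_target_class <- function(atom) {
  if (atom %in% DNA_PHOSPHATE_ATOMS) "phosphate"
  else if (atom %in% DNA_SUGAR_ACCEPTORS) "deoxyribose"
  else "base"
}

# donor list for a protein residue: data.frame(donor, antecedent, side)
.protein_donors <- function(res_name, atoms) {
  rows <- list(c("N", "CA", "backbone"))
  sc <- PROTEIN_DONORS[[res_name]]
  if (!is.null(sc))
    for (d in sc) rows[[length(rows) + 1]] <- c(d[1], d[2], "side-chain")
  df <- do.call(rbind, rows)
  df <- data.frame(donor = df[, 1], antecedent = df[, 2], side = df[, 3],
                   stringsAsFactors = FALSE)
  df[df$donor %in% atoms & df$antecedent %in% atoms, , drop = FALSE]
}

.protein_acceptors <- function(res_name, atoms) {
  acc <- c("O")
  side <- "backbone"
  sc <- PROTEIN_ACCEPTORS[[res_name]]
  out <- data.frame(acceptor = "O", side = "backbone",
                    stringsAsFactors = FALSE)
  if (!is.null(sc))
    out <- rbind(out, data.frame(acceptor = sc, side = "side-chain",
                                 stringsAsFactors = FALSE))
  out[out$acceptor %in% atoms, , drop = FALSE]
}

#' Detect protein-DNA hydrogen bonds geometrically
#'
#' Donor-acceptor heavy-atom pairs within `dist_cutoff` Angstrom whose
#' donor-antecedent--donor--acceptor angle is at least `angle_cutoff`
#' degrees.  Both directions are scanned (protein donor -> DNA acceptor and
#' DNA donor -> protein acceptor).  Each bond is classified by protein side
#' (backbone / side-chain) and DNA target (base / deoxyribose / phosphate).
#'
#' @param model a `StructureModel`.
#' @param protein_keys optional residue keys to restrict the protein side.
#' @param dist_cutoff heavy-atom distance cutoff (default 3.5).
#' @param angle_cutoff minimum donor-antecedent-donor-acceptor angle
#'   (default 90).
#' @return data.frame of hydrogen bonds.
#' @export
detect_hbonds <- function(model, protein_keys = NULL, dist_cutoff = 3.5,
                          angle_cutoff = 90) {
  res <- residue_table(model)
  prot <- res[res$kind == "protein", , drop = FALSE]
  if (!is.null(protein_keys)) prot <- prot[prot$key %in% protein_keys, ,
                                           drop = FALSE]
  dna <- res[res$kind == "dna", , drop = FALSE]
  out <- list()
  add <- function(pkey, ptype, patom, side, nkey, nbase, natom, d, ang,
                  direction) {
    out[[length(out) + 1]] <<- data.frame(
      residue_key = pkey, residue_type = ptype, protein_atom = patom,
      protein_side = side, nuc_key = nkey, base = nbase, dna_atom = natom,
      dna_target = .dna_target_class(natom), distance = d, angle = ang,
      direction = direction, stringsAsFactors = FALSE)
  }
  get_xyz <- function(ra, nm) {
    s <- ra[ra$atom == nm, , drop = FALSE]
    if (nrow(s) != 1) return(NULL)
    c(s$x, s$y, s$z)
  }
  for (i in seq_len(nrow(prot))) {
    pr <- prot[i, ]
    pa <- .residue_atoms(model, pr$key)
    for (j in seq_len(nrow(dna))) {
      nu <- dna[j, ]
      na_ <- .residue_atoms(model, nu$key)
      # quick reject
      if (min_dist(.coords(.heavy(pa)), .coords(.heavy(na_))) > dist_cutoff + 4)
        next
      # protein donors -> DNA acceptors
      don <- .protein_donors(pr$res_name, pa$atom)
      dna_acc <- c(DNA_PHOSPHATE_ATOMS, DNA_SUGAR_ACCEPTORS,
                   DNA_BASE_ACCEPTORS[[nu$res_name]])
      dna_acc <- intersect(dna_acc, na_$atom)
      for (k in seq_len(nrow(don))) {
        D <- get_xyz(pa, don$donor[k]); A0 <- get_xyz(pa, don$antecedent[k])
        if (is.null(D) || is.null(A0)) next
        for (acc in dna_acc) {
          A <- get_xyz(na_, acc)
          d <- vnorm(D - A)
          if (d > dist_cutoff) next
          ang <- angle3(A0, D, A)
          if (ang < angle_cutoff) next
          add(pr$key, pr$res_name, don$donor[k], don$side[k], nu$key,
              nu$res_name, acc, d, ang, "protein-donor")
        }
      }
      # DNA donors -> protein acceptors
      ddon <- DNA_BASE_DONORS[[nu$res_name]]
      pacc <- .protein_acceptors(pr$res_name, pa$atom)
      for (dd in ddon) {
        D <- get_xyz(na_, dd[1]); A0 <- get_xyz(na_, dd[2])
        if (is.null(D) || is.null(A0)) next
        for (k in seq_len(nrow(pacc))) {
          A <- get_xyz(pa, pacc$acceptor[k])
          if (is.null(A)) next
          d <- vnorm(D - A)
          if (d > dist_cutoff) next
          ang <- angle3(A0, D, A)
          if (ang < angle_cutoff) next
          add(pr$key, pr$res_name, pacc$acceptor[k], pacc$side[k], nu$key,
              nu$res_name, dd[1], d, ang, "dna-donor")
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(residue_key = character(0), residue_type = character(0),
                      protein_atom = character(0), protein_side = character(0),
                      nuc_key = character(0), base = character(0),
                      dna_atom = character(0), dna_target = character(0),
                      distance = numeric(0), angle = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Classify van der Waals protein-DNA contacts
#'
#' Heavy-atom pairs within `cutoff` Angstrom that are not already counted
#' as hydrogen bonds, tagged by DNA target class.
#'
#' @param model a `StructureModel`.
#' @param hbonds hydrogen-bond table from [detect_hbonds()] (pairs listed
#'   there are excluded).
#' @param protein_keys optional restriction of the protein side.
#' @param cutoff distance cutoff (default 4.0).
#' @return data.frame of contacts.
#' @export
classify_vdw_contacts <- function(model, hbonds = NULL, protein_keys = NULL,
                                  cutoff = 4.0) {
  res <- residue_table(model)
  prot <- res[res$kind == "protein", , drop = FALSE]
  if (!is.null(protein_keys)) prot <- prot[prot$key %in% protein_keys, ,
                                           drop = FALSE]
  dna <- res[res$kind == "dna", , drop = FALSE]
  hb_id <- if (!is.null(hbonds) && nrow(hbonds))
    paste(hbonds$residue_key, hbonds$protein_atom, hbonds$nuc_key,
          hbonds$dna_atom)
  else character(0)
  out <- list()
  for (i in seq_len(nrow(prot))) {
    pa <- .heavy(.residue_atoms(model, prot$key[i]))
    for (j in seq_len(nrow(dna))) {
      na_ <- .heavy(.residue_atoms(model, dna$key[j]))
      D <- cross_dist(.coords(pa), .coords(na_))
      hits <- which(D <= cutoff, arr.ind = TRUE)
      for (h in seq_len(nrow(hits))) {
        patom <- pa$atom[hits[h, 1]]; natom <- na_$atom[hits[h, 2]]
        id <- paste(prot$key[i], patom, dna$key[j], natom)
        if (id %in% hb_id) next
        out[[length(out) + 1]] <- data.frame(
          residue_key = prot$key[i], residue_type = prot$res_name[i],
          protein_atom = patom,
          protein_side = if (patom %in% c("N", "CA", "C", "O")) "backbone"
                         else "side-chain",
          nuc_key = dna$key[j], base = dna$res_name[j], dna_atom = natom,
          dna_target = .dna_target_class(natom),
          distance = D[hits[h, 1], hits[h, 2]], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(residue_key = character(0), residue_type = character(0),
                      protein_atom = character(0), protein_side = character(0),
                      nuc_key = character(0), base = character(0),
                      dna_atom = character(0), dna_target = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

# ---------------------------------------------------------------------------

#' Kabsch superposition of matched point sets
#'
#' Least-squares optimal proper rotation and translation mapping `coords_a`
#' onto `coords_b`, with the residual RMSD.
#'
#' @param coords_a,coords_b n x 3 matrices of matched points (n >= 3,
#'   non-collinear).
#' @return list(rotation 3x3, translation 3-vector, rmsd), such that
#'   `coords_a %*% t(rotation) + translation` best fits `coords_b`.
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  A <- as.matrix(coords_a); B <- as.matrix(coords_b)
  if (nrow(A) != nrow(B) || ncol(A) != 3 || ncol(B) != 3)
    stop("point sets must be matched n x 3 matrices")
  if (nrow(A) < 3) stop("need at least 3 matched points")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  if (svd(A0)$d[2] < 1e-8 || svd(B0)$d[2] < 1e-8)
    stop("degenerate (collinear) point set")
  H <- t(A0) %*% B0
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- A0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - B0)^2)))
  translation <- cb - as.vector(R %*% ca)
  list(rotation = R, translation = translation, rmsd = rmsd)
}

#' Representative step by minimal total RMSD
#'
#' Given matched coordinate sets (one per dinucleotide step, identical atom
#' correspondence), returns the index of the step minimizing the sum of
#' pairwise Kabsch RMSDs to all other steps; ties go to the lowest index.
#'
#' @param steps list of n x 3 coordinate matrices.
#' @param tol sums within `tol` of the minimum count as tied (absorbs
#'   floating-point noise in the superposition).
#' @return integer index into `steps`.
#' @export
representative_step <- function(steps, tol = 1e-9) {
  if (!length(steps)) stop("empty step list")
  if (length(steps) == 1) return(1L)
  m <- length(steps)
  rms <- matrix(0, m, m)
  for (i in seq_len(m - 1))
    for (j in (i + 1):m) {
      r <- kabsch_superpose(steps[[i]], steps[[j]])$rmsd
      rms[i, j] <- rms[j, i] <- r
    }
  sums <- rowSums(rms)
  which(sums <= min(sums) + tol)[1]
}
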