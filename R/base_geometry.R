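# Idealized nucleobase and Watson-Crick pair geometry used by the fiber-model
# generator.  Bases are built procedurally (regular-polygon rings, standard
# bond lengths) in a planar pair frame; the pair frame is then embedded
# helically with form-specific parameters.  The phosphate cylindrical
# placement is calibrated against the canonical ideal-form groove widths
# (see FIBER_FORMS below and the methods vignette).

.geom_cache <- new.env(parent = emptyenv())

# 2D rigid (proper) least-squares fit of points A onto points B; returns
# list(R, t) with B ~ A %*% t(R) + t.
.fit2d <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  # optimal 2D rotation angle from the cross-covariance
  num <- sum(A0[, 1] * B0[, 2] - A0[, 2] * B0[, 1])
  den <- sum(A0[, 1] * B0[, 1] + A0[, 2] * B0[, 2])
  th <- atan2(num, den)
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  t <- cb - as.vector(R %*% ca)
  list(R = R, t = t)
}

.apply2d <- function(coords, fit) {
  sweep(coords %*% t(fit$R), 2, fit$t, "+")
}

# Planar heavy-atom coordinates of one base, glycosidic C1' included.
# Rings are regular polygons (bond 1.39), exocyclic substituents radial.
.base2d <- function(base) {
  key <- paste0("base2d_", base)
  if (!is.null(.geom_cache[[key]])) return(.geom_cache[[key]])
  r6 <- 1.39
  hex_names <- c("N1", "C2", "N3", "C4", "C5", "C6")
  hex_ang <- deg2rad(c(90, 30, -30, -90, -150, 150))
  hex <- cbind(r6 * cos(hex_ang), r6 * sin(hex_ang))
  rownames(hex) <- hex_names
  radial <- function(p, extra) p * (1 + extra / vnorm(p))

  if (base %in% c("dA", "dG")) {
    # fuse a regular pentagon (C4, N9, C8, N7, C5) on the C4-C5 edge
    A <- hex["C4", ]; B <- hex["C5", ]
    mid <- (A + B) / 2
    n_out <- mid / vnorm(mid)
    s <- vnorm(B - A)
    center <- mid + (s / (2 * tan(pi / 5))) * n_out
    vA <- A - center
    rotp <- function(v, deg) {
      th <- deg2rad(deg)
      c(cos(th) * v[1] - sin(th) * v[2], sin(th) * v[1] + cos(th) * v[2])
    }
    # choose the rotation direction that leaves the pentagon outside the ring
    cand1 <- center + rotp(vA, 72)
    cand2 <- center + rotp(vA, -72)
    sgn <- if (vnorm(cand1) > vnorm(cand2)) 72 else -72
    N9 <- center + rotp(vA, sgn)
    C8 <- center + rotp(vA, 2 * sgn)
    N7 <- center + rotp(vA, 3 * sgn)
    pen_center <- center
    C1p <- N9 + 1.47 * (N9 - pen_center) / vnorm(N9 - pen_center)
    coords <- rbind(hex, N9 = N9, C8 = C8, N7 = N7)
    if (base == "dA") {
      coords <- rbind(coords, N6 = radial(hex["C6", ], 1.34))
    } else {
      coords <- rbind(coords,
                      O6 = radial(hex["C6", ], 1.23),
                      N2 = radial(hex["C2", ], 1.34))
    }
    coords <- rbind(coords, "C1'" = C1p)
  } else {
    coords <- rbind(hex, O2 = radial(hex["C2", ], 1.23))
    if (base == "dT") {
      coords <- rbind(coords,
                      O4 = radial(hex["C4", ], 1.23),
                      C7 = radial(hex["C5", ], 1.50))
    } else {
      coords <- rbind(coords, N4 = radial(hex["C4", ], 1.34))
    }
    coords <- rbind(coords, "C1'" = radial(hex["N1", ], 1.47))
  }
  .geom_cache[[key]] <- coords
  coords
}

# Watson-Crick pair template for a given strand-1 base.  Returns a list with
# named 3-column matrices `s1` and `s2` (z = 0), normalized so the C1'-C1'
# midpoint is at the origin, strand-1 C1' lies on the -x axis, and the
# minor-groove edge (purine N3 / pyrimidine O2) faces -y.
.pair_template <- function(base1) {
  key <- paste0("pair_", base1)
  if (!is.null(.geom_cache[[key]])) return(.geom_cache[[key]])

  purine_first <- base1 %in% PURINES
  pur <- if (purine_first) base1 else paste0("d", DNA_COMPLEMENT[substring(base1, 2)])
  pyr <- if (purine_first) paste0("d", DNA_COMPLEMENT[substring(base1, 2)]) else base1

  P <- .base2d(pur)
  Y <- .base2d(pyr)
  # Bases are planar, so the strand-2 base is placed by a proper in-plane
  # rotation; the apparent "flip" of the second strand is absorbed by the
  # pair-level dyad used when the helix is assembled.
  Ym <- Y

  # Hydrogen bonds across a WC pair run roughly parallel to the pairing
  # axis, taken here as the radial direction at the purine N1.
  dirP <- P["N1", ] / vnorm(P["N1", ])
  if (pur == "dA") {
    # A:T -- N1...N3 (2.85), N6...O4 (2.90)
    tgt <- rbind(P["N1", ] + 2.85 * dirP,
                 P["N6", ] + 2.90 * dirP)
    src <- Ym[c("N3", "O4"), ]
  } else {
    # G:C -- N1...N3 (2.88), O6...N4 (2.91), N2...O2 (2.86)
    tgt <- rbind(P["N1", ] + 2.88 * dirP,
                 P["O6", ] + 2.91 * dirP,
                 P["N2", ] + 2.86 * dirP)
    src <- Ym[c("N3", "N4", "O2"), ]
  }
  fit <- .fit2d(src, tgt)
  Yp <- .apply2d(Ym, fit)

  if (purine_first) { s1 <- P; s2 <- Yp } else { s1 <- Yp; s2 <- P }

  # normalize the pair frame
  c1 <- s1["C1'", ]; c2 <- s2["C1'", ]
  midc <- (c1 + c2) / 2
  s1 <- sweep(s1, 2, midc); s2 <- sweep(s2, 2, midc)
  xdir <- (s2["C1'", ] - s1["C1'", ])
  th <- -atan2(xdir[2], xdir[1])
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  s1 <- s1 %*% t(R); s2 <- s2 %*% t(R)
  rownames(s1) <- rownames(if (purine_first) P else Yp)
  rownames(s2) <- rownames(if (purine_first) Yp else P)

  # minor-groove edge to -y
  minor1 <- REFERENCE_ATOM_MAP[[base1]]["minor"]
  base2 <- paste0("d", DNA_COMPLEMENT[substring(base1, 2)])
  minor2 <- REFERENCE_ATOM_MAP[[base2]]["minor"]
  if (mean(c(s1[minor1, 2], s2[minor2, 2])) > 0) {
    s1[, 2] <- -s1[, 2]; s2[, 2] <- -s2[, 2]
  }
  out <- list(s1 = cbind(s1, 0), s2 = cbind(s2, 0),
              base1 = base1, base2 = base2)
  colnames(out$s1) <- colnames(out$s2) <- c("x", "y", "z")
  .geom_cache[[key]] <- out
  out
}

unitv2 <- function(v) v / vnorm(v)

# ---------------------------------------------------------------------------
# Deoxyribose ring with a prescribed pseudorotation phase/amplitude, built in
# a local frame with C1' at the origin.  Only nu1 and nu2 are imposed
# directly; the remaining endocyclic torsions follow from the near-closed
# ring and land within a few degrees of the Altona-Sundaralingam target,
# comfortably inside the 36-degree-wide classification bins.
.sugar_ring_local <- function(phase, tau) {
  nu1 <- tau * cospi((phase - 144) / 180)
  nu2 <- tau * cospi(phase / 180)
  C1 <- c(0, 0, 0)
  O4 <- c(1.41, 0, 0)
  ang <- deg2rad(106)
  C2 <- 1.52 * c(cos(ang), sin(ang), 0)
  C3 <- place_atom(O4, C1, C2, 1.53, 102.5, nu1)
  C4 <- place_atom(C1, C2, C3, 1.53, 103.2, nu2)
  rbind("C1'" = C1, "O4'" = O4, "C2'" = C2, "C3'" = C3, "C4'" = C4)
}

# Orient a local sugar ring at a C1' world position: the glycosidic direction
# is aligned to the base nitrogen and the residual twist is chosen (coarse
# deterministic scan) so C4'/C3' face their phosphates.
.orient_sugar <- function(ring, c1_world, n_world, p_own, p_next) {
  u1 <- unitv(ring["O4'", ])
  u2 <- unitv(ring["C2'", ])
  nrm <- unitv(cross3(u1, u2))
  g_loc <- unitv(-(u1 + u2) + 1.0 * nrm)
  g_world <- unitv(n_world - c1_world)
  R1 <- rotation_between(g_loc, g_world)
  best <- NULL; best_score <- Inf
  # aim for chemically sensible bridge separations: C4'...P(own) ~ 3.9 A
  # (through C5'-O5'), C3'...P(next) ~ 2.6 A (through O3')
  for (th in seq(0, 355, by = 5)) {
    R <- rotation_about_axis(g_world, th) %*% R1
    c4 <- c1_world + as.vector(R %*% ring["C4'", ])
    c3 <- c1_world + as.vector(R %*% ring["C3'", ])
    sc <- (vnorm(c4 - p_own) - 3.9)^2 + (vnorm(c3 - p_next) - 2.6)^2
    if (sc < best_score) { best_score <- sc; best <- R }
  }
  out <- t(apply(ring, 1, function(v) c1_world + as.vector(best %*% v)))
  rownames(out) <- rownames(ring)
  out
}

# ---------------------------------------------------------------------------
# Fiber-form helical constants.  twist/rise are the canonical fiber values.
# The pair-frame y-displacement and the phosphate cylindrical coordinates
# (radius, azimuth relative to the pair frame, z-offset) were calibrated so
# that the implemented cross-strand P-P width convention reproduces the
# canonical ideal-form minor groove widths (A: 18.5 Angstrom, B: ~11.7
# Angstrom) while keeping phosphate-sugar distances chemically plausible.
# Pucker targets: C3'-endo for A-form, C2'-endo for B-form.
FIBER_FORMS <- list(
  A = list(twist = 32.7, rise = 2.56,
           disp_y = 4.50, p_radius = 9.40, p_phi = 135.8149, p_z = -3.40,
           pucker_phase = 13, pucker_tau = 37),
  B = list(twist = 36.0, rise = 3.38,
           disp_y = -1.50, p_radius = 9.60, p_phi = 187.6704, p_z = -1.40,
           pucker_phase = 160, pucker_tau = 36)
)

# Cylindrical positions of the strand-1 / strand-2 phosphorus for pair index i
# (0-based).  Strand 2 follows from the pair-level dyad (rotation by pi about
# the y axis): azimuth phi -> 180 - phi, z -> -z.
.p_position <- function(form, i, strand) {
  fp <- FIBER_FORMS[[form]]
  if (strand == 1) {
    ang <- i * fp$twist + fp$p_phi
    z <- i * fp$rise + fp$p_z
  } else {
    ang <- i * fp$twist + (180 - fp$p_phi)
    z <- i * fp$rise - fp$p_z
  }
  c(fp$p_radius * cos(deg2rad(ang)), fp$p_radius * sin(deg2rad(ang)), z)
}
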