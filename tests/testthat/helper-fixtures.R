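# Shared fixtures and independent oracles.  Fixtures are generated in code
# and cached per session; oracles are deliberately written along different
# code paths than the implementations they check.

.fixture_cache <- new.env(parent = emptyenv())

fixture_duplex <- function(form = "B", sequence = "ATGCATGCAT") {
  key <- paste(form, sequence)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generate_fiber_duplex(form, sequence,
                                                   structure_id = key)
  .fixture_cache[[key]]
}

fixture_duplexes_of <- function(model) {
  build_duplexes(detect_base_pairs(model), model)
}

# rigid motion of a whole model (proper rotation + translation)
transform_model <- function(model, axis = c(1, 2, 3), angle = 37,
                            shift = c(5, -3, 11)) {
  R <- groovescan:::rotation_about_axis(axis, angle)
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, shift, "+")
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]; model$atoms$z <- xyz[, 3]
  model
}

# --- independent oracles ---------------------------------------------------

# dihedral via normal-vector acos with explicit sign (different path from
# the package's atan2 formulation)
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cx <- function(a, b) c(a[2]*b[3]-a[3]*b[2], a[3]*b[1]-a[1]*b[3],
                         a[1]*b[2]-a[2]*b[1])
  n1 <- cx(b1, b2); n2 <- cx(b2, b3)
  cosv <- sum(n1*n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(max(-1, min(1, cosv))) * 180 / pi
  if (sum(cx(n1, n2) * b2) < 0) ang <- -ang
  ang
}

# Altona-Sundaralingam phase from a nucleotide's ring atoms, written
# independently (tan + quadrant handling instead of atan2)
oracle_pucker_phase <- function(atoms) {
  g <- function(nm) {
    s <- atoms[atoms$atom == nm, ]
    c(s$x, s$y, s$z)
  }
  C1 <- g("C1'"); C2 <- g("C2'"); C3 <- g("C3'"); C4 <- g("C4'"); O4 <- g("O4'")
  nu <- c(oracle_dihedral(C4, O4, C1, C2),
          oracle_dihedral(O4, C1, C2, C3),
          oracle_dihedral(C1, C2, C3, C4),
          oracle_dihedral(C2, C3, C4, O4),
          oracle_dihedral(C3, C4, O4, C1))
  num <- (nu[5] + nu[2]) - (nu[4] + nu[1])
  den <- 2 * nu[3] * (sin(36 * pi / 180) + sin(72 * pi / 180))
  if (abs(den) < 1e-300) return(if (num >= 0) 90 else 270)
  P <- atan(num / den) * 180 / pi
  if (den < 0) P <- P + 180            # quadrant fix: sign of nu2
  if (P < 0) P <- P + 360
  P
}

# one-sided Mann-Whitney p by exhaustive labeling, with U computed by
# direct pairwise counting (not ranks)
oracle_mw_p <- function(x, y) {
  u_of <- function(a, b) {
    u <- 0
    for (xi in a) for (yj in b) u <- u + (xi > yj) + 0.5 * (xi == yj)
    u
  }
  U <- u_of(x, y)
  pooled <- c(x, y)
  n1 <- length(x)
  combs <- utils::combn(length(pooled), n1)
  ge <- 0
  for (k in seq_len(ncol(combs))) {
    xs <- pooled[combs[, k]]; ys <- pooled[-combs[, k]]
    if (u_of(xs, ys) >= U - 1e-9) ge <- ge + 1
  }
  ge / ncol(combs)
}

# brute-force minimal RMSD over rigid motions (quaternion multi-start optim)
oracle_min_rmsd <- function(A, B) {
  A0 <- sweep(A, 2, colMeans(A)); B0 <- sweep(B, 2, colMeans(B))
  rot <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1-2*(y^2+z^2), 2*(x*y-w*z), 2*(x*z+w*y),
             2*(x*y+w*z), 1-2*(x^2+z^2), 2*(y*z-w*x),
             2*(x*z-w*y), 2*(y*z+w*x), 1-2*(x^2+y^2)), 3, 3, byrow = TRUE)
  }
  obj <- function(q) {
    R <- rot(q)
    sqrt(mean(rowSums((A0 %*% t(R) - B0)^2)))
  }
  best <- Inf
  set.seed(42)
  for (s in 1:40) {
    q0 <- stats::rnorm(4)
    o <- stats::optim(q0, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}

# Hand-built 4-pair toy duplex (minimal atoms) with GLY probes at chosen x
# positions along the helix axis; used for exactly controlled
# step-assignment geometry.
toy_duplex_fixture <- function(probe_xs = numeric(0)) {
  mk_nt <- function(chain, seq, base, x0) {
    ref <- reference_atoms(base)["minor"]
    wc <- if (base %in% c("dA", "dG")) "N1" else "N3"
    ywc <- if (chain == "A") 1.4 else -1.4
    data.frame(chain = chain, res_name = base, res_seq = seq, ins = "",
               atom = c("C1'", wc, ref, "P"),
               element = c("C", "N", substr(ref, 1, 1), "P"),
               x = x0, y = c(5.2 * ifelse(chain == "A", 1, -1), ywc, 0, 6),
               z = c(0, 0, 0, 2),
               occupancy = 1, altloc = "", hetatm = FALSE,
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (i in 1:4) {
    rows[[length(rows) + 1]] <- mk_nt("A", i, "dA", i * 3.4)
    rows[[length(rows) + 1]] <- mk_nt("B", 5 - i, "dT", i * 3.4)
  }
  for (k in seq_along(probe_xs)) {
    rows[[length(rows) + 1]] <- data.frame(
      chain = "P", res_name = "GLY", res_seq = k, ins = "",
      atom = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
      x = probe_xs[k], y = c(0, 0.3, -0.3, 0), z = -4,
      occupancy = 1, altloc = "", hetatm = FALSE, stringsAsFactors = FALSE)
  }
  model <- new_structure_model(do.call(rbind, rows), "toy")
  dups <- list(structure(list(
    pairs = data.frame(pair_index = 0:3,
                       key_i = paste0("A:", 1:4, ":."), chain_i = "A",
                       res_i = 1:4, base_i = "dA",
                       key_j = paste0("B:", 4:1, ":."), chain_j = "B",
                       res_j = 4:1, base_j = "dT", stringsAsFactors = FALSE),
    n = 4L, sequence = "AAAA"), class = "Duplex"))
  list(model = model, dups = dups)
}
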