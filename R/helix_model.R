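# Base-pair detection, duplex assembly, minor groove width computation
# (cross-strand phosphate-distance convention) and sugar pucker
# pseudorotation analysis.

# Geometric Watson-Crick criteria: complementary bases, glycosidic-nitrogen
# donor pair (purine N1 -- pyrimidine N3) within WC_N_DIST, C1'-C1' distance
# inside the canonical window.
WC_N_DIST <- 3.5
WC_C1_RANGE <- c(9.5, 11.5)

.is_complementary <- function(b1, b2) {
  paste0("d", DNA_COMPLEMENT[substring(b1, 2)]) == b2
}

#' Detect Watson-Crick base pairs
#'
#' Scans all standard nucleotides of a model for complementary
#' purine/pyrimidine pairs satisfying the geometric criteria; each
#' nucleotide enters at most one pair (greedy by hydrogen-bond distance).
#'
#' @param model a `StructureModel`.
#' @return data.frame of pairs (residue keys, chains, bases, geometry);
#'   zero rows when nothing pairs.
#' @export
detect_base_pairs <- function(model) {
  res <- residue_table(model)
  res <- res[res$kind == "dna", , drop = FALSE]
  empty <- data.frame(key_i = character(0), key_j = character(0),
                      chain_i = character(0), res_i = integer(0),
                      base_i = character(0), chain_j = character(0),
                      res_j = integer(0), base_j = character(0),
                      d_n = numeric(0), d_c1 = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(res) < 2) return(empty)
  # cache the two anchor atoms per nucleotide
  anchors <- lapply(seq_len(nrow(res)), function(i) {
    r <- res[i, ]
    ra <- .residue_atoms(model, r$key)
    wc_atom <- if (r$res_name %in% PURINES) "N1" else "N3"
    c1 <- ra[ra$atom == "C1'", , drop = FALSE]
    wc <- ra[ra$atom == wc_atom, , drop = FALSE]
    if (nrow(c1) != 1 || nrow(wc) != 1) return(NULL)
    list(c1 = c(c1$x, c1$y, c1$z), wc = c(wc$x, wc$y, wc$z))
  })
  cand <- list()
  pur_idx <- which(res$res_name %in% PURINES)
  pyr_idx <- which(res$res_name %in% PYRIMIDINES)
  for (i in pur_idx) {
    if (is.null(anchors[[i]])) next
    for (j in pyr_idx) {
      if (is.null(anchors[[j]])) next
      if (!.is_complementary(res$res_name[i], res$res_name[j])) next
      dn <- vnorm(anchors[[i]]$wc - anchors[[j]]$wc)
      if (dn > WC_N_DIST) next
      dc <- vnorm(anchors[[i]]$c1 - anchors[[j]]$c1)
      if (dc < WC_C1_RANGE[1] || dc > WC_C1_RANGE[2]) next
      cand[[length(cand) + 1]] <- data.frame(
        key_i = res$key[i], key_j = res$key[j],
        chain_i = res$chain[i], res_i = res$res_seq[i],
        base_i = res$res_name[i], chain_j = res$chain[j],
        res_j = res$res_seq[j], base_j = res$res_name[j],
        d_n = dn, d_c1 = dc, stringsAsFactors = FALSE)
    }
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$d_n), , drop = FALSE]
  used <- character(0); keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (cand$key_i[k] %in% used || cand$key_j[k] %in% used) next
    keep[k] <- TRUE
    used <- c(used, cand$key_i[k], cand$key_j[k])
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble duplexes from detected base pairs
#'
#' Maximal runs of pairs that are sequence-adjacent on both strands (file
#' order, antiparallel) become duplexes; runs shorter than `min_length`
#' pairs are discarded.
#'
#' @param pairs data.frame from [detect_base_pairs()].
#' @param model the corresponding `StructureModel`.
#' @param min_length minimum number of pairs per duplex (default 3).
#' @return list of `Duplex` objects; each holds a `pairs` data.frame indexed
#'   0..n-1 with strand-1 read 5'->3'.
#' @export
build_duplexes <- function(pairs, model, min_length = 3) {
  if (nrow(pairs) == 0) return(list())
  res <- residue_table(model)
  res <- res[res$kind == "dna", , drop = FALSE]
  pos <- stats::setNames(ave(seq_len(nrow(res)), res$chain, FUN = seq_along),
                         res$key)
  # orient each pair: strand 1 = lexicographically smaller chain (or the
  # lower file position for hairpins)
  ori <- pairs
  swap <- ori$chain_j < ori$chain_i |
    (ori$chain_j == ori$chain_i & pos[ori$key_j] < pos[ori$key_i])
  flip <- function(df, s) {
    tmp <- df[s, c("key_i", "chain_i", "res_i", "base_i")]
    df[s, c("key_i", "chain_i", "res_i", "base_i")] <-
      df[s, c("key_j", "chain_j", "res_j", "base_j")]
    df[s, c("key_j", "chain_j", "res_j", "base_j")] <- tmp
    df
  }
  ori <- flip(ori, swap)
  ori$pos_i <- pos[ori$key_i]; ori$pos_j <- pos[ori$key_j]
  ori <- ori[order(ori$chain_i, ori$chain_j, ori$pos_i), , drop = FALSE]
  duplexes <- list(); run <- list()
  flush <- function() {
    if (length(run) >= min_length) {
      df <- do.call(rbind, run)
      df$pair_index <- seq_len(nrow(df)) - 1L
      duplexes[[length(duplexes) + 1]] <<- structure(
        list(pairs = df, n = nrow(df),
             sequence = paste(substring(df$base_i, 2), collapse = "")),
        class = "Duplex")
    }
    run <<- list()
  }
  for (k in seq_len(nrow(ori))) {
    r <- ori[k, ]
    if (length(run)) {
      prev <- run[[length(run)]]
      contiguous <- r$chain_i == prev$chain_i && r$chain_j == prev$chain_j &&
        r$pos_i == prev$pos_i + 1 && r$pos_j == prev$pos_j - 1
      if (!contiguous) flush()
    }
    run[[length(run) + 1]] <- r
  }
  flush()
  duplexes
}

#' @export
print.Duplex <- function(x, ...) {
  cat("Duplex of", x$n, "base pairs:", x$sequence, "\n")
  invisible(x)
}

# Phosphorus position of the strand-1 / strand-2 nucleotide at a pair index.
.duplex_P <- function(model, duplex, pair_index, strand) {
  p <- duplex$pairs[duplex$pairs$pair_index == pair_index, , drop = FALSE]
  if (nrow(p) != 1) return(NULL)
  key <- if (strand == 1) p$key_i else p$key_j
  ra <- .residue_atoms(model, key)
  sel <- ra[ra$atom == "P", , drop = FALSE]
  if (nrow(sel) != 1) return(NULL)
  c(sel$x, sel$y, sel$z)
}

#' Minor groove width at a dinucleotide step
#'
#' Direct cross-strand phosphorus-phosphorus convention (no van der Waals
#' subtraction): for step s (pairs s, s+1; 0-based) the width is the minimum
#' P-P distance over the level combinations (s+1, s-1), (s+2, s-1) and
#' (s+2, s) of strand-1/strand-2 phosphates flanking the step.  Steps whose
#' window reaches past the duplex ends are undefined (NA); a missing
#' phosphate gives NA with a reason attribute.
#'
#' @param duplex a `Duplex`.
#' @param model the `StructureModel` the duplex came from.
#' @param step_index 0-based step index in 0..n-2.
#' @return width in Angstrom, or NA (with attribute `reason`).
#' @export
compute_minor_groove_width <- function(duplex, model, step_index) {
  n <- duplex$n
  s <- step_index
  if (s < 0 || s > n - 2) stop("step index out of range: ", s)
  combos <- list(c(s + 1, s - 1), c(s + 2, s - 1), c(s + 2, s))
  if (s - 1 < 0 || s + 2 > n - 1)
    return(structure(NA_real_, reason = "step too close to duplex end"))
  d <- Inf
  for (cb in combos) {
    p1 <- .duplex_P(model, duplex, cb[1], 1)
    p2 <- .duplex_P(model, duplex, cb[2], 2)
    if (is.null(p1) || is.null(p2))
      return(structure(NA_real_, reason = sprintf(
        "missing phosphate in width window (levels %d/%d)", cb[1], cb[2])))
    d <- min(d, vnorm(p1 - p2))
  }
  d
}

#' Widths for all steps of a duplex
#'
#' @param duplex a `Duplex`.
#' @param model the parent `StructureModel`.
#' @return numeric vector of length n-1 (NA where undefined), named by
#'   0-based step index.
#' @export
duplex_widths <- function(duplex, model) {
  idx <- 0:(duplex$n - 2)
  w <- vapply(idx, function(s)
    as.numeric(compute_minor_groove_width(duplex, model, s)), numeric(1))
  names(w) <- idx
  w
}

#' Sugar pucker from the pseudorotation phase
#'
#' Computes the Altona-Sundaralingam pseudorotation phase and amplitude from
#' the five endocyclic torsions nu0..nu4 of the deoxyribose ring, and labels
#' the conformer: C3'-endo for phase in [0, 36), C2'-endo for [144, 180),
#' otherwise "other".  Near-planar rings (amplitude < 5 degrees) are labelled
#' "other" with a note.
#'
#' @param model a `StructureModel`.
#' @param key residue key (see [residue_table()]), or pass `atoms` directly.
#' @param atoms optional atom data.frame of a single nucleotide.
#' @return list(phase, amplitude, label, note).
#' @export
compute_sugar_pucker <- function(model = NULL, key = NULL, atoms = NULL) {
  if (is.null(atoms)) atoms <- .residue_atoms(model, key)
  get <- function(nm) {
    sel <- atoms[atoms$atom == nm, , drop = FALSE]
    if (nrow(sel) != 1) stop("missing furanose ring atom: ", nm)
    c(sel$x, sel$y, sel$z)
  }
  C1 <- get("C1'"); C2 <- get("C2'"); C3 <- get("C3'")
  C4 <- get("C4'"); O4 <- get("O4'")
  nu0 <- torsion_angle(C4, O4, C1, C2)
  nu1 <- torsion_angle(O4, C1, C2, C3)
  nu2 <- torsion_angle(C1, C2, C3, C4)
  nu3 <- torsion_angle(C2, C3, C4, O4)
  nu4 <- torsion_angle(C3, C4, O4, C1)
  den <- 2 * nu2 * (sinpi(36 / 180) + sinpi(72 / 180))
  num <- (nu4 + nu1) - (nu3 + nu0)
  # atan2 formulation keeps the quadrant consistent with sign(nu2)
  phase <- rad2deg(atan2(num, den))
  if (phase < 0) phase <- phase + 360
  amplitude <- sqrt(num^2 + den^2) / (2 * (sinpi(36 / 180) + sinpi(72 / 180)))
  note <- NULL
  if (amplitude < 5) {
    label <- "other"; note <- "near-planar"
  } else if (phase >= 0 && phase < 36) label <- "C3'-endo"
  else if (phase >= 144 && phase < 180) label <- "C2'-endo"
  else label <- "other"
  list(phase = phase, amplitude = amplitude, label = label, note = note)
}

#' Import a groove-width table
#'
#' Reads a plain-text, tab-separated table with columns `step_index` and
#' `width` (the layout written by [write_groove_widths()], compatible with
#' column-extracted 3DNA output) and matches it to the steps of a duplex.
#'
#' @param path file path.
#' @param duplex optional `Duplex`; when given, rows that do not match a
#'   step of the duplex are reported in the `unmatched` attribute.
#' @return named numeric vector step_index -> width.
#' @export
import_groove_widths <- function(path, duplex = NULL) {
  tab <- tryCatch(utils::read.table(path, header = TRUE, sep = "\t",
                                    stringsAsFactors = FALSE),
                  error = function(e) stop("parse error in width table ", path,
                                           ": ", conditionMessage(e),
                                           call. = FALSE))
  if (nrow(tab) == 0)
    return(structure(stats::setNames(numeric(0), character(0)),
                     unmatched = integer(0)))
  if (!all(c("step_index", "width") %in% names(tab)))
    stop("width table must have columns step_index and width")
  w <- stats::setNames(as.numeric(tab$width), as.character(tab$step_index))
  unmatched <- integer(0)
  if (!is.null(duplex)) {
    valid <- 0:(duplex$n - 2)
    bad <- !(tab$step_index %in% valid)
    unmatched <- tab$step_index[bad]
    w <- w[!bad]
  }
  structure(w, unmatched = unmatched)
}

#' Write a groove-width table
#' @param widths named numeric vector (names = 0-based step indices).
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_groove_widths <- function(widths, path) {
  df <- data.frame(step_index = as.integer(names(widths)),
                   width = as.numeric(widths))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
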