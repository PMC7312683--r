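# Minor-groove contact detection: per-nucleobase reference atoms, the
# nearest-reference-atom groove assignment with a strict 6.0 Angstrom
# cutoff, association of each contacting residue with a dinucleotide step,
# and assembly of the analysis table (DS1-style), with optional
# protein-family pruning (DS2-style).

#' Groove reference atoms of a base
#'
#' @param base one of dA, dC, dG, dT.
#' @return named character vector c(minor=, major=).
#' @export
reference_atoms <- function(base) {
  if (!base %in% DNA_BASES) stop("non-standard base: ", base)
  REFERENCE_ATOM_MAP[[base]]
}

# Reference atoms restricted to nucleotides belonging to given duplexes.
.duplex_reference_atoms <- function(model, duplexes) {
  refs <- .reference_atom_table(model)
  keys <- unlist(lapply(duplexes, function(d) c(d$pairs$key_i, d$pairs$key_j)))
  refs[refs$key %in% keys, , drop = FALSE]
}

# Locate a nucleotide inside the duplex list: returns (duplex number,
# pair index, strand) or NULL.
.locate_nucleotide <- function(duplexes, key) {
  for (di in seq_along(duplexes)) {
    p <- duplexes[[di]]$pairs
    i <- match(key, p$key_i)
    if (!is.na(i)) return(list(duplex = di, pair = p$pair_index[i], strand = 1))
    j <- match(key, p$key_j)
    if (!is.na(j)) return(list(duplex = di, pair = p$pair_index[j], strand = 2))
  }
  NULL
}

# Minimum heavy-atom distance from one residue to a set of points.
.res_min_dists <- function(model, key, pts) {
  A <- .coords(.heavy(.residue_atoms(model, key)))
  apply(cross_dist(A, as.matrix(pts)), 2, min)
}

#' Find minor-groove-contacting amino acid residues
#'
#' For every amino acid residue, the nearest groove reference atom across
#' all duplex nucleotides is found (distance = minimum over the residue's
#' heavy atoms).  The residue is labelled minor-groove-contacting if and
#' only if that globally nearest reference atom is a minor-groove atom and
#' the distance is strictly below `cutoff`.
#'
#' @param model a `StructureModel` (chains classified or not).
#' @param duplexes list of `Duplex` objects from [build_duplexes()].
#' @param cutoff contact cutoff in Angstrom (default 6.0, strict `<`).
#' @return data.frame of contact records (one per retained residue) with the
#'   contacted nucleotide and the contact distance.
#' @export
find_groove_contacts <- function(model, duplexes, cutoff = 6.0) {
  empty <- data.frame(structure_id = character(0), chain = character(0),
                      residue_type = character(0), residue_seq = integer(0),
                      residue_key = character(0),
                      nuc_chain = character(0), nuc_seq = integer(0),
                      nuc_key = character(0), groove = character(0),
                      distance = numeric(0), duplex = integer(0),
                      pair_index = integer(0), strand = integer(0),
                      stringsAsFactors = FALSE)
  if (!length(duplexes)) return(empty)
  refs <- .duplex_reference_atoms(model, duplexes)
  if (is.null(refs) || nrow(refs) == 0) return(empty)
  pts <- as.matrix(refs[, c("x", "y", "z")])
  res <- residue_table(model)
  res <- res[res$kind == "protein", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(res))) {
    r <- res[i, ]
    d <- .res_min_dists(model, r$key, pts)
    k <- which.min(d)
    if (refs$groove[k] != "minor") next
    if (d[k] >= cutoff) next
    loc <- .locate_nucleotide(duplexes, refs$key[k])
    out[[length(out) + 1]] <- data.frame(
      structure_id = model$structure_id, chain = r$chain,
      residue_type = r$res_name, residue_seq = r$res_seq,
      residue_key = r$key,
      nuc_chain = refs$chain[k], nuc_seq = refs$res_seq[k],
      nuc_key = refs$key[k], groove = "minor", distance = d[k],
      duplex = loc$duplex, pair_index = loc$pair, strand = loc$strand,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Assign the dinucleotide step of a contact
#'
#' The step consists of the nearest contacted nucleotide and the closer of
#' its two sequence-adjacent neighbours on the same strand (distances from
#' the residue's heavy atoms to the neighbours' minor-groove reference
#' atoms).  A terminal nucleotide has a single neighbour; an exact tie goes
#' to the 5' neighbour.
#'
#' @param contact one row of the [find_groove_contacts()] table.
#' @param duplexes the duplex list the contact refers to.
#' @param model the `StructureModel`.
#' @return list(step_index, step_sequence) where step_index is the 0-based
#'   duplex step and step_sequence the strand-1 dinucleotide.
#' @export
assign_dinucleotide_step <- function(contact, duplexes, model) {
  dup <- duplexes[[contact$duplex]]
  p <- contact$pair_index
  strand <- contact$strand
  n <- dup$n
  # pair-index direction of the 5' neighbour on this strand
  five_prime <- if (strand == 1) p - 1 else p + 1
  three_prime <- if (strand == 1) p + 1 else p - 1
  cand <- c(five_prime, three_prime)
  cand <- cand[cand >= 0 & cand <= n - 1]
  if (!length(cand)) stop("duplex too short for step assignment")
  dists <- vapply(cand, function(q) {
    row <- dup$pairs[dup$pairs$pair_index == q, , drop = FALSE]
    key <- if (strand == 1) row$key_i else row$key_j
    ra <- .residue_atoms(model, key)
    base <- if (strand == 1) row$base_i else row$base_j
    ref <- REFERENCE_ATOM_MAP[[base]]["minor"]
    sel <- ra[ra$atom == ref, , drop = FALSE]
    if (nrow(sel) != 1) return(Inf)
    min(.res_min_dists(model, contact$residue_key,
                       matrix(c(sel$x, sel$y, sel$z), 1)))
  }, numeric(1))
  # strict tie -> 5' neighbour, which is first in `cand` when present
  chosen <- cand[which.min(dists)]
  s <- min(p, chosen)
  row1 <- dup$pairs[dup$pairs$pair_index == s, , drop = FALSE]
  row2 <- dup$pairs[dup$pairs$pair_index == s + 1, , drop = FALSE]
  list(step_index = s,
       step_sequence = paste0(substring(row1$base_i, 2),
                              substring(row2$base_i, 2)))
}

#' Assemble the contact dataset (DS1-style)
#'
#' One record per (residue, step): step assignment, local minor groove
#' width, width category; records with undefined width are dropped with a
#' logged reason, blacklisted residues removed.
#'
#' @param contacts table from [find_groove_contacts()].
#' @param duplexes duplex list.
#' @param model the `StructureModel`.
#' @param blacklist optional character vector of residue keys
#'   ("structure_id:chain:res_seq:ins" or residue_key values) to remove,
#'   standing in for manual curation.
#' @param label dataset label (default "DS1").
#' @return a `DatasetTable` data.frame with attributes `label`,
#'   `provenance` and `log`.
#' @export
build_dataset <- function(contacts, duplexes, model, blacklist = NULL,
                          label = "DS1", narrow = 11.0, wide = 17.0) {
  log <- list()
  note <- function(key, why) log[[length(log) + 1]] <<- c(key, why)
  widths <- lapply(duplexes, duplex_widths, model = model)
  rows <- list()
  for (i in seq_len(nrow(contacts))) {
    ct <- contacts[i, ]
    st <- assign_dinucleotide_step(ct, duplexes, model)
    w <- widths[[ct$duplex]][as.character(st$step_index)]
    full_key <- paste(ct$structure_id, ct$residue_key, sep = ":")
    if (!is.null(blacklist) &&
        (full_key %in% blacklist || ct$residue_key %in% blacklist)) {
      note(full_key, "blacklisted")
      next
    }
    if (is.na(w)) {
      note(full_key, paste0("undefined width at step ", st$step_index))
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      structure_id = ct$structure_id, chain = ct$chain,
      residue_type = ct$residue_type, residue_seq = ct$residue_seq,
      residue_key = ct$residue_key, nucleotide = ct$nuc_key,
      duplex = ct$duplex, step_index = st$step_index,
      step_sequence = st$step_sequence, groove = ct$groove,
      distance = ct$distance, width = as.numeric(w),
      category = categorize_width(as.numeric(w), narrow, wide),
      stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(structure_id = character(0), chain = character(0),
               residue_type = character(0), residue_seq = integer(0),
               residue_key = character(0), nucleotide = character(0),
               duplex = integer(0), step_index = integer(0),
               step_sequence = character(0), groove = character(0),
               distance = numeric(0), width = numeric(0),
               category = character(0), stringsAsFactors = FALSE)
  # uniqueness of (residue, step)
  dup_id <- paste(tab$structure_id, tab$residue_key, tab$duplex,
                  tab$step_index)
  tab <- tab[!duplicated(dup_id), , drop = FALSE]
  rownames(tab) <- NULL
  log <- if (length(log))
    data.frame(key = vapply(log, `[`, "", 1),
               reason = vapply(log, `[`, "", 2), stringsAsFactors = FALSE)
  else data.frame(key = character(0), reason = character(0))
  structure(tab, label = label,
            provenance = list(blacklist_size = length(blacklist)),
            log = log, class = c("DatasetTable", "data.frame"))
}

#' Prune records of excluded protein families (DS2-style)
#'
#' Removes records whose residue is annotated with one of the excluded
#' family accessions; unannotated residues are retained.  Identity when the
#' excluded set is empty; idempotent for a fixed family set.
#'
#' @param table a `DatasetTable`.
#' @param family_annotations data.frame with columns `structure_id`,
#'   `chain`, `residue_seq`, `family` (e.g. Pfam accessions).
#' @param excluded_families accessions to drop (defaults: the high-mobility
#'   group and TATA-box binding protein families).
#' @param label new label (default "DS2").
#' @return the pruned `DatasetTable`.
#' @export
ds_prune <- function(table, family_annotations,
                     excluded_families = c("PF00505", "PF00352"),
                     label = "DS2") {
  if (!is.null(family_annotations)) {
    need <- c("structure_id", "chain", "residue_seq", "family")
    if (!all(need %in% names(family_annotations)))
      stop("annotation table must have columns: ",
           paste(need, collapse = ", "))
  }
  if (!length(excluded_families) || is.null(family_annotations) ||
      nrow(family_annotations) == 0) {
    attr(table, "label") <- label
    return(table)
  }
  ann <- family_annotations[family_annotations$family %in% excluded_families, ,
                            drop = FALSE]
  bad <- paste(ann$structure_id, ann$chain, ann$residue_seq)
  id <- paste(table$structure_id, table$chain, table$residue_seq)
  out <- table[!(id %in% bad), , drop = FALSE]
  rownames(out) <- NULL
  prov <- attr(table, "provenance")
  prov$excluded_families <- excluded_families
  structure(out, label = label, provenance = prov, log = attr(table, "log"),
            class = c("DatasetTable", "data.frame"))
}

#' Write / read a DatasetTable as TSV
#' @param table a `DatasetTable`.
#' @param path file path.
#' @return invisibly, the path (write) or the table (read).
#' @export
write_dataset_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset_table
#' @export
read_dataset_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  structure(tab, class = c("DatasetTable", "data.frame"))
}
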