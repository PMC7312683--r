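# Structure parsing, chain classification, DNA validation and dataset-level
# filtering.  The in-memory representation is a light S3 object holding one
# atom table in file order plus experimental metadata; PDB reading is
# delegated to bio3d, writing is a small fixed-width formatter so models
# survive a write/parse round trip to 3 decimals.

#' Construct a StructureModel from an atom table
#'
#' @param atoms data.frame with columns `chain`, `res_name`, `res_seq`,
#'   `ins`, `atom`, `element`, `x`, `y`, `z`, `occupancy`, `altloc`,
#'   `hetatm`.
#' @param structure_id identifier (PDB id or synthetic label).
#' @param metadata list with optional `method` and `resolution` entries.
#' @return an object of class `StructureModel`.
#' @export
new_structure_model <- function(atoms, structure_id, metadata = list()) {
  needed <- c("chain", "res_name", "res_seq", "ins", "atom", "element",
              "x", "y", "z", "occupancy", "altloc", "hetatm")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in atom table")
  rownames(atoms) <- NULL
  structure(list(structure_id = structure_id, atoms = atoms,
                 metadata = metadata),
            class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  res <- residue_table(x)
  cat("StructureModel", x$structure_id, "-", nrow(x$atoms), "atoms,",
      nrow(res), "residues,", length(unique(x$atoms$chain)), "chains\n")
  invisible(x)
}

.residue_key <- function(chain, res_seq, ins) {
  paste(chain, res_seq, ifelse(is.na(ins) | ins == "", ".", ins), sep = ":")
}

#' Residue-level view of a model
#'
#' One row per residue in file order, with the residue kind
#' (protein/dna/other) derived from naming tables.
#' @param model a `StructureModel`.
#' @return data.frame with chain, res_name, res_seq, ins, key, kind.
#' @export
residue_table <- function(model) {
  a <- model$atoms
  key <- .residue_key(a$chain, a$res_seq, a$ins)
  idx <- !duplicated(key)
  out <- data.frame(chain = a$chain[idx], res_name = a$res_name[idx],
                    res_seq = a$res_seq[idx], ins = a$ins[idx],
                    key = key[idx], stringsAsFactors = FALSE)
  out$kind <- ifelse(out$res_name %in% AMINO_ACIDS, "protein",
                     ifelse(out$res_name %in% DNA_BASES, "dna", "other"))
  out
}

.residue_atoms <- function(model, key) {
  a <- model$atoms
  a[.residue_key(a$chain, a$res_seq, a$ins) == key, , drop = FALSE]
}

.coords <- function(atoms) as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])

.heavy <- function(atoms) atoms[atoms$element != "H" & atoms$element != "D", ,
                                drop = FALSE]

.guess_element <- function(name) {
  base <- gsub("[^A-Za-z]", "", name)
  first <- toupper(substring(base, 1, 1))
  ifelse(first %in% c("C", "N", "O", "P", "S", "H"), first,
         toupper(substring(base, 1, 2)))
}

# Normalize nucleotide naming dialects (DA / A-with-deoxyribose -> dA) and
# atom-name aliases (O1P -> OP1, primes).
.normalize_names <- function(atoms) {
  al <- ATOM_NAME_ALIASES[atoms$atom]
  atoms$atom <- ifelse(is.na(al), atoms$atom, unname(al))
  rn <- RESNAME_ALIASES[atoms$res_name]
  atoms$res_name <- ifelse(is.na(rn), atoms$res_name, unname(rn))
  # bare A/C/G/T chains: deoxyribose (C2' present, no O2') -> dN
  bare <- atoms$res_name %in% c("A", "C", "G", "T")
  if (any(bare)) {
    key <- .residue_key(atoms$chain, atoms$res_seq, atoms$ins)
    for (k in unique(key[bare])) {
      sel <- key == k
      nm <- atoms$atom[sel]
      if ("C2'" %in% nm && !("O2'" %in% nm))
        atoms$res_name[sel] <- paste0("d", atoms$res_name[sel][1])
    }
  }
  atoms
}

# Altloc policy: keep the highest-occupancy conformer per atom; ties go to
# the first conformer in file order.
.resolve_altlocs <- function(atoms) {
  if (all(atoms$altloc %in% c("", " "))) return(atoms)
  id <- paste(.residue_key(atoms$chain, atoms$res_seq, atoms$ins),
              atoms$atom, sep = "|")
  keep <- rep(TRUE, nrow(atoms))
  for (g in unique(id[duplicated(id)])) {
    sel <- which(id == g)
    best <- sel[which.max(atoms$occupancy[sel])]
    keep[setdiff(sel, best)] <- FALSE
  }
  atoms[keep, , drop = FALSE]
}

#' Parse a 3D structure file into a StructureModel
#'
#' Reads PDB (mandatory) or mmCIF (when bio3d provides `read.cif`) files.
#' Only the first MODEL of multi-model entries is used; alternate locations
#' keep the highest-occupancy conformer; nucleotide naming dialects are
#' normalized to dA/dC/dG/dT.
#'
#' @param path file path.
#' @param format "pdb" or "mmcif".
#' @param structure_id identifier; default is the file base name.
#' @param metadata optional list(method=, resolution=).
#' @return a `StructureModel`.
#' @export
parse_structure <- function(path, format = c("pdb", "mmcif"),
                            structure_id = NULL, metadata = list()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("parse error: empty structure file: ", path)
  pdb <- tryCatch({
    if (format == "pdb") bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                         verbose = FALSE)
    else {
      if (!"read.cif" %in% getNamespaceExports("bio3d"))
        stop("mmCIF support requires bio3d::read.cif")
      bio3d::read.cif(path, verbose = FALSE)
    }
  }, error = function(e) stop("parse error reading ", path, ": ",
                              conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) stop("parse error: no atoms in ", path)
  elem <- at$elesy
  if (is.null(elem)) elem <- NA_character_
  elem <- ifelse(is.na(elem) | trimws(elem) == "",
                 .guess_element(at$elety), trimws(elem))
  atoms <- data.frame(
    chain = ifelse(is.na(at$chain), "", at$chain),
    res_name = trimws(at$resid),
    res_seq = at$resno,
    ins = ifelse(is.na(at$insert), "", at$insert),
    atom = trimws(at$elety),
    element = toupper(elem),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    altloc = ifelse(is.na(at$alt), "", at$alt),
    hetatm = at$type == "HETATM",
    stringsAsFactors = FALSE)
  atoms <- .resolve_altlocs(atoms)
  atoms <- .normalize_names(atoms)
  if (is.null(structure_id))
    structure_id <- sub("\\.[^.]*$", "", basename(path))
  new_structure_model(atoms, structure_id, metadata)
}

#' Write a StructureModel as a PDB file
#'
#' Fixed-width PDB writer (coordinates to 3 decimals); normalized nucleotide
#' names are written back in the PDB dialect (dA -> DA).
#' @param model a `StructureModel`.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_pdb <- function(model, path) {
  a <- model$atoms
  rev_res <- c(dA = "DA", dC = "DC", dG = "DG", dT = "DT")
  rn <- rev_res[a$res_name]
  rn <- ifelse(is.na(rn), a$res_name, unname(rn))
  rec <- ifelse(a$hetatm, "HETATM", "ATOM  ")
  name4 <- ifelse(nchar(a$atom) >= 4, substr(a$atom, 1, 4),
                  sprintf(" %-3s", a$atom))
  lines <- sprintf("%s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, seq_len(nrow(a)), name4, " ", rn,
                   substr(paste0(a$chain, " "), 1, 1), a$res_seq,
                   substr(paste0(a$ins, " "), 1, 1),
                   a$x, a$y, a$z, a$occupancy, 0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Annotate chain kinds (protein / dna / mixed / other)
#'
#' Chains containing both protein and DNA residues are flagged mixed;
#' otherwise the majority residue kind wins.  Idempotent.
#' @param model a `StructureModel`.
#' @return the model with a `chains` data.frame (chain, kind, n_res) attached.
#' @export
classify_chains <- function(model) {
  res <- residue_table(model)
  kinds <- vapply(split(res$kind, res$chain), function(k) {
    n_prot <- sum(k == "protein"); n_dna <- sum(k == "dna")
    n_other <- sum(k == "other")
    if (n_prot > 0 && n_dna > 0) "mixed"
    else if (n_prot > 0 && n_prot >= n_other) "protein"
    else if (n_dna > 0 && n_dna >= n_other) "dna"
    else "other"
  }, character(1))
  model$chains <- data.frame(chain = names(kinds), kind = unname(kinds),
                             n_res = as.vector(table(res$chain)[names(kinds)]),
                             stringsAsFactors = FALSE)
  model
}

#' Validate a DNA chain
#'
#' A chain passes when every residue is a standard deoxyribonucleotide
#' (dA/dC/dG/dT), carries no HETATM-flagged atoms, and has a complete
#' heavy-atom inventory (the 5'-terminal phosphate group is optional).
#'
#' @param model a `StructureModel`.
#' @param chain_id chain identifier.
#' @return list with `pass` (logical) and `reasons` (data.frame key/reason).
#' @export
validate_dna_chain <- function(model, chain_id) {
  res <- residue_table(model)
  res <- res[res$chain == chain_id, , drop = FALSE]
  if (nrow(res) == 0) stop("no residues on chain ", chain_id)
  reasons <- list()
  add <- function(key, why) reasons[[length(reasons) + 1]] <<- c(key, why)
  for (i in seq_len(nrow(res))) {
    r <- res[i, ]
    ra <- .residue_atoms(model, r$key)
    if (!(r$res_name %in% DNA_BASES)) {
      add(r$key, paste0("non-standard residue: ", r$res_name))
      next
    }
    if (any(ra$hetatm)) add(r$key, "HETATM-flagged nucleotide atoms")
    inventory <- c(SUGAR_PHOSPHATE_ATOMS, BASE_ATOMS[[r$res_name]])
    if (i == 1) inventory <- setdiff(inventory, FIVE_PRIME_OPTIONAL_ATOMS)
    miss <- setdiff(inventory, .heavy(ra)$atom)
    if (length(miss))
      add(r$key, paste0("missing heavy atom: ", paste(miss, collapse = ",")))
  }
  reasons <- if (length(reasons))
    data.frame(key = vapply(reasons, `[`, "", 1),
               reason = vapply(reasons, `[`, "", 2),
               stringsAsFactors = FALSE)
  else data.frame(key = character(0), reason = character(0))
  list(pass = nrow(reasons) == 0, reasons = reasons)
}

#' Dataset filter criteria
#'
#' @param max_resolution maximum resolution in Angstrom (inclusive).
#' @param allowed_methods experimental method labels to retain.
#' @param chain_allowlist optional data.frame(structure_id, chain) restricting
#'   the protein chains considered (a stand-in for non-redundancy pipelines).
#' @return a `DatasetFilterCriteria` list.
#' @export
dataset_filter_criteria <- function(max_resolution = 3.5,
                                    allowed_methods = "X-RAY DIFFRACTION",
                                    chain_allowlist = NULL) {
  stopifnot(max_resolution > 0)
  structure(list(max_resolution = max_resolution,
                 allowed_methods = allowed_methods,
                 chain_allowlist = chain_allowlist),
            class = "DatasetFilterCriteria")
}

#' Apply dataset-level filters to structure metadata
#'
#' Retains structures solved with an allowed method at the required
#' resolution (inclusive threshold); structures missing resolution metadata
#' are excluded with a logged reason.  When an allowlist is given, protein
#' chains not on it are removed and structures with none left are dropped.
#'
#' @param models list of `StructureModel`s.
#' @param criteria a `DatasetFilterCriteria`.
#' @return filtered list, order preserved, with a `filter_log` attribute.
#' @export
apply_dataset_filters <- function(models, criteria) {
  keep <- list(); log <- list()
  note <- function(id, why) log[[length(log) + 1]] <<- c(id, why)
  for (m in models) {
    md <- m$metadata
    if (!is.null(criteria$allowed_methods)) {
      if (is.null(md$method) || !(md$method %in% criteria$allowed_methods)) {
        note(m$structure_id, paste0("method not allowed: ",
                                    if (is.null(md$method)) "<missing>" else md$method))
        next
      }
    }
    if (is.null(md$resolution) || is.na(md$resolution)) {
      note(m$structure_id, "missing resolution metadata")
      next
    }
    if (md$resolution > criteria$max_resolution) {
      note(m$structure_id, sprintf("resolution %.2f worse than %.2f",
                                   md$resolution, criteria$max_resolution))
      next
    }
    if (!is.null(criteria$chain_allowlist)) {
      al <- criteria$chain_allowlist
      allowed <- al$chain[al$structure_id == m$structure_id]
      mm <- classify_chains(m)
      prot <- mm$chains$chain[mm$chains$kind %in% c("protein", "mixed")]
      drop_chains <- setdiff(prot, allowed)
      if (length(drop_chains)) {
        mm$atoms <- mm$atoms[!(mm$atoms$chain %in% drop_chains), , drop = FALSE]
        mm <- classify_chains(mm)
      }
      if (!any(mm$chains$kind %in% c("protein", "mixed"))) {
        note(m$structure_id, "no protein chains on the allowlist")
        next
      }
      m <- mm
    }
    keep[[length(keep) + 1]] <- m
  }
  log <- if (length(log))
    data.frame(structure_id = vapply(log, `[`, "", 1),
               reason = vapply(log, `[`, "", 2), stringsAsFactors = FALSE)
  else data.frame(structure_id = character(0), reason = character(0))
  attr(keep, "filter_log") <- log
  keep
}
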