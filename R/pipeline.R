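# End-to-end orchestration: synthetic fixture bundles, dataset construction
# (parse -> filter -> validate -> duplexes -> widths -> contacts -> table)
# and the report stage.  All tunable constants live in the configuration,
# never in the stage logic.

#' Default pipeline configuration
#'
#' @param outdir output directory.
#' @param seed integer seed propagated to every stochastic stage.
#' @return a `PipelineConfig` list.
#' @export
default_config <- function(outdir = tempfile("groovescan_"), seed = 1) {
  structure(list(
    input = character(0),          # structure file paths
    models = NULL,                 # or in-memory StructureModels
    metadata = NULL,               # data.frame(structure_id, method, resolution)
    max_resolution = 3.5,
    allowed_methods = "X-RAY DIFFRACTION",
    chain_allowlist = NULL,
    cutoff = 6.0,                  # contact cutoff, Angstrom (strict <)
    narrow = 11.0, wide = 17.0,    # width category bounds, Angstrom
    max_gap = 2,                   # interface gap limit, steps
    excluded_families = c("PF00505", "PF00352"),
    blacklist = NULL,              # residue keys or a file of keys
    alpha = 0.05,
    seed = seed,
    outdir = outdir), class = "PipelineConfig")
}

#' Read a pipeline configuration file (YAML key-value)
#'
#' Unknown keys are rejected; missing keys keep their defaults.
#' @param path YAML file.
#' @return a `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- default_config()
  user <- yaml::read_yaml(path)
  bad <- setdiff(names(user), names(cfg))
  if (length(bad)) stop("unknown configuration keys: ",
                        paste(bad, collapse = ", "))
  for (k in names(user)) cfg[[k]] <- user[[k]]
  stopifnot(cfg$cutoff > 0, cfg$narrow > 0, cfg$wide > cfg$narrow)
  cfg
}

#' Demo synthetic-study specification
#'
#' Three small complexes: a B-form duplex with probes straddling the
#' contact cutoff, an A-form duplex (wide grooves) and a B-form duplex with
#' inward-perturbed (narrowed) central steps.
#' @return list of complex specifications for [run_synth()].
#' @export
demo_synth_spec <- function() {
  list(
    list(id = "demo1", form = "B", sequence = "ATGCATGCAT",
         probes = data.frame(
           aa = c("ARG", "LEU", "SER", "LYS"),
           nuc_chain = "A", nuc_seq = c(4, 5, 6, 5),
           groove = c("minor", "minor", "minor", "major"),
           distance = c(4.0, 5.0, 6.5, 4.0), stringsAsFactors = FALSE)),
    list(id = "demo2", form = "A", sequence = "GCGCGCATGCGC",
         probes = data.frame(
           aa = c("PHE", "ALA", "GLY", "TYR", "VAL"),
           nuc_chain = "A", nuc_seq = c(5, 6, 7, 8, 9),
           groove = "minor", distance = c(4.5, 5.0, 5.5, 4.8, 5.4),
           stringsAsFactors = FALSE)),
    list(id = "demo3", form = "B", sequence = "AATTAATTAA",
         perturb = list(steps = 4, displacement = -1.0),
         probes = data.frame(
           aa = c("ASN", "THR"),
           nuc_chain = "A", nuc_seq = c(5, 6),
           groove = "minor", distance = c(4.5, 5.2),
           stringsAsFactors = FALSE)))
}

#' Generate a reproducible synthetic fixture bundle
#'
#' Builds every complex of the specification (duplex, optional groove
#' perturbation, planted probes), writes PDB files, ledgers (pairs and
#' probes, TSV) and the generating configuration, all deterministically.
#'
#' @param spec list of complex specifications (see [demo_synth_spec()]).
#' @param outdir output directory (created if needed).
#' @param seed integer seed (perturbation jitter).
#' @return invisibly, a list of bundles (model + ledger + probes).
#' @export
run_synth <- function(spec = demo_synth_spec(), outdir, seed = 1) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  bundles <- list()
  for (cx in spec) {
    for (f in c("id", "form", "sequence"))
      if (is.null(cx[[f]])) stop("synthetic spec missing field: ", f)
    g <- generate_fiber_duplex(cx$form, cx$sequence, structure_id = cx$id)
    if (!is.null(cx$perturb))
      g <- perturb_groove(g, cx$perturb$steps, cx$perturb$displacement,
                          seed = seed,
                          jitter_sd = if (is.null(cx$perturb$jitter_sd)) 0
                                      else cx$perturb$jitter_sd)
    probes <- NULL
    if (!is.null(cx$probes) && nrow(cx$probes)) {
      pl <- plant_probe_residues(g$model, cx$probes)
      g$model <- pl$model
      probes <- pl$probes
    }
    write_pdb(g$model, file.path(outdir, paste0(cx$id, ".pdb")))
    utils::write.table(g$ledger$pairs,
                       file.path(outdir, paste0(cx$id, "_pairs.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(probes))
      utils::write.table(probes,
                         file.path(outdir, paste0(cx$id, "_probes.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    bundles[[cx$id]] <- list(model = g$model, ledger = g$ledger,
                             probes = probes)
  }
  yaml::write_yaml(list(seed = seed, n_complexes = length(spec),
                        ids = vapply(spec, `[[`, "", "id")),
                   file.path(outdir, "synth_config.yaml"))
  invisible(bundles)
}

#' Build the contact dataset from structures
#'
#' Stage order: metadata filters -> chain classification -> DNA validation
#' -> base pairs -> duplexes -> groove widths -> contacts -> step
#' assignment -> blacklist -> table.  Every dropped record carries a logged
#' reason in the manifest.
#'
#' @param config a `PipelineConfig`; structures come from `config$models`
#'   (in-memory) or `config$input` (paths).
#' @return list(table = `DatasetTable`, manifest = run manifest).
#' @export
run_build <- function(config) {
  models <- config$models
  if (is.null(models)) {
    if (!length(config$input)) stop("no input structures configured")
    models <- lapply(config$input, function(p) {
      m <- parse_structure(p)
      if (!is.null(config$metadata)) {
        md <- config$metadata[config$metadata$structure_id == m$structure_id, ,
                              drop = FALSE]
        if (nrow(md) == 1)
          m$metadata <- list(method = md$method, resolution = md$resolution)
      }
      m
    })
  }
  criteria <- dataset_filter_criteria(config$max_resolution,
                                      config$allowed_methods,
                                      config$chain_allowlist)
  filtered <- apply_dataset_filters(models, criteria)
  filter_log <- attr(filtered, "filter_log")
  blacklist <- config$blacklist
  if (length(blacklist) == 1 && file.exists(blacklist))
    blacklist <- readLines(blacklist)

  tables <- list(); struct_rows <- list(); drop_rows <- list()
  for (m in filtered) {
    m <- classify_chains(m)
    dna_chains <- m$chains$chain[m$chains$kind == "dna"]
    valid <- character(0)
    for (ch in dna_chains) {
      v <- validate_dna_chain(m, ch)
      if (v$pass) valid <- c(valid, ch)
      else drop_rows[[length(drop_rows) + 1]] <- data.frame(
        structure_id = m$structure_id, stage = "validation",
        key = paste(m$structure_id, ch, sep = ":"),
        reason = paste(v$reasons$reason, collapse = "; "),
        stringsAsFactors = FALSE)
    }
    mv <- m
    mv$atoms <- m$atoms[m$atoms$chain %in%
                          c(valid, m$chains$chain[m$chains$kind != "dna"]), ,
                        drop = FALSE]
    pairs <- detect_base_pairs(mv)
    duplexes <- build_duplexes(pairs, mv)
    contacts <- find_groove_contacts(mv, duplexes, cutoff = config$cutoff)
    tab <- build_dataset(contacts, duplexes, mv, blacklist = blacklist,
                         narrow = config$narrow, wide = config$wide)
    lg <- attr(tab, "log")
    if (nrow(lg))
      drop_rows[[length(drop_rows) + 1]] <- data.frame(
        structure_id = m$structure_id, stage = "dataset",
        key = lg$key, reason = lg$reason, stringsAsFactors = FALSE)
    struct_rows[[length(struct_rows) + 1]] <- data.frame(
      structure_id = m$structure_id,
      n_dna_chains = length(dna_chains), n_valid_chains = length(valid),
      n_pairs = nrow(pairs), n_duplexes = length(duplexes),
      n_contacts = nrow(contacts), n_records = nrow(tab),
      stringsAsFactors = FALSE)
    tables[[length(tables) + 1]] <- tab
  }
  if (!length(tables)) {
    manifest <- list(filter_log = filter_log, structures = NULL,
                     drops = do.call(rbind, drop_rows), config = config)
    stop(structure(class = c("groovescan_no_structures", "error", "condition"),
                   list(message = "no structures survived the filters",
                        call = sys.call(), manifest = manifest)))
  }
  table <- do.call(rbind, tables)
  attrs <- attributes(tables[[1]])
  attr(table, "label") <- attrs$label
  class(table) <- c("DatasetTable", "data.frame")
  manifest <- list(
    version = tryCatch(as.character(utils::packageVersion("groovescan")),
                       error = function(e) "dev"),
    config = config[setdiff(names(config), "models")],
    filter_log = filter_log,
    structures = do.call(rbind, struct_rows),
    drops = if (length(drop_rows)) do.call(rbind, drop_rows) else NULL,
    counts = c(models_in = length(models), models_kept = length(filtered),
               contacts = sum(vapply(struct_rows, `[[`, 0, "n_contacts")),
               records = nrow(table)))
  list(table = table, manifest = manifest)
}

#' Analyze a contact dataset and emit report tables
#'
#' Emits composition frequencies, relative entropies between the category
#' compositions, the per-amino-acid width tests, percentile thresholds,
#' dinucleotide sequence preferences and, when the source models are
#' supplied, hexamer/GC tables, secondary-structure cross-tabs,
#' Ramachandran data and hydrogen-bond / van der Waals interaction tables.
#'
#' @param table a `DatasetTable`.
#' @param config a `PipelineConfig`.
#' @param models optional named list of `StructureModel`s (names =
#'   structure_id) enabling the structure-dependent reports.
#' @param outdir output directory for TSV files (default from config; NULL
#'   suppresses writing).
#' @return invisibly, a list of all computed report objects plus notes on
#'   skipped reports.
#' @export
run_analyze <- function(table, config = default_config(), models = NULL,
                        outdir = config$outdir) {
  if (nrow(table) == 0) stop("empty dataset table")
  notes <- character(0)
  comp <- category_frequencies(table)
  ent <- data.frame(
    comparison = c("narrow_to_standard", "wide_to_standard",
                   "wide_to_narrow"),
    stringsAsFactors = FALSE)
  dpair <- list(c("narrow", "standard"), c("wide", "standard"),
                c("wide", "narrow"))
  ent$entropy_bits <- vapply(dpair, function(pr) {
    if (attr(comp[[pr[1]]], "empty") || attr(comp[[pr[2]]], "empty"))
      return(NA_real_)
    relative_entropy(comp[[pr[1]]], comp[[pr[2]]])
  }, numeric(1))
  ent$computable <- !is.na(ent$entropy_bits)
  if (any(!ent$computable))
    notes <- c(notes, "entropy rows with empty categories flagged not-computable")
  tests <- run_width_tests(table, alpha = config$alpha)
  thresholds <- tryCatch(percentile_thresholds(table),
                         error = function(e) c(NA_real_, NA_real_))
  seqpref <- sequence_preferences(table)

  hex_windows <- NULL; by_gc <- NULL; ss_tab <- NULL; rama <- NULL
  hb <- NULL; vdw <- NULL
  if (!is.null(models)) {
    hex_rows <- list()
    for (sid in unique(table$structure_id)) {
      m <- models[[sid]]
      if (is.null(m)) { notes <- c(notes, paste("no model for", sid)); next }
      m <- classify_chains(m)
      duplexes <- build_duplexes(detect_base_pairs(m), m)
      sub <- table[table$structure_id == sid, , drop = FALSE]
      for (d in unique(sub$duplex)) {
        if (d > length(duplexes)) next
        dup <- duplexes[[d]]
        w <- duplex_widths(dup, m)
        dsub <- sub[sub$duplex == d, , drop = FALSE]
        step_res <- split(paste0(dsub$residue_type, ":", dsub$residue_key),
                          as.character(dsub$step_index))
        segs <- build_interfaces(unique(dsub$step_index),
                                 max_gap = config$max_gap)
        for (sg in segs) {
          hw <- sliding_hexamers(sg, dup, w, step_res)
          if (nrow(hw)) {
            hw$structure_id <- sid; hw$duplex <- d
            hex_rows[[length(hex_rows) + 1]] <- hw
          }
        }
      }
    }
    if (length(hex_rows)) {
      hex_windows <- do.call(rbind, hex_rows)
      by_gc <- width_by_gc(hex_windows)
    } else notes <- c(notes, "no hexamer windows (interfaces shorter than 6 nt)")

    ss_rows <- list(); hb_rows <- list(); vdw_rows <- list()
    for (sid in unique(table$structure_id)) {
      m <- models[[sid]]
      if (is.null(m)) next
      m <- classify_chains(m)
      keys <- table$residue_key[table$structure_id == sid]
      prot_chains <- unique(table$chain[table$structure_id == sid])
      for (ch in prot_chains) {
        ss <- tryCatch(assign_secondary_structure(m, ch),
                       error = function(e) NULL)
        if (!is.null(ss)) {
          ss$structure_id <- sid
          ss_rows[[length(ss_rows) + 1]] <- ss[ss$key %in% keys, ,
                                               drop = FALSE]
        }
      }
      hbx <- detect_hbonds(m, protein_keys = keys)
      if (nrow(hbx)) { hbx$structure_id <- sid
        hb_rows[[length(hb_rows) + 1]] <- hbx }
      vd <- classify_vdw_contacts(m, hbonds = hbx, protein_keys = keys)
      if (nrow(vd)) { vd$structure_id <- sid
        vdw_rows[[length(vdw_rows) + 1]] <- vd }
    }
    if (length(ss_rows)) {
      rama <- do.call(rbind, ss_rows)
      cat_of <- stats::setNames(table$category,
                                paste(table$structure_id, table$residue_key))
      rama$category <- cat_of[paste(rama$structure_id, rama$key)]
      ss_tab <- as.data.frame(table(residue = rama$res_name, ss = rama$ss,
                                    category = rama$category),
                              stringsAsFactors = FALSE)
      names(ss_tab)[4] <- "count"
      ss_tab <- ss_tab[ss_tab$count > 0, , drop = FALSE]
    }
    hb <- if (length(hb_rows)) do.call(rbind, hb_rows) else NULL
    vdw <- if (length(vdw_rows)) do.call(rbind, vdw_rows) else NULL
  } else {
    notes <- c(notes,
               "no models supplied: secondary-structure, hexamer and interaction reports skipped")
  }

  out <- list(composition = comp, entropies = ent, width_tests = tests,
              thresholds = thresholds, sequence_preferences = seqpref,
              hexamers = hex_windows, width_by_gc = by_gc,
              secondary_structure = ss_tab, ramachandran = rama,
              hbonds = hb, vdw = vdw, notes = notes)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    lab <- attr(table, "label"); if (is.null(lab)) lab <- "DS"
    wtsv <- function(df, name) {
      if (is.null(df)) return(invisible(NULL))
      utils::write.table(df, file.path(outdir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    compdf <- do.call(rbind, lapply(names(comp), function(cat) {
      df <- comp[[cat]]; df$category <- cat; df }))
    wtsv(compdf, paste0("composition_", lab, ".tsv"))
    wtsv(ent, paste0("entropies_", lab, ".tsv"))
    wtsv(tests, paste0("width_tests_", lab, ".tsv"))
    wtsv(data.frame(percentile = c(15, 85), width = thresholds),
         paste0("thresholds_", lab, ".tsv"))
    wtsv(seqpref, paste0("sequence_preferences_", lab, ".tsv"))
    wtsv(hex_windows, paste0("hexamers_", lab, ".tsv"))
    if (!is.null(by_gc)) {
      wtsv(by_gc$pooled, paste0("width_by_gc_pooled_", lab, ".tsv"))
      wtsv(by_gc$per_aa, paste0("width_by_gc_per_aa_", lab, ".tsv"))
    }
    wtsv(ss_tab, paste0("secondary_structure_", lab, ".tsv"))
    wtsv(rama, paste0("ramachandran_", lab, ".tsv"))
    wtsv(hb, paste0("hbonds_", lab, ".tsv"))
    wtsv(vdw, paste0("vdw_", lab, ".tsv"))
    writeLines(notes, file.path(outdir, paste0("notes_", lab, ".txt")))
  }
  invisible(out)
}
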