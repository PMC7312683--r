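# Width categorization, interface segmentation with bounded gaps, hexamer
# sliding windows with central-step widths and GC content, and
# complement-pooled dinucleotide sequence preferences.

#' Categorize a minor groove width
#'
#' Narrow for width <= 11.0 Angstrom, wide for width >= 17.0, standard in
#' between (thresholds chosen near the 15th/85th percentile of typical
#' protein-bound groove width distributions).
#'
#' @param width width in Angstrom (> 0); vectorized.
#' @param narrow,wide category boundaries.
#' @return character vector of labels.
#' @export
categorize_width <- function(width, narrow = 11.0, wide = 17.0) {
  if (any(is.na(width))) stop("undefined width cannot be categorized")
  if (any(width <= 0)) stop("width must be positive")
  ifelse(width <= narrow, "narrow", ifelse(width >= wide, "wide", "standard"))
}

#' Segment contacted steps into interfaces
#'
#' A protein-DNA interface is a maximal run of dinucleotide steps contacted
#' by amino acid residues in which breaks of at most `max_gap` consecutive
#' non-contacted steps are bridged.  Returned segments cover the full index
#' range including bridged gaps, ordered 5'->3'.
#'
#' @param contacted_steps integer vector of contacted (0-based) step indices.
#' @param max_gap largest bridgeable run of non-contacted steps (default 2).
#' @return list of `InterfaceSegment` lists (start, end, steps).
#' @export
build_interfaces <- function(contacted_steps, max_gap = 2) {
  s <- sort(unique(as.integer(contacted_steps)))
  if (!length(s)) return(list())
  segs <- list()
  start <- s[1]; prev <- s[1]
  for (x in s[-1]) {
    if (x - prev - 1 > max_gap) {
      segs[[length(segs) + 1]] <- list(start = start, end = prev,
                                       steps = start:prev)
      start <- x
    }
    prev <- x
  }
  segs[[length(segs) + 1]] <- list(start = start, end = prev,
                                   steps = start:prev)
  lapply(segs, function(g) structure(g, class = "InterfaceSegment"))
}

#' Slide 6-nucleotide windows along an interface
#'
#' A segment spanning steps start..end covers end - start + 2 nucleotides;
#' each window covers 6 consecutive nucleotides (5 steps), advancing by one
#' nucleotide.  The window width is the width of its central step; windows
#' whose central step has no defined width are skipped (logged in the
#' `skipped` attribute).  The contacting-residue set of a window is the
#' union over its five internal steps.
#'
#' @param segment an `InterfaceSegment`.
#' @param duplex the `Duplex` the steps belong to.
#' @param widths named numeric vector from [duplex_widths()].
#' @param step_residues optional named list: step index (character) ->
#'   character vector of residue identifiers contacting that step.
#' @return data.frame of windows (start nucleotide = pair index, sequence,
#'   gc_content, width, residues as comma-separated string).
#' @export
sliding_hexamers <- function(segment, duplex, widths, step_residues = NULL) {
  L <- segment$end - segment$start + 2   # nucleotides spanned
  empty <- data.frame(nuc_start = integer(0), sequence = character(0),
                      gc_content = numeric(0), width = numeric(0),
                      residues = character(0), stringsAsFactors = FALSE)
  if (L < 6) return(structure(empty, skipped = integer(0)))
  seqchars <- strsplit(duplex$sequence, "")[[1]]
  skipped <- integer(0)
  rows <- list()
  for (p in segment$start:(segment$end + 1 - 5)) {
    central <- p + 2
    w <- widths[as.character(central)]
    if (is.null(w) || length(w) == 0 || is.na(w)) {
      skipped <- c(skipped, p)
      next
    }
    nts <- seqchars[(p + 1):(p + 6)]
    gc <- sum(nts %in% c("G", "C")) / 6
    res <- character(0)
    if (!is.null(step_residues)) {
      for (st in p:(p + 4)) {
        rr <- step_residues[[as.character(st)]]
        if (!is.null(rr)) res <- union(res, rr)
      }
    }
    rows[[length(rows) + 1]] <- data.frame(
      nuc_start = p, sequence = paste(nts, collapse = ""),
      gc_content = gc, width = as.numeric(w),
      residues = paste(sort(res), collapse = ","), stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  structure(out, skipped = skipped)
}

#' GC content of a hexamer window
#'
#' Fraction of G/C nucleotides among the six strand-1 positions (each G or C
#' strand-1 nucleotide belongs to a GC pair).
#' @param window one row of the [sliding_hexamers()] table, or a sequence
#'   string of length 6.
#' @return fraction in {0, 1/6, ..., 1}.
#' @export
gc_content <- function(window) {
  s <- if (is.character(window)) window else window$sequence
  ch <- strsplit(s, "")[[1]]
  if (length(ch) != 6) stop("hexamer sequence must have 6 nucleotides")
  sum(ch %in% c("G", "C")) / 6
}

#' Width distributions by GC level
#'
#' Pools hexamer widths by the seven possible GC-content levels, both over
#' all windows and per contacting amino acid (a window enters an amino
#' acid's table iff that type is among its contacting residues).
#'
#' @param windows data.frame of hexamer windows (with `residues` column
#'   holding comma-separated "TYPE:key" or plain type identifiers).
#' @param per_amino_acid also compute per-type tables (default TRUE).
#' @return list(pooled = data.frame(gc_level, width), per_aa = data.frame(
#'   amino_acid, gc_level, width)).
#' @export
width_by_gc <- function(windows, per_amino_acid = TRUE) {
  pooled <- data.frame(gc_level = round(windows$gc_content * 6),
                       width = windows$width)
  per_aa <- NULL
  if (per_amino_acid) {
    rows <- list()
    for (i in seq_len(nrow(windows))) {
      res <- strsplit(windows$residues[i], ",")[[1]]
      res <- res[nzchar(res)]
      types <- unique(sub(":.*$", "", res))
      for (t in types)
        rows[[length(rows) + 1]] <- data.frame(
          amino_acid = t, gc_level = round(windows$gc_content[i] * 6),
          width = windows$width[i], stringsAsFactors = FALSE)
    }
    per_aa <- if (length(rows)) do.call(rbind, rows) else
      data.frame(amino_acid = character(0), gc_level = integer(0),
                 width = numeric(0), stringsAsFactors = FALSE)
  }
  list(pooled = pooled, per_aa = per_aa)
}

# Canonical complement-pooled class of a dinucleotide step sequence,
# formatted like "ApA/TpT" (self-complementary steps collapse to "ApT").
step_class <- function(step_seq) {
  vapply(step_seq, function(s) {
    ch <- strsplit(s, "")[[1]]
    rc <- paste0(DNA_COMPLEMENT[ch[2]], DNA_COMPLEMENT[ch[1]])
    fmt <- function(x) paste0(substring(x, 1, 1), "p", substring(x, 2, 2))
    if (s == rc) fmt(s)
    else {
      a <- sort(c(s, rc))
      paste0(fmt(a[1]), "/", fmt(a[2]))
    }
  }, character(1), USE.NAMES = FALSE)
}

#' Per-amino-acid dinucleotide sequence preferences
#'
#' Frequencies of contacted dinucleotide step sequences per amino acid over
#' the 10 complement-pooled step classes; rows sum to 1.
#'
#' @param table a `DatasetTable`.
#' @return data.frame amino_acid x step class frequency matrix (long
#'   format: amino_acid, class, count, frequency).
#' @export
sequence_preferences <- function(table) {
  if (nrow(table) == 0)
    return(data.frame(amino_acid = character(0), class = character(0),
                      count = integer(0), frequency = numeric(0),
                      stringsAsFactors = FALSE))
  cls <- step_class(table$step_sequence)
  tab <- as.data.frame(table(amino_acid = table$residue_type, class = cls),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "count"
  totals <- stats::ave(tab$count, tab$amino_acid, FUN = sum)
  tab$frequency <- ifelse(totals > 0, tab$count / totals, 0)
  tab <- tab[tab$count > 0 | totals > 0, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
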