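# Composition distributions per width category, relative entropy between
# them, the one-sided Mann-Whitney width-testing scheme with the
# hydrophobic / non-hydrophobic design and arginine exclusion, and
# percentile thresholds for the category boundaries.

#' Amino-acid composition per width category
#'
#' @param table a `DatasetTable` with `residue_type` and `category` columns.
#' @return list of three `AminoAcidDistribution` data.frames (narrow,
#'   standard, wide), each with amino_acid, count, frequency and an `empty`
#'   attribute flagging zero-count categories.
#' @export
category_frequencies <- function(table) {
  out <- list()
  for (cat in c("narrow", "standard", "wide")) {
    sub <- table[table$category == cat, , drop = FALSE]
    counts <- table(factor(sub$residue_type, levels = AMINO_ACIDS))
    total <- sum(counts)
    df <- data.frame(amino_acid = AMINO_ACIDS,
                     count = as.integer(counts),
                     frequency = if (total > 0) as.numeric(counts) / total
                                 else rep(0, length(AMINO_ACIDS)),
                     stringsAsFactors = FALSE)
    attr(df, "context") <- cat
    attr(df, "empty") <- total == 0
    out[[cat]] <- df
  }
  out
}

#' Relative entropy (Kullback-Leibler divergence) in bits
#'
#' D(p || q) = sum p_i log2(p_i / q_i), with 0 log(0/x) = 0.  When (and only
#' when) the reference distribution q has zero mass somewhere p does not,
#' q is smoothed by adding `pseudocount` to every category count before
#' normalization, keeping the divergence finite; otherwise both
#' distributions are used exactly, so D = 0 holds iff p = q.
#'
#' @param p,q numeric count or frequency vectors on the same support, or
#'   `AminoAcidDistribution` data.frames from [category_frequencies()].
#' @param pseudocount smoothing constant added to q (default 0.5).
#' @return divergence in bits (>= 0).
#' @export
relative_entropy <- function(p, q, pseudocount = 0.5) {
  if (is.data.frame(p)) p <- p$count
  if (is.data.frame(q)) q <- q$count
  if (length(p) != length(q)) stop("p and q must share a support")
  if (any(p < 0) || any(q < 0)) stop("negative weights")
  if (sum(p) <= 0) stop("p has no mass")
  p <- p / sum(p)
  if (any(q == 0 & p > 0)) q <- q + pseudocount
  if (sum(q) <= 0) stop("q has no mass")
  q <- q / sum(q)
  if (any(q == 0 & p > 0)) stop("q has zero mass where p is positive")
  sel <- p > 0
  sum(p[sel] * log2(p[sel] / q[sel]))
}

#' One-sided Mann-Whitney U test (alternative: median of x greater)
#'
#' U is the rank-sum statistic for x with midranks for ties.  The p-value is
#' computed by exact full enumeration of all C(n1+n2, n1) labelings whenever
#' that count is at most `exact_limit`; otherwise a tie-corrected normal
#' approximation with continuity correction is used.  If all pooled values
#' are identical the test is degenerate and p = 1 is reported with a flag.
#'
#' @param x,y numeric samples (widths).
#' @param exact_limit maximum number of labelings for the exact path.
#' @return list(U, p, n1, n2, method, degenerate).
#' @export
mann_whitney_one_sided <- function(x, y, exact_limit = 50000) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both samples must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (length(unique(pooled)) == 1)
    return(list(U = U, p = 1, n1 = n1, n2 = n2, method = "degenerate",
                degenerate = TRUE))
  if (choose(n1 + n2, n1) <= exact_limit) {
    combs <- utils::combn(n1 + n2, n1)
    ge <- 0
    for (k in seq_len(ncol(combs))) {
      rr <- sum(r[combs[, k]]) - n1 * (n1 + 1) / 2
      if (rr >= U - 1e-9) ge <- ge + 1
    }
    p <- ge / ncol(combs)
    return(list(U = U, p = p, n1 = n1, n2 = n2,
                method = "exact-permutation", degenerate = FALSE))
  }
  N <- n1 + n2
  mu <- n1 * n2 / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  z <- (U - mu - 0.5) / sqrt(sigma2)
  p <- stats::pnorm(z, lower.tail = FALSE)
  list(U = U, p = p, n1 = n1, n2 = n2, method = "normal-approximation",
       degenerate = FALSE)
}

#' Default hydrophobicity grouping
#'
#' @return list(hydrophobic, non_hydrophobic, excluded).
#' @export
group_definition <- function() {
  list(hydrophobic = HYDROPHOBIC_AA,
       non_hydrophobic = NON_HYDROPHOBIC_AA,
       excluded = EXCLUDED_AA)
}

#' Run the per-amino-acid width tests
#'
#' Widths associated with arginine-contacted steps are excluded from all
#' comparison populations.  Each hydrophobic amino acid's width distribution
#' is tested against the pooled widths of the whole non-hydrophobic group;
#' each non-hydrophobic amino acid is tested against the pooled widths of
#' all other non-hydrophobic amino acids.  The alternative hypothesis is
#' always that the amino acid's median width is greater.
#'
#' @param table a `DatasetTable` (needs residue_type and width).
#' @param groups grouping from [group_definition()].
#' @param alpha significance level for the `significant` flag.
#' @return data.frame with one row per testable amino acid: amino_acid,
#'   group, n1, n2, U, p, method, significant; skipped amino acids are
#'   reported in the `skipped` attribute.
#' @export
run_width_tests <- function(table, groups = group_definition(),
                            alpha = 0.05) {
  tab <- table[!(table$residue_type %in% groups$excluded), , drop = FALSE]
  widths_of <- function(types) tab$width[tab$residue_type %in% types]
  rows <- list(); skipped <- character(0)
  for (aa in c(groups$hydrophobic, groups$non_hydrophobic)) {
    x <- widths_of(aa)
    if (length(x) == 0) {
      skipped <- c(skipped, aa)
      next
    }
    hydro <- aa %in% groups$hydrophobic
    y <- if (hydro) widths_of(groups$non_hydrophobic)
         else widths_of(setdiff(groups$non_hydrophobic, aa))
    if (length(y) == 0) {
      skipped <- c(skipped, aa)
      next
    }
    t <- mann_whitney_one_sided(x, y)
    rows[[length(rows) + 1]] <- data.frame(
      amino_acid = aa, group = if (hydro) "hydrophobic" else "non-hydrophobic",
      n1 = t$n1, n2 = t$n2, U = t$U, p = t$p, method = t$method,
      significant = t$p < alpha, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(amino_acid = character(0), group = character(0),
               n1 = integer(0), n2 = integer(0), U = numeric(0),
               p = numeric(0), method = character(0),
               significant = logical(0), stringsAsFactors = FALSE)
  structure(out, skipped = skipped, n_tests = nrow(out), alpha = alpha)
}

#' Percentile thresholds of the width distribution
#'
#' Linear-interpolation percentiles (R's default type-7 quantile) of the
#' width multiset; the defaults bracket the narrow/wide category boundaries.
#'
#' @param table a `DatasetTable`, or a numeric width vector.
#' @param percentiles two percentiles in (0, 100).
#' @return numeric vector of the two thresholds in Angstrom.
#' @export
percentile_thresholds <- function(table, percentiles = c(15, 85)) {
  w <- if (is.numeric(table)) table else table$width
  if (!length(w)) stop("no widths available")
  unname(stats::quantile(w, percentiles / 100, type = 7))
}
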