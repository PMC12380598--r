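#' CPM-normalize and log2-transform a count matrix
#'
#' \code{log2(1 + 1e6 * count / library_size)}, with the library size taken
#' as the per-sample column sum. Columns are invariant to rescaling all
#' counts of a sample. No composition (TMM-style) correction is applied.
#'
#' @param counts Non-negative genes x samples matrix.
#' @return Matrix of the same shape, log2(CPM + 1) values.
#' @export
cpmLog2 <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  libsize <- colSums(counts)
  if (any(libsize <= 0)) stop("library size must be positive for every sample")
  log2(1 + sweep(counts, 2, libsize, "/") * 1e6)
}

#' Gene-set (module) score with expression-matched control genes
#'
#' Per-sample score of a gene set relative to expression-matched background:
#' genes are binned into \code{n_bins} bins of average expression; for each
#' set member, \code{n_ctrl} control genes are drawn (without replacement,
#' capped at bin size, all set members excluded) from the member's bin; the
#' score is
#' the mean over members of (member expression - mean control expression).
#' Random sets on exchangeable data score around 0; a set uniformly
#' upshifted by +1 in a sample scores about +1 there.
#'
#' @param mat Normalized (log2 CPM) genes x samples matrix.
#' @param members Character vector of set member genes; members absent from
#'   \code{mat} are dropped with a warning.
#' @param name Set name, used in messages.
#' @param n_bins Number of average-expression bins (default 25).
#' @param n_ctrl Controls drawn per member (default 50).
#' @param seed Optional integer seed for the control draw.
#' @return Named numeric vector of per-sample scores.
#' @export
geneSetScore <- function(mat, members, name = "gene set",
                         n_bins = 25, n_ctrl = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  present <- intersect(members, rownames(mat))
  if (!length(present))
    stop("no members of '", name, "' present in the expression matrix")
  if (length(present) < length(members))
    warning(length(members) - length(present), " member(s) of '", name,
            "' absent from the matrix; dropped")
  avg <- rowMeans(mat)
  n_bins <- min(n_bins, length(avg))
  bin <- cut(rank(avg, ties.method = "first"), breaks = n_bins, labels = FALSE)
  names(bin) <- rownames(mat)
  ctrl_means <- matrix(0, length(present), ncol(mat))
  for (i in seq_along(present)) {
    g <- present[i]
    pool <- setdiff(names(bin)[bin == bin[g]], present)
    if (!length(pool)) pool <- setdiff(names(bin), present)
    ctrl <- sample(pool, min(n_ctrl, length(pool)))
    ctrl_means[i, ] <- colMeans(mat[ctrl, , drop = FALSE])
  }
  scores <- colMeans(mat[present, , drop = FALSE] - ctrl_means)
  setNames(scores, colnames(mat))
}

#' Associate gene-set scores with MRD
#'
#' Spearman correlation of per-sample scores with MRD at a timepoint, plus a
#' label-permutation empirical p-value: MRD values are permuted across
#' samples \code{B} times, the statistic is |rho|, and extremeness is
#' one-sided (ge) with add-one smoothing.
#'
#' @param scores Named numeric vector (per sample, names = patient ids).
#' @param cohort An \linkS4class{MRDCohort}.
#' @param timepoint \code{"mid"}, \code{"eoi"} or \code{"eoc"}.
#' @param B Number of permutations (default 1000).
#' @param seed Optional integer seed.
#' @return List with \code{rho}, \code{p} (t-approximation),
#'   \code{empirical_p}, \code{n}, \code{B}.
#' @export
scoreMrdAssociation <- function(scores, cohort, timepoint, B = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mrd <- mrdValues(cohort, timepoint)
  common <- intersect(names(scores), names(mrd)[!is.na(mrd)])
  if (length(common) < 3) stop("need >= 3 paired score/MRD observations")
  s <- scores[common]; m <- mrd[common]
  obs <- spearmanCor(s, m)
  null_stats <- vapply(seq_len(B), function(b)
    abs(spearmanCor(s, sample(m))$rho), numeric(1))
  list(rho = obs$rho, p = obs$p.value,
       empirical_p = empiricalP(abs(obs$rho), null_stats, "ge"),
       n = length(common), B = B)
}

#' Per-gene/sample copy-number status from carrier matrices
#'
#' Combines deletion and gain carrier matrices into the fixed vocabulary
#' del / neutral / gain / unknown (unknown when a patient carries both a
#' deletion and a gain over the gene).
#'
#' @param del_carriers,gain_carriers Patient x gene carrier matrices with
#'   identical dimnames (see \code{\link{carrierMatrix}}).
#' @return Character matrix, genes x patients.
#' @export
cnStatusFromCarriers <- function(del_carriers, gain_carriers) {
  stopifnot(identical(dimnames(del_carriers), dimnames(gain_carriers)))
  st <- matrix("neutral", ncol(del_carriers), nrow(del_carriers),
               dimnames = list(colnames(del_carriers), rownames(del_carriers)))
  d <- t(del_carriers) == 1L
  g <- t(gain_carriers) == 1L
  st[d & !g] <- "del"
  st[g & !d] <- "gain"
  st[d & g] <- "unknown"
  st
}

#' Test copy-number effect on gene expression
#'
#' For each gene, samples in the gene's dominant alteration state (deletion
#' or gain, whichever is more frequent; ties favour deletion) are compared
#' to copy-neutral samples with a Welch two-sample t-test on normalized
#' expression. Genes lacking at least \code{min_per_state} samples in both
#' states are skipped and logged. BH q-values are computed over the tested
#' genes; the conventional FDR reporting tiers are q < 0.01, < 0.05, < 0.1.
#'
#' @param mat Normalized (log2 CPM) genes x samples matrix.
#' @param cn_status Character matrix genes x samples with values del /
#'   neutral / gain / unknown (see \code{\link{cnStatusFromCarriers}});
#'   unknown samples are excluded per gene.
#' @param genes Genes to test (default: rows shared by \code{mat} and
#'   \code{cn_status}).
#' @param min_per_state Minimum samples per state (default 2).
#' @return data.frame with \code{gene}, \code{alteration}, \code{n_alt},
#'   \code{n_neutral}, \code{effect} (mean altered - mean neutral, log2
#'   units), \code{p}, \code{q}; skipped genes in attribute \code{skipped}.
#' @export
cnExpressionTest <- function(mat, cn_status, genes = NULL, min_per_state = 2) {
  if (is.null(genes))
    genes <- intersect(rownames(mat), rownames(cn_status))
  absent <- setdiff(genes, intersect(rownames(mat), rownames(cn_status)))
  genes <- setdiff(genes, absent)
  samples <- intersect(colnames(mat), colnames(cn_status))
  skipped <- if (length(absent))
    data.frame(gene = absent, reason = "absent from matrix or cn table")
  else data.frame(gene = character(), reason = character())
  rows <- list()
  for (g in genes) {
    st <- cn_status[g, samples]
    ndel <- sum(st == "del"); ngain <- sum(st == "gain")
    if (ndel == 0 && ngain == 0) {
      skipped <- rbind(skipped, data.frame(gene = g, reason = "single CN state"))
      next
    }
    alt <- if (ndel >= ngain) "del" else "gain"
    xa <- mat[g, samples[st == alt]]
    xn <- mat[g, samples[st == "neutral"]]
    if (length(xa) < min_per_state || length(xn) < min_per_state) {
      skipped <- rbind(skipped, data.frame(gene = g, reason = "too few samples per state"))
      next
    }
    tt <- tryCatch(t.test(xa, xn), error = function(e) NULL)
    if (is.null(tt)) {
      skipped <- rbind(skipped, data.frame(gene = g, reason = "degenerate test"))
      next
    }
    rows[[g]] <- data.frame(gene = g, alteration = alt,
                            n_alt = length(xa), n_neutral = length(xn),
                            effect = mean(xa) - mean(xn), p = tt$p.value)
  }
  res <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
  else data.frame(gene = character(), alteration = character(),
                  n_alt = integer(), n_neutral = integer(),
                  effect = numeric(), p = numeric())
  res$q <- if (nrow(res)) bhFDR(res$p) else numeric(0)
  attr(res, "skipped") <- skipped
  res
}

#' Select expressed, copy-number-concordant genes
#'
#' Post-filter on \code{\link{cnExpressionTest}} results: keeps genes whose
#' mean normalized expression reaches \code{floor} in at least one response
#' group and whose expression effect sign is concordant with the copy-number
#' direction (deletion with lower, gain with higher expression). Genes with
#' conflicting evidence are excluded.
#'
#' @param mat Normalized genes x samples matrix.
#' @param tests Result of \code{\link{cnExpressionTest}}.
#' @param groups Named factor over samples (any number of levels, e.g. the
#'   three EOI response groups); used for the per-group expression floor.
#' @param floor Mean log2(CPM+1) required in at least one group (default 1).
#' @return Character vector of retained genes; attribute \code{excluded}
#'   gives per-gene reasons.
#' @export
selectExpressedCnvGenes <- function(mat, tests, groups, floor = 1) {
  groups <- groups[!is.na(groups)]
  samples <- intersect(colnames(mat), names(groups))
  g <- factor(groups[samples])
  keep <- character(); excl <- list()
  for (i in seq_len(nrow(tests))) {
    gene <- tests$gene[i]
    if (!gene %in% rownames(mat)) { excl[[gene]] <- "absent"; next }
    grp_means <- tapply(mat[gene, samples], g, mean)
    if (all(grp_means < floor)) { excl[[gene]] <- "lowly expressed"; next }
    concordant <- (tests$alteration[i] == "del" && tests$effect[i] < 0) ||
      (tests$alteration[i] == "gain" && tests$effect[i] > 0)
    if (!concordant) { excl[[gene]] <- "expression conflicts with CN status"; next }
    keep <- c(keep, gene)
  }
  structure(keep, excluded = unlist(excl))
}
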