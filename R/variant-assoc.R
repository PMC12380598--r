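.functional_classes <- c("missense", "nonsense", "frameshift", "splice",
                         "inframe_indel")
.variant_classes <- c(.functional_classes, "synonymous", "other")

#' Filter variant calls to functional coding events
#'
#' Keeps coding SNVs/InDels with predicted impact on protein function:
#' missense, nonsense, frameshift, splice and in-frame indel classes.
#' Synonymous and non-coding calls are removed. The whitelist is
#' configurable.
#'
#' @param variants data.frame with columns \code{patient_id}, \code{gene},
#'   \code{variant_class} and \code{coding} (logical).
#' @param classes Character vector of retained classes.
#' @return Filtered data.frame; attribute \code{filter_log} holds counts.
#' @export
filterFunctional <- function(variants, classes = .functional_classes) {
  need <- c("patient_id", "gene", "variant_class", "coding")
  miss <- setdiff(need, names(variants))
  if (length(miss)) stop("variants lack column(s): ", paste(miss, collapse = ", "))
  bad <- !variants$variant_class %in% .variant_classes
  if (any(bad))
    stop("unknown variant_class value(s): ",
         paste(unique(variants$variant_class[bad]), collapse = ", "))
  keep <- variants$coding & variants$variant_class %in% classes
  out <- variants[keep, , drop = FALSE]
  attr(out, "filter_log") <- list(input = nrow(variants), kept = nrow(out),
                                  removed = nrow(variants) - nrow(out))
  out
}

#' Per-gene mutation prevalence test across a response dichotomy
#'
#' For each gene, patients are counted once as carriers regardless of how
#' many qualifying variants they have, a 2x2 carrier-by-group table is
#' formed over all patients with a group assignment, and a two-sided
#' Fisher's exact test applied. Raw p-values are reported alongside BH
#' q-values (the conventional DNA-level significance threshold is 0.1 on
#' the raw p).
#'
#' @param variants data.frame of (functionally filtered) variant calls.
#' @param groups Named two-level factor over patients (NA dropped). Patients
#'   absent from \code{variants} count as non-carriers.
#' @param genes Genes to test; default all genes present in \code{variants}.
#' @return data.frame with per-gene carrier counts, group proportions,
#'   the 2x2 table entries (a,b = carriers in group A/B; c,d = non-carriers),
#'   \code{p} and \code{q}.
#' @export
genePrevalenceTest <- function(variants, groups, genes = NULL) {
  groups <- groups[!is.na(groups)]
  if (nlevels(groups) != 2L) stop("groups must be a two-level factor")
  if (is.null(genes)) genes <- sort(unique(variants$gene))
  patients <- names(groups)
  nA <- sum(groups == levels(groups)[1]); nB <- sum(groups == levels(groups)[2])
  res <- do.call(rbind, lapply(genes, function(g) {
    carr <- unique(variants$patient_id[variants$gene == g])
    carr <- intersect(carr, patients)
    a <- sum(groups[carr] == levels(groups)[1])
    b <- length(carr) - a
    data.frame(gene = g, a = a, b = b, c = nA - a, d = nB - b,
               prop_a = a / nA, prop_b = b / nB,
               p = fisherExact2x2(a = a, b = b, c = nA - a, d = nB - b))
  }))
  res$q <- bhFDR(res$p)
  attr(res, "groups") <- setNames(c(nA, nB), levels(groups))
  res
}

#' Validate a CRISPR-screen ranking table
#'
#' @param screen data.frame with columns \code{gene}, \code{drug},
#'   \code{direction} (sensitizing/resistance), \code{rank} (positive
#'   integer) and \code{fdr}.
#' @return The validated data.frame.
#' @export
validateScreen <- function(screen) {
  need <- c("gene", "drug", "direction", "rank", "fdr")
  miss <- setdiff(need, names(screen))
  if (length(miss)) stop("screen lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(screen$direction %in% c("sensitizing", "resistance")))
    stop("direction must be sensitizing or resistance")
  if (anyDuplicated(screen[c("gene", "drug", "direction")]))
    stop("duplicate (gene, drug, direction) entries")
  if (any(screen$rank < 1)) stop("ranks must be positive")
  screen
}

#' Select a screen gene set by cut-off
#'
#' @param screen Validated screen ranking table.
#' @param drug,direction Which screen arm to use.
#' @param cutoff \code{"top100"}, \code{"top200"} or \code{"fdr"}
#'   (FDR < \code{fdr_max}).
#' @param fdr_max FDR threshold for \code{cutoff = "fdr"} (default 0.25).
#' @return Character vector of gene ids.
#' @export
screenGeneSet <- function(screen, drug, direction,
                          cutoff = c("top100", "top200", "fdr"),
                          fdr_max = 0.25) {
  cutoff <- match.arg(cutoff)
  sub <- screen[screen$drug == drug & screen$direction == direction, ]
  switch(cutoff,
         top100 = sub$gene[sub$rank <= 100],
         top200 = sub$gene[sub$rank <= 200],
         fdr = sub$gene[sub$fdr < fdr_max])
}

#' Deletion burden over screen-hit genes across a dichotomy
#'
#' Counts, per patient, how many genes of a CRISPR-screen hit set are
#' covered by a deletion, then compares the counts between the two response
#' groups with the rank-sum test, and additionally tests any-hit carrier
#' status (count >= 1) with Fisher's exact test.
#'
#' @param del_carriers Deletion carrier matrix at gene loci
#'   (\code{\link{carrierMatrix}} with \code{cnv_type = "del"}).
#' @param screen_genes Character vector of screen hit genes (e.g. from
#'   \code{\link{screenGeneSet}}); genes absent from the matrix are ignored.
#' @param groups Named two-level factor over patients.
#' @return List with \code{counts} (named integer per patient),
#'   \code{rank_sum} (list: statistic, p.value), \code{any_hit_p} (Fisher),
#'   \code{median_by_group}.
#' @export
screenDeletionBurden <- function(del_carriers, screen_genes, groups) {
  groups <- groups[!is.na(groups)]
  common <- intersect(rownames(del_carriers), names(groups))
  g <- factor(groups[common], levels = levels(groups))
  genes <- intersect(screen_genes, colnames(del_carriers))
  counts <- if (length(genes))
    rowSums(del_carriers[common, genes, drop = FALSE]) else
      setNames(rep(0, length(common)), common)
  if (all(counts == 0)) {
    rs <- list(statistic = NA_real_, p.value = 1, method = "degenerate")
  } else {
    rs <- rankSumTest(counts[g == levels(g)[1]], counts[g == levels(g)[2]],
                      mode = "normal_approx")
  }
  hit <- counts >= 1
  a <- sum(hit & g == levels(g)[1]); b <- sum(hit & g == levels(g)[2])
  anyp <- fisherExact2x2(a = a, b = b,
                         c = sum(g == levels(g)[1]) - a,
                         d = sum(g == levels(g)[2]) - b)
  list(counts = counts,
       rank_sum = rs,
       any_hit_p = anyp,
       median_by_group = tapply(counts, g, median))
}

#' Random-gene-set empirical p for screen-set deletion association
#'
#' Tests whether the between-group difference in any-hit deletion carrier
#' fraction for a screen gene set is larger than expected for a random gene
#' set of the same size drawn (uniformly, without replacement) from the gene
#' universe.
#'
#' @param del_carriers Deletion carrier matrix at gene loci; its columns are
#'   the default gene universe.
#' @param screen_genes Screen hit gene set.
#' @param groups Named two-level factor over patients.
#' @param B Number of random draws (default 1000).
#' @param universe Gene universe to draw from; defaults to genes with at
#'   least one observed deletion in the matrix.
#' @param seed Optional integer seed.
#' @return List with \code{observed} (absolute difference in any-hit
#'   fraction), \code{empirical_p}, \code{B}, \code{k} (set size used).
#' @export
screenSetEmpiricalP <- function(del_carriers, screen_genes, groups,
                                B = 1000, universe = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  groups <- groups[!is.na(groups)]
  common <- intersect(rownames(del_carriers), names(groups))
  g <- factor(groups[common], levels = levels(groups))
  cm <- del_carriers[common, , drop = FALSE]
  if (is.null(universe)) universe <- colnames(cm)[colSums(cm) > 0]
  genes <- intersect(screen_genes, colnames(cm))
  k <- length(genes)
  if (k > length(universe)) stop("screen set larger than gene universe")
  stat <- function(gs) {
    hit <- rowSums(cm[, gs, drop = FALSE]) >= 1
    abs(mean(hit[g == levels(g)[1]]) - mean(hit[g == levels(g)[2]]))
  }
  obs <- stat(genes)
  null_stats <- vapply(seq_len(B), function(b) stat(sample(universe, k)),
                       numeric(1))
  list(observed = obs,
       empirical_p = empiricalP(obs, null_stats, "ge"),
       B = B, k = k)
}
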