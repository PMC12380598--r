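#' Validate a CNV segment set
#'
#' CNV segments are represented as a \code{GRanges} with metadata columns
#' \code{patient_id}, \code{cnv_type} (del/gain/loh) and \code{source}
#' (wgs/array/panel). Coordinates are 1-based closed in memory (the GRanges
#' convention); BED-style 0-based half-open inputs are converted by the
#' readers.
#'
#' @param segments \code{GRanges} of CNV segments.
#' @param annotation A \linkS4class{GenomeAnnotation}; when supplied,
#'   segments on unknown chromosomes or beyond chromosome ends are dropped
#'   and reported (record-level errors, not fatal).
#' @return The validated \code{GRanges}; dropped records are summarised in
#'   \code{metadata()$dropped}.
#' @export
validateSegments <- function(segments, annotation = NULL) {
  need <- c("patient_id", "cnv_type", "source")
  miss <- setdiff(need, colnames(mcols(segments)))
  if (length(miss))
    stop("segments lack metadata column(s): ", paste(miss, collapse = ", "))
  bad_type <- !segments$cnv_type %in% c("del", "gain", "loh")
  if (any(bad_type))
    stop("unknown cnv_type value(s): ",
         paste(unique(segments$cnv_type[bad_type]), collapse = ", "))
  if (!is.null(annotation)) {
    sl <- chromLengths(annotation)
    chr <- as.character(seqnames(segments))
    off <- !(chr %in% names(sl)) | start(segments) < 1 |
      ifelse(chr %in% names(sl), end(segments) > sl[chr], TRUE)
    if (any(off)) {
      warning(sum(off), " segment(s) off-chromosome; dropped")
      dropped <- segments[off]
      segments <- segments[!off]
      metadata(segments)$dropped <- as.data.frame(dropped)
    }
  }
  segments
}

#' Filter CNV segments by size and blacklist overlap
#'
#' Retains deletions/gains longer than \code{min_len_bp} (strictly greater;
#' the working definition of a CNV here is an event > 1 Mb) whose overlap
#' with the blacklist, as a fraction of segment length, is below
#' \code{max_blacklist_overlap}. Removal counts per reason are recorded in
#' \code{metadata()$filter_log}. Filtering is idempotent.
#'
#' @param segments \code{GRanges} CNV segments (see
#'   \code{\link{validateSegments}}).
#' @param annotation A \linkS4class{GenomeAnnotation} providing the blacklist
#'   and chromosome bounds.
#' @param min_len_bp Minimum length in bp, exclusive (default 1e6).
#' @param max_blacklist_overlap Segments with blacklist-overlap fraction at
#'   or above this are removed (default 0.5).
#' @return Filtered \code{GRanges} with a \code{filter_log} in its metadata.
#' @export
filterSegments <- function(segments, annotation, min_len_bp = 1e6,
                           max_blacklist_overlap = 0.5) {
  segments <- validateSegments(segments, annotation)
  n0 <- length(segments)
  keep_size <- width(segments) > min_len_bp
  removed_size <- sum(!keep_size)
  segments <- segments[keep_size]
  bl <- reduce(blacklistRegions(annotation))
  frac <- rep(0, length(segments))
  if (length(bl) && length(segments)) {
    hits <- findOverlaps(segments, bl)
    if (length(hits)) {
      ov <- width(pintersect(segments[queryHits(hits)], bl[subjectHits(hits)]))
      ovsum <- tapply(ov, queryHits(hits), sum)
      frac[as.integer(names(ovsum))] <- ovsum / width(segments)[as.integer(names(ovsum))]
    }
  }
  keep_bl <- frac < max_blacklist_overlap
  removed_bl <- sum(!keep_bl)
  out <- segments[keep_bl]
  metadata(out)$filter_log <- list(
    input = n0, removed_size = removed_size,
    removed_blacklist = removed_bl, kept = length(out)
  )
  out
}

#' Harmonize CNV calls across assays
#'
#' When a patient was profiled on several assays, only the
#' highest-priority assay's segments are used, so each patient contributes
#' CNV calls from exactly one source. Identical duplicate segments within a
#' source are collapsed. Source provenance is retained in the \code{source}
#' column.
#'
#' @param segments \code{GRanges} CNV segments from all assays.
#' @param priority Character vector of sources, highest priority first
#'   (default \code{c("wgs", "array", "panel")}).
#' @param assays Optional named list (patient -> character vector of assays
#'   available), e.g. from \code{\link{patientAssays}}; lets patients whose
#'   best assay produced zero segments still be recognised. Defaults to the
#'   sources observed in \code{segments}.
#' @return \code{GRanges} with one source per patient;
#'   \code{metadata()$cnv_source} maps each patient with CNV data to the
#'   source used.
#' @export
harmonizeAssays <- function(segments, priority = c("wgs", "array", "panel"),
                            assays = NULL) {
  present <- unique(segments$source)
  if (!all(present %in% priority))
    stop("priority order does not cover source(s): ",
         paste(setdiff(present, priority), collapse = ", "))
  if (is.null(assays)) {
    assays <- split(segments$source, segments$patient_id)
  } else {
    assays <- lapply(assays, intersect, x = priority)
    assays <- assays[lengths(assays) > 0]
  }
  chosen <- vapply(assays, function(a) priority[min(match(unique(a), priority))],
                   character(1))
  keep <- segments$source == chosen[segments$patient_id] &
    !is.na(chosen[segments$patient_id])
  out <- segments[keep]
  key <- paste(out$patient_id, seqnames(out), start(out), end(out), out$cnv_type)
  out <- out[!duplicated(key)]
  metadata(out)$cnv_source <- chosen
  out
}

#' Patient-by-locus carrier matrix
#'
#' Binary matrix marking, for each patient and locus, whether the patient has
#' at least one CNV segment of the requested type overlapping the locus by at
#' least 1 bp.
#'
#' @param segments \code{GRanges} CNV segments (filtered and harmonized).
#' @param loci Named \code{GRanges} of loci (genes or fixed-width bins).
#' @param cnv_type \code{"del"} or \code{"gain"}.
#' @param patients Character vector defining the patient universe (rows);
#'   defaults to the patients present in \code{segments}. Patients without
#'   segments of \code{cnv_type} get all-zero rows.
#' @return Integer 0/1 matrix, patients x loci.
#' @export
carrierMatrix <- function(segments, loci, cnv_type, patients = NULL) {
  if (!cnv_type %in% c("del", "gain", "loh"))
    stop("unknown cnv_type: ", cnv_type)
  if (is.null(names(loci)) || anyDuplicated(names(loci)))
    stop("loci must have unique names")
  if (is.null(patients)) patients <- sort(unique(segments$patient_id))
  segs <- segments[segments$cnv_type == cnv_type &
                     segments$patient_id %in% patients]
  m <- matrix(0L, nrow = length(patients), ncol = length(loci),
              dimnames = list(patients, names(loci)))
  if (length(segs)) {
    hits <- findOverlaps(loci, segs)
    if (length(hits)) {
      ri <- match(segs$patient_id[subjectHits(hits)], patients)
      m[cbind(ri, queryHits(hits))] <- 1L
    }
  }
  m
}

#' Tile a chromosome into fixed-width loci
#'
#' @param annotation A \linkS4class{GenomeAnnotation}.
#' @param chrom Chromosome name.
#' @param bin_bp Bin width in bp (default 1e6).
#' @return Named \code{GRanges} of bins covering the chromosome.
#' @export
binLoci <- function(annotation, chrom, bin_bp = 1e6) {
  len <- chromLengths(annotation)[chrom]
  if (is.na(len)) stop("unknown chromosome: ", chrom)
  starts <- seq(1L, len, by = bin_bp)
  gr <- GRanges(chrom, IRanges(starts, pmin(starts + bin_bp - 1, len)))
  names(gr) <- sprintf("%s:%d-%d", chrom, start(gr) - 1L, end(gr))
  gr
}

#' Gene loci from an annotation
#'
#' @param annotation A \linkS4class{GenomeAnnotation}.
#' @param expressed.only Restrict to genes with detectable expression (the
#'   default locus set for empirical-p association).
#' @return Named \code{GRanges} of gene intervals.
#' @export
geneLoci <- function(annotation, expressed.only = TRUE) {
  g <- annotatedGenes(annotation, expressed.only = expressed.only)
  names(g) <- g$gene_id
  g
}

#' Carrier-frequency curves per response group
#'
#' For each locus (typically fixed-width bins along one chromosome) and each
#' side of a dichotomy, the fraction of patients carrying the CNV type.
#' Denominators are the group sizes among patients with CNV data (the rows of
#' \code{carriers}).
#'
#' @param carriers Carrier matrix from \code{\link{carrierMatrix}}.
#' @param groups Named two-level factor (e.g. from \code{dichotomize});
#'   patients with NA group are excluded.
#' @return data.frame with columns \code{locus}, \code{group},
#'   \code{carriers}, \code{n}, \code{fraction}.
#' @export
frequencyCurves <- function(carriers, groups) {
  groups <- groups[!is.na(groups)]
  common <- intersect(rownames(carriers), names(groups))
  if (!length(common)) stop("no patients shared between carriers and groups")
  g <- factor(groups[common], levels = levels(groups))
  if (any(table(g) == 0))
    stop("empty group among patients with CNV data: ",
         paste(levels(g)[table(g) == 0], collapse = ", "))
  cm <- carriers[common, , drop = FALSE]
  out <- do.call(rbind, lapply(levels(g), function(lv) {
    sub <- cm[g == lv, , drop = FALSE]
    data.frame(locus = colnames(cm), group = lv,
               carriers = as.integer(colSums(sub)), n = nrow(sub),
               fraction = colSums(sub) / nrow(sub), row.names = NULL)
  }))
  out
}

.segmentArms <- function(segments, annotation) {
  arms <- chromArms(annotation)
  hits <- findOverlaps(segments, arms)
  ov <- width(pintersect(segments[queryHits(hits)], arms[subjectHits(hits)]))
  best <- tapply(seq_along(ov), queryHits(hits), function(i) i[which.max(ov[i])])
  arm_idx <- rep(NA_integer_, length(segments))
  arm_idx[as.integer(names(best))] <- subjectHits(hits)[unlist(best)]
  if (anyNA(arm_idx)) stop("segment(s) overlap no chromosome arm")
  arm_idx
}

#' Randomize CNV segment positions within their chromosome arm
#'
#' The within-arm randomization null: each segment keeps its patient,
#' chromosome arm, length and CNV type, and its start is redrawn uniformly
#' over all placements that keep the segment entirely inside its original
#' arm (the arm with which it overlaps most). A segment longer than its arm
#' is pinned to the arm bounds with a warning. Uses the current R RNG; call
#' \code{set.seed} for reproducibility.
#'
#' @param segments \code{GRanges} CNV segments.
#' @param annotation A \linkS4class{GenomeAnnotation}.
#' @return \code{GRanges} with randomized positions (same order, widths,
#'   metadata).
#' @export
randomizeSegments <- function(segments, annotation) {
  if (!length(segments)) return(segments)
  arm_idx <- .segmentArms(segments, annotation)
  arms <- chromArms(annotation)
  .randomizeWithArms(segments, start(arms)[arm_idx], end(arms)[arm_idx])
}

.randomizeWithArms <- function(segments, arm_start, arm_end) {
  w <- width(segments)
  slack <- arm_end - arm_start + 1L - w
  if (any(slack < 0)) {
    warning(sum(slack < 0), " segment(s) longer than their arm; pinned to arm bounds")
  }
  new_start <- ifelse(slack <= 0, arm_start,
                      arm_start + floor(runif(length(segments)) * (slack + 1)))
  out <- GRanges(seqnames(segments), IRanges(new_start, width = w))
  mcols(out) <- mcols(segments)
  metadata(out) <- metadata(segments)
  out
}

.carrierCounts <- function(segments, loci, patient_group, n_loci) {
  # patient_group: named integer 1/2 per patient; returns 2 x n_loci carrier counts
  hits <- findOverlaps(loci, segments)
  cnt <- matrix(0L, 2L, n_loci)
  if (length(hits)) {
    li <- queryHits(hits)
    pi <- patient_group[segments$patient_id[subjectHits(hits)]]
    pair_id <- li * (length(patient_group) + 1) +
      match(segments$patient_id[subjectHits(hits)], names(patient_group))
    dup <- duplicated(pair_id)
    li <- li[!dup]; pi <- pi[!dup]
    cnt[1, ] <- tabulate(li[pi == 1L], nbins = n_loci)
    cnt[2, ] <- tabulate(li[pi == 2L], nbins = n_loci)
  }
  cnt
}

#' Locus-level CNV/response association with empirical p-values
#'
#' For each locus, an association statistic between CNV carrier status and a
#' two-group response dichotomy is compared against a randomization null in
#' which (by default) both the CNV coordinates are redrawn within their
#' chromosome arms and the group labels are permuted in every iteration.
#' Empirical p-values use add-one smoothing (\code{\link{empiricalP}}).
#'
#' @param segments Filtered, harmonized \code{GRanges} CNV segments.
#' @param loci Named \code{GRanges} of loci, typically the expressed genes
#'   (\code{\link{geneLoci}}).
#' @param groups Named two-level factor over patients (NA dropped).
#' @param annotation A \linkS4class{GenomeAnnotation}.
#' @param cnv_type \code{"del"} or \code{"gain"}.
#' @param B Number of randomizations (default 1000; >= 100 recommended for
#'   reportable results).
#' @param statistic \code{"freq_diff"} (absolute difference in carrier
#'   fraction; direction ge) or \code{"fisher_p"} (two-sided Fisher p;
#'   direction le).
#' @param randomize \code{"both"} (coordinates and labels, the default),
#'   \code{"labels"} or \code{"coords"} (diagnostic nulls).
#' @param seed Optional integer seed applied via \code{set.seed}.
#' @return data.frame with columns \code{locus}, \code{carriers_a},
#'   \code{carriers_b}, \code{n_a}, \code{n_b}, \code{observed} (statistic)
#'   and \code{empirical_p}; attributes \code{B}, \code{seed},
#'   \code{statistic}.
#' @export
cnvEmpiricalP <- function(segments, loci, groups, annotation,
                          cnv_type = "del", B = 1000,
                          statistic = c("freq_diff", "fisher_p"),
                          randomize = c("both", "labels", "coords"),
                          seed = NULL) {
  statistic <- match.arg(statistic)
  randomize <- match.arg(randomize)
  if (B < 1) stop("B must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  groups <- groups[!is.na(groups)]
  patients <- names(groups)
  segs <- segments[segments$cnv_type == cnv_type &
                     segments$patient_id %in% patients]
  n_loci <- length(loci)
  pgrp <- setNames(as.integer(groups), patients)
  n_a <- sum(pgrp == 1L); n_b <- sum(pgrp == 2L)
  if (n_a == 0 || n_b == 0) stop("both groups must be non-empty")

  stat_fun <- if (statistic == "freq_diff") {
    function(cnt) abs(cnt[1, ] / n_a - cnt[2, ] / n_b)
  } else {
    function(cnt) vapply(seq_len(n_loci), function(j) {
      fisherExact2x2(matrix(c(cnt[1, j], cnt[2, j],
                              n_a - cnt[1, j], n_b - cnt[2, j]), 2L, byrow = TRUE))
    }, numeric(1))
  }
  cnt_obs <- .carrierCounts(segs, loci, pgrp, n_loci)
  obs <- stat_fun(cnt_obs)

  arm_idx <- if (length(segs)) .segmentArms(segs, annotation) else integer(0)
  arms <- chromArms(annotation)
  a_start <- start(arms)[arm_idx]; a_end <- end(arms)[arm_idx]

  exceed <- integer(n_loci)
  for (b in seq_len(B)) {
    segs_b <- if (randomize %in% c("both", "coords"))
      .randomizeWithArms(segs, a_start, a_end) else segs
    pgrp_b <- if (randomize %in% c("both", "labels"))
      setNames(sample(pgrp), patients) else pgrp
    stat_b <- stat_fun(.carrierCounts(segs_b, loci, pgrp_b, n_loci))
    exceed <- exceed + if (statistic == "freq_diff")
      (stat_b >= obs) else (stat_b <= obs)
  }
  res <- data.frame(
    locus = names(loci),
    carriers_a = cnt_obs[1, ], carriers_b = cnt_obs[2, ],
    n_a = n_a, n_b = n_b,
    observed = obs,
    empirical_p = (1 + exceed) / (B + 1),
    row.names = NULL
  )
  attr(res, "B") <- B
  attr(res, "seed") <- seed
  attr(res, "statistic") <- statistic
  res
}

#' Plot carrier-frequency curves along a chromosome
#'
#' Line plot of per-bin carrier fractions for the two sides of a dichotomy
#' (base graphics; direct the output with \code{png()}/\code{svg()} as
#' needed). Bins are drawn in genomic order on the x-axis in Mb.
#'
#' @param curves data.frame from \code{\link{frequencyCurves}} computed on
#'   \code{\link{binLoci}} bins of a single chromosome.
#' @param main Plot title.
#' @param col Two colours, one per group level.
#' @return Invisibly, the reshaped fraction matrix (bins x groups).
#' @export
plotFrequencyCurves <- function(curves, main = "CNV carrier frequency",
                                col = c("red", "darkgreen")) {
  groups <- unique(curves$group)
  if (length(groups) != 2) stop("curves must carry exactly two groups")
  loci <- unique(curves$locus)
  pos <- as.numeric(sub(".*:(\\d+)-.*", "\\1", loci)) / 1e6
  ord <- order(pos)
  m <- vapply(groups, function(g)
    curves$fraction[curves$group == g][ord], numeric(length(loci)))
  graphics::matplot(pos[ord], m, type = "l", lty = 1, lwd = 2, col = col,
                    xlab = "position (Mb)", ylab = "carrier fraction",
                    ylim = c(0, max(m, 0.05)), main = main)
  graphics::legend("topright", legend = groups, col = col, lwd = 2,
                   bty = "n")
  invisible(`colnames<-`(m, as.character(groups)))
}
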