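#' Toy genome annotation for simulation and examples
#'
#' A deterministic three-chromosome genome (chr9, chr12, chr21 at roughly
#' their real lengths) with centromere-delimited arms, ~280 evenly spaced
#' 100 kb gene models (~70\% flagged expressed) and a fixed set of 1.5-2.5 Mb
#' blacklist intervals. A handful of genes at the recurrently altered loci
#' carry their real-world names (ETV6, KRAS, EMP1 on 12p; SYK, ERCC6L2, INIP
#' on 9q; mutation-recurrent genes such as ARID5B, NF1, TP53 elsewhere) so
#' simulated results read naturally; everything else is G-numbered.
#'
#' @return A \linkS4class{GenomeAnnotation}.
#' @export
toyGenomeAnnotation <- function() {
  lens <- c(chr9 = 141e6, chr12 = 133e6, chr21 = 48e6)
  cen <- list(chr9 = c(43e6, 47e6), chr12 = c(34e6, 38e6), chr21 = c(11e6, 13e6))
  arms <- do.call(rbind, lapply(names(lens), function(ch) {
    data.frame(chrom = ch,
               start = c(0, cen[[ch]][2]),
               end = c(cen[[ch]][1], lens[[ch]]),
               arm = paste0(ch, c("p", "q")))
  }))
  # genes every 1.1 Mb within arms, 100 kb wide
  genes <- do.call(rbind, lapply(seq_len(nrow(arms)), function(i) {
    starts <- seq(arms$start[i] + 2e5, arms$end[i] - 2e5, by = 1.1e6)
    data.frame(chrom = arms$chrom[i], start = starts, end = starts + 1e5,
               arm = arms$arm[i])
  }))
  genes$gene_id <- sprintf("G%03d", seq_len(nrow(genes)))
  genes$expressed <- (seq_len(nrow(genes)) %% 10) < 7
  rename_at <- function(g, chrom, pos, name) {
    i <- which(g$chrom == chrom)[which.min(abs(g$start[g$chrom == chrom] - pos))]
    g$gene_id[i] <- name
    g$expressed[i] <- TRUE
    g
  }
  marquee <- list(
    c("chr12", 0.4e6, "KDM5A"), c("chr12", 4.3e6, "TIGAR"),
    c("chr12", 6.9e6, "USP5"), c("chr12", 7.2e6, "PHB2"),
    c("chr12", 11.8e6, "ETV6"), c("chr12", 25.2e6, "KRAS"),
    c("chr12", 12.9e6, "EMP1"),
    c("chr9", 90.5e6, "SYK"), c("chr9", 98.3e6, "ERCC6L2"),
    c("chr9", 110e6, "INIP"),
    c("chr9", 5e6, "ARID5B"), c("chr9", 10e6, "MSH2"),
    c("chr9", 15e6, "IKZF2"), c("chr21", 15e6, "NF1"),
    c("chr21", 20e6, "TP53"), c("chr21", 25e6, "SIN3A"),
    c("chr21", 30e6, "INTS1"), c("chr21", 35e6, "KANSL1"),
    c("chr21", 40e6, "UGGT2")
  )
  for (m in marquee)
    genes <- rename_at(genes, m[[1]], as.numeric(m[[2]]), m[[3]])
  bl <- data.frame(
    chrom = c("chr9", "chr9", "chr12", "chr12", "chr21"),
    start = c(20e6, 60e6, 60e6, 100e6, 30e6),
    end   = c(22e6, 61.5e6, 62e6, 101.5e6, 31.5e6)
  )
  GenomeAnnotation(lens, arms = arms[c("chrom", "start", "end", "arm")],
                   genes = genes[c("chrom", "start", "end", "gene_id", "expressed")],
                   blacklist = bl)
}

#' Simulation configuration
#'
#' Assembles (and validates) the full parameter set for
#' \code{\link{simulateCohort}}. Defaults emulate the cohort structure and
#' planted effects the package's analyses are designed to detect: EOI group
#' proportions targeting 116 fast / 156 intermediate / 84 slow per 356;
#' a 12p deletion enriched in fast responders (0.45 vs 0.10), a short
#' proximal 12p gain enriched in slow responders, 9q deletion and 21q gain
#' enriched in slow responders; gene-level mutation prevalences per response
#' dichotomy; APOBEC-like signature exposure increasing as mid-induction MRD
#' decreases; negative-binomial expression with copy-number dosage and an
#' S-phase program anti-correlated with MRD.
#'
#' @param n_patients Cohort size (default 358).
#' @param seed Master seed; all stage seeds derive from it.
#' @param genome A \linkS4class{GenomeAnnotation}
#'   (default \code{\link{toyGenomeAnnotation}}).
#' @param mrd_model Per-timepoint list(p0, meanlog, sdlog) plus
#'   \code{latent_cor}; see Details in the package vignette.
#' @param cnv_regions data.frame of planted regions: chrom, start, end
#'   (0-based half-open), cnv_type, prev_fast, prev_intermediate, prev_slow
#'   (EOI-group carrier probabilities).
#' @param background_cnv_rate Mean background segments per patient (Poisson).
#' @param background_len_range Log-uniform background length range in bp
#'   (straddles the 1 Mb filter so size filtering is exercised).
#' @param blacklist_frac Fraction of background segments planted inside
#'   blacklist intervals.
#' @param assay_props Probabilities that a patient has each DNA assay.
#' @param rnaseq_n Number of patients with RNA-seq.
#' @param mutation_genes data.frame(gene, scheme, prev_main, prev_rest):
#'   per-dichotomy carrier probabilities for planted mutation genes.
#' @param signature_model list(base, slope, noise_sd, n_mut_meanlog,
#'   n_mut_sdlog): exposure fractions are
#'   \code{pmax(0.01, base + slope * z + noise)} normalized, with z the
#'   standardized -log10(MRD_mid + 1e-6) and noise N(0, noise_sd) per
#'   sample and signature (inter-patient exposure variability beyond the
#'   MRD link).
#' @param expression_model list(mean_log_mean, mean_log_sd, size,
#'   dosage_effect, sphase_loading, g2m_loading, program_noise_sd,
#'   set_size): per-sample program activity is loading x standardized
#'   -log10(MRD_mid + 1e-6) plus N(0, program_noise_sd) of MRD-independent
#'   variability.
#' @param screen_drugs Drugs for the synthetic screen rankings.
#' @param screen_n Ranked genes per drug/direction.
#' @return A validated list of class \code{SimConfig}.
#' @export
simConfig <- function(n_patients = 358,
                      seed = 1,
                      genome = toyGenomeAnnotation(),
                      mrd_model = NULL,
                      cnv_regions = NULL,
                      background_cnv_rate = 3,
                      background_len_range = c(3e5, 8e6),
                      blacklist_frac = 0.05,
                      assay_props = c(wgs = 33 / 358, array = 0.25, panel = 0.75),
                      rnaseq_n = 51,
                      mutation_genes = NULL,
                      signature_model = NULL,
                      expression_model = NULL,
                      screen_drugs = c("daunorubicin", "dexamethasone", "vincristine"),
                      screen_n = 250) {
  if (is.null(mrd_model)) mrd_model <- list(
    mid = list(p0 = 0.02, meanlog = log(0.1) - qnorm(1 - 0.15 / 0.98) * 2, sdlog = 2),
    eoi = list(p0 = 116 / 356, meanlog = log(1e-3) - qnorm(1 - 84 / 240) * 2.5, sdlog = 2.5),
    eoc = list(p0 = 0.85, meanlog = -9, sdlog = 2),
    latent_cor = 0.8
  )
  if (is.null(cnv_regions)) cnv_regions <- data.frame(
    name = c("del12p", "gain12p", "del9q", "gain21q"),
    chrom = c("chr12", "chr12", "chr9", "chr21"),
    start = c(8e6, 0, 70e6, 13e6),
    end = c(33e6, 12e6, 100e6, 48e6),
    cnv_type = c("del", "gain", "del", "gain"),
    prev_fast = c(0.45, 0.05, 0.05, 0.08),
    prev_intermediate = c(0.10, 0.10, 0.10, 0.10),
    prev_slow = c(0.10, 0.40, 0.30, 0.30)
  )
  if (is.null(mutation_genes)) mutation_genes <- data.frame(
    gene = c("ARID5B", "MSH2", "ETV6", "IKZF2", "NF1", "UGGT2", "SIN3A",
             "TP53", "KANSL1", "INTS1"),
    scheme = c("mid_slow_vs_fast", "slow_vs_rest", "slow_vs_rest",
               "fast_vs_rest", "eoc_pos_vs_neg", "eoc_pos_vs_neg",
               "eoc_pos_vs_neg", "eoc_pos_vs_neg", "eoc_pos_vs_neg",
               "eoc_pos_vs_neg"),
    prev_main = c(0.059, 0.072, 0.10, 0.031, 0.111, 0.130, 0.056, 0.056,
                  0.074, 0.074),
    prev_rest = c(0.010, 0.000, 0.030, 0.000, 0.013, 0.018, 0.004, 0.004,
                  0.009, 0.013)
  )
  if (is.null(signature_model)) signature_model <- list(
    base = c(SBS1 = 0.25, SBS2 = 0.15, SBS8 = 0.15, SBS13 = 0.10, FLAT = 0.35),
    slope = c(SBS1 = -0.05, SBS2 = 0.08, SBS8 = -0.04, SBS13 = 0.05, FLAT = 0),
    noise_sd = 0.06,
    n_mut_meanlog = log(1900), n_mut_sdlog = 0.4
  )
  if (is.null(expression_model)) expression_model <- list(
    mean_log_mean = log(150), mean_log_sd = 1, size = 8,
    dosage_effect = 1, sphase_loading = 0.5, g2m_loading = 0.25,
    program_noise_sd = 0.8, set_size = 30
  )
  cfg <- list(n_patients = n_patients, seed = seed, genome = genome,
              mrd_model = mrd_model, cnv_regions = cnv_regions,
              background_cnv_rate = background_cnv_rate,
              background_len_range = background_len_range,
              blacklist_frac = blacklist_frac,
              assay_props = assay_props, rnaseq_n = rnaseq_n,
              mutation_genes = mutation_genes,
              signature_model = signature_model,
              expression_model = expression_model,
              screen_drugs = screen_drugs, screen_n = screen_n)
  class(cfg) <- "SimConfig"
  validateSimConfig(cfg)
  cfg
}

#' Validate a SimConfig
#'
#' Checks probability bounds and that every planted region fits within one
#' chromosome arm of the genome; fails before any file is written.
#'
#' @param cfg A \code{SimConfig}.
#' @return Invisibly \code{TRUE}, or an error.
#' @export
validateSimConfig <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  for (tp in c("mid", "eoi", "eoc")) {
    p0 <- cfg$mrd_model[[tp]]$p0
    if (p0 < 0 || p0 > 1) stop("mrd_model$", tp, "$p0 outside [0,1]")
  }
  prevs <- unlist(cfg$cnv_regions[c("prev_fast", "prev_intermediate", "prev_slow")])
  if (any(prevs < 0 | prevs > 1)) stop("CNV prevalences outside [0,1]")
  arms <- chromArms(cfg$genome)
  for (i in seq_len(nrow(cfg$cnv_regions))) {
    r <- cfg$cnv_regions[i, ]
    reg <- GRanges(r$chrom, IRanges(r$start + 1, r$end))
    within <- any(start(arms) <= start(reg) & end(arms) >= end(reg) &
                    as.character(seqnames(arms)) == r$chrom)
    if (!within)
      stop("planted region ", r$name, " does not fit within one chromosome arm")
  }
  mp <- unlist(cfg$mutation_genes[c("prev_main", "prev_rest")])
  if (any(mp < 0 | mp > 1)) stop("mutation prevalences outside [0,1]")
  if (!all(cfg$mutation_genes$gene %in% annotatedGenes(cfg$genome)$gene_id))
    stop("mutation gene(s) absent from annotation")
  invisible(TRUE)
}

#' Simulate per-patient MRD triplets
#'
#' One latent severity per patient induces positively correlated MRD values
#' across the three timepoints. At each timepoint the severity quantile
#' below \code{p0} maps to MRD = 0 (undetectable) and the remainder is
#' quantile-transformed through a log-normal tail, capped at 1.
#'
#' @param n Number of patients.
#' @param mrd_model As in \code{\link{simConfig}}.
#' @return data.frame(patient_id, mrd_mid, mrd_eoi, mrd_eoc). Uses the
#'   current RNG state.
#' @export
simulateMRD <- function(n, mrd_model) {
  z <- rnorm(n)
  r <- mrd_model$latent_cor
  draw <- function(m) {
    e <- r * z + sqrt(1 - r^2) * rnorm(n)
    u <- pnorm(e)
    mrd <- rep(0, n)
    pos <- u >= m$p0
    v <- (u[pos] - m$p0) / (1 - m$p0)
    mrd[pos] <- pmin(1, qlnorm(v, m$meanlog, m$sdlog))
    mrd
  }
  data.frame(patient_id = sprintf("P%04d", seq_len(n)),
             mrd_mid = draw(mrd_model$mid),
             mrd_eoi = draw(mrd_model$eoi),
             mrd_eoc = draw(mrd_model$eoc))
}

.jitter_within <- function(lo, hi, arm_lo, arm_hi, amount = 1e6) {
  s <- round(lo + runif(length(lo), -amount, amount))
  e <- round(hi + runif(length(hi), -amount, amount))
  s <- pmax(arm_lo, pmin(s, e - 1e5))
  e <- pmin(arm_hi, pmax(e, s + 1e5))
  cbind(s, e)
}

#' Simulate CNV segments per assay
#'
#' Planted recurrent regions are drawn per patient with EOI-group-dependent
#' carrier probabilities and +/-1 Mb breakpoint jitter (clipped to the arm);
#' background segments have Poisson counts per patient, log-uniform lengths
#' straddling 1 Mb, uniform within-arm placement, and a configured fraction
#' centred inside blacklist intervals. Each patient's segments are emitted
#' once per DNA assay the patient has (identical coordinates per source), so
#' downstream assay harmonization is exercised.
#'
#' @param cohort An \linkS4class{MRDCohort} (with assay annotations).
#' @param cfg A \code{SimConfig}.
#' @return \code{GRanges} with patient_id, cnv_type, source and (for planted
#'   segments) region metadata columns. Uses the current RNG state.
#' @export
simulateCNVs <- function(cohort, cfg) {
  ann <- cfg$genome
  arms <- chromArms(ann)
  eoi <- responseLabels(cohort, "eoi")
  ids <- patientIDs(cohort)
  rows <- list()
  for (i in seq_len(nrow(cfg$cnv_regions))) {
    r <- cfg$cnv_regions[i, ]
    prev <- c(fast = r$prev_fast, intermediate = r$prev_intermediate,
              slow = r$prev_slow)[as.character(eoi)]
    prev[is.na(prev)] <- mean(c(r$prev_fast, r$prev_intermediate, r$prev_slow))
    carrier <- runif(length(ids)) < prev
    if (!any(carrier)) next
    arm_i <- which(start(arms) <= r$start + 1 & end(arms) >= r$end &
                     as.character(seqnames(arms)) == r$chrom)[1]
    se <- .jitter_within(rep(r$start, sum(carrier)), rep(r$end, sum(carrier)),
                         start(arms)[arm_i] - 1, end(arms)[arm_i])
    rows[[r$name]] <- data.frame(patient_id = ids[carrier], chrom = r$chrom,
                                 start = se[, 1], end = se[, 2],
                                 cnv_type = r$cnv_type, region = r$name)
  }
  # background
  lens <- chromLengths(ann)
  arm_df <- data.frame(chrom = as.character(seqnames(arms)),
                       lo = start(arms) - 1, hi = end(arms),
                       w = width(arms))
  bl <- blacklistRegions(ann)
  n_bg <- stats::rpois(length(ids), cfg$background_cnv_rate)
  tot <- sum(n_bg)
  if (tot > 0) {
    pid <- rep(ids, n_bg)
    len <- round(exp(runif(tot, log(cfg$background_len_range[1]),
                           log(cfg$background_len_range[2]))))
    in_bl <- runif(tot) < cfg$blacklist_frac & length(bl) > 0
    arm_pick <- sample.int(nrow(arm_df), tot, replace = TRUE,
                           prob = arm_df$w)
    len <- pmin(len, arm_df$w[arm_pick] - 1)
    s <- arm_df$lo[arm_pick] +
      floor(runif(tot) * (arm_df$w[arm_pick] - len))
    e <- s + len
    chroms <- arm_df$chrom[arm_pick]
    if (any(in_bl)) {
      bi <- sample.int(length(bl), sum(in_bl), replace = TRUE)
      ctr <- floor((start(bl[bi]) + end(bl[bi])) / 2)
      lb <- pmin(len[in_bl], 2 * (end(bl[bi]) - start(bl[bi])))
      s[in_bl] <- pmax(0, ctr - floor(lb / 2))
      e[in_bl] <- s[in_bl] + lb
      ch <- as.character(seqnames(bl[bi]))
      e[in_bl] <- pmin(e[in_bl], lens[ch])
      chroms[in_bl] <- ch
    }
    rows[["background"]] <- data.frame(
      patient_id = pid, chrom = chroms, start = s, end = e,
      cnv_type = sample(c("del", "gain"), tot, replace = TRUE),
      region = "background")
  }
  allseg <- do.call(rbind, rows)
  # emit once per DNA assay of each patient
  assays <- patientAssays(cohort)
  out <- do.call(rbind, lapply(c("wgs", "array", "panel"), function(src) {
    has <- names(assays)[vapply(assays, function(a) src %in% a, logical(1))]
    sub <- allseg[allseg$patient_id %in% has, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    sub$source <- src
    sub
  }))
  gr <- GRanges(out$chrom, IRanges(out$start + 1, out$end))
  mcols(gr) <- DataFrame(patient_id = out$patient_id,
                         cnv_type = out$cnv_type, source = out$source,
                         region = out$region)
  sort(gr)
}

#' Simulate planted gene mutations
#'
#' Each configured gene gets per-patient carrier draws with
#' dichotomy-dependent probability; carriers receive one functional variant
#' (class drawn from the functional mix). Background passenger variants
#' (including synonymous and non-coding calls, so functional filtering is
#' exercised) are added per patient. Only patients with a WGS or panel assay
#' yield variant calls.
#'
#' @param cohort An \linkS4class{MRDCohort}.
#' @param cfg A \code{SimConfig}.
#' @param background_rate Mean passenger variants per patient (default 1.5).
#' @return data.frame(patient_id, gene, variant_class, coding). Uses the
#'   current RNG state.
#' @export
simulateMutations <- function(cohort, cfg, background_rate = 1.5) {
  assays <- patientAssays(cohort)
  ids <- names(assays)[vapply(assays, function(a)
    any(c("wgs", "panel") %in% a), logical(1))]
  funclasses <- c("missense", "nonsense", "frameshift", "splice", "inframe_indel")
  funp <- c(0.55, 0.12, 0.15, 0.08, 0.10)
  rows <- list()
  for (i in seq_len(nrow(cfg$mutation_genes))) {
    mg <- cfg$mutation_genes[i, ]
    grp <- dichotomize(cohort, mg$scheme)[ids]
    prob <- ifelse(is.na(grp), mg$prev_rest,
                   ifelse(grp == levels(grp)[1], mg$prev_main, mg$prev_rest))
    carrier <- runif(length(ids)) < prob
    if (!any(carrier)) next
    rows[[mg$gene]] <- data.frame(
      patient_id = ids[carrier], gene = mg$gene,
      variant_class = sample(funclasses, sum(carrier), replace = TRUE, prob = funp),
      coding = TRUE)
  }
  genes <- annotatedGenes(cfg$genome)$gene_id
  nbg <- stats::rpois(length(ids), background_rate)
  if (sum(nbg) > 0) {
    cls <- sample(c(funclasses, "synonymous", "other"), sum(nbg), replace = TRUE,
                  prob = c(funp * 0.5, 0.3, 0.2))
    rows[["background"]] <- data.frame(
      patient_id = rep(ids, nbg),
      gene = sample(genes, sum(nbg), replace = TRUE),
      variant_class = cls,
      coding = cls != "other" & runif(sum(nbg)) < 0.9)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Synthetic reference sequence for context counting
#'
#' A single random contig (default 120 kb) used as the coordinate space for
#' simulated SNVs; long enough that all 32 pyrimidine-strand trinucleotide
#' contexts occur thousands of times.
#'
#' @param length Contig length in bp.
#' @return Named \link[Biostrings]{DNAStringSet} with one contig
#'   \code{"ref1"}. Uses the current RNG state.
#' @export
toyReference <- function(length = 120000) {
  seq <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
               collapse = "")
  DNAStringSet(setNames(seq, "ref1"))
}

.context_index <- function(reference) {
  # positions (2..L-1) per pyrimidine-strand trinucleotide context
  seq_str <- as.character(reference[[1]])
  L <- nchar(seq_str)
  pos <- 2:(L - 1)
  tri <- substring(seq_str, pos - 1, pos + 1)
  ctr <- substring(tri, 2, 2)
  pur <- ctr %in% c("A", "G")
  tri[pur] <- .revcomp3(tri[pur])
  split(pos, tri)
}

#' Simulate per-sample SNV lists from a signature mixture
#'
#' For each WGS sample, exposure fractions over the signature catalog are
#' computed from the configured base + slope model on standardized
#' -log10(mid-induction MRD + 1e-6), channel counts are drawn multinomially
#' from the mixed profile, and each mutation is materialized at a reference
#' position whose trinucleotide matches its channel (on either strand), so
#' that context counting round-trips exactly.
#'
#' @param cohort An \linkS4class{MRDCohort}; samples are patients with a WGS
#'   assay.
#' @param cfg A \code{SimConfig}.
#' @param signatures A \linkS4class{SignatureCatalog} (default the synthetic
#'   catalog); must contain the signatures named in the model.
#' @param reference Reference from \code{\link{toyReference}}.
#' @return List with \code{snvs} (data.frame sample_id, chrom, pos, ref,
#'   alt), \code{exposures} (true fraction matrix, signatures x samples) and
#'   \code{n_mut}. Uses the current RNG state.
#' @export
simulateMutationCatalogs <- function(cohort, cfg,
                                     signatures = syntheticSignatureCatalog(),
                                     reference = toyReference()) {
  sm <- cfg$signature_model
  S <- profileMatrix(signatures)
  if (!all(names(sm$base) %in% colnames(S)))
    stop("signature model names absent from catalog")
  assays <- patientAssays(cohort)
  ids <- names(assays)[vapply(assays, function(a) "wgs" %in% a, logical(1))]
  mrd <- mrdValues(cohort, "mid")[ids]
  zl <- -log10(mrd + 1e-6)
  z <- if (sd(zl) > 0) (zl - mean(zl)) / sd(zl) else zl * 0
  noise_sd <- if (is.null(sm$noise_sd)) 0 else sm$noise_sd
  expo <- matrix(vapply(z, function(zi) {
    w <- pmax(0.01, sm$base + sm$slope * zi +
                rnorm(length(sm$base), 0, noise_sd))
    w / sum(w)
  }, numeric(length(sm$base))), nrow = length(sm$base))
  rownames(expo) <- names(sm$base); colnames(expo) <- ids
  idx <- .context_index(reference)
  contig <- names(reference)[1]
  seq_chars <- strsplit(as.character(reference[[1]]), "")[[1]]
  n_mut <- pmax(50, round(rlnorm(length(ids), sm$n_mut_meanlog, sm$n_mut_sdlog)))
  names(n_mut) <- ids
  ctx <- sbsContexts()
  ctx_tri <- paste0(substring(ctx, 1, 1), substring(ctx, 3, 3), substring(ctx, 7, 7))
  ctx_alt <- substring(ctx, 5, 5)
  snv_list <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    mix <- as.vector(S[, names(sm$base), drop = FALSE] %*% expo[, k])
    counts <- as.vector(rmultinom(1, n_mut[k], mix))
    tot <- sum(counts)
    pos <- integer(tot); alt <- character(tot); o <- 1L
    for (ch in which(counts > 0)) {
      m <- counts[ch]
      cand <- idx[[ctx_tri[ch]]]
      p <- cand[ceiling(runif(m) * length(cand))]
      a <- rep(ctx_alt[ch], m)
      pur <- seq_chars[p] %in% c("A", "G")
      a[pur] <- .complement[a[pur]]
      pos[o:(o + m - 1)] <- p
      alt[o:(o + m - 1)] <- a
      o <- o + m
    }
    snv_list[[k]] <- data.frame(sample_id = ids[k], chrom = contig, pos = pos,
                                ref = seq_chars[pos], alt = alt)
  }
  list(snvs = do.call(rbind, snv_list), exposures = expo, n_mut = n_mut)
}

#' Simulate a gene expression count matrix
#'
#' Negative-binomial counts per gene and RNA-seq sample. Gene baseline means
#' are log-normal; genes covered by a patient's deletion (gain) have their
#' mean scaled by 2^-dosage (2^+dosage); S-phase and G2M program genes have
#' their log2 mean shifted by a per-sample program activity, loading x
#' standardized -log10(MRD_mid + 1e-6) plus MRD-independent noise, making
#' the programs moderately anti-correlated with MRD.
#'
#' @param cohort An \linkS4class{MRDCohort}; samples are patients with an
#'   rnaseq assay.
#' @param segments Simulated CNV \code{GRanges} (for dosage).
#' @param cfg A \code{SimConfig}.
#' @return List with \code{counts} (genes x samples integer matrix),
#'   \code{gene_sets} (list S_PHASE, G2M) and \code{base_means}. Uses the
#'   current RNG state.
#' @export
simulateExpression <- function(cohort, segments, cfg) {
  em <- cfg$expression_model
  ann <- cfg$genome
  genes <- annotatedGenes(ann)
  assays <- patientAssays(cohort)
  ids <- names(assays)[vapply(assays, function(a) "rnaseq" %in% a, logical(1))]
  gl <- geneLoci(ann, expressed.only = FALSE)
  base <- rlnorm(length(gl), em$mean_log_mean, em$mean_log_sd)
  names(base) <- names(gl)
  # gene sets: expressed genes not under planted CNV regions
  planted <- GRanges(cfg$cnv_regions$chrom,
                     IRanges(cfg$cnv_regions$start + 1, cfg$cnv_regions$end))
  free <- names(gl)[genes$expressed & !overlapsAny(gl, planted)]
  sphase <- sample(free, em$set_size)
  sets <- list(S_PHASE = sphase,
               G2M = sample(setdiff(free, sphase), em$set_size))
  mrd <- mrdValues(cohort, "mid")[ids]
  zl <- -log10(mrd + 1e-6)
  z <- if (sd(zl) > 0) (zl - mean(zl)) / sd(zl) else zl * 0
  dels <- carrierMatrix(segments, gl, "del", patients = ids)
  gains <- carrierMatrix(segments, gl, "gain", patients = ids)
  mu <- matrix(rep(base, length(ids)), nrow = length(base),
               dimnames = list(names(base), ids))
  lfc <- em$dosage_effect * (t(gains) - t(dels))
  mu <- mu * 2^lfc
  prog_sd <- if (is.null(em$program_noise_sd)) 0 else em$program_noise_sd
  for (sname in names(sets)) {
    loading <- if (sname == "S_PHASE") em$sphase_loading else em$g2m_loading
    activity <- loading * z + rnorm(length(ids), 0, prog_sd)
    mu[sets[[sname]], ] <- mu[sets[[sname]], ] *
      2^matrix(rep(activity, each = length(sets[[sname]])),
               nrow = length(sets[[sname]]))
  }
  counts <- matrix(rnbinom(length(mu), mu = as.vector(mu), size = em$size),
                   nrow = nrow(mu), dimnames = dimnames(mu))
  list(counts = counts, gene_sets = sets, base_means = base)
}

#' Simulate CRISPR-screen ranking tables
#'
#' Uniformly random ranked gene lists per drug and direction with increasing
#' FDR along the ranking; no real association is planted (screen sets are
#' annotation, not phenotype).
#'
#' @param cfg A \code{SimConfig}.
#' @return data.frame(gene, drug, direction, rank, fdr). Uses the current
#'   RNG state.
#' @export
simulateScreens <- function(cfg) {
  genes <- annotatedGenes(cfg$genome)$gene_id
  n <- min(cfg$screen_n, length(genes))
  do.call(rbind, lapply(cfg$screen_drugs, function(dr)
    do.call(rbind, lapply(c("sensitizing", "resistance"), function(dir) {
      gs <- sample(genes, n)
      data.frame(gene = gs, drug = dr, direction = dir, rank = seq_len(n),
                 fdr = round(sort(runif(n, 0.001, 1)), 4))
    }))))
}

#' Simulate a complete cohort bundle
#'
#' Runs every generator stage under seeds derived deterministically from
#' \code{cfg$seed} (so any two runs with the same config are identical) and
#' optionally writes the bundle to disk in the formats the readers consume,
#' together with a truth file recording every planted parameter.
#'
#' @param cfg A \code{SimConfig}.
#' @param dir Optional output directory (created if needed); when given, the
#'   MRD table, per-assay segment TSVs, variant TSV, SNV TSV, reference
#'   FASTA, counts TSV, gene-set GMT, screen TSV and \code{truth.json} are
#'   written.
#' @return A list (the cohort bundle): \code{cohort}, \code{annotation},
#'   \code{segments}, \code{variants}, \code{snvs}, \code{reference},
#'   \code{exposures}, \code{counts}, \code{gene_sets}, \code{screens},
#'   \code{truth}.
#' @examples
#' bundle <- simulateCohort(simConfig(n_patients = 40, rnaseq_n = 10, seed = 7))
#' bundle$cohort
#' @export
simulateCohort <- function(cfg, dir = NULL) {
  validateSimConfig(cfg)
  set.seed(cfg$seed)
  ss <- sample.int(2^31 - 2, 7)
  set.seed(ss[1])
  mrd <- simulateMRD(cfg$n_patients, cfg$mrd_model)
  set.seed(ss[2])
  n <- cfg$n_patients
  draw_assays <- function() {
    a <- c("wgs", "array", "panel")[runif(3) < cfg$assay_props]
    if (!length(a)) "panel" else a
  }
  assay_list <- replicate(n, draw_assays(), simplify = FALSE)
  rna <- sample.int(n, min(cfg$rnaseq_n, n))
  assay_list[rna] <- lapply(assay_list[rna], c, "rnaseq")
  mrd$assays <- vapply(assay_list, paste, character(1), collapse = ",")
  cohort <- MRDCohort(mrd)
  set.seed(ss[3])
  segments <- simulateCNVs(cohort, cfg)
  set.seed(ss[4])
  variants <- simulateMutations(cohort, cfg)
  set.seed(ss[5])
  reference <- toyReference()
  cat_sim <- simulateMutationCatalogs(cohort, cfg, reference = reference)
  set.seed(ss[6])
  expr <- simulateExpression(cohort, segments, cfg)
  set.seed(ss[7])
  screens <- simulateScreens(cfg)
  truth <- list(
    seed = cfg$seed,
    n_patients = cfg$n_patients,
    group_sizes = lapply(c(mid = "mid", eoi = "eoi", eoc = "eoc"), function(tp)
      as.list(table(responseLabels(cohort, tp)))),
    cnv_regions = cfg$cnv_regions,
    mutation_genes = cfg$mutation_genes,
    signature_model = cfg$signature_model[c("base", "slope")],
    true_exposures = cat_sim$exposures,
    dosage_effect = cfg$expression_model$dosage_effect,
    sphase_loading = cfg$expression_model$sphase_loading,
    gene_sets = expr$gene_sets
  )
  bundle <- list(cohort = cohort, annotation = cfg$genome,
                 segments = segments, variants = variants,
                 snvs = cat_sim$snvs, reference = reference,
                 exposures = cat_sim$exposures,
                 counts = expr$counts, gene_sets = expr$gene_sets,
                 screens = screens, truth = truth)
  if (!is.null(dir)) writeCohortBundle(bundle, dir)
  bundle
}
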