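#' Default pipeline configuration
#'
#' @param out_dir Output directory.
#' @param seed Master seed for every stochastic stage.
#' @param input_dir Optional bundle directory (from
#'   \code{\link{writeCohortBundle}}); when NULL a cohort is simulated with
#'   \code{simulate} parameters.
#' @param simulate Named list of \code{\link{simConfig}} overrides.
#' @param B_cnv,B_score,B_screen Randomization counts for the CNV
#'   empirical-p, score permutation and random-gene-set tests.
#' @param min_cnv_len,max_blacklist_overlap,expression_floor Filter
#'   thresholds (see the stage functions).
#' @param stages Stages to run, in order.
#' @return Named list (a pipeline configuration).
#' @export
pipelineConfig <- function(out_dir, seed = 1, input_dir = NULL,
                           simulate = list(),
                           B_cnv = 1000, B_score = 1000, B_screen = 500,
                           min_cnv_len = 1e6, max_blacklist_overlap = 0.5,
                           expression_floor = 1,
                           stages = c("classify", "cnv", "variants",
                                      "signatures", "expression", "report")) {
  list(out_dir = out_dir, seed = seed, input_dir = input_dir,
       simulate = simulate, B_cnv = B_cnv, B_score = B_score,
       B_screen = B_screen, min_cnv_len = min_cnv_len,
       max_blacklist_overlap = max_blacklist_overlap,
       expression_floor = expression_floor, stages = stages)
}

.pipe_prepare_cnv <- function(bundle, config) {
  segs <- filterSegments(bundle$segments, bundle$annotation,
                         min_len_bp = config$min_cnv_len,
                         max_blacklist_overlap = config$max_blacklist_overlap)
  harmonizeAssays(segs, assays = patientAssays(bundle$cohort))
}

#' Run the full association pipeline
#'
#' Drives every analysis stage over a cohort bundle (simulated in place or
#' read from \code{input_dir}) and writes one TSV per result plus a JSON run
#' manifest carrying the seed and a hash of the configuration. All
#' randomness derives from \code{config$seed}, so a rerun with the same
#' configuration reproduces the result tables byte for byte. Outputs are
#' staged in a temporary directory and only moved into \code{out_dir} on
#' success.
#'
#' @param config A list from \code{\link{pipelineConfig}} or the path to a
#'   YAML file with the same fields.
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  defaults <- pipelineConfig(out_dir = config$out_dir)
  config <- utils::modifyList(defaults, config)
  if (!is.null(config$input_dir) && !dir.exists(config$input_dir))
    stop("input_dir does not exist: ", config$input_dir)

  set.seed(config$seed)
  ss <- sample.int(2^31 - 2, 8)

  bundle <- if (!is.null(config$input_dir)) {
    readCohortBundle(config$input_dir)
  } else {
    sim_args <- config$simulate
    sim_args$seed <- ss[1]
    simulateCohort(do.call(simConfig, sim_args))
  }

  staging <- file.path(tempfile("pipeline_"), "out")
  dir.create(staging, recursive = TRUE)
  files <- character()
  emit <- function(df, name) {
    .write_tsv(df, file.path(staging, name))
    files <<- c(files, name)
  }
  cohort <- bundle$cohort
  ann <- bundle$annotation

  if ("classify" %in% config$stages) {
    lab <- data.frame(patient_id = patientIDs(cohort))
    for (tp in c("mid", "eoi", "eoc"))
      lab[[paste0("response_", tp)]] <- as.character(responseLabels(cohort, tp))
    emit(lab, "response_labels.tsv")
  }

  harm <- NULL
  if (any(c("cnv", "variants", "expression") %in% config$stages))
    harm <- .pipe_prepare_cnv(bundle, config)

  if ("cnv" %in% config$stages) {
    set.seed(ss[2])
    loci <- geneLoci(ann, expressed.only = TRUE)
    res <- list()
    for (scheme in c("slow_vs_rest", "fast_vs_rest")) {
      grp <- dichotomize(cohort, scheme)
      for (ty in c("del", "gain")) {
        r <- cnvEmpiricalP(harm, loci, grp, ann, cnv_type = ty,
                           B = config$B_cnv)
        r$scheme <- scheme; r$cnv_type <- ty
        res[[paste(scheme, ty)]] <- r
      }
    }
    emit(do.call(rbind, res), "cnv_empirical_p.tsv")
    bins <- binLoci(ann, "chr12", 1e6)
    curves <- list()
    for (scheme in c("slow_vs_rest", "fast_vs_rest")) {
      grp <- dichotomize(cohort, scheme)
      for (ty in c("del", "gain")) {
        cm <- carrierMatrix(harm, bins, ty,
                            patients = unique(harm$patient_id))
        cv <- frequencyCurves(cm, grp)
        cv$scheme <- scheme; cv$cnv_type <- ty
        curves[[paste(scheme, ty)]] <- cv
      }
    }
    emit(do.call(rbind, curves), "cnv_curves_chr12.tsv")
  }

  if ("variants" %in% config$stages) {
    set.seed(ss[3])
    fvars <- filterFunctional(bundle$variants)
    prev <- list()
    for (scheme in c("slow_vs_rest", "mid_slow_vs_fast", "eoc_pos_vs_neg")) {
      grp <- dichotomize(cohort, scheme)
      r <- genePrevalenceTest(fvars, grp)
      r$scheme <- scheme
      prev[[scheme]] <- r
    }
    emit(do.call(rbind, prev), "mutation_prevalence.tsv")
    gl <- geneLoci(ann, expressed.only = FALSE)
    delcm <- carrierMatrix(harm, gl, "del",
                           patients = unique(harm$patient_id))
    grp <- dichotomize(cohort, "mid_slow_vs_fast")
    burden <- list()
    for (dr in unique(bundle$screens$drug)) {
      for (dir in c("sensitizing", "resistance")) {
        gs <- screenGeneSet(bundle$screens, dr, dir, "top100")
        b <- screenDeletionBurden(delcm, gs, grp)
        e <- screenSetEmpiricalP(delcm, gs, grp, B = config$B_screen)
        burden[[paste(dr, dir)]] <- data.frame(
          drug = dr, direction = dir, cutoff = "top100",
          rank_sum_p = b$rank_sum$p.value, any_hit_p = b$any_hit_p,
          median_a = b$median_by_group[1], median_b = b$median_by_group[2],
          observed_diff = e$observed, empirical_p = e$empirical_p)
      }
    }
    emit(do.call(rbind, c(burden, make.row.names = FALSE)),
         "screen_deletion_burden.tsv")
  }

  if ("signatures" %in% config$stages) {
    set.seed(ss[4])
    catal <- countContexts(bundle$snvs, bundle$reference)
    sigs <- syntheticSignatureCatalog()
    fit <- fitExposures(catal, sigs)
    emit(data.frame(sample_id = colnames(fit$fractions),
                    t(fit$fractions), residual = fit$residual,
                    check.names = FALSE),
         "signature_exposures.tsv")
    cors <- list()
    for (tp in c("mid", "eoi")) {
      r <- exposureMrdCorrelation(fit, cohort, tp)
      r$timepoint <- tp
      cors[[tp]] <- r
    }
    emit(do.call(rbind, cors), "signature_mrd_correlation.tsv")
  }

  if ("expression" %in% config$stages) {
    set.seed(ss[5])
    norm <- cpmLog2(bundle$counts)
    score_rows <- list()
    for (sname in names(bundle$gene_sets)) {
      sc <- geneSetScore(norm, bundle$gene_sets[[sname]], name = sname)
      for (tp in c("mid", "eoi")) {
        a <- scoreMrdAssociation(sc, cohort, tp, B = config$B_score)
        score_rows[[paste(sname, tp)]] <- data.frame(
          gene_set = sname, timepoint = tp, rho = a$rho, p = a$p,
          empirical_p = a$empirical_p, n = a$n)
      }
    }
    emit(do.call(rbind, c(score_rows, make.row.names = FALSE)),
         "gene_set_mrd.tsv")
    rna <- colnames(norm)
    gl <- geneLoci(ann, expressed.only = FALSE)
    delcm <- carrierMatrix(harm, gl, "del", patients = rna)
    gaincm <- carrierMatrix(harm, gl, "gain", patients = rna)
    cn <- cnStatusFromCarriers(delcm, gaincm)
    tests <- cnExpressionTest(norm, cn)
    emit(tests, "cn_expression.tsv")
    eoi3 <- responseLabels(cohort, "eoi")
    sel <- selectExpressedCnvGenes(norm, tests, eoi3[rna],
                                   floor = config$expression_floor)
    emit(data.frame(gene = sel), "cn_expression_selected_genes.tsv")
  }

  if ("report" %in% config$stages) {
    # merge the headline rows of every stage that ran into one table
    rows <- list()
    add <- function(stage, id, statistic, value, p) {
      rows[[length(rows) + 1]] <<- data.frame(
        stage = stage, id = id, statistic = statistic,
        value = value, p = p)
    }
    pick <- function(name) file.path(staging, name)
    if (file.exists(pick("cnv_empirical_p.tsv"))) {
      cnv <- read.delim(pick("cnv_empirical_p.tsv"))
      top <- head(cnv[order(cnv$empirical_p, -abs(cnv$observed)), ], 10)
      for (i in seq_len(nrow(top)))
        add("cnv", paste(top$locus[i], top$cnv_type[i], top$scheme[i]),
            "freq_diff", top$observed[i], top$empirical_p[i])
    }
    if (file.exists(pick("mutation_prevalence.tsv"))) {
      mut <- read.delim(pick("mutation_prevalence.tsv"))
      hits <- mut[mut$p < significanceThresholds()$dna, ]
      for (i in seq_len(nrow(hits)))
        add("mutation", paste(hits$gene[i], hits$scheme[i]),
            "prop_diff", hits$prop_a[i] - hits$prop_b[i], hits$p[i])
    }
    if (file.exists(pick("signature_mrd_correlation.tsv"))) {
      sg <- read.delim(pick("signature_mrd_correlation.tsv"))
      for (i in seq_len(nrow(sg)))
        add("signature", paste(sg$signature[i], sg$timepoint[i]),
            "spearman_rho", sg$rho[i], sg$p[i])
    }
    if (file.exists(pick("gene_set_mrd.tsv"))) {
      gs <- read.delim(pick("gene_set_mrd.tsv"))
      for (i in seq_len(nrow(gs)))
        add("gene_set", paste(gs$gene_set[i], gs$timepoint[i]),
            "spearman_rho", gs$rho[i], gs$empirical_p[i])
    }
    if (length(rows))
      emit(do.call(rbind, rows), "report_summary.tsv")
  }

  manifest <- list(
    package = "MRDassoc",
    version = as.character(utils::packageVersion("MRDassoc")),
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    B = list(cnv = config$B_cnv, score = config$B_score,
             screen = config$B_screen),
    stages = config$stages,
    files = files
  )
  jsonlite::write_json(manifest, file.path(staging, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, "manifest.json")

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  for (f in files)
    file.copy(file.path(staging, f), file.path(config$out_dir, f),
              overwrite = TRUE)
  unlink(dirname(staging), recursive = TRUE)
  invisible(manifest)
}
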