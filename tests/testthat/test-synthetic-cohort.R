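# A reduced config keeps generator tests fast; statistical checks use the
# default study-scale config where group proportions matter.
small_cfg <- function(seed = 101, ...) {
  simConfig(n_patients = 60, rnaseq_n = 15, seed = seed, ...)
}

test_that("the toy annotation is internally consistent", {
  ann <- toyGenomeAnnotation()
  expect_setequal(names(chromLengths(ann)), c("chr9", "chr12", "chr21"))
  arms <- chromArms(ann)
  expect_equal(length(arms), 6L)
  g <- annotatedGenes(ann)
  expect_gt(length(g), 200)
  expect_gt(sum(g$expressed), 150)
  expect_true(all(c("ETV6", "KRAS", "SYK", "TP53") %in% g$gene_id))
  expect_true(validObject(ann))
})

test_that("an infeasible config fails validation before generating anything", {
  bad_regions <- data.frame(name = "huge", chrom = "chr21", start = 0,
                            end = 48e6, cnv_type = "del",
                            prev_fast = 0.2, prev_intermediate = 0.2,
                            prev_slow = 0.2)
  expect_error(simConfig(cnv_regions = bad_regions), "arm")
  expect_error(simConfig(mutation_genes = data.frame(
    gene = "NOT_A_GENE", scheme = "slow_vs_rest", prev_main = 0.1,
    prev_rest = 0.01)), "absent")
})

test_that("the same config and seed reproduce a byte-identical bundle", {
  d1 <- file.path(tempdir(), "bundle_a")
  d2 <- file.path(tempdir(), "bundle_b")
  unlink(c(d1, d2), recursive = TRUE)
  simulateCohort(small_cfg(), dir = d1)
  simulateCohort(small_cfg(), dir = d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_setequal(f1, f2)
  for (f in f1)
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7),
                     info = f)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("MRD marginals hit the configured group proportions", {
  cfg <- simConfig(seed = 202)
  b <- simulateCohort(cfg)
  tb <- table(responseLabels(b$cohort, "eoi"))
  n <- cfg$n_patients
  # binomial 95% CI around the targeted proportions
  targets <- c(fast = 116 / 356, intermediate = 156 / 356, slow = 84 / 356)
  for (g in names(targets)) {
    phat <- tb[[g]] / n
    se <- sqrt(targets[g] * (1 - targets[g]) / n)
    expect_lt(abs(phat - targets[g]), 1.96 * se + 0.01)
  }
  # timepoints share a latent severity
  mid <- mrdValues(b$cohort, "mid"); eoi <- mrdValues(b$cohort, "eoi")
  expect_gt(spearmanCor(mid, eoi)$rho, 0.3)
  expect_true(all(mid >= 0 & mid <= 1))
})

test_that("a degenerate MRD model produces all-fast, all-negative patients", {
  model <- list(mid = list(p0 = 1, meanlog = -5, sdlog = 1),
                eoi = list(p0 = 1, meanlog = -5, sdlog = 1),
                eoc = list(p0 = 1, meanlog = -5, sdlog = 1),
                latent_cor = 0.5)
  set.seed(1)
  mrd <- simulateMRD(50, model)
  expect_true(all(mrd$mrd_mid == 0 & mrd$mrd_eoi == 0 & mrd$mrd_eoc == 0))
})

test_that("simulated segments respect genome bounds and planted prevalences", {
  cfg <- simConfig(seed = 303)
  b <- simulateCohort(cfg)
  segs <- b$segments
  sl <- chromLengths(b$annotation)
  expect_true(all(end(segs) <= sl[as.character(seqnames(segs))]))
  expect_true(all(start(segs) >= 1))
  eoi <- responseLabels(b$cohort, "eoi")
  harm <- harmonizeAssays(segs, assays = patientAssays(b$cohort))
  planted <- harm[harm$region == "del12p"]
  carr_fast <- length(unique(planted$patient_id[
    planted$patient_id %in% names(eoi)[eoi == "fast"]]))
  n_fast <- sum(eoi == "fast")
  se <- sqrt(0.45 * 0.55 / n_fast)
  expect_lt(abs(carr_fast / n_fast - 0.45), 1.96 * se + 0.02)
})

test_that("zero background rate leaves only planted segments", {
  cfg <- small_cfg(seed = 404, background_cnv_rate = 0)
  b <- simulateCohort(cfg)
  expect_true(all(b$segments$region != "background"))
})

test_that("simulated SNVs match the reference and round-trip through refitting", {
  cfg <- small_cfg(seed = 505)
  b <- simulateCohort(cfg)
  seq_string <- as.character(b$reference[[1]])
  expect_true(all(substring(seq_string, b$snvs$pos, b$snvs$pos) == b$snvs$ref))
  # pure-SBS2 model: refit contribution >= 0.95
  cfg2 <- small_cfg(seed = 606,
                    signature_model = list(
                      base = c(SBS2 = 1), slope = c(SBS2 = 0),
                      noise_sd = 0, n_mut_meanlog = log(2000),
                      n_mut_sdlog = 0.1))
  b2 <- simulateCohort(cfg2)
  cat2 <- countContexts(b2$snvs, b2$reference)
  fit <- fitExposures(cat2, syntheticSignatureCatalog())
  expect_true(all(fit$fractions["SBS2", ] >= 0.95))
})

test_that("expression counts are non-negative with planted dosage visible", {
  cfg <- simConfig(seed = 707)
  b <- simulateCohort(cfg)
  expect_true(all(b$counts >= 0))
  expect_setequal(names(b$gene_sets), c("S_PHASE", "G2M"))
  expect_length(b$gene_sets$S_PHASE, cfg$expression_model$set_size)
  # deleted genes show reduced expression in carriers
  norm <- cpmLog2(b$counts)
  harm <- harmonizeAssays(b$segments, assays = patientAssays(b$cohort))
  gl <- geneLoci(b$annotation, expressed.only = FALSE)
  rna <- colnames(norm)
  dels <- carrierMatrix(harm, gl, "del", patients = rna)
  kras_del <- rna[dels[, "KRAS"] == 1]
  kras_neut <- rna[dels[, "KRAS"] == 0]
  expect_gt(length(kras_del), 3)
  expect_lt(mean(norm["KRAS", kras_del]), mean(norm["KRAS", kras_neut]))
})

test_that("screen rankings are valid and cover each drug and direction", {
  b <- simulateCohort(small_cfg(seed = 808))
  expect_silent(validateScreen(b$screens))
  expect_setequal(unique(b$screens$drug),
                  c("daunorubicin", "dexamethasone", "vincristine"))
  expect_equal(nrow(b$screens) %% 2, 0)
})

test_that("the truth file records every planted parameter", {
  d <- file.path(tempdir(), "bundle_truth")
  unlink(d, recursive = TRUE)
  b <- simulateCohort(small_cfg(seed = 909), dir = d)
  truth <- jsonlite::read_json(file.path(d, "truth.json"))
  expect_equal(truth$seed, 909)
  expect_equal(length(truth$cnv_regions), 4)
  expect_true("sphase_loading" %in% names(truth))
  expect_equal(sort(unlist(truth$gene_sets$S_PHASE)),
               sort(b$gene_sets$S_PHASE))
  unlink(d, recursive = TRUE)
})
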