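test_that("the 96 channels are in canonical order with expected structure", {
  ctx <- sbsContexts()
  expect_length(ctx, 96L)
  expect_false(anyDuplicated(ctx) > 0)
  expect_equal(ctx[1], "A[C>A]A")
  expect_equal(ctx[17], "A[C>G]A")
  expect_equal(ctx[96], "T[T>G]T")
  expect_true(all(substring(ctx, 3, 3) %in% c("C", "T")))
})

test_that("context counting bins pyrimidine and purine variants correctly", {
  ref <- DNAStringSet(c(ref1 = "AACATGCA"))
  # pos 4 (A C A context around? seq: A A C A T G C A): pos 3 is C with A_A
  snvs <- data.frame(sample_id = "S1", chrom = "ref1",
                     pos = c(3, 6), ref = c("C", "G"), alt = c("A", "T"))
  cat <- countContexts(snvs, ref)
  expect_equal(unname(cat["A[C>A]A", "S1"]), 1L)
  # G>T at T_G_C reverse-complements to G[C>A]A
  expect_equal(unname(cat["G[C>A]A", "S1"]), 1L)
  expect_equal(sum(cat), 2)
})

test_that("empty variant list gives a zero catalog and edge cases are skipped", {
  ref <- DNAStringSet(c(ref1 = "ACGTACGT"))
  cat0 <- countContexts(data.frame(sample_id = character(), chrom = character(),
                                   pos = integer(), ref = character(),
                                   alt = character()), ref, samples = "S1")
  expect_equal(sum(cat0), 0)
  snvs <- data.frame(sample_id = "S1", chrom = c("ref1", "ref1", "chrX"),
                     pos = c(1, 3, 5), ref = c("A", "G", "C"),
                     alt = c("T", "A", "T"))
  expect_warning(cat1 <- countContexts(snvs, ref), "skipped")
  err <- attr(cat1, "errors")
  expect_setequal(err$reason, c("contig edge", "unknown contig"))
  expect_equal(sum(cat1), 1)
  # ref mismatch reported with position
  bad <- data.frame(sample_id = "S1", chrom = "ref1", pos = 2, ref = "G",
                    alt = "A")
  expect_warning(cat2 <- countContexts(bad, ref), "skipped")
  expect_equal(attr(cat2, "errors")$reason, "ref mismatch")
  expect_equal(attr(cat2, "errors")$pos, 2L)
})

test_that("channel conservation and strand symmetry hold on random variants", {
  set.seed(14)
  ref <- toyReference(5000)
  seq_chars <- strsplit(as.character(ref[[1]]), "")[[1]]
  pos <- sample(2:4999, 300)
  refb <- seq_chars[pos]
  alt <- vapply(refb, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1))
  snvs <- data.frame(sample_id = "S1", chrom = "ref1", pos = pos,
                     ref = refb, alt = alt)
  cat1 <- countContexts(snvs, ref)
  expect_equal(sum(cat1), 300)
  # complement every variant and the reference: identical catalog
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref_rc <- DNAStringSet(setNames(as.character(
    reverseComplement(ref[[1]])), "ref1"))
  L <- 5000
  snvs_rc <- data.frame(sample_id = "S1", chrom = "ref1", pos = L - pos + 1,
                        ref = comp[refb], alt = comp[alt])
  cat2 <- countContexts(snvs_rc, ref_rc)
  expect_equal(cat1, cat2)
})

test_that("context counting matches the per-variant manual oracle", {
  set.seed(77)
  ref <- toyReference(20000)
  seq_string <- as.character(ref[[1]])
  pos <- sample(2:19999, 100)
  refb <- substring(seq_string, pos, pos)
  alt <- vapply(refb, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1))
  snvs <- data.frame(sample_id = "S1", chrom = "ref1", pos = pos,
                     ref = refb, alt = alt)
  cat <- countContexts(snvs, ref)
  expected <- table(vapply(seq_along(pos), function(i)
    manual_channel(seq_string, pos[i], refb[i], alt[i]), character(1)))
  for (ch in names(expected))
    expect_equal(unname(cat[ch, "S1"]), unname(as.integer(expected[ch])))
  expect_equal(sum(cat), 100)
})

test_that("signature catalog class validates and reorders rows", {
  sigs <- syntheticSignatureCatalog()
  m <- profileMatrix(sigs)
  expect_equal(colSums(m), setNames(rep(1, 5), signatureNames(sigs)))
  shuffled <- m[sample(96), ]
  sc <- SignatureCatalog(shuffled)
  expect_equal(profileMatrix(sc), m)
  bad <- m; bad[1, 1] <- bad[1, 1] + 0.5
  expect_error(SignatureCatalog(bad), "sum to 1")
})

test_that("NNLS refitting recovers pure and mixed exposures", {
  sigs <- syntheticSignatureCatalog()
  S <- profileMatrix(sigs)
  pure <- 1000 * S[, "SBS2"]
  fit <- fitExposures(pure, sigs)
  expect_equal(unname(fit$fractions["SBS2", 1]), 1.0, tolerance = 1e-9)
  expect_lt(fit$residual[1], 1e-9)
  # noiseless 60/40 mixture lies in the non-negative span: residual ~ 0
  mix <- 5000 * (0.6 * S[, "SBS1"] + 0.4 * S[, "SBS13"])
  fit2 <- fitExposures(mix, sigs)
  expect_equal(unname(fit2$fractions["SBS1", 1]), 0.6, tolerance = 1e-8)
  expect_lt(fit2$residual[1], 1e-9)
  # Poisson-noised mixture recovered within 0.05
  set.seed(5)
  noisy <- rpois(96, mix)
  fit3 <- fitExposures(noisy, sigs)
  expect_lt(abs(fit3$fractions["SBS1", 1] - 0.6), 0.05)
  expect_lt(abs(fit3$fractions["SBS13", 1] - 0.4), 0.05)
})

test_that("degenerate catalogs are handled: zero counts and off-span targets", {
  sigs <- syntheticSignatureCatalog()
  z <- rep(0, 96)
  fit <- fitExposures(z, sigs)
  expect_true(fit$empty[1])
  expect_true(all(fit$weights == 0))
  # a catalog concentrated on one T>A channel is far from all signatures
  odd <- rep(0, 96); odd[which(sbsContexts() == "A[T>A]A")] <- 1000
  fit2 <- fitExposures(odd, sigs)
  expect_true(all(fit2$weights >= 0))
  expect_gt(fit2$residual[1], 0.3)
})

test_that("exposure-MRD correlation recovers a monotone relationship", {
  coh <- MRDCohort(data.frame(patient_id = paste0("S", 1:6),
                              mrd_mid = c(0.3, 0.2, 0.1, 0.05, 0.01, 0.001),
                              mrd_eoi = 0, mrd_eoc = 0))
  fr <- matrix(c(seq(0.1, 0.6, 0.1)), 1, 6,
               dimnames = list("SBS2", paste0("S", 1:6)))
  res <- exposureMrdCorrelation(fr, coh, "mid")
  expect_equal(res$rho, -1)
  expect_error(exposureMrdCorrelation(fr[, 1:2, drop = FALSE], coh, "mid"),
               ">= 3")
})
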