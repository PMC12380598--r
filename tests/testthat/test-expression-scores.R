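test_that("CPM log2 normalization follows its definition and is scale-invariant", {
  m <- matrix(c(0, 10, 90, 50, 0, 50), 3, 2,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  norm <- cpmLog2(m)
  expect_equal(norm["g1", "s1"], 0)
  expect_equal(norm["g2", "s1"], log2(1 + 1e6 * 10 / 100))
  # single-gene sample: count = library size
  single <- matrix(c(100), 1, 1, dimnames = list("g", "s"))
  expect_equal(cpmLog2(single)[1, 1], log2(1 + 1e6))
  m2 <- m; m2[, 2] <- m2[, 2] * 7
  expect_equal(cpmLog2(m2)[, 2], norm[, 2])
  expect_error(cpmLog2(matrix(0, 2, 1)), "library size")
})

test_that("gene-set scores detect an upshift and are seed-reproducible", {
  set.seed(10)
  mat <- matrix(rnorm(400 * 40, 5, 0.3), 400, 40,
                dimnames = list(sprintf("g%03d", 1:400), paste0("s", 1:40)))
  members <- sample(rownames(mat), 25)
  mat[members, c("s1", "s2")] <- mat[members, c("s1", "s2")] + 1
  sc <- geneSetScore(mat, members, seed = 3)
  expect_equal(unname(sc["s1"]), 1, tolerance = 0.15)
  expect_equal(unname(sc["s2"]), 1, tolerance = 0.15)
  expect_lt(max(abs(sc[paste0("s", 3:40)])), 0.5)
  expect_identical(sc, geneSetScore(mat, members, seed = 3))
  expect_error(geneSetScore(mat, c("nope1", "nope2"), name = "mySet"), "mySet")
  expect_warning(geneSetScore(mat, c(members[1:3], "nope"), seed = 1),
                 "absent")
})

test_that("random matched sets center at zero on exchangeable data", {
  set.seed(22)
  mat <- matrix(rnorm(300 * 10, 5), 300, 10,
                dimnames = list(sprintf("g%03d", 1:300), paste0("s", 1:10)))
  means <- vapply(1:50, function(s) {
    set.seed(s)
    members <- sample(rownames(mat), 20)
    mean(geneSetScore(mat, members, seed = s + 1000))
  }, numeric(1))
  expect_lt(abs(mean(means)), 0.05)
})

test_that("score/MRD association recovers monotone dependence with minimal empirical p", {
  coh <- MRDCohort(data.frame(patient_id = paste0("s", 1:10),
                              mrd_mid = seq(0.001, 0.5, length.out = 10),
                              mrd_eoi = 0, mrd_eoc = 0))
  scores <- setNames(seq(10, 1), paste0("s", 1:10))
  res <- scoreMrdAssociation(scores, coh, "mid", B = 199, seed = 4)
  expect_equal(res$rho, -1)
  expect_equal(res$empirical_p, 1 / 200)
  res2 <- scoreMrdAssociation(scores, coh, "mid", B = 199, seed = 4)
  expect_identical(res, res2)
})

test_that("CN status combination follows the fixed vocabulary", {
  ids <- paste0("P", 1:3); genes <- c("g1", "g2")
  del <- matrix(c(1L, 0L, 1L, 0L, 0L, 0L), 3, 2, dimnames = list(ids, genes))
  gain <- matrix(c(0L, 1L, 1L, 0L, 0L, 0L), 3, 2, dimnames = list(ids, genes))
  st <- cnStatusFromCarriers(del, gain)
  expect_equal(st["g1", ], c(P1 = "del", P2 = "gain", P3 = "unknown"))
  expect_equal(unname(st["g2", ]), rep("neutral", 3))
})

test_that("copy-number dosage effects on expression are detected with correct sign", {
  set.seed(33)
  n <- 25
  genes <- sprintf("g%02d", 1:40)
  samples <- sprintf("s%02d", 1:(2 * n))
  base <- rlnorm(40, log(200), 0.5)
  mu <- matrix(rep(base, 2 * n), 40, 2 * n, dimnames = list(genes, samples))
  cn <- matrix("neutral", 40, 2 * n, dimnames = list(genes, samples))
  affected <- genes[1:20]
  mu[affected, 1:n] <- mu[affected, 1:n] / 2  # one-copy loss
  cn[affected, 1:n] <- "del"
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 8), 40, 2 * n,
                   dimnames = dimnames(mu))
  tests <- cnExpressionTest(cpmLog2(counts), cn)
  hit <- tests$gene[tests$q < 0.1 & tests$effect < 0]
  expect_gte(length(intersect(hit, affected)), 18)
  expect_true(all(tests$alteration[tests$gene %in% affected] == "del"))
  # unaffected genes are skipped (single CN state)
  expect_true(all(attr(tests, "skipped")$reason == "single CN state"))
})

test_that("permuted CN labels give approximately uniform p-values", {
  set.seed(44)
  n <- 25
  genes <- sprintf("g%02d", 1:60)
  samples <- sprintf("s%02d", 1:(2 * n))
  counts <- matrix(rnbinom(60 * 2 * n, mu = 300, size = 8), 60, 2 * n,
                   dimnames = list(genes, samples))
  cn <- matrix("neutral", 60, 2 * n, dimnames = list(genes, samples))
  cn[, sample(2 * n, n)] <- "del"  # labels independent of expression
  tests <- cnExpressionTest(cpmLog2(counts), cn)
  ks <- suppressWarnings(ks.test(tests$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("gene selection drops lowly expressed and CN-discordant genes", {
  mat <- matrix(c(5, 5, 5, 5,   # gA: expressed
                  0.1, 0.2, 0.1, 0.2),  # gB: low everywhere
                2, 4, byrow = TRUE,
                dimnames = list(c("gA", "gB"), paste0("s", 1:4)))
  groups <- mk_groups(paste0("s", 1:4), c("g1", "g1", "g2", "g2"))
  tests <- data.frame(gene = c("gA", "gB", "gC"),
                      alteration = c("del", "del", "del"),
                      effect = c(-1, -1, -1), p = 0.01, q = 0.01)
  sel <- selectExpressedCnvGenes(mat, tests, groups, floor = 1)
  expect_equal(as.character(sel), "gA")
  reasons <- attr(sel, "excluded")
  expect_match(reasons[["gB"]], "lowly")
  # discordant: deleted gene with higher expression
  tests2 <- data.frame(gene = "gA", alteration = "del", effect = +1,
                       p = 0.01, q = 0.01)
  sel2 <- selectExpressedCnvGenes(mat, tests2, groups, floor = 1)
  expect_length(sel2, 0)
  expect_match(attr(sel2, "excluded")[["gA"]], "conflicts")
})
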