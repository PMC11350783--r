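test_that("text PLINK round trip preserves calls, map and missingness", {
  calls <- matrix(c(0L, 1L, 2L,
                    2L, NA, 0L), nrow = 3,
                  dimnames = list(c("x1", "x2", "x3"), NULL))
  g <- toy_geno(calls, a1 = c("A", "C"), a2 = c("G", "T"))
  prefix <- file.path(withr::local_tempdir(), "toy")
  write_plink(g, prefix, format = "ped")
  g2 <- read_plink(prefix, format = "ped")
  expect_equal(unname(g2$calls), unname(g$calls))
  expect_equal(g2$animal_ids, g$animal_ids)
  expect_equal(g2$map$pos, g$map$pos)
  expect_true(is.na(g2$calls["x2", 2]))  # "0 0" genotype -> missing
})

test_that("bed and ped encodings of the same data load identically", {
  set.seed(42)
  calls <- hwe_calls(17, 9, seed = 5)  # odd n exercises byte padding
  calls[sample(length(calls), 10)] <- NA
  g <- toy_geno(calls)
  dir <- withr::local_tempdir()
  write_plink(g, file.path(dir, "t"), format = "ped")
  write_plink(g, file.path(dir, "t"), format = "bed")
  gp <- read_plink(file.path(dir, "t"), format = "ped")
  gb <- read_plink(file.path(dir, "t"), format = "bed")
  # text reader counts the minor allele; flip where conventions differ
  cb <- gb$calls
  flip <- gb$map$a1 != gp$map$a1
  cb[, flip] <- 2L - cb[, flip]
  expect_equal(unname(gp$calls), unname(cb))
  expect_equal(gp$map$pos, gb$map$pos)
})

test_that("merge_panels intersects SNPs, flips alleles, stacks animals", {
  callsA <- matrix(c(0L, 1L, 2L, 0L, 1L, 1L), nrow = 2,
                   dimnames = list(c("a1", "a2"), NULL))
  gA <- toy_geno(callsA, a1 = rep("A", 3), a2 = rep("B", 3))
  callsB <- matrix(c(2L, 1L, 0L, 2L), nrow = 2,
                   dimnames = list(c("b1", "b2"), NULL))
  mapB <- data.frame(snp = c("snp001", "snp002"), chrom = "1",
                     pos = c(1000L, 2000L),
                     a1 = c("B", "A"), a2 = c("A", "B"))
  gB <- genotype_set(callsB, mapB)
  m <- merge_panels(gA, gB)
  expect_equal(ncol(m$calls), 2L)       # intersection only
  expect_equal(nrow(m$calls), 4L)
  # snp001 flipped in panel B: counted allele A
  expect_equal(unname(m$calls[c("b1", "b2"), "snp001"]), c(0L, 1L))
  expect_equal(unname(m$calls[c("b1", "b2"), "snp002"]), c(0L, 2L))

  expect_error(merge_panels(gA, gA), "share animals")
  gC <- toy_geno(matrix(0L, 2, 1, dimnames = list(c("c1", "c2"), NULL)))
  gC$map$snp <- "other"
  expect_error(merge_panels(gA, gC), "no common")
})

test_that("irreconcilable alleles are dropped with a warning", {
  gA <- toy_geno(matrix(c(0L, 1L), 2, 1,
                        dimnames = list(c("a1", "a2"), NULL)),
                 a1 = "A", a2 = "B")
  gB <- toy_geno(matrix(c(2L, 1L), 2, 1,
                        dimnames = list(c("b1", "b2"), NULL)),
                 a1 = "C", a2 = "D")
  expect_error(expect_warning(merge_panels(gA, gB), "irreconcilable"),
               "no reconcilable")
})

test_that("call-rate QC keeps the boundary and removes below it", {
  # 20 animals: 1 missing call = rate 0.95 kept; 2 missing = 0.90 removed
  calls <- matrix(1L, 20, 3)
  rownames(calls) <- sprintf("an%02d", 1:20)
  calls[1, 2] <- NA
  calls[1:2, 3] <- NA
  g <- toy_geno(calls)
  suppressMessages(g2 <- qc_call_rate(g, 0.95))
  expect_equal(g2$map$snp, c("snp001", "snp002"))
  expect_equal(attr(g2, "n_removed"), 1L)

  # staircase missingness 0..9 of 20 -> kept iff <= 1 missing
  stair <- matrix(1L, 20, 10)
  rownames(stair) <- sprintf("st%02d", 1:20)
  for (j in 1:10) if (j > 1) stair[seq_len(j - 1L), j] <- NA
  gs <- toy_geno(stair)
  suppressMessages(kept <- qc_call_rate(gs, 0.95))
  expect_equal(ncol(kept$calls), 2L)
  allmiss <- stair
  allmiss[1, ] <- NA  # every SNP now has at least one missing call
  expect_error(suppressMessages(qc_call_rate(toy_geno(allmiss), 1)),
               "every SNP")
})

test_that("center_matrix centres, mean-imputes and flags monomorphs", {
  calls <- cbind(c(0L, 1L, 2L), c(2L, 2L, 0L), c(NA, NA, NA), c(1L, NA, 1L))
  rownames(calls) <- c("u", "v", "w")
  g <- toy_geno(calls)
  Z <- center_matrix(g)
  expect_equal(unname(Z[, 1]), c(-1, 0, 1))
  expect_equal(unname(Z[, 2]), c(2 / 3, 2 / 3, -4 / 3))
  expect_equal(sum(Z[, 2]), 0)
  expect_equal(unname(Z[, 3]), c(0, 0, 0))
  expect_true(attr(Z, "monomorphic")[3])
  expect_equal(unname(Z[2, 4]), 0)  # missing call imputed to the mean
})

test_that("g_matrix matches the single-SNP oracle and weight scaling", {
  g <- toy_geno(matrix(c(0L, 1L, 2L), 3, 1,
                       dimnames = list(c("u", "v", "w"), NULL)))
  Z <- center_matrix(g)
  G <- g_matrix(Z, 1, g$p_hat)
  expect_equal(unclass(G),
               matrix(c(2, 0, -2, 0, 0, 0, -2, 0, 2), 3),
               ignore_attr = TRUE)
  # doubling all weights then renormalizing to mean 1 changes nothing
  G2 <- g_matrix(Z, (2 * 1) / mean(2 * 1), g$p_hat)
  expect_equal(unclass(G2), unclass(G), ignore_attr = TRUE)
  mono <- toy_geno(matrix(2L, 3, 1))
  expect_error(g_matrix(center_matrix(mono), 1, mono$p_hat), "monomorphic")
})

test_that("mean diagonal of G is near 1 for unrelated HWE animals", {
  calls <- hwe_calls(50, 200, seed = 9)
  g <- toy_geno(calls)
  G <- g_matrix(center_matrix(g), rep(1, 200), g$p_hat)
  expect_lt(abs(mean(diag(G)) - 1), 0.1)  # founders: mean F = 0
})

test_that("columns of Z sum to ~0 without missingness (property)", {
  calls <- hwe_calls(40, 100, seed = 13)
  Z <- center_matrix(toy_geno(calls))
  expect_lt(max(abs(colSums(Z))), 1e-8 * nrow(Z))
})

test_that("blend_tune: identity cases and moment matching", {
  ped <- as_ped_table(random_ped_df(30L, seed = 2))
  ids <- ped$animal[1:5]
  A22m <- a22(ped, ids)
  expect_equal(unclass(blend_tune(rel_matrix(unclass(A22m), "G"), A22m,
                                  alpha = 0.5)),
               unclass(A22m), ignore_attr = TRUE, tolerance = 1e-12)
  set.seed(1)
  Gr <- crossprod(matrix(rnorm(50), 10, 5)) / 10 * 3 + 0.2
  dimnames(Gr) <- dimnames(A22m)
  G <- rel_matrix(Gr, "G")
  expect_equal(unclass(blend_tune(G, A22m, alpha = 1, tune = FALSE)),
               unclass(G), ignore_attr = TRUE)
  tuned <- blend_tune(G, A22m, alpha = 1, tune = TRUE)
  expect_equal(mean(diag(tuned)), mean(diag(A22m)), tolerance = 1e-10)
  off <- row(tuned) != col(tuned)
  expect_equal(mean(tuned[off]), mean(unclass(A22m)[off]),
               tolerance = 1e-10)
  expect_error(blend_tune(G, A22m, alpha = 0), "alpha")
})

test_that("blending keeps G invertible", {
  # low-rank G from few SNPs over many animals
  calls <- hwe_calls(30, 5, seed = 21)
  g <- toy_geno(calls)
  G <- g_matrix(center_matrix(g), rep(1, 5), g$p_hat)
  ped <- as_ped_table(data.frame(animal = rownames(calls),
                                 sire = NA_character_,
                                 dam = NA_character_))
  A22m <- a22(ped, rownames(calls))
  Gb <- blend_tune(G, A22m, alpha = 0.95, tune = TRUE)
  ev <- eigen(unclass(Gb), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), (1 - 0.95) * 1 - 1e-8)  # lambda_min(A22) = 1 here
})

test_that("QC and panel merging commute on aligned missingness", {
  set.seed(33)
  callsA <- hwe_calls(20, 8, seed = 31)
  callsB <- hwe_calls(20, 8, seed = 32)
  rownames(callsB) <- sprintf("bn%02d", 1:20)
  # same cells missing in both panels' shared SNPs
  miss <- matrix(runif(160) < 0.08, 20, 8)
  callsA[miss] <- NA
  callsB[miss] <- NA
  gA <- toy_geno(callsA)
  gB <- toy_geno(callsB)
  m_then_qc <- suppressMessages(qc_call_rate(merge_panels(gA, gB), 0.95))
  qc_then_m <- suppressMessages(
    merge_panels(qc_call_rate(gA, 0.95), qc_call_rate(gB, 0.95)))
  expect_equal(m_then_qc$map$snp, qc_then_m$map$snp)
  expect_equal(m_then_qc$calls[, m_then_qc$map$snp],
               qc_then_m$calls[, qc_then_m$map$snp])
})

test_that("relationship matrices export as square CSV with id header", {
  calls <- hwe_calls(6, 20, seed = 35)
  g <- toy_geno(calls)
  G <- g_matrix(center_matrix(g), rep(1, 20), g$p_hat)
  f <- withr::local_tempfile(fileext = ".csv")
  write_rel_csv(G, f)
  back <- read.csv(f, check.names = FALSE)
  expect_equal(back$id, rownames(G))
  expect_equal(as.matrix(back[, -1]), unclass(G), ignore_attr = TRUE,
               tolerance = 1e-12)
})
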