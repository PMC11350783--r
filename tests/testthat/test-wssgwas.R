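test_that("backsolve recovers effects exactly in the single-SNP case", {
  g <- toy_geno(matrix(c(0L, 1L, 2L), 3, 1,
                       dimnames = list(c("u", "v", "w"), NULL)))
  Z <- center_matrix(g)
  G <- g_matrix(Z, 1, g$p_hat)   # rank 1: pseudo-inverse path
  truth <- 0.7
  u_hat <- as.numeric(Z %*% truth)
  ghat <- backsolve_snp_effects(Z, 1, G, u_hat, p_hat = g$p_hat)
  expect_equal(unname(ghat), truth, tolerance = 1e-10)
  expect_equal(unname(backsolve_snp_effects(Z, 1, G, rep(0, 3),
                                            p_hat = g$p_hat)), 0)
  expect_error(backsolve_snp_effects(Z, c(1, 1), G, u_hat,
                                     p_hat = g$p_hat), "weights_D")
})

test_that("backsolved effects reproduce GEBVs through Z (unblended G)", {
  calls <- hwe_calls(50, 300, seed = 17)
  g <- toy_geno(calls)
  Z <- center_matrix(g)
  G <- g_matrix(Z, rep(1, 300), g$p_hat)
  set.seed(1)
  u_hat <- as.numeric(unclass(G) %*% rnorm(50))  # any vector in range(G)
  ghat <- backsolve_snp_effects(Z, rep(1, 300), G, u_hat, p_hat = g$p_hat)
  expect_gt(cor(as.numeric(Z %*% ghat), u_hat), 0.99)
})

test_that("update_weights: normalization, ratios, floor, reset", {
  w <- update_weights(rep(0.2, 10), rep(0.3, 10))
  expect_equal(unname(w), rep(1, 10))
  g_one_big <- c(10, rep(1, 99))
  w2 <- g_one_big^2 * 2 * 0.3 * 0.7
  expect_equal(w2[1] / w2[2], 100)
  w2n <- update_weights(g_one_big, rep(0.3, 100))
  expect_equal(mean(w2n), 1)
  expect_equal(unname(w2n[1] / w2n[2]), 100, tolerance = 1e-12)
  # monomorphic SNP gets the floor
  w3 <- update_weights(c(1, 1), c(0.5, 0))
  expect_equal(unname(w3[2] * mean(pmax(c(1^2 * 2 * 0.25, 1e-8), 1e-8))),
               1e-8, tolerance = 1e-12)
  expect_warning(w4 <- update_weights(rep(0, 5), rep(0.2, 5)), "reset")
  expect_equal(unname(w4), rep(1, 5))
})

test_that("window_variance matches hand-computed toy cases", {
  # 2-SNP toy: Z columns (-1,0,1) and (0,0,0), g = (1,5)
  Z <- cbind(c(-1, 0, 1), c(0, 0, 0))
  rownames(Z) <- c("a", "b", "c")
  map <- data.frame(snp = c("s1", "s2"), chrom = c("1", "1"),
                    pos = c(100L, 200L))
  scan <- window_variance(Z, c(1, 5), map, sigma2_a = 1)
  expect_equal(scan$pct_var[1], var(c(-1, 0, 1)) * 100)
  expect_equal(scan$n_snps[1], 2L)

  # whole genome in one window: exactly 100% by definition
  calls <- hwe_calls(30, 50, seed = 19)
  g <- toy_geno(calls, pos = seq(1000L, by = 100L, length.out = 50L))
  Zc <- center_matrix(g)
  set.seed(2)
  gh <- rnorm(50, 0, 0.05)
  s2a <- var(as.numeric(Zc %*% gh))
  scan2 <- window_variance(Zc, gh, g$map, s2a)
  expect_equal(scan2$pct_var[1], 100)

  # zero effects -> all windows 0
  scan3 <- window_variance(Zc, rep(0, 50), g$map, s2a)
  expect_true(all(scan3$pct_var == 0))
  expect_true(all(scan3$pct_var >= 0))
  expect_error(window_variance(Zc, gh, g$map, 0), "positive")
})

test_that("window percentage is invariant to reversing SNPs in a window", {
  calls <- hwe_calls(25, 20, seed = 23)
  g <- toy_geno(calls, pos = seq(1000L, by = 50L, length.out = 20L))
  Z <- center_matrix(g)
  set.seed(3)
  gh <- rnorm(20)
  s1 <- window_variance(Z, gh, g$map, 1)
  rev_idx <- rev(seq_len(20))
  # reversed column order, positions re-sorted ascending -> same windows
  g2 <- toy_geno(calls[, rev_idx],
                 pos = seq(1000L, by = 50L, length.out = 20L))
  Z2 <- center_matrix(toy_geno(calls))[, , drop = FALSE]
  expect_equal(window_variance(Z, gh, g$map, 1)$pct_var[1],
               s1$pct_var[1])
})

test_that("select_regions: strict threshold, merging, chromosomes", {
  scan <- data.frame(chrom = c("1", "1", "1", "2"),
                     start_bp = c(100L, 500L, 5000L, 100L),
                     end_bp = c(900L, 1500L, 6000L, 800L),
                     pct_var = c(1.00, 2.0, 1.5, 3.0))
  scan$significant <- scan$pct_var > 1
  # pct exactly 1.00 is NOT selected
  reg <- select_regions(scan, 1)
  expect_equal(nrow(reg), 3L)
  expect_false(any(reg$start_bp == 100L & reg$chrom == "1"))
  # overlapping flagged windows merge with max pct
  scan2 <- data.frame(chrom = "3", start_bp = c(1L, 50L, 90L),
                      end_bp = c(60L, 120L, 200L),
                      pct_var = c(1.5, 2.5, 1.2))
  reg2 <- select_regions(scan2, 1)
  expect_equal(nrow(reg2), 1L)
  expect_equal(reg2$max_pct, 2.5)
  expect_equal(reg2$start_bp, 1L)
  expect_equal(reg2$end_bp, 200L)
  expect_equal(nrow(select_regions(scan[0, ], 1)), 0L)
})

test_that("manhattan_export TSV round-trips the scan values", {
  calls <- hwe_calls(20, 30, seed = 29)
  g <- toy_geno(calls, chrom = rep(c("1", "2"), each = 15),
                pos = rep(seq(1e5, by = 5e4, length.out = 15), 2))
  Z <- center_matrix(g)
  set.seed(4)
  scan <- window_variance(Z, rnorm(30, 0, 0.1), g$map, 0.5)
  out <- file.path(withr::local_tempdir(), "scan")
  paths <- manhattan_export(scan, out)
  expect_true(file.exists(paste0(out, ".tsv")))
  expect_true(file.exists(paste0(out, ".png")))
  back <- read.delim(paste0(out, ".tsv"))
  expect_equal(back$pct_var, scan$pct_var)
  expect_equal(back$significant, scan$significant)
})

test_that("run_wssgblup: round 1 is unweighted, runs are deterministic", {
  dat <- simulate_dataset(fast_sim_cfg(seed = 5,
                                       qtl_spec = data.frame(chrom = 1,
                                                             center_bp = 2e6,
                                                             frac = 0.4)))
  spec <- univ_spec()
  vc <- variance_components(0.3, 0.7, traits = "Y")
  r1 <- run_wssgblup(dat$ped, dat$geno, dat$pheno, spec, n_iter = 1,
                     vc = vc)
  expect_equal(unname(r1$weights_trace[[1]]),
               rep(1, ncol(dat$geno$calls)))
  r1b <- run_wssgblup(dat$ped, dat$geno, dat$pheno, spec, n_iter = 1,
                      vc = vc)
  expect_identical(r1$scan$pct_var, r1b$scan$pct_var)
  expect_identical(r1$snp_effects, r1b$snp_effects)
})

test_that("weighting concentrates variance on the QTL window", {
  cfg <- sim_config(n_founders = 100L, n_generations = 4L, n_snps = 1000L,
                    n_chromosomes = 5L, chrom_length_bp = 8e6,
                    traits = "Y", h2_targets = 0.3,
                    rg_matrix = matrix(1, 1, 1),
                    prevalence = list(c(0.82, 0.14, 0.04)),
                    pe_variance = 0, observed = "liability",
                    qtl_spec = data.frame(chrom = 2, center_bp = 4e6,
                                          frac = 0.4),
                    genotyped_fraction = 0.6, missing_call_rate = 0.01,
                    seed = 1001)
  dat <- simulate_dataset(cfg)
  spec <- univ_spec()
  r1 <- run_wssgblup(dat$ped, dat$geno, dat$pheno, spec, n_iter = 1,
                     reml_method = "ai")
  r2 <- run_wssgblup(dat$ped, dat$geno, dat$pheno, spec, n_iter = 2,
                     vc = r1$vc)
  ctr <- 4e6
  inwin <- r2$scan$chrom == "2" & r2$scan$start_bp <= ctr + 5e5 &
    r2$scan$end_bp >= ctr - 5e5
  i <- which(inwin)[which.max(r1$scan$pct_var[inwin])]
  rank1 <- rank(-r1$scan$pct_var)[i]
  rank2 <- rank(-r2$scan$pct_var)[i]
  expect_lte(rank2, rank1)
  expect_gt(max(r2$scan$pct_var[inwin]), max(r1$scan$pct_var[inwin]))
})
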