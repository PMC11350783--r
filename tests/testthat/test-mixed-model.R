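make_toy_pheno <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(animal = sprintf("P%04d", seq_len(n)),
             Y = rnorm(n),
             sex = sample(c("M", "F"), n, TRUE),
             age = sample(c("young", "adult"), n, TRUE),
             coat = sample(c("bay", "chestnut", "black", "grey"), n, TRUE),
             area = sample(c("ES", "EU", "NX", "SC"), n, TRUE),
             F = runif(n, 0, 0.1), stringsAsFactors = FALSE)
}

test_that("build_design: coding, column counts, PE incidence, errors", {
  ph <- make_toy_pheno(40)
  ids <- ph$animal
  spec <- univ_spec()
  d <- build_design(ph, spec, ids)
  # intercept + (2-1) + (2-1) + (4-1) + (4-1) + 1 covariate = 10
  expect_equal(ncol(d$X), 10L)
  expect_equal(qr(d$X)$rank, 10L)
  expect_equal(unname(colSums(d$Z)), rep(1, 40))
  expect_null(d$W)  # single records: PE dropped under "auto"
  expect_equal(abs(sum(d$X[, "F"])), 0, tolerance = 1e-12)  # centred

  # repeated records: W has one column per animal, two 1s for the repeat
  ph2 <- rbind(ph, ph[1, ])
  d2 <- build_design(ph2, spec, ids)
  expect_equal(dim(d2$W), c(41L, 40L))
  expect_equal(sum(d2$W[, 1]), 2)

  expect_error(build_design(ph, spec, ids[-1]), "absent from pedigree")
  spec2 <- model_spec("Y", factors = "sex",
                      factor_levels = list(sex = c("M")))
  expect_error(build_design(ph, spec2, ids), "unseen level")
})

test_that("solve_mme approaches OLS as additive variance vanishes", {
  ph <- make_toy_pheno(60, seed = 2)
  d <- build_design(ph, univ_spec(), ph$animal)
  H <- diag(60); dimnames(H) <- list(ph$animal, ph$animal)
  vc <- variance_components(G0 = 1e-12, R0 = 1, traits = "Y")
  fit <- solve_mme(d$X, d$Z, NULL, solve(H), vc, d$Y)
  ols <- qr.solve(d$X, ph$Y)
  expect_equal(unname(fit$b_hat[, 1]), unname(ols), tolerance = 1e-4)
  expect_lt(fit$mme_residual, 1e-8)
})

test_that("solve_mme shrinks by the heritability ratio when H = I", {
  n <- 50
  set.seed(3)
  y <- rnorm(n, 5, 1.5)
  ph <- data.frame(animal = sprintf("A%02d", 1:n), Y = y,
                   stringsAsFactors = FALSE)
  spec <- model_spec("Y")
  d <- build_design(ph, spec, ph$animal)
  s2a <- 0.4; s2e <- 0.6
  vc <- variance_components(s2a, s2e, traits = "Y")
  Hinv <- diag(n); dimnames(Hinv) <- list(ph$animal, ph$animal)
  fit <- solve_mme(d$X, d$Z, NULL, Hinv, vc, d$Y)
  k <- s2a / (s2a + s2e)
  expect_equal(unname(fit$a_hat[, 1]),
               k * (y - fit$b_hat[1, 1]), tolerance = 1e-8)
})

test_that("solve_mme agrees with the dense GLS oracle", {
  ped <- as_ped_table(random_ped_df(60L, seed = 10))
  ph <- make_toy_pheno(60, seed = 4)
  ph$animal <- ped$animal
  d <- build_design(ph, univ_spec(), ped$animal)
  A <- unclass(a_matrix(ped))
  vc <- variance_components(0.5, 1.2, traits = "Y")
  fit <- solve_mme(d$X, d$Z, NULL, a_inverse(ped), vc, d$Y)
  # independent route: GLS on V = Z A Z' s2a + I s2e
  V <- d$Z %*% A %*% t(d$Z) * 0.5 + diag(60) * 1.2
  Vi <- solve(V)
  b <- solve(t(d$X) %*% Vi %*% d$X, t(d$X) %*% Vi %*% ph$Y)
  a <- 0.5 * A %*% t(d$Z) %*% Vi %*% (ph$Y - d$X %*% b)
  expect_equal(unname(fit$b_hat[, 1]), unname(b[, 1]), tolerance = 1e-6)
  expect_equal(unname(fit$a_hat[, 1]), unname(a[, 1]), tolerance = 1e-6)
})

test_that("rank-deficient fixed effects are named in the error", {
  ph <- make_toy_pheno(30, seed = 5)
  ph$dup <- as.numeric(ph$sex == "M")  # aliased with sex dummy
  spec <- model_spec("Y", factors = "sex", covariates = "dup")
  Hinv <- diag(30); dimnames(Hinv) <- list(ph$animal, ph$animal)
  d0 <- list()
  expect_error(
    reml(ph, spec, Hinv, method = "em", max_iter = 2),
    "confounded")
})

test_that("EM-REML trace is monotone and AI agrees with EM", {
  dat <- simulate_dataset(fast_sim_cfg(n_founders = 80L, seed = 3))
  Ainv <- as.matrix(a_inverse(dat$ped))
  em <- suppressWarnings(reml(dat$pheno, univ_spec(), Ainv, method = "em",
                              max_iter = 300, tol = 1e-7))
  expect_true(all(diff(em$m2ll_trace) <= 1e-8))
  ai <- reml(dat$pheno, univ_spec(), Ainv, method = "ai")
  expect_true(ai$converged)
  expect_lt(abs(ai$vc$G0[1, 1] - em$vc$G0[1, 1]), 0.02)
  expect_lt(abs(ai$vc$R0[1, 1] - em$vc$R0[1, 1]), 0.02)
  expect_equal(nrow(ai$a_hat), nrow(dat$ped))  # GEBV for every animal
})

test_that("REML estimates are invariant to relabeling animals", {
  dat <- simulate_dataset(fast_sim_cfg(seed = 20))
  Ainv <- as.matrix(a_inverse(dat$ped))
  f1 <- reml(dat$pheno, univ_spec(), Ainv, method = "ai")
  perm <- sample(nrow(dat$ped))
  Ainv2 <- Ainv[perm, perm]
  ph2 <- dat$pheno[sample(nrow(dat$pheno)), ]
  f2 <- reml(ph2, univ_spec(), Ainv2, method = "ai")
  expect_equal(f1$vc$G0, f2$vc$G0, tolerance = 1e-4)
  expect_equal(f1$vc$R0, f2$vc$R0, tolerance = 1e-4)
  expect_equal(f1$a_hat[rownames(f2$a_hat), 1], f2$a_hat[, 1],
               tolerance = 1e-4)
})

test_that("null simulation drives the additive variance to the boundary", {
  cfg <- fast_sim_cfg(n_founders = 80L, seed = 31)
  cfg$h2_targets <- 0
  dat <- simulate_dataset(cfg)
  expect_equal(dat$truth$realized_sigma2_a[[1]], 0)
  fit <- suppressWarnings(reml(dat$pheno, univ_spec(),
                               as.matrix(a_inverse(dat$ped)),
                               method = "ai", max_iter = 100))
  expect_lt(fit$vc$G0[1, 1], 0.02 * fit$vc$R0[1, 1])
})

test_that("bivariate REML with missing traits runs and stays finite", {
  cfg <- fast_sim_cfg(seed = 44, traits = c("T1", "T2"),
                      h2_targets = c(0.25, 0.3),
                      rg_matrix = matrix(c(1, 0.6, 0.6, 1), 2),
                      prevalence = list(c(0.8, 0.15, 0.05),
                                        c(0.8, 0.15, 0.05)))
  dat <- simulate_dataset(cfg)
  ph <- dat$pheno
  set.seed(1)
  ph$T2[sample(nrow(ph), 40)] <- NA  # trait-wise missingness
  spec <- model_spec(c("T1", "T2"), factors = c("sex", "age"),
                     covariates = "F")
  expect_message(
    fit <- suppressWarnings(reml(ph, spec, as.matrix(a_inverse(dat$ped)),
                                 method = "ai", max_iter = 60)),
    "complete")  # AI falls back to EM
  expect_true(all(is.finite(fit$vc$G0)))
  expect_true(all(eigen(fit$vc$G0)$values > 0))
  expect_true(all(is.finite(fit$h2)))
})

test_that("PE variance is recovered from repeated records", {
  set.seed(7)
  n <- 150; reps <- 3
  ids <- sprintf("R%03d", 1:n)
  a <- rnorm(n, 0, sqrt(0.3))
  pe <- rnorm(n, 0, sqrt(0.3))
  ph <- data.frame(animal = rep(ids, each = reps),
                   Y = rep(a + pe, each = reps) + rnorm(n * reps, 0,
                                                        sqrt(0.4)),
                   stringsAsFactors = FALSE)
  spec <- model_spec("Y", pe = TRUE)
  Hinv <- diag(n); dimnames(Hinv) <- list(ids, ids)
  fit <- suppressWarnings(reml(ph, spec, Hinv, method = "ai",
                               max_iter = 200))
  expect_lt(abs(fit$vc$P0[[1]] - 0.3), 0.15)
  expect_lt(abs(fit$vc$R0[1, 1] - 0.4), 0.1)
})

test_that("heritability and genetic correlation arithmetic", {
  vc <- variance_components(G0 = 0.61, R0 = 1.55, traits = "VN")
  expect_equal(round(unname(heritability(vc)), 2), 0.28)
  vc0 <- variance_components(G0 = 0, R0 = 1, traits = "t")
  expect_equal(unname(heritability(vc0)), 0)
  vc5 <- variance_components(G0 = 2, R0 = 2, traits = "t")
  expect_equal(unname(heritability(vc5)), 0.5)
  expect_error(heritability(variance_components(0, 0, traits = "t")),
               "zero total")

  G0 <- matrix(c(0.4, 0.3, 0.3, 0.5), 2)
  vc2 <- variance_components(G0, diag(2), traits = c("a", "b"))
  expect_equal(genetic_correlation(vc2, "a", "b"), 0.3 / sqrt(0.2),
               tolerance = 1e-12)
  expect_equal(genetic_correlation(vc2, "a", "a"), 1)
  G0z <- matrix(c(0.4, 0, 0, 0.5), 2)
  expect_equal(genetic_correlation(variance_components(G0z, diag(2),
                                                       traits = c("a", "b")),
                                   "a", "b"), 0)
})
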