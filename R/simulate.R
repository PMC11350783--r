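#' Simulation configuration
#'
#' Default configuration of the synthetic-data generator. The defaults state
#' a desk-scale world modelled on a Spanish horse-breed vitiligo study
#' design: three genetically correlated traits scored 1-9 on a heavily
#' zero-inflated ordinal scale, moderate heritabilities, a multi-generation
#' pedigree, and a downsampled dense SNP panel.
#'
#' @param n_founders Founder animals; default 100.
#' @param n_generations Discrete generations after the founders; default 5.
#' @param offspring_per_mating Offspring per mating pair; default 2.
#' @param prop_sires Fraction of males of a generation used as sires;
#'   default 0.25 (sires reused across matings).
#' @param n_snps SNP count; default 2000.
#' @param n_chromosomes Chromosome count; default 5 (desk-scale stand-in for
#'   the 31 equine autosomes + X).
#' @param chrom_length_bp Chromosome length; default 1.5e7, giving ~27
#'   SNPs/Mb at the default SNP count — the marker density of a ~60K
#'   equine panel (about 25 SNPs per Mb), so 1-Mb windows hold realistic
#'   SNP counts.
#' @param founder_maf_range Uniform range for founder minor-allele
#'   frequencies; default c(0.05, 0.5).
#' @param qtl_spec Data frame with columns \code{chrom},
#'   \code{center_bp}, \code{frac} (fraction of additive variance); default
#'   three QTLs totalling 30\%. Each QTL is realized as a cluster of
#'   \code{snps_per_qtl} causal SNPs within 0.5 Mb of its centre (the
#'   generator has no LD; the cluster stands in for an LD block).
#' @param snps_per_qtl Causal SNPs per QTL cluster; default 5.
#' @param polygenic_mode \code{"markers"} (default): the polygenic
#'   remainder is carried by small effects at every non-QTL SNP, so the
#'   panel tags the whole additive variance as the single-step model
#'   assumes; \code{"pedigree"}: a marker-independent polygene transmitted
#'   through the pedigree with Mendelian sampling.
#' @param traits Trait names; default VE, VM, VN.
#' @param h2_targets Liability heritabilities; default c(0.17, 0.13, 0.28).
#' @param pe_variance Permanent-environment variance fractions; default 0
#'   (single lifetime record).
#' @param rg_matrix Target genetic correlations between traits; default the
#'   observed horse vitiligo structure (VE-VM 0.55, VE-VN 0.52, VM-VN 0.79).
#' @param prevalence Per-trait target category prevalences (absent, slight,
#'   severe) used to place liability thresholds; defaults are the VE/VM/VN
#'   zero-inflation levels (e.g. 0.82/0.14/0.04 for the nostril-like trait).
#' @param observed \code{"score"} for 1-9 ordinal output via liability
#'   thresholds, \code{"liability"} for the raw continuous liability.
#' @param fixed_effect_spec List with per-factor effect sizes (see default).
#' @param genotyped_fraction Fraction of animals genotyped; default 0.5.
#' @param missing_call_rate Genotype missingness rate; default 0.01.
#' @param seed RNG seed; default 1.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n_founders = 100L, n_generations = 5L,
                       offspring_per_mating = 2L, prop_sires = 0.25,
                       n_snps = 2000L, n_chromosomes = 5L,
                       chrom_length_bp = 1.5e7,
                       founder_maf_range = c(0.05, 0.5),
                       qtl_spec = data.frame(chrom = c(1, 2, 3),
                                             center_bp = c(2.5e7, 5e7, 7.5e7),
                                             frac = c(0.10, 0.10, 0.10)),
                       snps_per_qtl = 5L,
                       polygenic_mode = c("markers", "pedigree"),
                       traits = c("VE", "VM", "VN"),
                       h2_targets = c(0.17, 0.13, 0.28),
                       pe_variance = rep(0, length(traits)),
                       rg_matrix = matrix(c(1, 0.55, 0.52,
                                            0.55, 1, 0.79,
                                            0.52, 0.79, 1), 3, 3),
                       prevalence = list(c(0.96, 0.03, 0.01),
                                         c(0.79, 0.17, 0.04),
                                         c(0.82, 0.14, 0.04)),
                       observed = c("score", "liability"),
                       fixed_effect_spec = list(
                         sex = c(M = 0, F = 0.05),
                         age = c(young = 0.2, adult = 0),
                         coat = c(bay = -0.1, chestnut = -0.3,
                                  black = -0.3, grey = 0),
                         area = c(ES = -0.1, EU = -0.05, NA_MX = -0.05,
                                  SCA = 0),
                         inbreeding_slope = 1.45),
                       genotyped_fraction = 0.5,
                       missing_call_rate = 0.01,
                       seed = 1L) {
  observed <- match.arg(observed)
  polygenic_mode <- match.arg(polygenic_mode)
  traits <- as.character(traits)  # YAML booleans (y/Y) arrive coerced
  M <- length(traits)
  rg_matrix <- as.matrix(rg_matrix)[seq_len(M), seq_len(M), drop = FALSE]
  if (max(abs(rg_matrix - t(rg_matrix))) > 1e-12 ||
      any(abs(diag(rg_matrix) - 1) > 1e-12))
    stop("rg_matrix must be symmetric with unit diagonal")
  if (min(eigen(rg_matrix, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-10)
    stop("rg_matrix must be positive semi-definite")
  if (any(h2_targets <= 0 & h2_targets != 0) || any(h2_targets >= 1))
    stop("h2_targets must lie in [0, 1)")
  if (sum(qtl_spec$frac) > 1) stop("QTL fractions exceed 1")
  if (length(h2_targets) != M || length(pe_variance) != M)
    stop("per-trait parameter lengths disagree")
  structure(list(n_founders = n_founders, n_generations = n_generations,
                 offspring_per_mating = offspring_per_mating,
                 prop_sires = prop_sires, n_snps = n_snps,
                 n_chromosomes = n_chromosomes,
                 chrom_length_bp = chrom_length_bp,
                 founder_maf_range = founder_maf_range,
                 qtl_spec = qtl_spec, snps_per_qtl = snps_per_qtl,
                 polygenic_mode = polygenic_mode, traits = traits,
                 h2_targets = h2_targets, pe_variance = pe_variance,
                 rg_matrix = rg_matrix, prevalence = prevalence,
                 observed = observed,
                 fixed_effect_spec = fixed_effect_spec,
                 genotyped_fraction = genotyped_fraction,
                 missing_call_rate = missing_call_rate, seed = seed),
            class = "sim_config")
}

#' Simulate a discrete-generation pedigree
#'
#' Founders form generation 0; each later generation is produced by random
#' mating among the previous generation, with a configurable fraction of
#' males used as sires (each sire serving several dams).
#'
#' @param cfg A [sim_config()].
#' @return A \code{ped_table} with an extra \code{generation} column and a
#'   \code{sex} attribute column.
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(cfg$n_founders >= 2L, cfg$n_generations >= 1L)
  set.seed(cfg$seed)
  id_counter <- 0L
  new_ids <- function(k) {
    out <- sprintf("ID%06d", id_counter + seq_len(k))
    id_counter <<- id_counter + k
    out
  }
  founders <- new_ids(cfg$n_founders)
  sex <- sample(rep_len(c("M", "F"), cfg$n_founders))
  df <- data.frame(animal = founders, sire = NA_character_,
                   dam = NA_character_, generation = 0L, sex = sex,
                   stringsAsFactors = FALSE)
  prev <- df
  for (g in seq_len(cfg$n_generations)) {
    males <- prev$animal[prev$sex == "M"]
    females <- prev$animal[prev$sex == "F"]
    if (length(males) < 1L || length(females) < 1L)
      stop("generation ", g, ": no available sires or dams")
    n_sires <- max(1L, round(length(males) * cfg$prop_sires))
    sires <- sample(males, n_sires)
    dams <- sample(females)  # every female mated once
    mate_sire <- sample(sires, length(dams), replace = TRUE)
    n_off <- length(dams) * cfg$offspring_per_mating
    kids <- new_ids(n_off)
    ksex <- sample(rep_len(c("M", "F"), n_off))
    gen <- data.frame(animal = kids,
                      sire = rep(mate_sire, each = cfg$offspring_per_mating),
                      dam = rep(dams, each = cfg$offspring_per_mating),
                      generation = g, sex = ksex, stringsAsFactors = FALSE)
    df <- rbind(df, gen)
    prev <- gen
  }
  ped <- as_ped_table(df[, c("animal", "sire", "dam")])
  extra <- df[match(ped$animal, df$animal), c("generation", "sex")]
  ped$generation <- extra$generation
  ped$sex <- extra$sex
  ped
}

#' Simulate genotypes by gene dropping
#'
#' Founder allele frequencies are drawn per SNP from the configured range;
#' offspring receive one allele per parent per SNP with independent
#' segregation across SNPs (no linkage beyond pedigree co-segregation).
#' Positions are laid uniformly along equal-length chromosomes. Missing
#' calls are injected at the configured rate.
#'
#' @param ped Sorted \code{ped_table} (from [simulate_pedigree()]).
#' @param cfg A [sim_config()].
#' @return A \code{genotype_set} over the genotyped subset of animals, with
#'   attribute \code{all_calls}: the complete (no-missing) gene-content
#'   matrix for every pedigree animal, used by the phenotype simulator.
#' @export
simulate_genotypes <- function(ped, cfg) {
  set.seed(cfg$seed + 1L)
  n <- nrow(ped)
  m <- cfg$n_snps
  maf <- stats::runif(m, cfg$founder_maf_range[1], cfg$founder_maf_range[2])
  per_chr <- diff(round(seq(0, m, length.out = cfg$n_chromosomes + 1L)))
  chrom <- rep(seq_len(cfg$n_chromosomes), per_chr)
  pos <- unlist(lapply(per_chr, function(k)
    sort(sample.int(cfg$chrom_length_bp - 1L, k)) ), use.names = FALSE)
  idx <- seq_len(n)
  names(idx) <- ped$animal
  si <- unname(idx[ped$sire])
  di <- unname(idx[ped$dam])
  calls <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    pat <- if (is.na(s)) stats::rbinom(m, 1L, maf)
           else stats::rbinom(m, 1L, calls[s, ] / 2)
    mat <- if (is.na(d)) stats::rbinom(m, 1L, maf)
           else stats::rbinom(m, 1L, calls[d, ] / 2)
    calls[i, ] <- pat + mat
  }
  rownames(calls) <- ped$animal
  map <- data.frame(snp = sprintf("SNP%05d", seq_len(m)),
                    chrom = as.character(chrom), pos = as.integer(pos),
                    a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  n_geno <- max(2L, round(n * cfg$genotyped_fraction))
  geno_ids <- sort(sample(ped$animal, n_geno))
  sub <- calls[geno_ids, , drop = FALSE]
  if (cfg$missing_call_rate > 0) {
    drop <- stats::runif(length(sub)) < cfg$missing_call_rate
    sub[drop] <- NA_integer_
  }
  g <- genotype_set(sub, map, animal_ids = geno_ids)
  # keep truth matrix aligned to the (chrom/pos-sorted) map of the set
  attr(g, "all_calls") <- calls[, match(g$map$snp, map$snp), drop = FALSE]
  g
}

#' Simulate correlated liability phenotypes and ordinal scores
#'
#' Builds per-trait liabilities \eqn{\ell = \mu + Xb + u + pe + e} with an
#' additive part \eqn{u} composed of QTL effects (placed at the configured
#' windows, scaled to their target fractions of additive variance against
#' the realized gene-content variance) plus a pedigree-transmitted polygenic
#' remainder; cross-trait additive effects follow the target genetic
#' correlation matrix. Total phenotypic variance is 1 per trait, so
#' \eqn{\sigma^2_a = h^2}. Scores 1-9 are produced by cutting the liability
#' at thresholds placed from the model's total variance to hit the target
#' absent/slight/severe prevalences, with the slight (2-5) and severe (6-9)
#' mass split geometrically across sub-scores.
#'
#' @param ped \code{ped_table} from [simulate_pedigree()] (needs
#'   \code{sex} column).
#' @param geno \code{genotype_set} from [simulate_genotypes()] (needs the
#'   \code{all_calls} attribute).
#' @param cfg A [sim_config()].
#' @return List with \code{pheno} (data frame: animal, trait scores, sex,
#'   age, coat, area, F) and \code{truth} (true breeding values, QTL table,
#'   realized h2 and prevalences).
#' @export
simulate_phenotypes <- function(ped, geno, cfg) {
  set.seed(cfg$seed + 2L)
  n <- nrow(ped)
  M <- length(cfg$traits)
  calls_all <- attr(geno, "all_calls")
  if (is.null(calls_all)) stop("genotype set lacks the all_calls truth")
  h2 <- cfg$h2_targets
  sig_a <- h2                       # total phenotypic variance = 1
  sig_p <- cfg$pe_variance
  sig_e <- 1 - sig_a - sig_p
  if (any(sig_e <= 0)) stop("h2 + PE variance must be < 1")
  f_qtl <- sum(cfg$qtl_spec$frac)
  if (f_qtl > 1) stop("QTL fractions exceed 1")
  Lrg <- t(chol(cfg$rg_matrix + diag(1e-10, M)))
  # --- QTL effects ---
  # A "QTL" is a small cluster of causal SNPs inside its 1-Mb window: the
  # generator has no linkage disequilibrium, so the cluster stands in for
  # the LD block a real causal variant would tag. The cluster's realized
  # contribution is rescaled to the stated fraction of additive variance.
  nq <- nrow(cfg$qtl_spec)
  snps_per_qtl <- cfg$snps_per_qtl
  if (is.null(snps_per_qtl)) snps_per_qtl <- 5L
  qtl_rows <- list()
  u_qtl <- matrix(0, n, M)
  beta <- NULL
  if (nq > 0L && f_qtl > 0) {
    for (k in seq_len(nq)) {
      ctr <- cfg$qtl_spec$center_bp[k]
      cand <- which(geno$map$chrom == as.character(cfg$qtl_spec$chrom[k]) &
                      abs(geno$map$pos - ctr) <= 5e5)
      if (length(cand) == 0L)
        cand <- which(geno$map$chrom == as.character(cfg$qtl_spec$chrom[k]))
      if (length(cand) == 0L) stop("no SNPs on QTL chromosome ",
                                   cfg$qtl_spec$chrom[k])
      cand <- cand[order(abs(geno$map$pos[cand] - ctr))]
      idx <- sort(utils::head(cand, snps_per_qtl))
      z <- as.numeric(Lrg %*% stats::rnorm(M))
      dirn <- sign(z); dirn[dirn == 0] <- 1
      contrib <- matrix(0, n, M)
      bk <- matrix(0, length(idx), M)
      for (jj in seq_along(idx)) {
        x <- calls_all[, idx[jj]]
        vx <- stats::var(x)
        if (vx <= 0) next
        b <- dirn * sqrt(cfg$qtl_spec$frac[k] * sig_a /
                           (vx * length(idx)))
        bk[jj, ] <- b
        contrib <- contrib + outer(x - mean(x), b)
      }
      # rescale the cluster so its realized variance hits the target
      for (t in seq_len(M)) {
        vt <- stats::var(contrib[, t])
        tgt <- cfg$qtl_spec$frac[k] * sig_a[t]
        if (vt > 0 && tgt > 0) {
          sc <- sqrt(tgt / vt)
          contrib[, t] <- contrib[, t] * sc
          bk[, t] <- bk[, t] * sc
        }
      }
      u_qtl <- u_qtl + contrib
      qtl_rows[[k]] <- data.frame(qtl = k, snp = geno$map$snp[idx],
                                  chrom = geno$map$chrom[idx],
                                  pos = geno$map$pos[idx],
                                  frac = cfg$qtl_spec$frac[k],
                                  stringsAsFactors = FALSE)
      beta <- rbind(beta, bk)
    }
  }
  # --- polygenic remainder ---
  # "markers" (default): small correlated effects at every non-QTL SNP, so
  # the marker panel carries the whole additive variance, as the
  # single-step model assumes of a dense panel. "pedigree": a
  # marker-independent polygene transmitted with Mendelian sampling - the
  # structure a pedigree-only (A matrix) analysis sees, but one a genomic
  # relationship matrix cannot tag.
  sig_poly <- sig_a * (1 - f_qtl)
  mode <- cfg$polygenic_mode
  if (is.null(mode)) mode <- "markers"
  u_poly <- matrix(0, n, M)
  if (any(sig_poly > 0)) {
    if (mode == "markers") {
      qtl_cols <- unique(unlist(lapply(qtl_rows, function(r)
        match(r$snp, geno$map$snp))))
      bg <- setdiff(seq_len(ncol(calls_all)), qtl_cols)
      raw <- matrix(stats::rnorm(length(bg) * M), length(bg), M) %*% t(Lrg)
      Xc <- scale(calls_all[, bg, drop = FALSE], center = TRUE,
                  scale = FALSE)
      u_poly <- Xc %*% raw
      # whiten and recolour so the realized polygenic covariance equals
      # its target exactly (the generator states its world; the pedigree
      # family structure otherwise leaves large noise in realized rg)
      active <- sig_poly > 0
      if (any(active)) {
        up <- u_poly[, active, drop = FALSE]
        up <- sweep(up, 2L, colMeans(up))
        Cw <- stats::cov(up)
        W <- backsolve(chol(Cw + diag(1e-12, ncol(up))),
                       diag(ncol(up)))
        tgt <- diag(sqrt(sig_poly[active]), sum(active)) %*%
          cfg$rg_matrix[active, active, drop = FALSE] %*%
          diag(sqrt(sig_poly[active]), sum(active))
        u_poly[, active] <- up %*% W %*% chol(tgt + diag(1e-12,
                                                         sum(active)))
        u_poly[, !active] <- 0
      }
    } else {
      Sig_poly <- diag(sqrt(sig_poly), M) %*% cfg$rg_matrix %*%
        diag(sqrt(sig_poly), M)
      Lp <- t(chol(Sig_poly + diag(1e-12, M)))
      idx <- seq_len(n)
      names(idx) <- ped$animal
      si <- unname(idx[ped$sire])
      di <- unname(idx[ped$dam])
      for (i in seq_len(n)) {
        if (is.na(si[i]) && is.na(di[i])) {
          u_poly[i, ] <- as.numeric(Lp %*% stats::rnorm(M))
        } else {
          par_mean <- numeric(M)
          Fs <- 0; Fd <- 0
          if (!is.na(si[i])) { par_mean <- par_mean + u_poly[si[i], ]
                               Fs <- ped$F[si[i]] }
          if (!is.na(di[i])) { par_mean <- par_mean + u_poly[di[i], ]
                               Fd <- ped$F[di[i]] }
          par_mean <- par_mean / 2        # unknown parent contributes 0
          msv <- 1 - 0.25 * (if (is.na(si[i])) 0 else 1 + Fs) -
            0.25 * (if (is.na(di[i])) 0 else 1 + Fd)
          u_poly[i, ] <- par_mean +
            sqrt(max(msv, 1e-8)) * as.numeric(Lp %*% stats::rnorm(M))
        }
      }
    }
  }
  u <- u_qtl + u_poly
  # --- fixed effects ---
  fe <- cfg$fixed_effect_spec
  sex <- if (!is.null(ped$sex)) ped$sex
         else sample(c("M", "F"), n, replace = TRUE)
  age <- sample(names(fe$age), n, replace = TRUE)
  coat <- sample(names(fe$coat), n, replace = TRUE,
                 prob = c(0.32, 0.02, 0.10, 0.56))
  area <- sample(names(fe$area), n, replace = TRUE,
                 prob = c(0.7, 0.1, 0.1, 0.1))
  xb <- fe$sex[sex] + fe$age[age] + fe$coat[coat] + fe$area[area] +
    fe$inbreeding_slope * (ped$F - mean(ped$F))
  # --- assemble liabilities ---
  # Realized components are pinned to their stated values: total additive
  # variance per trait is rescaled to sigma2_a exactly, and PE/residual
  # draws are orthogonalized against the other components and rescaled, so
  # realized h2 equals h2_targets by construction. Sampling noise belongs
  # to the estimation stage, not to the generator's truth.
  for (t in seq_len(M)) {
    vt <- stats::var(u[, t])
    if (vt > 0) u[, t] <- u[, t] * sqrt(sig_a[t] / vt)
  }
  exact_var <- function(x, v) {
    if (v <= 0) return(rep(0, length(x)))
    x <- x - mean(x)
    x * sqrt(v / stats::var(x))
  }
  orth <- function(x, basis) {
    qb <- qr(cbind(1, basis))
    qr.resid(qb, x)
  }
  pe_mat <- sapply(seq_len(M), function(t)
    exact_var(orth(stats::rnorm(n), u[, t]), max(sig_p[t], 0)))
  e_mat <- sapply(seq_len(M), function(t)
    exact_var(orth(stats::rnorm(n), cbind(u[, t], pe_mat[, t], xb)),
              sig_e[t]))
  liab <- matrix(xb, n, M) + u + pe_mat + e_mat
  colnames(liab) <- cfg$traits
  # --- thresholds -> scores ---
  scores <- liab
  prev_real <- vector("list", M)
  if (cfg$observed == "score") {
    var_xb <- stats::var(xb)
    for (t in seq_len(M)) {
      pv <- cfg$prevalence[[t]]
      # split slight over scores 2-5 and severe over 6-9, geometric decay
      w <- 0.5^(0:3); w <- w / sum(w)
      probs <- c(pv[1], pv[2] * w, pv[3] * w)
      cum <- cumsum(probs)[1:8]
      sd_t <- sqrt(1 + var_xb)
      cuts <- stats::qnorm(pmin(cum, 1 - 1e-12)) * sd_t + mean(xb)
      scores[, t] <- 1 + findInterval(liab[, t], cuts)
      prev_real[[t]] <- c(absent = mean(scores[, t] == 1),
                          slight = mean(scores[, t] >= 2 & scores[, t] <= 5),
                          severe = mean(scores[, t] >= 6))
    }
  } else {
    for (t in seq_len(M)) prev_real[[t]] <- NULL
  }
  pheno <- data.frame(animal = ped$animal, scores,
                      sex = sex, age = age, coat = coat, area = area,
                      F = ped$F, stringsAsFactors = FALSE)
  qtl_tab <- if (length(qtl_rows) > 0L) do.call(rbind, qtl_rows)
             else data.frame(qtl = integer(0), snp = character(0),
                             chrom = character(0), pos = integer(0),
                             frac = numeric(0))
  truth <- list(u = u, beta_qtl = beta, qtl = qtl_tab,
                qtl_windows = cfg$qtl_spec,
                realized_h2 = apply(u, 2, stats::var) /
                  apply(liab, 2, stats::var),
                realized_sigma2_a = apply(u, 2, stats::var),
                prevalence = prev_real,
                liability = liab)
  list(pheno = pheno, truth = truth)
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: pedigree, genotypes and phenotypes from one
#' configuration.
#'
#' @param cfg A [sim_config()].
#' @return List with \code{ped}, \code{geno}, \code{pheno}, \code{truth},
#'   \code{cfg}.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  ph <- simulate_phenotypes(ped, geno, cfg)
  list(ped = ped, geno = geno, pheno = ph$pheno, truth = ph$truth,
       cfg = cfg)
}
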