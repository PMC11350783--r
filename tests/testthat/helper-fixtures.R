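# Shared fixtures: all built in code, nothing read from disk.

# simple named pedigree data frame
toy_ped_df <- function() {
  data.frame(animal = c("A", "B", "C", "D", "E"),
             sire = c(NA, NA, "A", "A", "C"),
             dam = c(NA, NA, "B", "B", "D"),
             stringsAsFactors = FALSE)
}

# random valid pedigree of n animals: founders + random matings generation
# by generation; returns unsorted rows to exercise internal sorting
random_ped_df <- function(n, seed) {
  set.seed(seed)
  n_f <- max(4L, round(n / 4))
  ids <- sprintf("P%04d", seq_len(n))
  sire <- rep(NA_character_, n)
  dam <- rep(NA_character_, n)
  for (i in (n_f + 1L):n) {
    avail <- ids[seq_len(i - 1L)]
    pp <- sample(avail, 2L)
    sire[i] <- pp[1L]
    dam[i] <- pp[2L]
  }
  df <- data.frame(animal = ids, sire = sire, dam = dam,
                   stringsAsFactors = FALSE)
  df[sample.int(n), ]
}

# small genotype set with given calls matrix (animals x SNPs)
toy_geno <- function(calls, chrom = NULL, pos = NULL, a1 = NULL, a2 = NULL) {
  m <- ncol(calls)
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("an%02d", seq_len(nrow(calls)))
  map <- data.frame(snp = sprintf("snp%03d", seq_len(m)),
                    chrom = if (is.null(chrom)) rep("1", m) else chrom,
                    pos = if (is.null(pos)) seq_len(m) * 1000L else pos,
                    a1 = if (is.null(a1)) rep("A", m) else a1,
                    a2 = if (is.null(a2)) rep("B", m) else a2,
                    stringsAsFactors = FALSE)
  genotype_set(calls, map)
}

# HWE genotypes for unrelated animals
hwe_calls <- function(n, m, maf_range = c(0.1, 0.5), seed = 1) {
  set.seed(seed)
  p <- runif(m, maf_range[1], maf_range[2])
  calls <- sapply(p, function(pj) rbinom(n, 2L, pj))
  rownames(calls) <- sprintf("an%02d", seq_len(n))
  calls
}

# tiny default simulation config for fast tests; any sim_config argument
# can be overridden
fast_sim_cfg <- function(..., seed = 1) {
  args <- list(n_founders = 40L, n_generations = 3L, n_snps = 300L,
               n_chromosomes = 3L, chrom_length_bp = 4e6,
               traits = "Y", h2_targets = 0.3,
               rg_matrix = matrix(1, 1, 1),
               prevalence = list(c(0.82, 0.14, 0.04)),
               pe_variance = 0, observed = "liability",
               qtl_spec = data.frame(chrom = 1, center_bp = 5e7,
                                     frac = 0.2),
               genotyped_fraction = 0.5, missing_call_rate = 0,
               seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  if (!is.null(dots$traits) && is.null(dots$pe_variance))
    args$pe_variance <- rep(0, length(dots$traits))
  do.call(sim_config, args)
}

univ_spec <- function() {
  model_spec("Y", factors = c("sex", "age", "coat", "area"),
             covariates = "F")
}
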