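#' Run configuration
#'
#' Resolves a pipeline configuration from defaults, an optional YAML file
#' and direct overrides. Defaults follow the analysis constants of the
#' underlying study design: call-rate threshold 0.95, 1 Mb windows, 1\%
#' significance threshold, two weighting rounds.
#'
#' @param yaml_path Optional YAML file with configuration keys.
#' @param ... Direct overrides (highest precedence).
#' @return A \code{run_config} list.
#' @export
run_config <- function(yaml_path = NULL, ...) {
  cfg <- list(qc_threshold = 0.95, alpha = 0.95, tune = TRUE,
              n_iter = 2L, window_bp = 1e6, threshold_pct = 1,
              reml_method = "ai", reestimate_vc = FALSE,
              backsolve_blended = TRUE, trait = 1L, seed = 1L,
              traits = NULL, factors = c("sex", "age", "coat", "area"),
              covariates = "F", pe = "auto", animal_col = "animal",
              pedigree = NULL, genotypes = NULL, genotype_format = "ped",
              phenotypes = NULL, outdir = NULL, verbose = FALSE)
  if (!is.null(yaml_path)) {
    y <- tryCatch(yaml::read_yaml(yaml_path), error = function(e)
      stop("cannot parse YAML config '", yaml_path, "': ",
           conditionMessage(e)))
    cfg[names(y)] <- y
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  class(cfg) <- "run_config"
  cfg
}

#' Write a simulated dataset to disk
#'
#' Writes pedigree CSV, PLINK text and binary filesets, phenotype TSV, the
#' simulation truth as JSON, and a manifest (seed + config hash + files).
#'
#' @param cfg A [sim_config()].
#' @param outdir Output directory (created if absent).
#' @return Manifest list, invisibly; also written as
#'   \code{manifest.json}.
#' @export
cmd_simulate <- function(cfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dat <- simulate_dataset(cfg)
  ped_path <- file.path(outdir, "pedigree.csv")
  ped_out <- data.frame(animal = dat$ped$animal,
                        sire = ifelse(is.na(dat$ped$sire), "0",
                                      dat$ped$sire),
                        dam = ifelse(is.na(dat$ped$dam), "0", dat$ped$dam))
  utils::write.table(ped_out, ped_path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  write_plink(dat$geno, file.path(outdir, "genotypes"), format = "ped")
  write_plink(dat$geno, file.path(outdir, "genotypes"), format = "bed")
  ph_path <- file.path(outdir, "phenotypes.tsv")
  utils::write.table(dat$pheno, ph_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth_path <- file.path(outdir, "truth.json")
  truth <- dat$truth
  truth$u <- NULL; truth$liability <- NULL  # keep JSON small
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  files <- c("pedigree.csv", "genotypes.ped", "genotypes.map",
             "genotypes.bed", "genotypes.bim", "genotypes.fam",
             "phenotypes.tsv", "truth.json")
  cfg_plain <- unclass(cfg)
  cfg_plain$qtl_spec <- as.list(cfg_plain$qtl_spec)
  manifest <- list(seed = cfg$seed,
                   config_hash = config_hash(cfg_plain),
                   files = files)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

config_hash <- function(x) {
  s <- paste(utils::capture.output(utils::str(x, digits.d = 15)),
             collapse = "\n")
  # small rolling hash; provenance marker, not cryptographic
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full weighted single-step GWAS pipeline
#'
#' Reads pedigree, genotypes and phenotypes from the paths in the
#' configuration, applies call-rate QC, builds relationship matrices, fits
#' the model, runs the weighting rounds and the 1-Mb window scan, and
#' writes: fit report JSON, solutions TSV, SNP-effect TSV, windows TSV,
#' regions TSV, Manhattan figure and the resolved configuration.
#'
#' @param cfg A [run_config()] with \code{pedigree}, \code{genotypes},
#'   \code{phenotypes} and \code{outdir} set.
#' @return List of outputs (fit, scan, regions, paths), invisibly.
#' @export
cmd_run <- function(cfg) {
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    if (isTRUE(cfg$verbose))
      message(sprintf("[%s] done in %.2fs", name,
                      proc.time()[["elapsed"]] - t0))
    out
  }
  for (k in c("pedigree", "genotypes", "phenotypes", "outdir"))
    if (is.null(cfg[[k]])) stop("run_config lacks '", k, "'")
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  ped <- stage("pedigree", read_pedigree(cfg$pedigree))
  geno <- stage("genotypes", read_plink(cfg$genotypes,
                                        format = cfg$genotype_format))
  bad <- setdiff(geno$animal_ids, ped$animal)
  if (length(bad) > 0L)
    stop("genotyped animal(s) missing from pedigree: ",
         paste(utils::head(bad, 3L), collapse = ", "))
  pheno <- stage("phenotypes",
                 utils::read.table(cfg$phenotypes, header = TRUE, sep = "\t",
                                   stringsAsFactors = FALSE,
                                   colClasses = c(animal = "character")))
  geno <- stage("qc", qc_call_rate(geno, cfg$qc_threshold))
  traits <- cfg$traits
  if (is.null(traits))
    traits <- setdiff(names(pheno),
                      c(cfg$animal_col, cfg$factors, cfg$covariates))
  spec <- model_spec(traits, factors = cfg$factors,
                     covariates = cfg$covariates, pe = cfg$pe,
                     animal_col = cfg$animal_col)
  res <- stage("wssgblup",
               run_wssgblup(ped, geno, pheno, spec,
                            n_iter = cfg$n_iter, alpha = cfg$alpha,
                            tune = cfg$tune,
                            backsolve_blended = cfg$backsolve_blended,
                            reestimate_vc = cfg$reestimate_vc,
                            reml_method = cfg$reml_method,
                            window_bp = cfg$window_bp,
                            threshold_pct = cfg$threshold_pct,
                            trait = cfg$trait))
  paths <- list(
    fit = file.path(cfg$outdir, "fit.json"),
    solutions = file.path(cfg$outdir, "solutions.tsv"),
    snp_effects = file.path(cfg$outdir, "snp_effects.tsv"),
    windows = file.path(cfg$outdir, "windows"),
    regions = file.path(cfg$outdir, "regions.tsv"),
    config = file.path(cfg$outdir, "config_resolved.json"))
  fit <- res$fit
  vc <- res$vc
  M <- length(spec$traits)
  rg <- if (M > 1L) {
    pairs <- utils::combn(spec$traits, 2L)
    stats::setNames(
      apply(pairs, 2L, function(pp) genetic_correlation(vc, pp[1], pp[2])),
      apply(pairs, 2L, paste, collapse = "-"))
  } else NULL
  report <- list(traits = spec$traits,
                 sigma2_a = as.list(diag(vc$G0)),
                 sigma2_e = as.list(diag(vc$R0)),
                 sigma2_p = if (is.null(vc$P0)) NULL else as.list(vc$P0),
                 h2 = as.list(heritability(vc)),
                 rg = if (is.null(rg)) NULL else as.list(rg),
                 h2_se = "not available",
                 converged = if (is.null(fit$converged)) NA
                             else fit$converged,
                 n_regions = nrow(res$regions),
                 loglik_trace = fit$loglik_trace)
  jsonlite::write_json(report, paths$fit, auto_unbox = TRUE, digits = NA,
                       null = "null")
  sol <- data.frame(animal = rownames(fit$a_hat), fit$a_hat,
                    check.names = FALSE)
  utils::write.table(sol, paths$solutions, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(snp = names(res$snp_effects), g_hat = res$snp_effects,
               weight = res$weights_trace[[length(res$weights_trace)]]),
    paths$snp_effects, sep = "\t", quote = FALSE, row.names = FALSE)
  manhattan_export(res$scan, paths$windows,
                   threshold_pct = cfg$threshold_pct)
  utils::write.table(res$regions, paths$regions, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(unclass(cfg), paths$config, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(list(fit = fit, vc = vc, scan = res$scan,
                 regions = res$regions, report = report, paths = paths))
}

#' Summarize a finished pipeline run
#'
#' Prints a human-readable summary of a run directory: variance components,
#' heritabilities and genetic correlations, score prevalence (when the
#' phenotype file sits next to the outputs), and the significant regions.
#'
#' @param outdir Directory written by [cmd_run()].
#' @param pheno_path Optional phenotype TSV for the prevalence table.
#' @return The parsed report list, invisibly.
#' @export
cmd_report <- function(outdir, pheno_path = NULL) {
  fit_path <- file.path(outdir, "fit.json")
  if (!file.exists(fit_path))
    stop("no fit.json in '", outdir, "'; run the pipeline first")
  rep <- jsonlite::read_json(fit_path, simplifyVector = TRUE)
  cat("== Variance components and genetic parameters ==\n")
  tab <- data.frame(trait = rep$traits,
                    sigma2_a = unlist(rep$sigma2_a),
                    sigma2_e = unlist(rep$sigma2_e),
                    h2 = unlist(rep$h2))
  print(tab, row.names = FALSE, digits = 3)
  if (!is.null(rep$rg)) {
    cat("\nGenetic correlations:\n")
    print(data.frame(pair = names(rep$rg), rg = unlist(rep$rg)),
          row.names = FALSE, digits = 3)
  }
  if (!is.null(pheno_path) && file.exists(pheno_path)) {
    ph <- utils::read.table(pheno_path, header = TRUE, sep = "\t")
    cat("\n== Score prevalence (%) ==\n")
    for (tr in rep$traits) {
      if (tr %in% names(ph)) {
        v <- ph[[tr]]
        cat(sprintf("%s: absent %.2f  slight %.2f  severe %.2f\n", tr,
                    100 * mean(v == 1), 100 * mean(v >= 2 & v <= 5),
                    100 * mean(v >= 6)))
      }
    }
  }
  reg_path <- file.path(outdir, "regions.tsv")
  if (file.exists(reg_path)) {
    reg <- utils::read.table(reg_path, header = TRUE, sep = "\t")
    cat("\n== Significant genomic regions (>",
        "1% additive variance) ==\n", sep = "")
    if (nrow(reg) == 0L) cat("(none)\n") else
      print(reg, row.names = FALSE, digits = 3)
  }
  invisible(rep)
}
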