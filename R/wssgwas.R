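#' Back-solve SNP effects from genomic breeding values
#'
#' Converts the GEBVs of genotyped animals into per-SNP allele-substitution
#' effects by the back-solving identity
#' \deqn{\hat g = D Z' G^{-1} \hat u / k, \quad k = \sum_j 2 p_j (1 - p_j),}
#' where Z is the centred gene-content matrix, D the diagonal SNP-weight
#' matrix and G the genomic relationship matrix used in the evaluation. When
#' G is singular (e.g. more animals than informative SNPs, or an unblended
#' toy G) a pseudo-inverse is used.
#'
#' @param Z Centred gene-content matrix of the genotyped animals.
#' @param weights_D Per-SNP weights (diagonal of D).
#' @param G_used The genomic relationship matrix that entered the evaluation
#'   (blended or not, per configuration).
#' @param u_hat GEBVs of the genotyped animals, in \code{G_used} id order.
#' @param denom_k Scaling \eqn{\sum 2p(1-p)}; computed from \code{p_hat} if
#'   omitted.
#' @param p_hat Counted-allele frequencies (needed when \code{denom_k} is
#'   missing).
#' @return Named numeric vector of SNP effects, with attribute
#'   \code{iteration} = NA (set by [run_wssgblup()]).
#' @export
backsolve_snp_effects <- function(Z, weights_D, G_used, u_hat,
                                  denom_k = NULL, p_hat = NULL) {
  if (nrow(Z) != nrow(G_used) || nrow(Z) != length(u_hat))
    stop("dimension mismatch between Z, G_used and u_hat")
  if (ncol(Z) != length(weights_D))
    stop("weights_D length does not match SNP count")
  if (is.null(denom_k)) {
    if (is.null(p_hat)) stop("need denom_k or p_hat")
    denom_k <- sum(2 * p_hat * (1 - p_hat))
  }
  Gm <- unclass(G_used)
  Giu <- tryCatch({
    rc <- rcond(Gm)
    if (!is.finite(rc) || rc < 1e-10) stop("ill-conditioned")
    solve(Gm, u_hat)
  }, error = function(e) MASS::ginv(Gm) %*% u_hat)
  g <- weights_D * as.numeric(crossprod(Z, Giu)) / denom_k
  names(g) <- colnames(Z)
  g
}

#' Update SNP weights from SNP effects
#'
#' Quadratic re-weighting: \eqn{w_j = \hat g_j^2 \, 2 p_j (1 - p_j)},
#' floored at 1e-8 and normalized to mean 1 so the overall scale of G is
#' preserved across weighting rounds.
#'
#' @param g_hat Per-SNP effects.
#' @param p_hat Counted-allele frequencies.
#' @return Weight vector with mean 1.
#' @export
update_weights <- function(g_hat, p_hat) {
  stopifnot(length(g_hat) == length(p_hat))
  w <- g_hat^2 * 2 * p_hat * (1 - p_hat)
  if (all(w == 0)) {
    warning("all SNP effects zero; weights reset to 1")
    return(stats::setNames(rep(1, length(w)), names(g_hat)))
  }
  w <- pmax(w, 1e-8)
  w <- w / mean(w)
  names(w) <- names(g_hat)
  w
}

#' Sliding 1-Mb window scan of additive genetic variance
#'
#' One window is anchored at every SNP: the maximal run of consecutive SNPs
#' on the same chromosome whose position is within \code{window_bp - 1} bp of
#' the anchor. The window's genetic value per animal is
#' \eqn{a_i = \sum_j Z_{ij} \hat g_j} over the window's SNPs, and the
#' reported percentage is the sample variance (n-1 denominator, over
#' genotyped animals) of \eqn{a_i} divided by the total additive variance.
#'
#' @param Z Centred gene-content matrix (genotyped animals x SNPs).
#' @param g_hat Per-SNP effects.
#' @param map Data frame with \code{snp}, \code{chrom}, \code{pos} (sorted
#'   within chromosome).
#' @param sigma2_a Total additive genetic variance (> 0).
#' @param window_bp Window span in bp; default 1,000,000.
#' @param threshold_pct Significance threshold used to pre-flag windows;
#'   default 1.
#' @return A \code{window_scan} data frame: \code{chrom}, \code{start_bp},
#'   \code{end_bp}, \code{first_snp}, \code{last_snp}, \code{n_snps},
#'   \code{pct_var}, \code{significant}.
#' @export
window_variance <- function(Z, g_hat, map, sigma2_a,
                            window_bp = 1e6, threshold_pct = 1) {
  if (sigma2_a <= 0) stop("sigma2_a must be positive")
  m <- ncol(Z)
  stopifnot(length(g_hat) == m, nrow(map) == m)
  V <- sweep(Z, 2L, g_hat, "*")
  n <- nrow(Z)
  chroms <- unique(map$chrom)
  out <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    sel <- which(map$chrom == chroms[ci])
    pos <- map$pos[sel]
    if (is.unsorted(pos)) stop("map not sorted within chromosome ",
                               chroms[ci])
    # cumulative per-animal window sums: S[, k] = rowSums(V[, sel[1:k]])
    S <- V[, sel, drop = FALSE]
    if (length(sel) > 1L)
      S <- t(apply(S, 1L, cumsum))
    ends <- findInterval(pos + window_bp - 1, pos)
    pct <- numeric(length(sel))
    for (k in seq_along(sel)) {
      e <- ends[k]
      a <- if (k == 1L) S[, e] else S[, e] - S[, k - 1L]
      pct[k] <- stats::var(a) / sigma2_a * 100
    }
    out[[ci]] <- data.frame(chrom = chroms[ci],
                            start_bp = pos,
                            end_bp = pos[ends],
                            first_snp = map$snp[sel],
                            last_snp = map$snp[sel[ends]],
                            n_snps = ends - seq_along(sel) + 1L,
                            pct_var = pct,
                            stringsAsFactors = FALSE)
  }
  scan <- do.call(rbind, out)
  scan$significant <- scan$pct_var > threshold_pct
  rownames(scan) <- NULL
  class(scan) <- c("window_scan", "data.frame")
  attr(scan, "window_bp") <- window_bp
  attr(scan, "threshold_pct") <- threshold_pct
  scan
}

#' Select significant genomic regions from a window scan
#'
#' Flags windows explaining strictly more than \code{threshold_pct} percent
#' of additive variance, and merges flagged windows on the same chromosome
#' that share at least one bp into regions, reporting each region's span and
#' maximum percentage.
#'
#' @param scan A \code{window_scan} from [window_variance()].
#' @param threshold_pct Strict selection threshold (percent); default 1.
#' @return Data frame with \code{chrom}, \code{start_bp}, \code{end_bp},
#'   \code{max_pct}, \code{n_windows}.
#' @export
select_regions <- function(scan, threshold_pct = 1) {
  sig <- scan[scan$pct_var > threshold_pct, , drop = FALSE]
  empty <- data.frame(chrom = character(0), start_bp = integer(0),
                      end_bp = integer(0), max_pct = numeric(0),
                      n_windows = integer(0), stringsAsFactors = FALSE)
  if (nrow(sig) == 0L) return(empty)
  res <- list()
  for (ch in unique(sig$chrom)) {
    s <- sig[sig$chrom == ch, , drop = FALSE]
    s <- s[order(s$start_bp), , drop = FALSE]
    cur_start <- s$start_bp[1L]; cur_end <- s$end_bp[1L]
    cur_max <- s$pct_var[1L]; cur_n <- 1L
    flush <- function() {
      res[[length(res) + 1L]] <<- data.frame(chrom = ch,
                                             start_bp = cur_start,
                                             end_bp = cur_end,
                                             max_pct = cur_max,
                                             n_windows = cur_n,
                                             stringsAsFactors = FALSE)
    }
    if (nrow(s) > 1L) {
      for (i in 2:nrow(s)) {
        if (s$start_bp[i] <= cur_end) {  # overlap of >= 1 bp
          cur_end <- max(cur_end, s$end_bp[i])
          cur_max <- max(cur_max, s$pct_var[i])
          cur_n <- cur_n + 1L
        } else {
          flush()
          cur_start <- s$start_bp[i]; cur_end <- s$end_bp[i]
          cur_max <- s$pct_var[i]; cur_n <- 1L
        }
      }
    }
    flush()
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Export a window scan as TSV and a Manhattan-style figure
#'
#' Writes the per-window table (chrom, start, end, percentage of additive
#' variance, significance flag) as a TSV, and renders a Manhattan-style plot
#' of window variance percentages with a red line at the significance
#' threshold.
#'
#' @param scan A \code{window_scan}.
#' @param out Output path prefix; writes \code{<out>.tsv} and
#'   \code{<out>.png}.
#' @param threshold_pct Reference-line threshold; defaults to the scan's.
#' @return Named list of written paths, invisibly.
#' @export
manhattan_export <- function(scan, out, threshold_pct = NULL) {
  if (is.null(threshold_pct))
    threshold_pct <- attr(scan, "threshold_pct")
  if (is.null(threshold_pct)) threshold_pct <- 1
  tsv <- paste0(out, ".tsv")
  png_path <- paste0(out, ".png")
  df <- as.data.frame(scan)[, c("chrom", "start_bp", "end_bp", "pct_var",
                                "significant")]
  ok <- tryCatch({
    utils::write.table(df, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write '", tsv, "': ",
                              conditionMessage(e)))
  chroms <- unique(df$chrom)
  offs <- c(0, cumsum(vapply(chroms, function(ch)
    max(df$end_bp[df$chrom == ch]), numeric(1))))
  xs <- df$start_bp + offs[match(df$chrom, chroms)]
  grDevices::png(png_path, width = 1200, height = 400)
  on.exit(grDevices::dev.off())
  cols <- c("grey30", "steelblue")[(match(df$chrom, chroms) %% 2L) + 1L]
  graphics::plot(xs, df$pct_var, pch = 16, cex = 0.5, col = cols,
                 xlab = "genome position (bp, chromosomes concatenated)",
                 ylab = "% additive genetic variance (1 Mb window)",
                 xaxt = "n")
  mid <- (offs[-length(offs)] + offs[-1]) / 2
  graphics::axis(1, at = mid, labels = chroms)
  graphics::abline(h = threshold_pct, col = "red")
  invisible(list(tsv = tsv, png = png_path))
}

#' Weighted single-step GBLUP with iterative SNP re-weighting
#'
#' Runs the full weighted single-step chain: round 1 fits the model with
#' unit SNP weights (D = I); each further round rebuilds the weighted
#' genomic relationship matrix from the current weights, re-solves the
#' model, and re-backsolves SNP effects. Variance components are estimated
#' by REML in round 1 and, by default, re-used in later rounds
#' (\code{reestimate_vc = TRUE} re-runs REML each round).
#'
#' @param ped A \code{ped_table}.
#' @param geno A \code{genotype_set} (post-QC).
#' @param pheno Phenotype data frame.
#' @param spec A [model_spec()].
#' @param n_iter Number of weighting rounds (>= 1); default 2.
#' @param vc Optional fixed [variance_components()]; skips REML.
#' @param alpha,tune Blending parameters passed to [blend_tune()].
#' @param backsolve_blended Use the blended G in back-solving (default TRUE,
#'   consistent with the fit); FALSE uses the raw weighted G.
#' @param reestimate_vc Re-run REML each round; default FALSE.
#' @param reml_method REML algorithm; default \code{"ai"}.
#' @param window_bp,threshold_pct Window-scan parameters.
#' @param trait Trait (name or index) whose GEBVs drive the scan; default
#'   first trait.
#' @param ... Further arguments to [reml()].
#' @return List with \code{fit} (final [reml()]/[solve_mme()] output),
#'   \code{snp_effects}, \code{weights_trace} (per-round weight vectors),
#'   \code{scan}, \code{regions}, \code{vc}.
#' @export
run_wssgblup <- function(ped, geno, pheno, spec, n_iter = 2L, vc = NULL,
                         alpha = 0.95, tune = TRUE,
                         backsolve_blended = TRUE, reestimate_vc = FALSE,
                         reml_method = "ai", window_bp = 1e6,
                         threshold_pct = 1, trait = 1L, ...) {
  stopifnot(n_iter >= 1L)
  gids <- geno$animal_ids
  A22m <- a22(ped, gids)
  Ainv <- a_inverse(ped)
  Z <- center_matrix(geno)
  p_hat <- geno$p_hat
  denom_k <- sum(2 * ifelse(is.nan(p_hat), 0, p_hat) *
                   (1 - ifelse(is.nan(p_hat), 0, p_hat)))
  weights <- rep(1, ncol(Z))
  names(weights) <- geno$map$snp
  weights_trace <- list()
  fit <- NULL
  g_hat <- NULL
  for (round in seq_len(n_iter)) {
    weights_trace[[round]] <- weights
    G <- g_matrix(Z, weights, p_hat)
    Gstar <- blend_tune(G, A22m, alpha = alpha, tune = tune)
    hinv <- h_inverse(Ainv, Gstar, A22m, gids)
    if (is.null(vc) || (reestimate_vc && round > 1L)) {
      fit <- reml(pheno, spec, hinv, method = reml_method, ...)
      vc_used <- fit$vc
      if (round == 1L && is.null(vc)) vc <- vc_used
    } else {
      des <- build_design(pheno, spec, rownames(as_matrix(hinv)))
      fit <- solve_mme(des$X, des$Z, des$W, hinv, vc, des$Y)
      fit$vc <- vc
    }
    u_hat <- fit$a_hat[gids, trait]
    G_bs <- if (backsolve_blended) Gstar else G
    g_hat <- backsolve_snp_effects(Z, weights, G_bs, u_hat,
                                   denom_k = denom_k)
    attr(g_hat, "iteration") <- round
    if (round < n_iter)
      weights <- update_weights(g_hat, p_hat)
  }
  sigma2_a <- fit$vc$G0[trait, trait]
  scan <- window_variance(Z, g_hat, geno$map, sigma2_a,
                          window_bp = window_bp,
                          threshold_pct = threshold_pct)
  regions <- select_regions(scan, threshold_pct = threshold_pct)
  list(fit = fit, snp_effects = g_hat, weights_trace = weights_trace,
       scan = scan, regions = regions, vc = fit$vc)
}
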