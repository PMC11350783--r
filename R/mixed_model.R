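#' Model specification for the animal model
#'
#' Describes the multivariate repeatability animal model
#' \deqn{y = Xb + Za + Wp + e} with \eqn{a \sim N(0, H \otimes G_0)},
#' \eqn{p \sim N(0, I \sigma_p^2)}, \eqn{e \sim N(0, I \otimes R_0)}:
#' which phenotype columns are traits, which are categorical fixed factors
#' (dummy-coded with the last level as reference), and which are linear
#' covariates (centred before fitting).
#'
#' @param traits Character vector of trait column names (1-3 traits).
#' @param factors Character vector of fixed-factor column names.
#' @param covariates Character vector of covariate column names.
#' @param pe Permanent-environment term: \code{"auto"} (dropped when every
#'   animal has a single record), \code{TRUE} or \code{FALSE}.
#' @param animal_col Name of the animal id column; default \code{"animal"}.
#' @param factor_levels Optional named list fixing the allowed levels of
#'   each factor (unseen levels in the data raise an error).
#' @return A \code{model_spec} list.
#' @export
model_spec <- function(traits, factors = character(0),
                       covariates = character(0), pe = "auto",
                       animal_col = "animal", factor_levels = NULL) {
  traits <- as.character(traits)
  stopifnot(length(traits) >= 1L, length(traits) <= 3L)
  structure(list(traits = traits, factors = factors,
                 covariates = covariates, pe = pe,
                 animal_col = animal_col, factor_levels = factor_levels),
            class = "model_spec")
}

#' Build design matrices for the animal model
#'
#' Constructs the fixed-effect matrix X (intercept, dummy-coded factors with
#' the last level as reference, centred covariates), the record-to-animal
#' incidence Z and the record-to-permanent-environment incidence W.
#'
#' @param pheno Phenotype data frame (one row per record).
#' @param spec A [model_spec()].
#' @param ids Pedigree animal ids, in pedigree order (columns of Z).
#' @return List with \code{X}, \code{Z}, \code{W} (dense matrices; \code{W}
#'   is \code{NULL} when the PE term is off), \code{pe_ids}, \code{Y}
#'   (records x traits, \code{NA} = missing trait) and \code{use_pe}.
#' @export
build_design <- function(pheno, spec, ids) {
  an <- as.character(pheno[[spec$animal_col]])
  if (is.null(an)) stop("phenotype table lacks column '", spec$animal_col, "'")
  bad <- setdiff(an, ids)
  if (length(bad) > 0L)
    stop("phenotyped animal(s) absent from pedigree: ",
         paste(utils::head(bad, 3L), collapse = ", "))
  n <- nrow(pheno)
  cols <- list(`(Intercept)` = rep(1, n))
  for (f in spec$factors) {
    v <- as.character(pheno[[f]])
    if (is.null(v)) stop("missing factor column '", f, "'")
    lev <- if (!is.null(spec$factor_levels[[f]])) {
      unseen <- setdiff(unique(v), spec$factor_levels[[f]])
      if (length(unseen) > 0L)
        stop("unseen level(s) in factor '", f, "': ",
             paste(unseen, collapse = ", "))
      spec$factor_levels[[f]]
    } else sort(unique(v))
    if (length(lev) > 1L) {
      for (l in lev[-length(lev)])  # last level = reference
        cols[[paste0(f, l)]] <- as.numeric(v == l)
    }
  }
  for (cv in spec$covariates) {
    v <- as.numeric(pheno[[cv]])
    if (is.null(pheno[[cv]])) stop("missing covariate column '", cv, "'")
    cols[[cv]] <- v - mean(v)
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  q <- length(ids)
  ai <- match(an, ids)
  Z <- matrix(0, n, q, dimnames = list(NULL, ids))
  Z[cbind(seq_len(n), ai)] <- 1
  single <- !any(duplicated(an))
  use_pe <- if (identical(spec$pe, "auto")) !single else isTRUE(spec$pe)
  if (use_pe && single)
    message("PE term requested but all animals have single records; ",
            "PE variance is confounded with the residual")
  W <- NULL
  pe_ids <- NULL
  if (use_pe) {
    pe_ids <- unique(an)
    W <- matrix(0, n, length(pe_ids), dimnames = list(NULL, pe_ids))
    W[cbind(seq_len(n), match(an, pe_ids))] <- 1
  }
  Y <- as.matrix(pheno[, spec$traits, drop = FALSE])
  storage.mode(Y) <- "double"
  list(X = X, Z = Z, W = W, pe_ids = pe_ids, Y = Y, use_pe = use_pe,
       animal = an)
}

#' Variance-component container
#'
#' @param G0 Additive genetic (co)variance matrix across traits.
#' @param R0 Residual (co)variance matrix across traits.
#' @param P0 Per-trait permanent-environment variances (or \code{NULL}).
#' @param traits Trait names.
#' @return A \code{variance_components} list.
#' @export
variance_components <- function(G0, R0, P0 = NULL, traits = NULL) {
  G0 <- as.matrix(G0); R0 <- as.matrix(R0)
  if (is.null(traits)) traits <- paste0("t", seq_len(nrow(G0)))
  dimnames(G0) <- dimnames(R0) <- list(traits, traits)
  if (!is.null(P0)) P0 <- stats::setNames(as.numeric(P0), traits)
  structure(list(G0 = G0, R0 = R0, P0 = P0, traits = traits),
            class = "variance_components")
}

#' Heritability from variance components
#'
#' \eqn{h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_p + \sigma^2_e)} per trait;
#' an absent permanent-environment term contributes 0.
#'
#' @param vc A [variance_components()] object.
#' @return Named per-trait heritabilities.
#' @export
heritability <- function(vc) {
  sa <- diag(vc$G0)
  se <- diag(vc$R0)
  sp <- if (is.null(vc$P0)) rep(0, length(sa)) else vc$P0
  tot <- sa + sp + se
  if (any(tot <= 0)) stop("zero total variance")
  stats::setNames(sa / tot, vc$traits)
}

#' Genetic correlation between two traits
#'
#' @param vc A [variance_components()] object.
#' @param t1,t2 Trait names or indices.
#' @return \eqn{r_g = \sigma_{a,12} / \sqrt{\sigma^2_{a,1}\sigma^2_{a,2}}},
#'   clamped to \eqn{[-1, 1]} (with a warning when the raw value exceeds the
#'   bound by more than 1e-6).
#' @export
genetic_correlation <- function(vc, t1, t2) {
  v1 <- vc$G0[t1, t1]; v2 <- vc$G0[t2, t2]
  if (v1 <= 0 || v2 <= 0) stop("zero additive variance")
  r <- vc$G0[t1, t2] / sqrt(v1 * v2)
  if (abs(r) > 1 + 1e-6)
    warning("raw genetic correlation ", format(r), " outside [-1, 1]")
  max(-1, min(1, r))
}

# ---- internal MME machinery -------------------------------------------------

# Pattern bookkeeping for records with missing traits. Returns per-pattern
# groups with cached crossproducts so the coefficient matrix can be
# re-assembled cheaply as R0 changes during REML.
mme_prepare <- function(X, Z, W, Y) {
  Md <- cbind(X, Z, if (!is.null(W)) W)
  p <- ncol(X); q <- ncol(Z); qpe <- if (is.null(W)) 0L else ncol(W)
  K <- ncol(Md)
  M <- ncol(Y)
  obs <- !is.na(Y)
  if (any(rowSums(obs) == 0L))
    stop("record(s) with no observed trait; drop them first")
  pat_key <- apply(obs, 1L, function(r) paste(as.integer(r), collapse = ""))
  groups <- lapply(split(seq_len(nrow(Y)), pat_key), function(rows) {
    o <- obs[rows[1L], ]
    Mg <- Md[rows, , drop = FALSE]
    Y0 <- Y[rows, , drop = FALSE]
    Y0[is.na(Y0)] <- 0
    list(rows = rows, observed = o, n = length(rows),
         MtM = crossprod(Mg),
         MtY = crossprod(Mg, Y0),
         YtY = crossprod(Y0))
  })
  list(Md = Md, Yobs = Y, groups = groups, p = p, q = q, qpe = qpe, K = K,
       M = M, n = nrow(Y), complete = length(groups) == 1L &&
         all(groups[[1L]]$observed))
}

# Embedded inverse of the observed submatrix of R0 (zeros elsewhere).
rinv_pattern <- function(R0, o) {
  out <- matrix(0, nrow(R0), ncol(R0))
  out[o, o] <- chol2inv(chol(R0[o, o, drop = FALSE]))
  out
}

# Assemble coefficient matrix + RHS for given variance components.
# Effect ordering is trait-outer: (b_1, a_1, p_1, b_2, a_2, p_2, ...).
mme_assemble <- function(prep, Hinv, vc) {
  M <- prep$M; K <- prep$K; p <- prep$p; q <- prep$q; qpe <- prep$qpe
  G0inv <- chol2inv(chol(vc$G0))
  dimtot <- M * K
  C <- matrix(0, dimtot, dimtot)
  rhs <- numeric(dimtot)
  rinvs <- lapply(prep$groups, function(g) rinv_pattern(vc$R0, g$observed))
  for (t in seq_len(M)) {
    rt <- (t - 1L) * K + seq_len(K)
    for (l in seq_len(M)) {
      cl <- (l - 1L) * K + seq_len(K)
      blk <- matrix(0, K, K)
      for (gi in seq_along(prep$groups)) {
        w <- rinvs[[gi]][t, l]
        if (w != 0) blk <- blk + w * prep$groups[[gi]]$MtM
      }
      ar <- p + seq_len(q)
      blk[ar, ar] <- blk[ar, ar] + G0inv[t, l] * Hinv
      if (t == l && qpe > 0L) {
        pr <- p + q + seq_len(qpe)
        diag(blk[pr, pr]) <- diag(blk[pr, pr]) + 1 / vc$P0[t]
        C[rt, cl] <- blk
      } else {
        C[rt, cl] <- blk
      }
      if (t == l) {
        v <- numeric(K)
        for (gi in seq_along(prep$groups)) {
          ri <- rinvs[[gi]]
          for (l2 in seq_len(M)) {
            if (ri[t, l2] != 0)
              v <- v + ri[t, l2] * prep$groups[[gi]]$MtY[, l2]
          }
        }
        rhs[rt] <- v
      }
    }
  }
  yry <- 0
  logdetR <- 0
  for (gi in seq_along(prep$groups)) {
    g <- prep$groups[[gi]]
    ri <- rinvs[[gi]]
    yry <- yry + sum(ri * g$YtY)
    o <- g$observed
    logdetR <- logdetR + g$n *
      determinant(vc$R0[o, o, drop = FALSE], logarithm = TRUE)$modulus
  }
  list(C = C, rhs = rhs, yry = yry, logdetR = as.numeric(logdetR),
       G0inv = G0inv, rinvs = rinvs)
}

# index helpers (trait-outer ordering)
idx_b <- function(prep, t) (t - 1L) * prep$K + seq_len(prep$p)
idx_a <- function(prep, t) (t - 1L) * prep$K + prep$p + seq_len(prep$q)
idx_p <- function(prep, t) (t - 1L) * prep$K + prep$p + prep$q +
  seq_len(prep$qpe)
idx_all <- function(prep, t) (t - 1L) * prep$K + seq_len(prep$K)

#' Solve Henderson's mixed-model equations
#'
#' Builds and solves the MME for given variance components, returning fixed
#' and random-effect solutions. Supports 1-3 traits with identical fixed
#' designs and trait-wise missing records.
#'
#' @param X,Z,W Design matrices from [build_design()] (\code{W = NULL} drops
#'   the permanent-environment term).
#' @param h_inv An [h_inverse()] object or a dense/sparse inverse
#'   relationship matrix conforming to the columns of \code{Z}.
#' @param vc [variance_components()] with as many traits as \code{Y} columns.
#' @param Y Records x traits response matrix (vector accepted for one trait).
#' @return List with \code{b_hat}, \code{a_hat}, \code{p_hat_pe},
#'   \code{residuals}, \code{mme_residual} (relative MME residual norm) and
#'   internals for reuse.
#' @export
solve_mme <- function(X, Z, W, h_inv, vc, Y) {
  Y <- as.matrix(Y)
  Hinv <- if (inherits(h_inv, "h_inverse")) as_matrix(h_inv)
          else as.matrix(h_inv)
  check_fixed_rank(X)
  prep <- mme_prepare(X, Z, W, Y)
  stopifnot(nrow(Hinv) == prep$q)
  asm <- mme_assemble(prep, Hinv, vc)
  ch <- tryCatch(chol(asm$C), error = function(e)
    stop("MME coefficient matrix not positive definite: ", conditionMessage(e)))
  sol <- backsolve(ch, backsolve(ch, asm$rhs, transpose = TRUE))
  mme_res <- sqrt(sum((asm$C %*% sol - asm$rhs)^2)) /
    max(sqrt(sum(asm$rhs^2)), 1e-300)
  shape_solution(prep, sol, X, Z, Y, vc, mme_residual = mme_res)
}

check_fixed_rank <- function(X) {
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    stop("fixed-effect design is rank deficient; confounded column(s): ",
         paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

shape_solution <- function(prep, sol, X, Z, Y, vc, ...) {
  M <- prep$M
  traits <- vc$traits
  Sol <- matrix(sol, prep$K, M)
  b <- Sol[seq_len(prep$p), , drop = FALSE]
  dimnames(b) <- list(colnames(X), traits)
  a <- Sol[prep$p + seq_len(prep$q), , drop = FALSE]
  dimnames(a) <- list(colnames(Z), traits)
  pe <- if (prep$qpe > 0L)
    Sol[prep$p + prep$q + seq_len(prep$qpe), , drop = FALSE] else NULL
  fitted <- prep$Md %*% Sol
  resid <- Y - fitted
  list(b_hat = b, a_hat = a, p_hat_pe = pe, residuals = resid,
       sol = sol, ...)
}

# -2 * restricted log-likelihood (up to an additive constant)
reml_m2ll <- function(prep, asm, sol, Hinv_logdet, vc) {
  ch <- attr(asm, "chol")
  logdetC <- 2 * sum(log(diag(ch)))
  ypy <- asm$yry - sum(sol * asm$rhs)
  ld_g <- prep$q * determinant(vc$G0, logarithm = TRUE)$modulus -
    prep$M * Hinv_logdet
  ld_p <- if (prep$qpe > 0L) prep$qpe * sum(log(vc$P0)) else 0
  as.numeric(asm$logdetR + ld_g + ld_p + logdetC + ypy)
}

floor_pd <- function(S, floor = 1e-8) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  ev <- pmax(e$values, floor)
  out <- e$vectors %*% (ev * t(e$vectors))
  dimnames(out) <- dimnames(S)
  (out + t(out)) / 2
}

#' REML estimation of variance components for the animal model
#'
#' Estimates additive, permanent-environment and residual (co)variances for
#' 1-3 traits by restricted maximum likelihood under the single-step animal
#' model, using either expectation-maximization updates (\code{method =
#' "em"}, monotone in the restricted likelihood) or average-information
#' updates with EM fallback on non-positive-definite steps (\code{method =
#' "ai"}; requires complete multi-trait records, otherwise EM is used).
#'
#' @param pheno Phenotype data frame.
#' @param spec A [model_spec()].
#' @param h_inv [h_inverse()] object or inverse relationship matrix over the
#'   pedigree ids (its dimnames define the animal order of \code{a_hat}).
#' @param init Optional [variance_components()] starting values.
#' @param method \code{"em"} or \code{"ai"}.
#' @param max_iter Maximum iterations; default 500.
#' @param tol Convergence tolerance on the maximum relative parameter
#'   change; default 1e-6.
#' @param verbose Print iteration progress.
#' @return A \code{model_fit} list: solutions (\code{b_hat}, \code{a_hat}
#'   for every pedigree animal, \code{p_hat_pe}), \code{vc}, per-trait
#'   \code{h2}, \code{loglik_trace} (-2 restricted log-likelihood, up to a
#'   constant), \code{converged}, \code{niter}.
#' @export
reml <- function(pheno, spec, h_inv, init = NULL,
                 method = c("em", "ai"), max_iter = 500L, tol = 1e-6,
                 verbose = FALSE) {
  method <- match.arg(method)
  stopifnot(tol > 0)
  Hinv <- if (inherits(h_inv, "h_inverse")) as_matrix(h_inv)
          else as.matrix(h_inv)
  ids <- rownames(Hinv)
  if (is.null(ids)) stop("h_inv must carry animal ids as dimnames")
  des <- build_design(pheno, spec, ids)
  keep <- rowSums(!is.na(des$Y)) > 0L
  if (!all(keep)) {
    des$X <- des$X[keep, , drop = FALSE]
    des$Z <- des$Z[keep, , drop = FALSE]
    if (!is.null(des$W)) des$W <- des$W[keep, , drop = FALSE]
    des$Y <- des$Y[keep, , drop = FALSE]
  }
  check_fixed_rank(des$X)
  M <- length(spec$traits)
  prep <- mme_prepare(des$X, des$Z, des$W, des$Y)
  if (method == "ai" && !prep$complete) {
    message("AI-REML requires complete multi-trait records; using EM")
    method <- "em"
  }
  if (is.null(init)) {
    vy <- apply(des$Y, 2L, stats::var, na.rm = TRUE)
    G0 <- diag(0.3 * vy, M)
    R0 <- diag((if (prep$qpe > 0L) 0.5 else 0.7) * vy, M)
    P0 <- if (prep$qpe > 0L) 0.2 * vy else NULL
    init <- variance_components(G0, R0, P0, traits = spec$traits)
  } else {
    init$traits <- spec$traits
    dimnames(init$G0) <- dimnames(init$R0) <-
      list(spec$traits, spec$traits)
  }
  vc <- init
  Hld <- 2 * sum(log(diag(chol(Hinv))))
  trace <- numeric(0)
  converged <- FALSE
  state <- NULL
  for (it in seq_len(max_iter)) {
    state <- reml_iterate(prep, Hinv, vc, Hld, method)
    trace <- c(trace, state$m2ll)
    delta <- rel_change(vc, state$vc_new)
    if (verbose)
      message(sprintf("iter %d  -2logL = %.6f  delta = %.3g", it,
                      state$m2ll, delta))
    vc <- state$vc_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("REML did not converge in ", max_iter,
            " iterations (last relative change ",
            format(rel_change(state$vc_prev, vc), digits = 3),
            "); returning last iterate")
  final <- mme_assemble(prep, Hinv, vc)
  ch <- chol(final$C)
  sol <- backsolve(ch, backsolve(ch, final$rhs, transpose = TRUE))
  fit <- shape_solution(prep, sol, des$X, des$Z, des$Y, vc)
  fit$vc <- vc
  fit$h2 <- heritability(vc)
  fit$loglik_trace <- -0.5 * trace  # restricted log-likelihood scale
  fit$m2ll_trace <- trace
  fit$converged <- converged
  fit$niter <- length(trace)
  fit$method <- method
  fit$spec <- spec
  fit$use_pe <- des$use_pe
  class(fit) <- "model_fit"
  fit
}

rel_change <- function(vc_old, vc_new) {
  pv <- function(v) c(v$G0[upper.tri(v$G0, diag = TRUE)],
                      v$R0[upper.tri(v$R0, diag = TRUE)], v$P0)
  a <- pv(vc_old); b <- pv(vc_new)
  max(abs(b - a) / pmax(abs(a), 1e-8))
}

# One REML iteration: assembles the MME at the current parameters, computes
# the -2 restricted log-likelihood, and proposes updated components.
reml_iterate <- function(prep, Hinv, vc, Hld, method) {
  asm <- mme_assemble(prep, Hinv, vc)
  ch <- chol(asm$C)
  attr(asm, "chol") <- ch
  sol <- backsolve(ch, backsolve(ch, asm$rhs, transpose = TRUE))
  m2ll <- reml_m2ll(prep, asm, sol, Hld, vc)
  Cinv <- chol2inv(ch)
  em <- em_update(prep, Hinv, vc, sol, Cinv)
  vc_new <- em$vc
  if (method == "ai") {
    cand <- try(ai_update(prep, Hinv, vc, sol, Cinv, asm), silent = TRUE)
    if (!inherits(cand, "try-error") && !is.null(cand)) vc_new <- cand
  }
  list(vc_new = vc_new, vc_prev = vc, m2ll = m2ll, sol = sol)
}

em_update <- function(prep, Hinv, vc, sol, Cinv) {
  M <- prep$M; q <- prep$q
  Sol <- matrix(sol, prep$K, M)
  A <- Sol[prep$p + seq_len(q), , drop = FALSE]
  G0n <- matrix(0, M, M)
  for (t in seq_len(M)) for (l in t:M) {
    tr <- sum(Cinv[idx_a(prep, t), idx_a(prep, l)] * Hinv)
    G0n[t, l] <- G0n[l, t] <-
      (crossprod(A[, t], Hinv %*% A[, l]) + tr) / q
  }
  # residuals over observed cells only
  fitted <- prep$Md %*% Sol
  R0n <- matrix(0, M, M)
  for (t in seq_len(M)) for (l in t:M) {
    num <- 0
    n_tl <- sum(vapply(prep$groups,
                       function(g) if (g$observed[t] && g$observed[l]) g$n
                       else 0L, integer(1)))
    if (n_tl == 0L) { R0n[t, l] <- R0n[l, t] <- vc$R0[t, l]; next }
    for (g in prep$groups) {
      o <- g$observed
      if (o[t] && o[l]) {
        rows <- g$rows
        et <- prep$Yobs[rows, t] - fitted[rows, t]
        el <- prep$Yobs[rows, l] - fitted[rows, l]
        num <- num + sum(et * el) +
          sum(Cinv[idx_all(prep, t), idx_all(prep, l)] * g$MtM)
      }
    }
    R0n[t, l] <- R0n[l, t] <- num / n_tl
  }
  P0n <- NULL
  if (prep$qpe > 0L) {
    P0n <- numeric(M)
    PE <- Sol[prep$p + prep$q + seq_len(prep$qpe), , drop = FALSE]
    for (t in seq_len(M)) {
      trp <- sum(diag(Cinv[idx_p(prep, t), idx_p(prep, t), drop = FALSE]))
      P0n[t] <- (sum(PE[, t]^2) + trp) / prep$qpe
    }
    P0n <- pmax(P0n, 1e-8)
  }
  list(vc = variance_components(floor_pd(G0n), floor_pd(R0n), P0n,
                                traits = vc$traits))
}

# Average-information update (complete records only). Returns NULL when the
# proposed step leaves the parameter space, triggering EM fallback.
ai_update <- function(prep, Hinv, vc, sol, Cinv, asm) {
  M <- prep$M; q <- prep$q; n <- prep$n
  Sol <- matrix(sol, prep$K, M)
  A <- Sol[prep$p + seq_len(q), , drop = FALSE]
  G0inv <- asm$G0inv
  R0inv <- chol2inv(chol(vc$R0))
  E <- prep$Yobs - prep$Md %*% Sol       # complete: all observed
  Etil <- E %*% R0inv
  HA <- Hinv %*% A
  S_a <- crossprod(A, HA)
  T_a <- matrix(0, M, M)
  T_r <- matrix(0, M, M)
  MtM <- prep$groups[[1L]]$MtM
  for (t in seq_len(M)) for (l in t:M) {
    T_a[t, l] <- T_a[l, t] <- sum(Cinv[idx_a(prep, t), idx_a(prep, l)] * Hinv)
    T_r[t, l] <- T_r[l, t] <-
      sum(Cinv[idx_all(prep, t), idx_all(prep, l)] * MtM)
  }
  # parameter list: vech(G0), vech(R0), P0
  ut <- which(upper.tri(diag(M), diag = TRUE), arr.ind = TRUE)
  npar_g <- nrow(ut)
  use_pe <- prep$qpe > 0L
  npar <- 2L * npar_g + if (use_pe) M else 0L
  score <- numeric(npar)
  Sg <- G0inv %*% (q * vc$G0 - T_a - S_a) %*% G0inv  # q*G0inv - G0inv(T+S)G0inv
  Sr <- n * R0inv - R0inv %*% T_r %*% R0inv - crossprod(Etil)
  for (k in seq_len(npar_g)) {
    i <- ut[k, 1L]; j <- ut[k, 2L]
    phi <- if (i == j) 1 else 2
    score[k] <- -0.5 * phi * Sg[i, j]
    score[npar_g + k] <- -0.5 * phi * Sr[i, j]
  }
  # AI matrix via working vectors (n x M matrices)
  Umats <- vector("list", npar)
  Atil <- A %*% G0inv
  ZA <- prep$Md[, prep$p + seq_len(q), drop = FALSE]  # Z incidence block
  for (k in seq_len(npar_g)) {
    i <- ut[k, 1L]; j <- ut[k, 2L]
    Phi <- matrix(0, M, M)
    Phi[i, j] <- Phi[j, i] <- 1
    Umats[[k]] <- ZA %*% (Atil %*% Phi)
    Umats[[npar_g + k]] <- Etil %*% Phi
  }
  if (use_pe) {
    Wd <- prep$Md[, prep$p + prep$q + seq_len(prep$qpe), drop = FALSE]
    PEsol <- Sol[prep$p + prep$q + seq_len(prep$qpe), , drop = FALSE]
    for (t in seq_len(M)) {
      U <- matrix(0, n, M)
      U[, t] <- Wd %*% crossprod(Wd, Etil[, t])
      Umats[[2L * npar_g + t]] <- U
      trp <- sum(diag(Cinv[idx_p(prep, t), idx_p(prep, t), drop = FALSE]))
      score[2L * npar_g + t] <-
        -0.5 * (prep$qpe / vc$P0[t] - trp / vc$P0[t]^2 -
                  sum(PEsol[, t]^2) / vc$P0[t]^2)
    }
  }
  Zs <- matrix(0, nrow(Cinv), npar)
  uru <- matrix(0, npar, npar)
  Ubars <- lapply(Umats, function(U) U %*% R0inv)
  for (k in seq_len(npar)) {
    Zm <- crossprod(prep$Md, Ubars[[k]])          # K x M
    Zs[, k] <- as.numeric(Zm)                     # trait-outer vec
  }
  for (k in seq_len(npar)) for (l in k:npar) {
    uru[k, l] <- uru[l, k] <- sum(Ubars[[k]] * Umats[[l]])
  }
  AI <- 0.5 * (uru - crossprod(Zs, Cinv %*% Zs))
  step <- try(solve(AI, score), silent = TRUE)
  if (inherits(step, "try-error")) return(NULL)
  for (halve in 0:4) {
    th <- step / 2^halve
    G0n <- vc$G0; R0n <- vc$R0
    for (k in seq_len(npar_g)) {
      i <- ut[k, 1L]; j <- ut[k, 2L]
      G0n[i, j] <- G0n[j, i] <- G0n[i, j] + th[k]
      R0n[i, j] <- R0n[j, i] <- R0n[i, j] + th[npar_g + k]
    }
    P0n <- vc$P0
    if (use_pe) P0n <- pmax(vc$P0 + th[2L * npar_g + seq_len(M)], 1e-8)
    # project onto the parameter space: a Newton step proposing a
    # non-PD matrix is clipped to the variance floor (boundary estimate)
    # rather than rejected outright, so null components pin at ~0 quickly
    G0n <- floor_pd(G0n, 1e-8)
    R0n <- floor_pd(R0n, 1e-8)
    ok <- !inherits(try(chol(G0n), silent = TRUE), "try-error") &&
      !inherits(try(chol(R0n), silent = TRUE), "try-error")
    if (ok)
      return(variance_components(G0n, R0n, P0n, traits = vc$traits))
  }
  NULL
}

#' @export
print.model_fit <- function(x, ...) {
  cat("<model_fit> ", length(x$spec$traits), " trait(s), ",
      nrow(x$a_hat), " animals; method ", x$method,
      ", ", x$niter, " iterations",
      if (x$converged) " (converged)" else " (NOT converged)", "\n", sep = "")
  cat("h2:", paste(sprintf("%s = %.3f", names(x$h2), x$h2),
                   collapse = ", "), "\n")
  invisible(x)
}
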