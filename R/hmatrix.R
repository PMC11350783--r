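#' Assemble the single-step inverse relationship matrix H-inverse
#'
#' Combines pedigree and genomic information as
#' \deqn{H^{-1} = A^{-1} + \begin{pmatrix} 0 & 0 \\ 0 & G^{-1} - A_{22}^{-1}
#' \end{pmatrix}} over the full pedigree id set, with the correction block on
#' the genotyped animals. Optional scaling coefficients for the two inverse
#' blocks (tau, omega) default to 1.
#'
#' @param a_inv Sparse A-inverse over all pedigree animals (from
#'   [a_inverse()]), with id dimnames.
#' @param G_star Blended genomic relationship matrix (kind \code{"G"}).
#' @param A22 Pedigree relationship matrix of the genotyped animals, same id
#'   order as \code{G_star}.
#' @param genotyped_ids Ids of genotyped animals (order of \code{G_star}).
#' @param tau,omega Scaling of \eqn{G^{-1}} and \eqn{A_{22}^{-1}}; default 1.
#' @return An \code{h_inverse} object: sparse base plus dense genomic
#'   correction block, with \code{as_matrix()}/\code{h_matvec()} access.
#' @export
h_inverse <- function(a_inv, G_star, A22, genotyped_ids,
                      tau = 1, omega = 1) {
  ids <- rownames(a_inv)
  if (is.null(ids)) stop("a_inv must carry id dimnames")
  genotyped_ids <- as.character(genotyped_ids)
  if (length(genotyped_ids) > 0L) {
    if (!identical(rownames(G_star), rownames(A22)))
      stop("G_star and A22 id order differ")
    if (!identical(rownames(G_star), genotyped_ids))
      stop("genotyped_ids must match G_star id order")
  }
  pos <- match(genotyped_ids, ids)
  if (anyNA(pos))
    stop("genotyped animals absent from pedigree: ",
         paste(genotyped_ids[is.na(pos)][1:min(3, sum(is.na(pos)))],
               collapse = ", "))
  if (length(genotyped_ids) > 0L) {
    rc <- tryCatch(rcond(unclass(G_star)), error = function(e) 0)
    if (!is.finite(rc) || rc < 1e-12)
      stop("G_star numerically singular (condition > 1e12); ",
           "blend with A22 (alpha < 1) before building H-inverse")
    Ginv <- chol2inv(chol(unclass(G_star)))
    A22inv <- chol2inv(chol(unclass(A22)))
    block <- tau * Ginv - omega * A22inv
    block <- (block + t(block)) / 2
  } else {
    block <- matrix(0, 0, 0)
  }
  structure(list(ids = ids, sparse_base = a_inv, genomic_block = block,
                 genotyped_positions = pos),
            class = "h_inverse")
}

#' Dense realization of an H-inverse
#'
#' @param h An \code{h_inverse} object.
#' @return Dense symmetric matrix over all pedigree animals.
#' @export
as_matrix <- function(h) {
  M <- as.matrix(h$sparse_base)
  p <- h$genotyped_positions
  if (length(p) > 0L)
    M[p, p] <- M[p, p] + h$genomic_block
  dimnames(M) <- list(h$ids, h$ids)
  M
}

#' Matrix-vector product with H-inverse
#'
#' @param h An \code{h_inverse} object.
#' @param x Numeric vector (or matrix) conforming to the pedigree ids.
#' @return \code{H^{-1} x}.
#' @export
h_matvec <- function(h, x) {
  x <- as.matrix(x)
  out <- as.matrix(h$sparse_base %*% x)
  p <- h$genotyped_positions
  if (length(p) > 0L)
    out[p, ] <- out[p, ] + h$genomic_block %*% x[p, , drop = FALSE]
  out
}

#' @export
print.h_inverse <- function(x, ...) {
  cat("<h_inverse> ", length(x$ids), " animals, ",
      length(x$genotyped_positions), " genotyped\n", sep = "")
  invisible(x)
}

#' Symmetry and conditional-PSD probe of an H-inverse
#'
#' Validation utility: checks the operator symmetry
#' \eqn{x' H^{-1} y = y' H^{-1} x} and the sign of random Rayleigh quotients
#' on seeded probe vectors.
#'
#' @param h An \code{h_inverse} object.
#' @param n_probe Number of random probe pairs (>= 1).
#' @param seed RNG seed for the probes.
#' @return List with \code{symmetric} (logical), \code{max_asym} (largest
#'   relative symmetry violation) and \code{min_rayleigh}.
#' @export
h_quadratic_check <- function(h, n_probe = 20L, seed = 1L) {
  stopifnot(n_probe >= 1L)
  n <- length(h$ids)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  max_asym <- 0
  min_ray <- Inf
  for (k in seq_len(n_probe)) {
    x <- stats::rnorm(n)
    y <- stats::rnorm(n)
    hx <- h_matvec(h, x)
    hy <- h_matvec(h, y)
    q1 <- sum(y * hx)
    q2 <- sum(x * hy)
    max_asym <- max(max_asym, abs(q1 - q2) / max(1, abs(q1)))
    min_ray <- min(min_ray, sum(x * hx) / sum(x * x))
  }
  list(symmetric = max_asym < 1e-8, max_asym = max_asym,
       min_rayleigh = min_ray)
}

# save/restore global RNG state so seeded utilities do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv())
}
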