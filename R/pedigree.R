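#' Read and validate a pedigree file
#'
#' Reads a delimited pedigree file with animal/sire/dam columns, normalizes
#' unknown-parent codes, auto-inserts parents that never appear as animals
#' (as founders, with a warning), checks for duplicates and cycles, and
#' returns a topologically sorted pedigree.
#'
#' @param path Path to a delimited text file.
#' @param dialect Named list mapping the roles \code{animal}, \code{sire},
#'   \code{dam} to column names in the file, plus \code{missing}: a character
#'   vector of codes that denote an unknown parent (default \code{"0"}, empty
#'   string and \code{"NA"}).
#' @param sep Field separator (default comma).
#' @return A \code{ped_table} data frame with columns \code{animal},
#'   \code{sire}, \code{dam} (NA = unknown parent), \code{ordinal_index} and
#'   the inbreeding coefficient \code{F}, sorted so parents precede offspring.
#' @export
read_pedigree <- function(path,
                          dialect = list(animal = "animal", sire = "sire",
                                         dam = "dam",
                                         missing = c("0", "", "NA")),
                          sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(dialect$animal, dialect$sire, dialect$dam)
  if (!all(need %in% names(raw)))
    stop("pedigree file lacks columns: ",
         paste(setdiff(need, names(raw)), collapse = ", "))
  miss_codes <- dialect$missing
  if (is.null(miss_codes)) miss_codes <- c("0", "", "NA")
  df <- data.frame(animal = trimws(raw[[dialect$animal]]),
                   sire   = trimws(raw[[dialect$sire]]),
                   dam    = trimws(raw[[dialect$dam]]),
                   stringsAsFactors = FALSE)
  df$sire[df$sire %in% miss_codes] <- NA_character_
  df$dam[df$dam %in% miss_codes] <- NA_character_
  as_ped_table(df)
}

#' Build a validated pedigree table from animal/sire/dam vectors
#'
#' @param df Data frame with character columns \code{animal}, \code{sire},
#'   \code{dam}; NA denotes an unknown parent.
#' @return A sorted, validated \code{ped_table} (see [read_pedigree()]).
#' @export
as_ped_table <- function(df) {
  stopifnot(all(c("animal", "sire", "dam") %in% names(df)))
  df$animal <- as.character(df$animal)
  df$sire <- as.character(df$sire)
  df$dam <- as.character(df$dam)
  if (anyNA(df$animal) || any(df$animal == ""))
    stop("missing animal id in pedigree")
  if (anyDuplicated(df$animal))
    stop("duplicate animal_id in pedigree: ",
         df$animal[duplicated(df$animal)][1L])
  parents <- unique(c(df$sire, df$dam))
  parents <- parents[!is.na(parents)]
  orphans <- setdiff(parents, df$animal)
  if (length(orphans) > 0L) {
    warning(length(orphans),
            " parent(s) not listed as animals; inserted as founders: ",
            paste(utils::head(orphans, 5L), collapse = ", "),
            if (length(orphans) > 5L) ", ..." else "")
    df <- rbind(data.frame(animal = orphans, sire = NA_character_,
                           dam = NA_character_, stringsAsFactors = FALSE),
                df[, c("animal", "sire", "dam")])
  }
  ord <- ped_toposort(df)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df$ordinal_index <- seq_len(nrow(df))
  df$F <- ped_inbreeding_sorted(df)
  class(df) <- c("ped_table", "data.frame")
  df
}

# Kahn's algorithm; errors with an animal on the cycle if one exists.
ped_toposort <- function(df) {
  n <- nrow(df)
  idx <- seq_len(n)
  names(idx) <- df$animal
  si <- idx[df$sire]  # NA where unknown
  di <- idx[df$dam]
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < n) {
    bad <- df$animal[setdiff(seq_len(n), out)][1L]
    stop("pedigree contains a cycle involving animal '", bad, "'")
  }
  out
}

# Inbreeding for a sorted pedigree via the tabular relationship recursion.
# O(n^2) time/memory; fine at desk scale, capped to stay honest about it.
ped_inbreeding_sorted <- function(df, cap = 5000L) {
  n <- nrow(df)
  if (n == 0L) return(numeric(0))
  if (n > cap)
    stop("pedigree of ", n, " animals exceeds the dense-inbreeding cap (",
         cap, ")")
  A <- ped_tabular_A(df)
  diag(A) - 1
}

# Dense tabular A over a sorted ped_table-like data frame.
ped_tabular_A <- function(df) {
  n <- nrow(df)
  idx <- seq_len(n)
  names(idx) <- df$animal
  si <- unname(idx[df$sire])
  di <- unname(idx[df$dam])
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(s)) row <- row + 0.5 * A[j, s]
      if (!is.na(d)) row <- row + 0.5 * A[j, d]
      A[j, i] <- row
      A[i, j] <- row
    }
    asd <- if (!is.na(s) && !is.na(d)) A[s, d] else 0
    A[i, i] <- 1 + 0.5 * asd
  }
  dimnames(A) <- list(df$animal, df$animal)
  A
}

#' Inbreeding coefficients
#'
#' Returns the inbreeding coefficient F for every animal, computed as half
#' the numerator relationship between its parents (0 for founders and for
#' animals with any unknown parent).
#'
#' @param ped A \code{ped_table}.
#' @return Named numeric vector of F in pedigree order.
#' @export
inbreeding <- function(ped) {
  stopifnot(inherits(ped, "ped_table"))
  stats::setNames(ped$F, ped$animal)
}

#' Numerator relationship matrix A
#'
#' Dense pedigree relationship matrix by the tabular method:
#' \eqn{a_{ii} = 1 + F_i}, \eqn{a_{ij} = (a_{j,s_i} + a_{j,d_i})/2} with
#' unknown parents contributing zero.
#'
#' @param ped A \code{ped_table}.
#' @param subset Optional character vector of animal ids; the returned matrix
#'   is restricted to these ids in the given order.
#' @param cap Maximum pedigree size for the dense computation.
#' @return A \code{rel_matrix} (dense symmetric matrix with a
#'   \code{kind} attribute \code{"A"} and animal ids as dimnames).
#' @export
a_matrix <- function(ped, subset = NULL, cap = 5000L) {
  stopifnot(inherits(ped, "ped_table"))
  if (nrow(ped) > cap)
    stop("pedigree exceeds dense A cap (", cap, " animals)")
  A <- ped_tabular_A(ped)
  if (!is.null(subset)) {
    missing_ids <- setdiff(subset, ped$animal)
    if (length(missing_ids) > 0L)
      stop("subset ids absent from pedigree: ",
           paste(missing_ids, collapse = ", "))
    A <- A[subset, subset, drop = FALSE]
  }
  rel_matrix(A, kind = "A")
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Assembles A-inverse directly from pedigree structure (Henderson's rules
#' with inbreeding): each animal contributes through its Mendelian-sampling
#' variance \eqn{d_i = 1 - (1+F_s)/4 - (1+F_d)/4}, terms dropped for unknown
#' parents.
#'
#' @param ped A \code{ped_table} (F already computed).
#' @return A sparse symmetric \code{\link[Matrix]{dsCMatrix}} with animal ids
#'   as dimnames, over all pedigree animals.
#' @export
a_inverse <- function(ped) {
  stopifnot(inherits(ped, "ped_table"))
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$animal
  si <- unname(idx[ped$sire])
  di <- unname(idx[ped$dam])
  Fv <- ped$F
  Fs <- ifelse(is.na(si), NA, Fv[si])
  Fd <- ifelse(is.na(di), NA, Fv[di])
  d <- 1 - ifelse(is.na(Fs), 0, 0.25 * (1 + Fs)) -
    ifelse(is.na(Fd), 0, 0.25 * (1 + Fd))
  if (any(d <= 0))
    stop("non-positive Mendelian sampling variance at animal '",
         ped$animal[which(d <= 0)[1L]], "' (corrupt inbreeding?)")
  w <- 1 / d
  ii <- jj <- integer(0)
  xx <- numeric(0)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v)
  }
  for (i in seq_len(n)) {
    s <- si[i]; d2 <- di[i]
    add(i, i, w[i])
    for (p in c(s, d2)) {
      if (!is.na(p)) {
        add(i, p, -0.5 * w[i]); add(p, i, -0.5 * w[i])
        add(p, p, 0.25 * w[i])
      }
    }
    if (!is.na(s) && !is.na(d2)) {
      add(s, d2, 0.25 * w[i]); add(d2, s, 0.25 * w[i])
    }
  }
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                            dimnames = list(ped$animal, ped$animal))
  Matrix::forceSymmetric(M)
}

#' Pedigree relationship block for genotyped animals (A22)
#'
#' @param ped A \code{ped_table}.
#' @param genotyped_ids Animal ids in genotype-file order.
#' @return \code{rel_matrix} of kind \code{"A22"} in \code{genotyped_ids}
#'   order.
#' @export
a22 <- function(ped, genotyped_ids) {
  if (length(genotyped_ids) == 0L) stop("empty genotyped id set")
  A <- a_matrix(ped, subset = genotyped_ids)
  attr(A, "kind") <- "A22"
  A
}

#' Construct a relationship-matrix object
#'
#' Thin wrapper tagging a symmetric numeric matrix with its kind
#' (\code{"A"}, \code{"A22"}, \code{"G"} or \code{"Hinv_block"}).
#'
#' @param m Symmetric numeric matrix with id dimnames.
#' @param kind Character tag.
#' @return The matrix with class \code{rel_matrix} and a \code{kind}
#'   attribute.
#' @export
rel_matrix <- function(m, kind = c("A", "A22", "G", "Hinv_block")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (nrow(m) > 0L && max(abs(m - t(m))) > 1e-10)
    stop("relationship matrix not symmetric")
  m <- (m + t(m)) / 2
  structure(m, kind = kind, class = c("rel_matrix", class(m)))
}

#' @export
print.ped_table <- function(x, ...) {
  cat("<ped_table> ", nrow(x), " animals, ",
      sum(is.na(x$sire) & is.na(x$dam)), " founders, mean F = ",
      format(mean(x$F), digits = 4), "\n", sep = "")
  NextMethod()
}

#' Export a sparse matrix in MatrixMarket coordinate format
#'
#' @param m A sparse (or dense) matrix.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_matrix_market <- function(m, path) {
  Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                          "generalMatrix"), "CsparseMatrix"),
                  path)
  invisible(path)
}
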