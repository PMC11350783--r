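#' Genotype container
#'
#' Builds the package's genotype container: a gene-content matrix (counted
#' copies of the A1 allele, \code{NA} = missing call) with a marker map,
#' per-SNP allele frequencies of the counted allele, and per-SNP weights
#' (the diagonal of D in the weighted genomic relationship matrix,
#' initialized to 1).
#'
#' @param calls Integer matrix animals x SNPs with entries 0/1/2/NA.
#' @param map Data frame with columns \code{snp}, \code{chrom}, \code{pos}
#'   (1-based bp) and optionally \code{a1}, \code{a2} allele labels.
#' @param animal_ids Character vector of row ids.
#' @return A \code{genotype_set} list with elements \code{calls}, \code{map},
#'   \code{animal_ids}, \code{p_hat}, \code{weights_D}.
#' @export
genotype_set <- function(calls, map, animal_ids = rownames(calls)) {
  stopifnot(is.matrix(calls), nrow(map) == ncol(calls))
  if (is.null(animal_ids)) stop("animal ids required")
  if (anyDuplicated(animal_ids)) stop("duplicate animal id in genotype set")
  if (anyDuplicated(map$snp)) stop("duplicate SNP id")
  if (any(map$pos <= 0)) stop("non-positive SNP position")
  if (is.null(map$a1)) map$a1 <- "A"
  if (is.null(map$a2)) map$a2 <- "B"
  # sort map (and columns) by chromosome then position
  ord <- order(chrom_rank(map$chrom), map$pos)
  map <- map[ord, , drop = FALSE]
  calls <- calls[, ord, drop = FALSE]
  rownames(map) <- NULL
  dimnames(calls) <- list(animal_ids, map$snp)
  g <- list(calls = calls, map = map, animal_ids = animal_ids,
            p_hat = allele_freq(calls),
            weights_D = stats::setNames(rep(1, nrow(map)), map$snp))
  class(g) <- "genotype_set"
  g
}

# numeric-first chromosome ordering; X/Y/MT after autosomes
chrom_rank <- function(ch) {
  num <- suppressWarnings(as.numeric(ch))
  rank_extra <- match(toupper(as.character(ch)), c("X", "Y", "MT"))
  ifelse(!is.na(num), num, 1000 + ifelse(is.na(rank_extra), 99, rank_extra))
}

allele_freq <- function(calls) {
  colMeans(calls, na.rm = TRUE) / 2
}

#' @export
print.genotype_set <- function(x, ...) {
  cat("<genotype_set> ", nrow(x$calls), " animals x ", ncol(x$calls),
      " SNPs on ", length(unique(x$map$chrom)), " chromosome(s); missing ",
      format(100 * mean(is.na(x$calls)), digits = 3), "%\n", sep = "")
  invisible(x)
}

#' Read PLINK genotypes
#'
#' Reads either text (\code{.ped}/\code{.map}) or binary
#' (\code{.bed}/\code{.bim}/\code{.fam}) PLINK filesets. For the binary
#' format the counted (A1) allele is taken from the \code{.bim}; for the
#' text format the counted allele is the minor allele observed in the data
#' (ties broken alphabetically).
#'
#' @param prefix Path prefix without extension.
#' @param format \code{"ped"} or \code{"bed"}.
#' @return A \code{genotype_set}.
#' @export
read_plink <- function(prefix, format = c("ped", "bed")) {
  format <- match.arg(format)
  if (format == "ped") read_plink_text(prefix) else read_plink_bed(prefix)
}

read_plink_text <- function(prefix) {
  map <- utils::read.table(paste0(prefix, ".map"), header = FALSE,
                           colClasses = "character")
  names(map)[1:4] <- c("chrom", "snp", "cm", "pos")
  map$pos <- as.integer(map$pos)
  if (any(is.na(map$pos))) stop("unparseable SNP position in .map")
  ped <- utils::read.table(paste0(prefix, ".ped"), header = FALSE,
                           colClasses = "character")
  m <- nrow(map)
  if (ncol(ped) != 6 + 2 * m)
    stop(".ped column count does not match .map (", ncol(ped), " vs ",
         6 + 2 * m, ")")
  ids <- ped[[2]]
  if (anyDuplicated(ids)) stop("duplicate animal in .ped")
  n <- nrow(ped)
  calls <- matrix(NA_integer_, n, m)
  a1 <- a2 <- character(m)
  for (j in seq_len(m)) {
    al1 <- ped[[6 + 2 * j - 1]]
    al2 <- ped[[6 + 2 * j]]
    obs <- c(al1, al2)
    obs <- obs[obs != "0"]
    alleles <- sort(unique(obs))
    if (length(alleles) > 2)
      stop("SNP ", map$snp[j], " has >2 alleles")
    if (length(alleles) == 0) alleles <- c("A", "B")
    if (length(alleles) == 1) alleles <- c(alleles, alleles)
    # counted allele = minor (alphabetical tie-break via sort order)
    cnt1 <- sum(obs == alleles[1])
    cnt2 <- sum(obs == alleles[2])
    counted <- if (cnt1 <= cnt2) alleles[1] else alleles[2]
    other <- setdiff(alleles, counted)
    if (length(other) == 0) other <- counted
    a1[j] <- counted
    a2[j] <- other[1]
    gj <- (al1 == counted) + (al2 == counted)
    gj[al1 == "0" | al2 == "0"] <- NA_integer_
    calls[, j] <- as.integer(gj)
  }
  genotype_set(calls,
               data.frame(snp = map$snp, chrom = map$chrom, pos = map$pos,
                          a1 = a1, a2 = a2, stringsAsFactors = FALSE),
               animal_ids = ids)
}

read_plink_bed <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           colClasses = "character")
  names(bim)[1:6] <- c("chrom", "snp", "cm", "pos", "a1", "a2")
  bim$pos <- as.integer(bim$pos)
  if (any(is.na(bim$pos))) stop("unparseable SNP position in .bim")
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           colClasses = "character")
  ids <- fam[[2]]
  if (anyDuplicated(ids)) stop("duplicate animal in .fam")
  n <- length(ids)
  m <- nrow(bim)
  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L)))
    stop("not a SNP-major PLINK .bed file")
  bytes_per_snp <- ceiling(n / 4)
  raw <- readBin(con, "raw", bytes_per_snp * m)
  if (length(raw) < bytes_per_snp * m) stop("truncated .bed file")
  # decode 2-bit codes: 00 -> 2 copies of A1, 10 -> 1, 11 -> 0, 01 -> NA
  codes <- matrix(NA_integer_, 4, length(raw))
  rw <- as.integer(raw)
  for (k in 0:3) {
    two_bits <- bitwAnd(bitwShiftR(rw, 2L * k), 3L)
    codes[k + 1, ] <- c(2L, NA_integer_, 1L, 0L)[two_bits + 1L]
  }
  dim(codes) <- c(4 * bytes_per_snp, m)
  calls <- codes[seq_len(n), , drop = FALSE]
  genotype_set(calls,
               data.frame(snp = bim$snp, chrom = bim$chrom, pos = bim$pos,
                          a1 = bim$a1, a2 = bim$a2, stringsAsFactors = FALSE),
               animal_ids = ids)
}

#' Write PLINK genotypes
#'
#' Writes a \code{genotype_set} as a PLINK fileset, text or binary.
#'
#' @param g A \code{genotype_set}.
#' @param prefix Output path prefix.
#' @param format \code{"ped"} or \code{"bed"}.
#' @return \code{prefix}, invisibly.
#' @export
write_plink <- function(g, prefix, format = c("ped", "bed")) {
  format <- match.arg(format)
  map <- g$map
  if (format == "ped") {
    utils::write.table(data.frame(map$chrom, map$snp, 0, map$pos),
                       paste0(prefix, ".map"), row.names = FALSE,
                       col.names = FALSE, quote = FALSE, sep = "\t")
    n <- nrow(g$calls)
    al <- matrix("0", n, 2L * ncol(g$calls))
    for (j in seq_len(ncol(g$calls))) {
      gj <- g$calls[, j]
      c1 <- ifelse(is.na(gj), "0", ifelse(gj >= 1, map$a1[j], map$a2[j]))
      c2 <- ifelse(is.na(gj), "0", ifelse(gj == 2, map$a1[j], map$a2[j]))
      al[, 2L * j - 1L] <- c1
      al[, 2L * j] <- c2
    }
    ped <- cbind(g$animal_ids, g$animal_ids, "0", "0", "0", "-9", al)
    utils::write.table(ped, paste0(prefix, ".ped"), row.names = FALSE,
                       col.names = FALSE, quote = FALSE, sep = " ")
  } else {
    utils::write.table(data.frame(map$chrom, map$snp, 0, map$pos,
                                  map$a1, map$a2),
                       paste0(prefix, ".bim"), row.names = FALSE,
                       col.names = FALSE, quote = FALSE, sep = "\t")
    utils::write.table(data.frame(g$animal_ids, g$animal_ids, 0, 0, 0, -9),
                       paste0(prefix, ".fam"), row.names = FALSE,
                       col.names = FALSE, quote = FALSE, sep = " ")
    n <- nrow(g$calls)
    bytes_per_snp <- ceiling(n / 4)
    con <- file(paste0(prefix, ".bed"), "wb")
    on.exit(close(con))
    writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
    code_of <- function(gj) {
      # gene content -> 2-bit code
      out <- integer(length(gj))
      out[is.na(gj)] <- 1L
      out[!is.na(gj) & gj == 2L] <- 0L
      out[!is.na(gj) & gj == 1L] <- 2L
      out[!is.na(gj) & gj == 0L] <- 3L
      out
    }
    buf <- raw(bytes_per_snp * ncol(g$calls))
    pos <- 1L
    for (j in seq_len(ncol(g$calls))) {
      cd <- code_of(g$calls[, j])
      length(cd) <- 4L * bytes_per_snp  # pads with NA
      cd[is.na(cd)] <- 0L
      cd <- matrix(cd, 4L)
      byte <- cd[1, ] + cd[2, ] * 4L + cd[3, ] * 16L + cd[4, ] * 64L
      buf[pos:(pos + bytes_per_snp - 1L)] <- as.raw(byte)
      pos <- pos + bytes_per_snp
    }
    writeBin(buf, con)
  }
  invisible(prefix)
}

#' Merge two genotyping panels on their common markers
#'
#' Keeps the SNPs present in both panels, harmonizes the counted allele
#' (flipping gene content 0<->2 where the panels count opposite alleles),
#' drops SNPs whose allele pairs cannot be reconciled (with a warning), and
#' stacks the animals.
#'
#' @param a,b \code{genotype_set}s with disjoint animal sets.
#' @return A merged \code{genotype_set}.
#' @export
merge_panels <- function(a, b) {
  if (length(intersect(a$animal_ids, b$animal_ids)) > 0L)
    stop("panels share animals: ",
         paste(utils::head(intersect(a$animal_ids, b$animal_ids), 3L),
               collapse = ", "))
  common <- intersect(a$map$snp, b$map$snp)
  if (length(common) == 0L) stop("no common SNPs between panels")
  ia <- match(common, a$map$snp)
  ib <- match(common, b$map$snp)
  ma <- a$map[ia, ]
  mb <- b$map[ib, ]
  same <- ma$a1 == mb$a1 & ma$a2 == mb$a2
  flip <- ma$a1 == mb$a2 & ma$a2 == mb$a1
  keep <- same | flip
  n_drop <- sum(!keep)
  if (n_drop > 0L)
    warning(n_drop, " common SNP(s) dropped: irreconcilable alleles")
  if (!any(keep)) stop("no reconcilable common SNPs between panels")
  ia <- ia[keep]; ib <- ib[keep]
  flip <- flip[keep]
  calls_b <- b$calls[, ib, drop = FALSE]
  calls_b[, flip] <- 2L - calls_b[, flip]
  calls <- rbind(a$calls[, ia, drop = FALSE], calls_b)
  genotype_set(calls, a$map[ia, c("snp", "chrom", "pos", "a1", "a2")],
               animal_ids = c(a$animal_ids, b$animal_ids))
}

#' Call-rate quality control
#'
#' Discards SNPs whose call rate (fraction of non-missing genotypes) is
#' strictly below the threshold; a SNP at exactly the threshold is kept.
#'
#' @param g A \code{genotype_set}.
#' @param threshold Minimum call rate in (0, 1]; default 0.95.
#' @return Filtered \code{genotype_set}; attribute \code{n_removed} records
#'   the number of discarded SNPs.
#' @export
qc_call_rate <- function(g, threshold = 0.95) {
  stopifnot(threshold > 0, threshold <= 1)
  cr <- colMeans(!is.na(g$calls))
  keep <- cr >= threshold
  if (!any(keep)) stop("call-rate QC removed every SNP")
  message(sum(!keep), " SNP(s) removed by call-rate QC (< ",
          threshold * 100, "%)")
  out <- genotype_set(g$calls[, keep, drop = FALSE],
                      g$map[keep, , drop = FALSE],
                      animal_ids = g$animal_ids)
  out$weights_D <- g$weights_D[keep]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Centred gene-content matrix Z
#'
#' Centres gene content by twice the counted-allele frequency; missing calls
#' are mean-imputed (0 after centring). Monomorphic SNPs yield all-zero
#' columns and are flagged.
#'
#' @param g A \code{genotype_set}.
#' @return Numeric matrix animals x SNPs with attribute \code{monomorphic}
#'   (logical per SNP).
#' @export
center_matrix <- function(g) {
  p <- g$p_hat
  Z <- sweep(g$calls, 2L, 2 * p)
  Z[is.na(Z)] <- 0
  mono <- is.nan(p) | p <= 0 | p >= 1
  if (any(mono)) {
    Z[, mono] <- 0
    p[is.nan(p)] <- 0
  }
  attr(Z, "monomorphic") <- unname(mono)
  Z
}

#' Genomic relationship matrix G
#'
#' VanRaden-style genomic relationship matrix with per-SNP weights:
#' \deqn{G = Z D Z' / \sum_j 2 p_j (1 - p_j)} where Z is the centred
#' gene-content matrix and D = diag(weights).
#'
#' @param Z Centred gene-content matrix (see [center_matrix()]).
#' @param weights_D Per-SNP positive weights; default all 1.
#' @param p_hat Counted-allele frequencies.
#' @return \code{rel_matrix} of kind \code{"G"}.
#' @export
g_matrix <- function(Z, weights_D = rep(1, ncol(Z)), p_hat) {
  stopifnot(ncol(Z) == length(weights_D), ncol(Z) == length(p_hat))
  p <- p_hat
  p[is.nan(p)] <- 0
  denom <- sum(2 * p * (1 - p))
  if (denom <= 0) stop("all SNPs monomorphic: zero 2p(1-p) denominator")
  G <- tcrossprod(sweep(Z, 2L, weights_D, "*"), Z) / denom
  G <- (G + t(G)) / 2
  dimnames(G) <- list(rownames(Z), rownames(Z))
  rel_matrix(G, kind = "G")
}

#' Export a relationship matrix as square CSV
#'
#' Writes a square CSV with animal ids as header and first column.
#'
#' @param m A \code{rel_matrix} (or any square matrix with id dimnames).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_rel_csv <- function(m, path) {
  df <- data.frame(id = rownames(m), unclass(m), check.names = FALSE)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Blend and tune G against A22
#'
#' Optionally rescales G so that its mean diagonal and mean off-diagonal
#' match those of A22 (two-coefficient moment tuning, \eqn{G^* = a + bG}),
#' then blends \eqn{\alpha G^* + (1-\alpha) A_{22}} so the result is
#' invertible for \eqn{\alpha < 1}.
#'
#' @param G \code{rel_matrix} of kind \code{"G"}.
#' @param A22 \code{rel_matrix} of kind \code{"A22"}, same id order.
#' @param alpha Blend weight on G, in (0, 1]; default 0.95.
#' @param tune Apply moment tuning first; default TRUE.
#' @return Blended \code{rel_matrix} of kind \code{"G"}.
#' @export
blend_tune <- function(G, A22, alpha = 0.95, tune = TRUE) {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (!identical(rownames(G), rownames(A22)))
    stop("G and A22 id order differ")
  n <- nrow(G)
  if (tune && n > 1) {
    off <- row(G) != col(G)
    mdG <- mean(diag(G)); moG <- mean(G[off])
    mdA <- mean(diag(A22)); moA <- mean(A22[off])
    if (abs(mdG - moG) < 1e-12) {
      b <- 1; a <- mdA - mdG
    } else {
      b <- (mdA - moA) / (mdG - moG)
      a <- mdA - b * mdG
    }
    G <- a + b * G
  }
  out <- alpha * G + (1 - alpha) * unclass(A22)
  rel_matrix(unclass(out), kind = "G")
}
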