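# Genotype file input/output (PLINK bed/bim/fam and delimited tables),
# the standard pre-treatment quality-control filters, genetic relatedness
# matrix computation and relatedness pruning.

# ---- readers / writers ----------------------------------------------------

#' Read a genotype matrix from disk
#'
#' @param path file path (tsv) or PLINK prefix (the `.bed`, `.bim`,
#'   `.fam` extensions are appended).
#' @param format `"tsv"` (tab-separated: header of variant ids, first
#'   column `IID`) or `"plink_bed"` (SNP-major bed v1.00).
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("tsv", "plink_bed")) {
  format <- match.arg(format)
  if (format == "tsv") return(read_genotypes_tsv(path))
  read_plink(path)
}

#' Write a genotype matrix to disk
#'
#' @param G a [genotype_matrix()].
#' @param path output path (tsv) or PLINK prefix.
#' @param format `"tsv"` or `"plink_bed"`.
#' @return the path/prefix, invisibly.
#' @export
write_genotypes <- function(G, path, format = c("tsv", "plink_bed")) {
  format <- match.arg(format)
  if (format == "tsv") write_genotypes_tsv(G, path) else write_plink(G, path)
  invisible(path)
}

read_genotypes_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  if (!"IID" %in% names(tab)) stop("tsv genotype file must have an IID column")
  ids <- tab$IID
  m <- as.matrix(tab[setdiff(names(tab), "IID")])
  suppressWarnings(storage <- matrix(as.numeric(m), nrow(m), ncol(m)))
  bad <- which((is.na(storage) & !(m %in% c("NA", ""))) |
                 (!is.na(storage) & !storage %in% c(0, 1, 2)))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(m))
    stop(sprintf("invalid genotype value '%s' at row %d, column '%s'",
                 m[bad[1]], rc[1], colnames(m)[rc[2]]))
  }
  genotype_matrix(storage, sample_ids = ids,
                  variant_ids = colnames(m))
}

write_genotypes_tsv <- function(G, path) {
  tab <- data.frame(IID = G$sample_ids, G$counts, check.names = FALSE)
  colnames(tab) <- c("IID", G$variant_ids)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write phenotypes/covariates as a FID/IID table
#'
#' @param ids sample ids (used for both FID and IID).
#' @param values vector or data frame of value columns.
#' @param path output path.
#' @param name column name when `values` is a bare vector.
#' @export
write_phenotype_tsv <- function(ids, values, path, name = "pheno") {
  if (is.null(dim(values))) {
    values <- stats::setNames(data.frame(values), name)
  }
  tab <- data.frame(FID = ids, IID = ids, values, check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# PLINK .bed v1.00, SNP-major. 2-bit codes per genotype, 4 per byte,
# low bits first: 00 = 2 copies of allele A1, 10 = 1 copy, 11 = 0 copies,
# 01 = missing. Counts stored here are dosages of A1.
.BED_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))
.BED_CODE <- c(`2` = 0L, miss = 1L, `1` = 2L, `0` = 3L)

write_plink <- function(G, prefix) {
  counts <- G$counts
  n <- nrow(counts); p <- ncol(counts)
  code <- matrix(.BED_CODE[["miss"]], n, p)
  code[!is.na(counts) & counts == 2] <- 0L
  code[!is.na(counts) & counts == 1] <- 2L
  code[!is.na(counts) & counts == 0] <- 3L
  bpv <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(.BED_MAGIC, con)
  pad <- 4 * bpv - n
  for (j in seq_len(p)) {
    cj <- c(code[, j], rep(0L, pad))
    dim(cj) <- c(4, bpv)
    bytes <- as.raw(cj[1, ] + cj[2, ] * 4L + cj[3, ] * 16L + cj[4, ] * 64L)
    writeBin(bytes, con)
  }
  bim <- data.frame(chr = 1L, id = G$variant_ids, cm = 0,
                    pos = seq_len(p), a1 = "A", a2 = "B")
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  fam <- data.frame(fid = G$sample_ids, iid = G$sample_ids, pid = 0L,
                    mid = 0L, sex = 0L, pheno = -9L)
  write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("file not found: ", f)
  bim_tab <- read.table(bim, header = FALSE, colClasses = "character")
  fam_tab <- read.table(fam, header = FALSE, colClasses = "character")
  p <- nrow(bim_tab); n <- nrow(fam_tab)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3 || !identical(raw[1:3], .BED_MAGIC)) {
    stop("not a SNP-major PLINK bed v1.00 file (bad magic bytes): ", bed)
  }
  body <- raw[-(1:3)]
  bpv <- ceiling(n / 4)
  if (length(body) != bpv * p) {
    stop(sprintf("bed size mismatch: %d data bytes, expected %d (n=%d, p=%d)",
                 length(body), bpv * p, n, p))
  }
  # unpack 2-bit codes: for each byte, 4 genotypes, low bits first
  b <- as.integer(body)
  codes <- rbind(b %% 4L, (b %/% 4L) %% 4L, (b %/% 16L) %% 4L, b %/% 64L)
  dim(codes) <- c(4 * bpv, p)
  codes <- codes[seq_len(n), , drop = FALSE]
  counts <- matrix(NA_integer_, n, p)
  counts[codes == 0L] <- 2L
  counts[codes == 2L] <- 1L
  counts[codes == 3L] <- 0L
  genotype_matrix(counts, sample_ids = fam_tab[[2]], variant_ids = bim_tab[[2]])
}

# ---- quality control ------------------------------------------------------

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit chi-square of the three genotype
#' counts against Hardy-Weinberg expectations at the estimated allele
#' frequency.
#'
#' @param n0,n1,n2 counts of individuals carrying 0, 1, 2 copies.
#' @return list with `chisq` and `p_value` (vectorized).
#' @export
hwe_test <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  f <- (2 * n2 + n1) / (2 * n)
  e0 <- n * (1 - f)^2; e1 <- n * 2 * f * (1 - f); e2 <- n * f^2
  chisq <- ifelse(n == 0 | f == 0 | f == 1, 0,
                  (n0 - e0)^2 / pmax(e0, .Machine$double.xmin) +
                  (n1 - e1)^2 / pmax(e1, .Machine$double.xmin) +
                  (n2 - e2)^2 / pmax(e2, .Machine$double.xmin))
  list(chisq = chisq, p_value = pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Quality-control filter for genotype matrices
#'
#' Applies, in a fixed documented order: (1) variant callrate, (2) sample
#' callrate, (3) minor allele frequency, (4) Hardy-Weinberg equilibrium
#' (chi-square, keep if p > `hwe_p_min`), (5) removal of remaining
#' monomorphic variants. Thresholds follow common GWAS pre-treatment
#' practice; semantics are strict "keep if better than threshold".
#'
#' @param G a [genotype_matrix()].
#' @param callrate_min minimum callrate for variants and samples
#'   (default 0.99).
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param hwe_p_min minimum HWE p-value (default 1e-7).
#' @return list with `geno` (filtered [genotype_matrix()]) and `report`
#'   (class `qc_report`: counts in/out and removal logs with reasons).
#' @export
qc_filter <- function(G, callrate_min = 0.99, maf_min = 0.01,
                      hwe_p_min = 1e-7) {
  stopifnot(callrate_min >= 0, callrate_min <= 1, maf_min >= 0, maf_min <= 1)
  counts <- G$counts
  n_in <- nrow(counts); p_in <- ncol(counts)
  removed_v <- data.frame(variant = character(0), reason = character(0))
  removed_s <- data.frame(sample = character(0), reason = character(0))
  vkeep <- rep(TRUE, p_in); skeep <- rep(TRUE, n_in)

  drop_variants <- function(idx, reason) {
    idx <- idx[vkeep[idx]]
    if (length(idx)) {
      removed_v <<- rbind(removed_v, data.frame(
        variant = G$variant_ids[idx], reason = reason))
      vkeep[idx] <<- FALSE
    }
  }
  # 1. variant callrate
  vcall <- colMeans(!is.na(counts))
  drop_variants(which(vcall < callrate_min), "callrate")
  # 2. sample callrate (on surviving variants)
  scall <- rowMeans(!is.na(counts[, vkeep, drop = FALSE]))
  bad_s <- which(scall < callrate_min)
  if (length(bad_s)) {
    removed_s <- rbind(removed_s, data.frame(
      sample = G$sample_ids[bad_s], reason = "callrate"))
    skeep[bad_s] <- FALSE
  }
  sub <- counts[skeep, , drop = FALSE]
  # 3. MAF
  frq <- colMeans(sub, na.rm = TRUE) / 2
  maf <- pmin(frq, 1 - frq)
  drop_variants(which(!(maf > maf_min) | is.na(maf)), "maf")
  # 4. HWE
  active <- which(vkeep)
  if (length(active)) {
    n0 <- colSums(sub[, active, drop = FALSE] == 0, na.rm = TRUE)
    n1 <- colSums(sub[, active, drop = FALSE] == 1, na.rm = TRUE)
    n2 <- colSums(sub[, active, drop = FALSE] == 2, na.rm = TRUE)
    hw <- hwe_test(n0, n1, n2)
    drop_variants(active[!(hw$p_value > hwe_p_min)], "hwe")
  }
  # 5. monomorphic leftovers (possible when maf_min = 0)
  active <- which(vkeep)
  if (length(active)) {
    st <- col_mean_sd(sub[, active, drop = FALSE])
    drop_variants(active[!(st[, 2] > 0)], "monomorphic")
  }
  if (!any(vkeep)) stop("all variants removed by QC")
  out <- genotype_matrix(counts[skeep, vkeep, drop = FALSE],
                         sample_ids = G$sample_ids[skeep],
                         variant_ids = G$variant_ids[vkeep],
                         true_freqs = G$true_freqs[vkeep])
  report <- structure(list(n_in = n_in, p_in = p_in,
                           n_out = sum(skeep), p_out = sum(vkeep),
                           removed_variants = removed_v,
                           removed_samples = removed_s,
                           thresholds = c(callrate = callrate_min,
                                          maf = maf_min, hwe = hwe_p_min)),
                      class = "qc_report")
  list(geno = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: samples %d -> %d, variants %d -> %d\n",
              x$n_in, x$n_out, x$p_in, x$p_out))
  if (nrow(x$removed_variants)) {
    print(table(x$removed_variants$reason))
  }
  invisible(x)
}

#' Mean-impute missing genotypes
#'
#' Replaces missing allele counts by the variant's mean count. Intended
#' to run after QC and before standardization.
#'
#' @param G a [genotype_matrix()].
#' @return a [genotype_matrix()]-like object whose counts matrix is
#'   numeric with no missing entries (imputed values are not integer
#'   dosages, so the \{0,1,2\} invariant is deliberately relaxed).
#' @export
mean_impute <- function(G) {
  counts <- G$counts
  miss <- is.na(counts)
  if (any(miss)) {
    mu <- colMeans(counts, na.rm = TRUE)
    counts[miss] <- mu[col(counts)[miss]]
  }
  out <- G
  out$counts <- counts
  out
}

# ---- GRM and relatedness --------------------------------------------------

#' Compute the genetic relatedness matrix
#'
#' `K = Z Z' / p` on standardized genotypes; the off-diagonals measure
#' genomic relatedness (expected 0 for unrelated individuals, with
#' standard deviation about `1/sqrt(p)` under linkage equilibrium).
#'
#' @param Z a `standardized_genotypes` object or numeric matrix.
#' @return object of class `grm`: list with `K` (n x n symmetric) and
#'   `sample_ids`; attribute `p` records the number of variants.
#' @export
compute_grm <- function(Z) {
  ids <- if (inherits(Z, "standardized_genotypes")) Z$sample_ids
  Zm <- if (inherits(Z, "standardized_genotypes")) Z$Z else as.matrix(Z)
  p <- ncol(Zm)
  if (p < 1) stop("need at least one variant")
  K <- tcrossprod(Zm) / p
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(Zm)))
  structure(list(K = K, sample_ids = ids), p = p, class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d samples, %d variants, mean diagonal %.3f\n",
              nrow(x$K), attr(x, "p"), mean(diag(x$K))))
  invisible(x)
}

#' Prune related individuals from a GRM
#'
#' Greedy removal: while any off-diagonal relatedness coefficient exceeds
#' the threshold, the individual involved in the most offending pairs is
#' removed (ties broken toward the later sample id), leaving one
#' individual per related cluster.
#'
#' @param grm a [compute_grm()] object (or bare symmetric matrix).
#' @param threshold relatedness cutoff (default 0.025).
#' @return list with `keep` (sample ids retained), `removed` (sample ids
#'   removed), `keep_idx` (row indices retained).
#' @export
prune_related <- function(grm, threshold = 0.025) {
  K <- if (inherits(grm, "grm")) grm$K else as.matrix(grm)
  ids <- if (inherits(grm, "grm")) grm$sample_ids else rownames(K) %||%
    paste0("s", seq_len(nrow(K)))
  n <- nrow(K)
  A <- abs(K) > threshold
  diag(A) <- FALSE
  alive <- rep(TRUE, n)
  removed <- integer(0)
  repeat {
    deg <- rowSums(A[, alive, drop = FALSE]) * alive
    if (!any(deg > 0)) break
    worst <- which(deg == max(deg))
    victim <- worst[length(worst)]  # tie: later sample id
    alive[victim] <- FALSE
    A[victim, ] <- FALSE
    A[, victim] <- FALSE
    removed <- c(removed, victim)
  }
  list(keep = ids[alive], removed = ids[removed], keep_idx = which(alive))
}

#' Write a GRM as a lower-triangle table
#'
#' @param grm a [compute_grm()] object.
#' @param path output path; columns `id1`, `id2`, `k`.
#' @export
write_grm_tsv <- function(grm, path) {
  n <- nrow(grm$K)
  idx <- which(lower.tri(grm$K, diag = TRUE), arr.ind = TRUE)
  tab <- data.frame(id1 = grm$sample_ids[idx[, 1]],
                    id2 = grm$sample_ids[idx[, 2]],
                    k = grm$K[idx])
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
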