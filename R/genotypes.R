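# Genotype panel container, QC filters, allele frequencies, centered
# marker matrix, genomic relationship matrix G (VanRaden method 1 with
# A22 blending) and the combined ssGBLUP inverse H^-1.

#' Construct a genotype panel
#'
#' A genotype panel couples an animal-by-SNP matrix of B-allele counts
#' (0/1/2, `NA` missing) with a marker map. Markers are sorted by
#' chromosome then position.
#'
#' @param codes numeric matrix, animals in rows, SNPs in columns; entries
#'   0, 1, 2 or `NA`. Row names are animal IDs, column names SNP IDs.
#' @param map data.frame with columns `snp`, `chrom`, `pos` (1-based bp);
#'   one row per column of `codes`.
#' @return Object of class `"genotype_panel"`: list with `codes`, `map`,
#'   `animals`, `snps`.
#' @export
genotype_panel <- function(codes, map) {
  codes <- as.matrix(codes)
  map <- as.data.frame(map)
  stopifnot(all(c("snp", "chrom", "pos") %in% names(map)),
            ncol(codes) == nrow(map))
  if (is.null(colnames(codes))) colnames(codes) <- map$snp
  stopifnot(identical(colnames(codes), as.character(map$snp)))
  if (is.null(rownames(codes))) rownames(codes) <- seq_len(nrow(codes))
  bad <- codes[!is.na(codes) & !(codes %in% c(0, 1, 2))]
  if (length(bad)) stop("genotype codes must be 0/1/2/NA; found ", bad[[1L]])
  ord <- order(.chrom_rank(map$chrom), map$pos)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  codes <- codes[, ord, drop = FALSE]
  structure(list(codes = codes,
                 map = map,
                 animals = rownames(codes),
                 snps = as.character(map$snp)),
            class = "genotype_panel")
}

# numeric chromosomes sort numerically; X/Y/MT after
.chrom_rank <- function(chrom) {
  chrom <- as.character(chrom)
  num <- suppressWarnings(as.numeric(chrom))
  ifelse(is.na(num), 1e6 + as.integer(factor(chrom)), num)
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("<genotype_panel> ", length(x$animals), " animals x ",
      length(x$snps), " SNPs on ",
      length(unique(x$map$chrom)), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' @rdname genotype_panel
#' @param x object to test.
#' @export
is.genotype_panel <- function(x) inherits(x, "genotype_panel")

#' B-allele frequencies and minor allele frequencies
#'
#' `freq(B) = (2 n_BB + n_AB) / (2 n_called)`; missing calls are excluded
#' from numerator and denominator. `MAF = min(freq, 1 - freq)`.
#'
#' @param panel a [genotype_panel].
#' @return data.frame with columns `snp`, `freq_b`, `maf`, `call_rate`,
#'   `n_called`. SNPs with zero calls get `NA` frequencies and are flagged
#'   in column `undefined`.
#' @export
allele_frequencies <- function(panel) {
  stopifnot(is.genotype_panel(panel))
  g <- panel$codes
  n_called <- colSums(!is.na(g))
  freq <- colSums(g, na.rm = TRUE) / (2 * n_called)
  freq[n_called == 0L] <- NA_real_
  data.frame(snp = panel$snps,
             freq_b = unname(freq),
             maf = unname(pmin(freq, 1 - freq)),
             call_rate = unname(n_called / nrow(g)),
             n_called = unname(n_called),
             undefined = unname(n_called == 0L),
             stringsAsFactors = FALSE)
}

#' MAF from genotype counts
#'
#' Convenience for published genotype-count tables: given counts of AA, AB
#' and BB animals, returns the minor allele frequency.
#'
#' @param n_aa,n_ab,n_bb genotype counts.
#' @return Minor allele frequency in `[0, 0.5]`.
#' @export
maf_from_counts <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  f <- (2 * n_bb + n_ab) / (2 * n)
  pmin(f, 1 - f)
}

#' Genotype quality control
#'
#' Removes, in order: SNPs mapped to sex chromosomes; monomorphic SNPs
#' (MAF = 0); SNPs with MAF below `maf_min`; SNPs with call rate below
#' `callrate_min`. Thresholds are strict: a SNP at exactly `maf_min` or
#' exactly `callrate_min` is retained. Each removed SNP is attributed to
#' the first filter that catches it.
#'
#' @param panel a [genotype_panel].
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param callrate_min minimum call rate (default 0.90).
#' @param autosomes_only drop sex-chromosome SNPs first (default TRUE).
#' @param sex_chroms chromosome labels treated as sex chromosomes.
#' @return list with `panel` (filtered [genotype_panel]) and `report`
#'   (class `"qc_report"`: removal counts per filter plus retained count).
#' @export
qc_filter <- function(panel, maf_min = 0.01, callrate_min = 0.90,
                      autosomes_only = TRUE, sex_chroms = c("X", "Y")) {
  stopifnot(is.genotype_panel(panel))
  m <- length(panel$snps)
  fr <- allele_frequencies(panel)
  caught <- rep(NA_character_, m)
  if (autosomes_only) {
    caught[is.na(caught) & panel$map$chrom %in% sex_chroms] <- "sex_chromosome"
  }
  caught[is.na(caught) & (!is.na(fr$maf) & fr$maf == 0)] <- "monomorphic"
  caught[is.na(caught) & !is.na(fr$maf) & fr$maf < maf_min] <- "low_maf"
  caught[is.na(caught) & fr$call_rate < callrate_min] <- "low_call_rate"
  keep <- is.na(caught)
  if (!any(keep)) stop("no SNPs survive quality control")
  report <- structure(list(
    n_input = m,
    removed = c(sex_chromosome = sum(caught == "sex_chromosome", na.rm = TRUE),
                monomorphic = sum(caught == "monomorphic", na.rm = TRUE),
                low_maf = sum(caught == "low_maf", na.rm = TRUE),
                low_call_rate = sum(caught == "low_call_rate", na.rm = TRUE)),
    retained = sum(keep),
    maf_min = maf_min, callrate_min = callrate_min
  ), class = "qc_report")
  out <- genotype_panel(panel$codes[, keep, drop = FALSE],
                        panel$map[keep, , drop = FALSE])
  list(panel = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> input:", x$n_input, "SNPs; retained:", x$retained, "\n")
  for (nm in names(x$removed)) {
    cat(sprintf("  removed %-14s %d\n", nm, x$removed[[nm]]))
  }
  invisible(x)
}

#' Write a QC report as TSV
#' @param report a `qc_report` from [qc_filter()].
#' @param path output path.
#' @export
write_qc_report <- function(report, path) {
  dt <- data.table::data.table(
    filter = c(names(report$removed), "retained", "input"),
    n_snps = c(unname(report$removed), report$retained, report$n_input))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Centered marker matrix
#'
#' Each entry becomes `code - 2 freq(B)`; missing codes are mean-imputed,
#' i.e. set to 0 after centering.
#'
#' @param panel a [genotype_panel].
#' @param freqs B-allele frequencies per SNP (defaults to observed
#'   frequencies from the panel).
#' @return Numeric matrix, animals by SNPs.
#' @export
center_markers <- function(panel, freqs = NULL) {
  stopifnot(is.genotype_panel(panel))
  if (is.null(freqs)) freqs <- allele_frequencies(panel)$freq_b
  stopifnot(length(freqs) == length(panel$snps))
  Z <- sweep(panel$codes, 2L, 2 * freqs, "-")
  Z[is.na(Z)] <- 0
  Z
}

#' Genomic relationship matrix (VanRaden method 1, blended)
#'
#' `G_raw = Z Z' / (2 sum p_j (1 - p_j))` with `Z` the centered marker
#' matrix; the returned matrix is
#' `blend_weight * G_raw + (1 - blend_weight) * A22`, which is positive
#' definite for `blend_weight < 1` and a positive-definite `A22`.
#'
#' @param panel a [genotype_panel] (post QC).
#' @param freqs B-allele frequencies used for centering and scaling
#'   (default observed).
#' @param blend_weight weight on the genomic component (default 0.95).
#' @param a22 pedigree relationships among the panel's animals, in panel
#'   order; required when `blend_weight < 1`. Identity may be supplied for
#'   pedigree-free analyses.
#' @return Object of class `"genomic_matrix"`: list with `G` (dense
#'   symmetric), `blend_weight`, `freqs`, `scale` (the `2 sum p(1-p)`
#'   denominator), `animals`.
#' @export
build_G <- function(panel, freqs = NULL, blend_weight = 0.95, a22 = NULL) {
  stopifnot(is.genotype_panel(panel))
  n <- length(panel$animals)
  if (n < 2L || length(panel$snps) < 2L) {
    stop("G requires at least 2 animals and 2 SNPs")
  }
  if (is.null(freqs)) freqs <- allele_frequencies(panel)$freq_b
  Z <- center_markers(panel, freqs)
  sc <- 2 * sum(freqs * (1 - freqs))
  if (sc <= 0) stop("all SNPs monomorphic: G scale is zero")
  G <- tcrossprod(Z) / sc
  if (blend_weight < 1) {
    if (is.null(a22)) stop("a22 is required for blending (blend_weight < 1)")
    a22 <- as.matrix(a22)
    if (!all(dim(a22) == n)) {
      stop("a22 dimensions (", nrow(a22), "x", ncol(a22),
           ") do not match the ", n, " panel animals")
    }
    G <- blend_weight * G + (1 - blend_weight) * a22
  }
  dimnames(G) <- list(panel$animals, panel$animals)
  structure(list(G = G, blend_weight = blend_weight, freqs = freqs,
                 scale = sc, animals = panel$animals),
            class = "genomic_matrix")
}

#' @export
print.genomic_matrix <- function(x, ...) {
  cat("<genomic_matrix> ", nrow(x$G), " animals, blend_weight = ",
      x$blend_weight, "\n", sep = "")
  invisible(x)
}

#' Combined pedigree-genomic inverse H^-1
#'
#' The single-step relationship inverse: `H^-1` equals `A^-1` everywhere,
#' plus `G^-1 - A22^-1` added in the genotyped-animal block.
#'
#' @param a_inv sparse `A^-1` over all pedigree animals (from
#'   [build_A_inverse()]), with ID dimnames.
#' @param g a `genomic_matrix` from [build_G()] (or a plain matrix) over
#'   the genotyped animals.
#' @param a22 pedigree relationship block for the same animals in the same
#'   order (from [subset_A22()]).
#' @param genotyped_ids IDs of the genotyped animals, ordered as in `g`.
#' @return Sparse symmetric `H^-1` with the same dimnames as `a_inv`.
#' @export
build_H_inverse <- function(a_inv, g, a22, genotyped_ids) {
  G <- if (inherits(g, "genomic_matrix")) g$G else as.matrix(g)
  genotyped_ids <- as.character(genotyped_ids)
  ids <- rownames(a_inv)
  if (is.null(ids)) stop("a_inv must carry animal IDs as dimnames")
  if (length(genotyped_ids) == 0L) return(a_inv)
  idx <- match(genotyped_ids, ids)
  if (anyNA(idx)) {
    stop("genotyped IDs absent from A^-1: ",
         paste(genotyped_ids[is.na(idx)][1:min(5, sum(is.na(idx)))],
               collapse = ", "))
  }
  stopifnot(all(dim(G) == length(idx)), all(dim(a22) == length(idx)))
  ev <- min(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < 1e-10) {
    stop("G is singular (min eigenvalue ", signif(ev, 3),
         "); blend with A22 (blend_weight < 1) before building H^-1")
  }
  Ginv <- chol2inv(chol(G))
  A22inv <- chol2inv(chol(as.matrix(a22)))
  delta <- (Ginv + t(Ginv)) / 2 - (A22inv + t(A22inv)) / 2
  H <- as(a_inv, "CsparseMatrix")
  H[idx, idx] <- H[idx, idx] + delta
  Matrix::forceSymmetric((H + Matrix::t(H)) / 2)
}

#' Read a genotype panel from PLINK-RAW-like TSV plus map TSV
#'
#' The genotype file has a header of SNP IDs preceded by an `animal`
#' column; one row per animal with codes 0/1/2 and `NA` for missing. The
#' map file has columns `snp`, `chrom`, `pos`.
#'
#' @param geno_path,map_path file paths.
#' @return A [genotype_panel].
#' @export
read_genotypes <- function(geno_path, map_path) {
  g <- data.table::fread(geno_path, header = TRUE, sep = "\t")
  stopifnot(names(g)[1L] == "animal")
  animals <- as.character(g$animal)
  codes <- as.matrix(g[, -1L, with = FALSE])
  rownames(codes) <- animals
  map <- data.table::fread(map_path, header = TRUE, sep = "\t",
                           colClasses = list(character = c("snp", "chrom")))
  map <- as.data.frame(map)[match(colnames(codes), map$snp), , drop = FALSE]
  if (anyNA(map$snp)) stop("map is missing SNPs present in the genotype file")
  genotype_panel(codes, map)
}

#' Write a genotype panel
#' @param panel a [genotype_panel].
#' @param geno_path,map_path output paths (TSV).
#' @export
write_genotypes <- function(panel, geno_path, map_path) {
  stopifnot(is.genotype_panel(panel))
  dt <- data.table::data.table(animal = panel$animals)
  dt <- cbind(dt, data.table::as.data.table(panel$codes))
  data.table::fwrite(dt, geno_path, sep = "\t", na = "NA", quote = FALSE)
  data.table::fwrite(panel$map, map_path, sep = "\t")
  invisible(geno_path)
}
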