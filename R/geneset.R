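# SNP-to-gene assignment (+/- 15 kb flank), significant-gene flagging
# from the top 1% of SNP effects, and exact hypergeometric gene-set
# enrichment.

#' Read a gene annotation from BED
#'
#' BED intervals are 0-based half-open on disk; they are converted to the
#' 1-based inclusive convention used internally (matching the marker map).
#'
#' @param path BED file (>= 4 columns: chrom, start, end, name).
#' @return data.frame `gene`, `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 4L) stop("BED file needs at least 4 columns (incl. name)")
  out <- data.frame(gene = as.character(dt[[4L]]),
                    chrom = as.character(dt[[1L]]),
                    start = as.integer(dt[[2L]]) + 1L,
                    end = as.integer(dt[[3L]]),
                    stringsAsFactors = FALSE)
  if (any(out$start > out$end)) stop("BED contains empty/negative intervals")
  if (anyDuplicated(out$gene)) stop("duplicated gene IDs in BED")
  out
}

#' Write a gene annotation as BED (0-based half-open)
#' @param annotation data.frame `gene`, `chrom`, `start`, `end` (1-based
#'   inclusive, as used internally).
#' @param path output path.
#' @export
write_bed <- function(annotation, path) {
  dt <- data.table::data.table(chrom = annotation$chrom,
                               start = annotation$start - 1L,
                               end = annotation$end,
                               name = annotation$gene)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' One set per line: name, description, then tab-separated gene IDs.
#'
#' @param path GMT file.
#' @return Named list of gene-ID vectors (class `"gmt_collection"`) with a
#'   `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, 1L) < 3L
  if (any(short)) stop("malformed GMT line(s): ", which(short)[1L])
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  attr(sets, "description") <- vapply(parts, `[[`, "", 2L)
  class(sets) <- "gmt_collection"
  sets
}

#' Write a GMT gene-set collection
#' @param sets named list of gene-ID vectors (optionally with a
#'   `description` attribute).
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- rep("", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Assign SNPs to genes within a flanking distance
#'
#' A SNP is assigned to a gene when its position lies within the gene or
#' at most `flank_bp` up- or downstream (boundaries inclusive):
#' `start - flank <= pos <= end + flank`. A SNP may hit several genes.
#'
#' @param map marker map data.frame (`snp`, `chrom`, `pos`; 1-based bp).
#' @param annotation gene annotation data.frame (`gene`, `chrom`, `start`,
#'   `end`; 1-based inclusive), e.g. from [read_bed()].
#' @param flank_bp flanking distance in bp (default 15 kb).
#' @return list with `assignment` (data.frame `snp`, `gene`) and
#'   `unassigned` (SNP IDs hitting no gene).
#' @export
assign_snps_to_genes <- function(map, annotation, flank_bp = 15000) {
  map <- as.data.frame(map)
  annotation <- as.data.frame(annotation)
  stopifnot(all(c("snp", "chrom", "pos") %in% names(map)),
            all(c("gene", "chrom", "start", "end") %in% names(annotation)))
  shared <- intersect(unique(map$chrom), unique(annotation$chrom))
  if (length(shared) == 0L) {
    warning("no shared chromosome labels between map (",
            length(unique(map$chrom)), ") and annotation (",
            length(unique(annotation$chrom)), ")")
  }
  snps <- data.table::data.table(chrom = as.character(map$chrom),
                                 start = map$pos, end = map$pos,
                                 snp = as.character(map$snp))
  genes <- data.table::data.table(chrom = as.character(annotation$chrom),
                                  start = annotation$start - flank_bp,
                                  end = annotation$end + flank_bp,
                                  gene = as.character(annotation$gene))
  data.table::setkey(genes, chrom, start, end)
  hits <- data.table::foverlaps(snps, genes, type = "within", nomatch = NULL)
  assignment <- data.frame(snp = hits$snp, gene = hits$gene,
                           stringsAsFactors = FALSE)
  assignment <- assignment[order(assignment$snp, assignment$gene), ,
                           drop = FALSE]
  rownames(assignment) <- NULL
  list(assignment = assignment,
       unassigned = setdiff(as.character(map$snp), assignment$snp))
}

#' Flag significant genes from top-ranked SNP effects
#'
#' Significant SNPs are the `ceiling(top_fraction * n_snps)` markers with
#' the largest absolute back-solved effects (ties broken by absolute
#' effect descending, then SNP ID ascending). `N` counts genes hit by at
#' least one analyzed SNP; significant genes are those hit by at least
#' one significant SNP, and `S` is their count.
#'
#' @param effects `marker_effects` (or data.frame with `snp`, `effect`).
#' @param mapping result of [assign_snps_to_genes()] (or its
#'   `assignment` data.frame).
#' @param top_fraction fraction of SNPs called significant (default 1%).
#' @return list: `significant_genes`, `universe` (analyzed genes), `N`,
#'   `S`, `significant_snps`.
#' @export
flag_significant_genes <- function(effects, mapping, top_fraction = 0.01) {
  assignment <- if (is.data.frame(mapping)) mapping else mapping$assignment
  stopifnot(all(c("snp", "gene") %in% names(assignment)),
            top_fraction > 0, top_fraction <= 1)
  n_top <- ceiling(top_fraction * nrow(effects))
  ord <- order(-abs(effects$effect), effects$snp)
  sig_snps <- effects$snp[ord][seq_len(n_top)]
  universe <- sort(unique(assignment$gene))
  sig_genes <- sort(unique(assignment$gene[assignment$snp %in% sig_snps]))
  list(significant_genes = sig_genes,
       universe = universe,
       N = length(universe),
       S = length(sig_genes),
       significant_snps = sig_snps)
}

#' Exact hypergeometric enrichment P-value
#'
#' Upper-tail probability of observing at least `g` significant genes in
#' a set of `k` genes, given `S` significant among `N` analyzed genes:
#' `P = 1 - sum_{i=0}^{g-1} C(S,i) C(N-S,k-i) / C(N,k)`, evaluated as the
#' upper-tail sum in log space for numerical safety.
#'
#' @param g observed significant genes in the set.
#' @param S total significant genes.
#' @param N total analyzed genes.
#' @param k genes in the set (among the analyzed genes).
#' @return P-value in (0, 1].
#' @export
hypergeometric_test <- function(g, S, N, k) {
  if (any(c(g, S, N, k) < 0) || g > k || g > S || S > N || k > N) {
    stop("inconsistent counts: need 0 <= g <= min(S, k) and S, k <= N")
  }
  if (g == 0) return(1)
  i <- seq(g, min(S, k))
  logp <- lchoose(S, i) + lchoose(N - S, k - i) - lchoose(N, k)
  mx <- max(logp)
  min(1, exp(mx + log(sum(exp(logp - mx)))))
}

#' Hypergeometric gene-set enrichment
#'
#' For every set in the collection, intersects it with the analyzed-gene
#' universe, counts `k` (set genes analyzed) and `g` (significant genes
#' in the set), and computes the exact upper-tail hypergeometric P. Only
#' raw P-values are used for the `significant` flag (the historical
#' convention for this analysis); Benjamini-Hochberg-adjusted values are
#' reported alongside.
#'
#' @param sig_genes significant gene IDs (the `S` genes).
#' @param universe analyzed gene IDs (the `N` genes).
#' @param sets a `gmt_collection` (named list of gene-ID vectors).
#' @param alpha flagging level on raw P (default 0.05).
#' @return data.frame `term_id`, `term_name`, `k`, `g`, `S`, `N`, `p`,
#'   `p_bh`, `significant`, `genes` (comma-separated significant genes in
#'   the term), sorted by `p`; terms with `k = 0` are excluded.
#' @export
run_enrichment <- function(sig_genes, universe, sets, alpha = 0.05) {
  if (length(sets) == 0L) {
    warning("empty gene-set collection")
    return(data.frame(term_id = character(0), term_name = character(0),
                      k = integer(0), g = integer(0), S = integer(0),
                      N = integer(0), p = numeric(0), p_bh = numeric(0),
                      significant = logical(0), genes = character(0),
                      stringsAsFactors = FALSE))
  }
  universe <- unique(as.character(universe))
  sig_genes <- intersect(unique(as.character(sig_genes)), universe)
  N <- length(universe)
  S <- length(sig_genes)
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- names(sets)
  rows <- lapply(seq_along(sets), function(i) {
    members <- intersect(sets[[i]], universe)
    k <- length(members)
    if (k == 0L) return(NULL)
    hit <- intersect(members, sig_genes)
    g <- length(hit)
    data.frame(term_id = names(sets)[i], term_name = desc[i],
               k = k, g = g, S = S, N = N,
               p = hypergeometric_test(g, S, N, k),
               genes = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    warning("no gene set overlaps the analyzed genes")
    return(run_enrichment(sig_genes, universe, list(), alpha))
  }
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p < alpha
  out <- out[order(out$p, out$term_id),
             c("term_id", "term_name", "k", "g", "S", "N", "p", "p_bh",
               "significant", "genes")]
  rownames(out) <- NULL
  out
}
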