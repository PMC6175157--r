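# Minimal per-stage summary figures (base graphics).

#' Manhattan-style plot of window variance percentages
#'
#' @param windows data.frame from [window_scan()].
#' @param threshold horizontal reference line (percent; default 0.5).
#' @param ... passed to [plot()].
#' @export
plot_window_scan <- function(windows, threshold = 0.5, ...) {
  chrom <- factor(windows$chrom, levels = unique(windows$chrom))
  offset <- c(0, cumsum(tapply(windows$end_bp, chrom, max)))
  x <- windows$start_bp + offset[as.integer(chrom)]
  plot(x, windows$pct_additive_variance,
       col = (as.integer(chrom) %% 2L) + 1L, pch = 16, cex = 0.5,
       xlab = "genome position", ylab = "% additive genetic variance",
       ...)
  graphics::abline(h = threshold, lty = 2, col = "grey40")
  invisible(NULL)
}

#' Phenotype distribution by genotype class
#'
#' Box plot of per-animal phenotypes for the three genotype classes of
#' one SNP (the usual display for a putative recessive locus).
#'
#' @param panel a [genotype_panel].
#' @param phen phenotype table (best record per animal is used).
#' @param snp SNP ID.
#' @param ... passed to [boxplot()].
#' @export
plot_genotype_phenotype <- function(panel, phen, snp, ...) {
  stopifnot(is.genotype_panel(panel), snp %in% panel$snps)
  best <- select_best_record(phen)
  codes <- panel$codes[, snp]
  y <- best$value[match(panel$animals, best$animal)]
  keep <- !is.na(codes) & !is.na(y)
  cls <- factor(codes[keep], levels = c(0, 1, 2),
                labels = c("AA", "AB", "BB"))
  graphics::boxplot(y[keep] ~ cls, xlab = snp, ylab = "phenotype", ...)
  invisible(NULL)
}
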