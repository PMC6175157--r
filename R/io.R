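# Shared readers/writers for phenotype tables and run metadata.

#' Read a phenotype table
#'
#' TSV with header `animal, record_id, value, reliability` plus optional
#' covariate columns. Reliabilities must lie in (0, 1] and values must be
#' finite; offending rows are reported with their line numbers.
#'
#' @param path TSV path.
#' @return data.frame of records.
#' @export
read_phenotypes <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t",
                          colClasses = list(character = "animal"))
  need <- c("animal", "record_id", "value", "reliability")
  if (!all(need %in% names(dt))) {
    stop("phenotype file must have columns ",
         paste(need, collapse = ", "), "; got: ",
         paste(names(dt), collapse = ", "))
  }
  phen <- as.data.frame(dt)
  bad_rel <- which(!is.finite(phen$reliability) | phen$reliability <= 0 |
                     phen$reliability > 1)
  bad_val <- which(!is.finite(phen$value))
  if (length(bad_rel) || length(bad_val)) {
    msg <- c(
      if (length(bad_rel)) paste0("reliability outside (0, 1] on line(s) ",
                                  paste(bad_rel + 1L, collapse = ", ")),
      if (length(bad_val)) paste0("non-finite value on line(s) ",
                                  paste(bad_val + 1L, collapse = ", ")))
    stop("invalid phenotype records: ", paste(msg, collapse = "; "))
  }
  phen
}

#' Write a phenotype table
#' @param phen phenotype data.frame.
#' @param path output TSV path.
#' @export
write_phenotypes <- function(phen, path) {
  data.table::fwrite(phen, path, sep = "\t")
  invisible(path)
}

#' Write window-scan results as TSV
#' @param windows data.frame from [window_scan()].
#' @param path output path.
#' @export
write_windows <- function(windows, path) {
  data.table::fwrite(windows, path, sep = "\t")
  invisible(path)
}

#' Write back-solved SNP effects as TSV
#' @param effects `marker_effects` data.frame.
#' @param path output path.
#' @export
write_effects <- function(effects, path) {
  data.table::fwrite(as.data.frame(effects)[, c("snp", "chrom", "pos",
                                                "effect")],
                     path, sep = "\t")
  invisible(path)
}

#' Read back-solved SNP effects (with allele frequencies if present)
#' @param path TSV from [write_effects()].
#' @return `marker_effects`-like data.frame.
#' @export
read_effects <- function(path) {
  out <- as.data.frame(data.table::fread(path, sep = "\t",
                                         colClasses = list(
                                           character = c("snp", "chrom"))))
  class(out) <- c("marker_effects", "data.frame")
  out
}

# provenance metadata written next to every stage output
.write_run_meta <- function(dir, stage, config, extra = list()) {
  meta <- c(list(stage = stage,
                 package = "sirescan",
                 version = as.character(utils::packageVersion("sirescan")),
                 r_version = as.character(getRversion()),
                 timestamp = format(Sys.time(), tz = "UTC"),
                 config = config),
            extra)
  jsonlite::write_json(meta, file.path(dir, paste0(stage, "_meta.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(meta)
}
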