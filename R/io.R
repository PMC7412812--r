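#' Write the designed pool as FASTA
#'
#' One record per probe, RNA alphabet, header `probe_id|set|start`.
#'
#' @param probes Probe data.frame from [design_pool()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pool_fasta <- function(probes, path) {
  x <- Biostrings::RNAStringSet(probes$rna_seq)
  names(x) <- sprintf("%s|%s|%d", probes$probe_id, probes$set_label,
                      probes$start)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a pool FASTA written by [write_pool_fasta()]
#'
#' @param path FASTA file.
#' @return data.frame (`probe_id`, `set_label`, `start`, `rna_seq`).
#' @export
read_pool_fasta <- function(path) {
  x <- Biostrings::readRNAStringSet(path)
  parts <- strsplit(names(x), "|", fixed = TRUE)
  data.frame(probe_id = vapply(parts, `[`, "", 1L),
             set_label = vapply(parts, `[`, "", 2L),
             start = as.integer(vapply(parts, `[`, "", 3L)),
             rna_seq = as.character(x), stringsAsFactors = FALSE)
}

#' Write the pool manifest TSV
#'
#' @param probes Probe data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pool_manifest <- function(probes, path) {
  utils::write.table(probes[c("probe_id", "set_label", "start",
                              "variable_seq", "rna_seq")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write coverage audit reports as JSON
#'
#' @param reports List of `kmer_coverage_report` objects from [design_pool()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_audit_json <- function(reports, path) {
  jsonlite::write_json(lapply(reports, unclass), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read per-sample peak calls from BED-like files
#'
#' Reads 3+ column BED (chrom, start, end; optional further columns).  The
#' q-value column, when given, is converted to a plain FDR-adjusted p
#' (`qcol_dialect = "minus_log10"` for narrowPeak-style -log10 values,
#' `"raw"` for plain probabilities).
#'
#' @param paths Character vector of BED files, one per sample; names become
#'   sample ids.
#' @param qcol Column index holding the q-value, or NA when the peaks are
#'   pre-filtered (default NA).
#' @param qcol_dialect `"minus_log10"` or `"raw"`.
#' @return Named list of data.frames (`chrom`, `start`, `end`[, `fdr_p`]).
#' @export
read_peak_beds <- function(paths, qcol = NA_integer_,
                           qcol_dialect = c("minus_log10", "raw")) {
  qcol_dialect <- match.arg(qcol_dialect)
  if (is.null(names(paths)))
    names(paths) <- sub("\\.[^.]*$", "", basename(paths))
  lapply(paths, function(p) {
    d <- utils::read.table(p, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
    out <- data.frame(chrom = d[[1L]], start = as.integer(d[[2L]]),
                      end = as.integer(d[[3L]]), stringsAsFactors = FALSE)
    if (!is.na(qcol)) {
      q <- d[[qcol]]
      out$fdr_p <- if (qcol_dialect == "minus_log10") 10^(-q) else q
    }
    out
  })
}

#' Write gene-level methylation calls as TSV
#'
#' @param calls Output of [call_methylation()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_methylation_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulation truth record as JSON
#'
#' @param truth The `truth` element returned by a `sim_*` generator.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
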