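# Writers/readers for screen results. Numeric columns are serialized with
# 17 significant digits so that read(write(x)) round-trips at full double
# precision.

.dml_columns <- function() {
  c("probe_id", "origin", "mean_diandric", "mean_digynic", "mean_normal",
    "mean_chm", "delta_beta", "q_value", "consistent", "elimination_reason",
    "cnv_overlap")
}

.fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))

#' Write a table of differentially methylated locus (DML) calls
#'
#' One row per probe, deterministic column order (probe id, parental
#' origin, the four group means, signed delta-beta, q-value, consistency
#' flag and elimination reason, CNV-overlap flag).
#'
#' @param calls data.frame of DML calls as produced by
#'   [call_candidate_dml()] / [consistency_filter()].
#' @param path output path (tab-separated).
#' @return `path`, invisibly.
#' @seealso [read_dml_table()] for the inverse.
#' @export
write_dml_table <- function(calls, path) {
  cols <- .dml_columns()
  if (nrow(calls) > 0) {
    miss <- setdiff(cols, names(calls))
    if (length(miss)) stop("calls missing column(s): ", paste(miss, collapse = ", "))
  } else {
    for (cc in setdiff(cols, names(calls))) calls[[cc]] <- logical(0)
  }
  out <- calls[cols]
  for (cc in c("mean_diandric", "mean_digynic", "mean_normal", "mean_chm",
               "delta_beta", "q_value"))
    out[[cc]] <- .fmt_num(as.numeric(out[[cc]]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(out) > 0) {
    utils::write.table(out, con, sep = "\t", quote = FALSE, na = "NA",
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read back a DML table written by [write_dml_table()]
#' @param path path to the TSV.
#' @return data.frame of calls with numeric/logical columns restored.
#' @export
read_dml_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  miss <- setdiff(.dml_columns(), names(df))
  if (length(miss)) stop("not a DML table, missing: ", paste(miss, collapse = ", "))
  for (cc in c("mean_diandric", "mean_digynic", "mean_normal", "mean_chm",
               "delta_beta", "q_value"))
    df[[cc]] <- as.numeric(df[[cc]])
  for (cc in c("consistent", "cnv_overlap"))
    df[[cc]] <- as.logical(df[[cc]])
  df$elimination_reason[is.na(df$elimination_reason)] <- ""
  df
}

#' Write DMRs as a BED6 file
#'
#' Converts the 1-based inclusive probe span of each DMR to 0-based
#' half-open BED coordinates, names each interval `GENE|origin` (probe id
#' for unannotated singletons), scores it `round(1000 * |mean delta-beta|)`
#' for browser display, and sorts by chromosome (1..22, X, Y) then start.
#' A gene carrying both a maternal and a paternal DMR yields two lines.
#'
#' @param dmrs data.frame of DMRs from [aggregate_dml_to_dmrs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  need <- c("dmr_id", "gene_symbol", "origin", "chromosome", "start", "end")
  miss <- setdiff(need, names(dmrs))
  if (length(miss)) stop("dmrs missing column(s): ", paste(miss, collapse = ", "))
  start0 <- dmrs$start - 1L
  end0 <- dmrs$end           # 1-based inclusive end == half-open end
  if (any(start0 >= end0)) stop("invalid interval: start >= end after BED conversion")
  score <- if (!is.null(dmrs$mean_delta_beta))
    round(1000 * abs(dmrs$mean_delta_beta)) else rep(0L, nrow(dmrs))
  name <- ifelse(dmrs$gene_symbol == "" | is.na(dmrs$gene_symbol),
                 paste0(sub("\\|.*$", "", dmrs$dmr_id), "|", dmrs$origin),
                 paste0(dmrs$gene_symbol, "|", dmrs$origin))
  chrom <- factor(as.character(dmrs$chromosome), levels = chromosome_levels())
  if (anyNA(chrom)) stop("chromosome label(s) outside 1..22/X/Y")
  ord <- order(chrom, start0, name)
  bed <- data.frame(chrom = as.character(chrom), start = start0, end = end0,
                    name = name, score = score, strand = ".",
                    stringsAsFactors = FALSE)[ord, ]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of genomic intervals (0-based half-open)
#'
#' Used to supply e.g. known-CNV tracks for [annotate_cnv_overlap()].
#' Only the first three columns are required.
#'
#' @param path path to a BED file.
#' @return data.frame with columns `chromosome`, `start`, `end` (and
#'   `name` when present).
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("BED file needs at least 3 columns")
  out <- data.frame(chromosome = sub("^chr", "", as.character(df[[1]])),
                    start = as.numeric(df[[2]]), end = as.numeric(df[[3]]),
                    stringsAsFactors = FALSE)
  if (ncol(df) >= 4) out$name <- as.character(df[[4]])
  if (any(is.na(out$start) | is.na(out$end)))
    stop("non-numeric BED coordinates")
  if (any(out$start >= out$end))
    stop("malformed interval(s): start >= end")
  out
}

#' Write a DMR classification table
#'
#' Tab-separated, one row per DMR with the tissue-differential,
#' placenta-specific, gestation-change, stable and known-imprinted flags.
#'
#' @param cls data.frame from [classify_dmrs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_classification_table <- function(cls, path) {
  utils::write.table(cls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
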