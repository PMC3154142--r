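#' Assign parental origin from the two triploid group means
#'
#' A probe more methylated in diandric (two paternal genomes) than in
#' digynic (two maternal genomes) placentas carries the methylation on the
#' paternal allele, and conversely. Exact equality leaves the origin
#' undefined (cannot occur after delta-beta thresholding).
#'
#' @param mean_diandric,mean_digynic group-mean beta values (vectorized).
#' @return character vector, `"paternal"` or `"maternal"`.
#' @examples
#' assign_parental_origin(0.60, 0.30)  # paternal
#' assign_parental_origin(0.20, 0.55)  # maternal
#' @export
assign_parental_origin <- function(mean_diandric, mean_digynic) {
  if (any(mean_diandric == mean_digynic, na.rm = TRUE))
    stop("undefined parental origin: equal diandric and digynic means")
  ifelse(mean_diandric > mean_digynic, "paternal", "maternal")
}

#' Candidate imprinted-DML screen
#'
#' Retains exactly the probes with SAM q-value <= `fdr_threshold`
#' (inclusive) and |mean_diandric - mean_digynic| strictly greater than
#' `delta_threshold`, and assigns each a parental origin. The reference
#' group means (normal placenta, CHM) are carried along for the
#' consistency filter.
#'
#' @param sam a `SamResult` from [sam_two_class()] on diandric vs digynic.
#' @param profiles probes x groups matrix from [group_means()] containing
#'   columns `diandric`, `digynic`, `normal_placenta`, `chm`.
#' @param fdr_threshold q-value cutoff in (0,1); default 0.001.
#' @param delta_threshold minimum absolute group-mean difference in (0,1);
#'   default 0.15.
#' @return data.frame of DML calls: probe_id, origin, the four group
#'   means, signed `delta_beta` (diandric - digynic), `q_value`, plus
#'   placeholder `consistent` / `elimination_reason` / `cnv_overlap`
#'   columns for the downstream filters.
#' @export
call_candidate_dml <- function(sam, profiles, fdr_threshold = 0.001,
                               delta_threshold = 0.15) {
  stopifnot(inherits(sam, "SamResult"))
  for (th in c(fdr_threshold, delta_threshold))
    if (length(th) != 1 || is.na(th) || th <= 0 || th >= 1)
      stop("thresholds must lie in (0,1)")
  need <- c("diandric", "digynic", "normal_placenta", "chm")
  miss <- setdiff(need, colnames(profiles))
  if (length(miss)) stop("profiles missing group(s): ", paste(miss, collapse = ", "))
  probes <- intersect(names(sam$q), rownames(profiles))
  A <- profiles[probes, "diandric"]; G <- profiles[probes, "digynic"]
  delta <- A - G
  keep <- sam$q[probes] <= fdr_threshold & abs(delta) > delta_threshold &
    abs(sam$d[probes]) > 0
  keep[is.na(keep)] <- FALSE
  probes <- probes[keep]
  data.frame(probe_id = probes,
             origin = if (length(probes)) assign_parental_origin(A[keep], G[keep]) else character(0),
             mean_diandric = unname(A[keep]),
             mean_digynic = unname(G[keep]),
             mean_normal = unname(profiles[probes, "normal_placenta"]),
             mean_chm = unname(profiles[probes, "chm"]),
             delta_beta = unname(delta[keep]),
             q_value = unname(sam$q[probes]),
             consistent = rep(NA, length(probes)),
             elimination_reason = rep("", length(probes)),
             cnv_overlap = rep(NA, length(probes)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Reference-pattern consistency filter
#'
#' An imprinted probe must satisfy both reference clauses: (a) the normal
#' biparental placenta mean lies within the closed interval between the
#' diandric and digynic means, and (b) the CHM (purely paternal) mean is
#' strictly closer to the diandric than to the digynic mean. Probes
#' violating a clause are flagged inconsistent with reason
#' `normal_not_intermediate` or `chm_not_diandric_like` (first violated
#' clause reported; a tie in clause (b) eliminates). Rows are flagged,
#' not dropped.
#'
#' @param calls data.frame of DML calls with populated `mean_diandric`,
#'   `mean_digynic`, `mean_normal`, `mean_chm`.
#' @return `calls` with `consistent` and `elimination_reason` filled in.
#' @export
consistency_filter <- function(calls) {
  need <- c("mean_diandric", "mean_digynic", "mean_normal", "mean_chm")
  miss <- setdiff(need, names(calls))
  if (length(miss)) stop("calls missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(calls) == 0) return(calls)
  if (anyNA(calls[need])) stop("missing reference group means")
  lo <- pmin(calls$mean_diandric, calls$mean_digynic)
  hi <- pmax(calls$mean_diandric, calls$mean_digynic)
  normal_ok <- calls$mean_normal >= lo & calls$mean_normal <= hi
  chm_ok <- abs(calls$mean_chm - calls$mean_diandric) <
    abs(calls$mean_chm - calls$mean_digynic)
  calls$consistent <- normal_ok & chm_ok
  calls$elimination_reason <- ifelse(!normal_ok, "normal_not_intermediate",
                                     ifelse(!chm_ok, "chm_not_diandric_like", ""))
  calls
}

#' Aggregate DML calls into DMRs
#'
#' Groups calls by (gene symbol, parental origin): one DMR per group, so a
#' gene carrying both maternal and paternal loci yields two DMRs (the
#' GNAS-type dual-origin case). Unannotated probes (empty gene symbol)
#' become singleton DMRs keyed by probe id. The DMR span is the 1-based
#' inclusive min..max position of its member probes.
#'
#' @param calls data.frame of (typically consistent) DML calls.
#' @param ann probe annotation (see [validate_probe_annotation()])
#'   covering every call.
#' @return data.frame of DMRs: `dmr_id`, `gene_symbol`, `origin`,
#'   `chromosome`, `start`, `end`, `n_probes`, `probe_ids` (list column),
#'   `mean_delta_beta`.
#' @export
aggregate_dml_to_dmrs <- function(calls, ann) {
  ann <- validate_probe_annotation(ann)
  if (nrow(calls) == 0)
    return(data.frame(dmr_id = character(0), gene_symbol = character(0),
                      origin = character(0), chromosome = character(0),
                      start = numeric(0), end = numeric(0),
                      n_probes = integer(0), probe_ids = I(list()),
                      mean_delta_beta = numeric(0), stringsAsFactors = FALSE))
  idx <- match(calls$probe_id, ann$probe_id)
  if (anyNA(idx))
    stop("unannotated probe id(s): ",
         paste(utils::head(calls$probe_id[is.na(idx)], 5), collapse = ", "))
  gene <- ann$gene_symbol[idx]
  key_gene <- ifelse(gene == "" | is.na(gene), calls$probe_id, gene)
  key <- paste(key_gene, calls$origin, sep = "|")
  pieces <- split(seq_len(nrow(calls)), key)
  rows <- lapply(names(pieces), function(k) {
    i <- pieces[[k]]
    chrom <- unique(ann$chromosome[idx[i]])
    if (length(chrom) != 1)
      stop("probes of DMR ", k, " map to multiple chromosomes")
    g <- unique(gene[i])
    data.frame(dmr_id = k,
               gene_symbol = if (g[1] == "" || is.na(g[1])) "" else g[1],
               origin = calls$origin[i[1]],
               chromosome = chrom,
               start = min(ann$position[idx[i]]),
               end = max(ann$position[idx[i]]),
               n_probes = length(i),
               probe_ids = I(list(calls$probe_id[i])),
               mean_delta_beta = mean(calls$delta_beta[i]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(factor(out$chromosome, levels = chromosome_levels()), out$start)
  out <- out[ord, ]
  rownames(out) <- NULL
  out
}

#' Flag DML calls overlapping user-supplied genomic intervals
#'
#' Intervals follow the BED convention (0-based half-open); a probe at
#' 1-based position p overlaps \[s, e) iff s <= p-1 < e. Typical use is a
#' known-CNV track, whose overlaps are reported as an annotation, not used
#' as a filter.
#'
#' @param calls data.frame of DML calls.
#' @param ann probe annotation covering the calls.
#' @param intervals data.frame with `chromosome`, `start`, `end`
#'   (0-based half-open), e.g. from [read_bed()]. May have zero rows.
#' @return `calls` with `cnv_overlap` set.
#' @export
annotate_cnv_overlap <- function(calls, ann, intervals) {
  ann <- validate_probe_annotation(ann)
  if (any(intervals$start >= intervals$end))
    stop("malformed interval(s): start >= end")
  idx <- match(calls$probe_id, ann$probe_id)
  if (anyNA(idx)) stop("unannotated probe id(s) in calls")
  chrom <- sub("^chr", "", as.character(ann$chromosome[idx]))
  pos <- ann$position[idx]
  ichrom <- sub("^chr", "", as.character(intervals$chromosome))
  calls$cnv_overlap <- vapply(seq_along(pos), function(i) {
    any(ichrom == chrom[i] & intervals$start <= pos[i] - 1 &
          pos[i] - 1 < intervals$end)
  }, logical(1))
  calls
}
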