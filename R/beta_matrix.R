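#' Methylation beta-value matrix
#'
#' Container for a probes x samples matrix of methylation beta values
#' (fraction methylated, in \[0,1\]) with an optional parallel matrix of
#' per-cell detection p-values. Rows are keyed by probe id and columns by
#' sample id; missing beta cells are permitted and are excluded from
#' downstream statistics.
#'
#' @param beta numeric matrix with unique probe-id rownames and unique
#'   sample-id colnames; values in \[0,1\] (tolerance 1e-9) or NA.
#' @param detection_p optional numeric matrix with the same dimnames,
#'   values in \[0,1\]; per-cell probability that the signal is
#'   indistinguishable from background.
#' @return an object of class `BetaMatrix`: a list with elements `beta`
#'   and `detection_p`.
#' @examples
#' b <- matrix(c(0.1, 0.5, 0.9, 0.2, 0.6, 0.8), nrow = 3,
#'             dimnames = list(paste0("cg", 1:3), c("s1", "s2")))
#' bm <- BetaMatrix(b)
#' dim(bm)
#' @export
BetaMatrix <- function(beta, detection_p = NULL) {
  beta <- as.matrix(beta)
  if (!is.numeric(beta)) stop("beta must be numeric")
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    stop("beta must have probe-id rownames and sample-id colnames")
  if (anyDuplicated(rownames(beta)))
    stop("duplicated probe ids: ",
         paste(unique(rownames(beta)[duplicated(rownames(beta))]), collapse = ", "))
  if (anyDuplicated(colnames(beta)))
    stop("duplicated sample ids: ",
         paste(unique(colnames(beta)[duplicated(colnames(beta))]), collapse = ", "))
  .check_beta_range(beta)
  # clamp float dust just outside [0,1]
  beta[] <- pmin(pmax(beta, 0), 1)
  if (!is.null(detection_p)) {
    detection_p <- as.matrix(detection_p)
    if (!identical(dim(detection_p), dim(beta)))
      stop("detection_p must have the same shape as beta")
    if (is.null(rownames(detection_p))) dimnames(detection_p) <- dimnames(beta)
    if (!identical(rownames(detection_p), rownames(beta)) ||
        !identical(colnames(detection_p), colnames(beta)))
      stop("detection_p dimnames must match beta")
    bad <- !is.na(detection_p) & (detection_p < 0 | detection_p > 1)
    if (any(bad)) stop("detection p-values must lie in [0,1]")
  }
  structure(list(beta = beta, detection_p = detection_p), class = "BetaMatrix")
}

.check_beta_range <- function(beta, tol = 1e-9) {
  bad <- which(!is.na(beta) & (beta < -tol | beta > 1 + tol), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, ]
    stop(sprintf(
      "beta value out of [0,1]: probe '%s', sample '%s' (value %g)%s",
      rownames(beta)[i[1]], colnames(beta)[i[2]], beta[i[1], i[2]],
      if (nrow(bad) > 1) sprintf(" and %d more cells", nrow(bad) - 1) else ""))
  }
  invisible(TRUE)
}

#' @export
dim.BetaMatrix <- function(x) dim(x$beta)

#' @export
print.BetaMatrix <- function(x, ...) {
  cat(sprintf("BetaMatrix: %d probes x %d samples%s\n",
              nrow(x$beta), ncol(x$beta),
              if (is.null(x$detection_p)) "" else " (with detection p-values)"))
  cat(sprintf("  missing beta cells: %d\n", sum(is.na(x$beta))))
  invisible(x)
}

#' Subset a BetaMatrix by probes and/or samples
#'
#' @param x a [BetaMatrix].
#' @param probes,samples character vectors of keys to keep (default: all).
#' @return a `BetaMatrix`.
#' @export
subset_beta <- function(x, probes = NULL, samples = NULL) {
  stopifnot(inherits(x, "BetaMatrix"))
  if (is.null(probes)) probes <- rownames(x$beta)
  if (is.null(samples)) samples <- colnames(x$beta)
  miss <- setdiff(probes, rownames(x$beta))
  if (length(miss)) stop("unknown probes: ", paste(utils::head(miss, 5), collapse = ", "))
  miss <- setdiff(samples, colnames(x$beta))
  if (length(miss)) stop("unknown samples: ", paste(utils::head(miss, 5), collapse = ", "))
  BetaMatrix(x$beta[probes, samples, drop = FALSE],
             if (!is.null(x$detection_p)) x$detection_p[probes, samples, drop = FALSE])
}

#' Read a beta-value table from a tab-separated file
#'
#' The expected layout is one probe per row with a probe-id column and one
#' numeric column per sample (the plain-TSV reduction of an array
#' series-matrix export). An optional second file of identical layout
#' supplies detection p-values.
#'
#' Non-numeric cells are reported with a warning and recorded as missing;
#' beta values outside \[0,1\] (beyond tolerance 1e-9), duplicated probe
#' rows and duplicated sample columns are errors.
#'
#' @param path path to the TSV beta table.
#' @param detection_path optional path to a parallel detection-p TSV.
#' @param id_col name of the probe-id column (default `"probe_id"`).
#' @return a [BetaMatrix].
#' @export
read_beta_table <- function(path, detection_path = NULL, id_col = "probe_id") {
  beta <- .read_keyed_matrix(path, id_col)
  detection_p <- NULL
  if (!is.null(detection_path)) {
    detection_p <- .read_keyed_matrix(detection_path, id_col)
    if (!identical(dimnames(detection_p), dimnames(beta)))
      stop("detection-p table keys do not match the beta table")
  }
  BetaMatrix(beta, detection_p)
}

.read_keyed_matrix <- function(path, id_col) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!id_col %in% names(df))
    stop(sprintf("format error: no '%s' column in %s", id_col, path))
  if (anyDuplicated(names(df)))
    stop("format error: duplicated sample column(s): ",
         paste(unique(names(df)[duplicated(names(df))]), collapse = ", "))
  ids <- df[[id_col]]
  if (anyDuplicated(ids))
    stop("duplicated probe row(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  val <- df[setdiff(names(df), id_col)]
  m <- matrix(NA_real_, nrow(df), ncol(val),
              dimnames = list(ids, names(val)))
  for (j in seq_along(val)) {
    raw <- val[[j]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- !is.na(raw) & raw != "" & raw != "NA" & is.na(num)
    if (any(bad))
      warning(sprintf("non-numeric cell(s) set to NA in column '%s' (probes %s)",
                      names(val)[j], paste(utils::head(ids[bad], 3), collapse = ", ")))
    m[, j] <- num
  }
  m
}

#' Read a probe annotation table
#'
#' Expects a TSV with columns `probe_id`, `gene_symbol`, `chromosome`,
#' `position`. Chromosomes must come from 1..22, X, Y; positions are
#' 1-based and >= 1; probe ids must be unique. An empty gene symbol marks
#' an unannotated probe.
#'
#' @param path path to the annotation TSV.
#' @return a data.frame with the four validated columns.
#' @export
read_probe_annotation <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("probe_id", "gene_symbol", "chromosome", "position")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation missing column(s): ", paste(miss, collapse = ", "))
  df <- df[need]
  df$position <- as.numeric(df$position)
  validate_probe_annotation(df)
}

#' Validate a probe annotation data.frame
#'
#' @param ann data.frame with columns `probe_id`, `gene_symbol`,
#'   `chromosome`, `position`.
#' @return the validated data.frame (gene NA normalized to "").
#' @export
validate_probe_annotation <- function(ann) {
  stopifnot(is.data.frame(ann))
  need <- c("probe_id", "gene_symbol", "chromosome", "position")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(ann$probe_id))
    stop("duplicated probe_id in annotation: ",
         paste(unique(ann$probe_id[duplicated(ann$probe_id)]), collapse = ", "))
  ann$gene_symbol[is.na(ann$gene_symbol)] <- ""
  bad <- setdiff(unique(ann$chromosome), chromosome_levels())
  if (length(bad)) stop("chromosome label(s) outside 1..22/X/Y: ",
                        paste(bad, collapse = ", "))
  if (any(is.na(ann$position) | ann$position < 1))
    stop("positions must be numeric and >= 1")
  ann
}

#' Closed chromosome vocabulary, in sort order
#' @return character vector `c("1", ..., "22", "X", "Y")`.
#' @export
chromosome_levels <- function() c(as.character(1:22), "X", "Y")

#' Read a sample sheet
#'
#' Comma- or tab-separated (chosen by extension: `.csv` vs anything else)
#' with columns `sample_id` and `group`, plus optional `sex`
#' (M/F/unknown) and `gestational_age` (weeks). Groups must come from the
#' closed study vocabulary.
#'
#' @param path path to the sample sheet.
#' @return a validated data.frame.
#' @export
read_sample_sheet <- function(path) {
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) utils::read.csv else utils::read.delim
  df <- reader(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_sample_sheet(df)
}

#' Closed vocabulary of study groups
#' @return character vector of admissible group labels.
#' @export
group_levels <- function() {
  c("diandric", "digynic", "normal_placenta", "chm", "maternal_blood",
    "brain", "kidney", "muscle", "placenta_mid", "placenta_term")
}

#' Validate a sample sheet data.frame
#' @param sheet data.frame with at least `sample_id` and `group`.
#' @return the validated sheet with `sex` and `gestational_age` filled in.
#' @export
validate_sample_sheet <- function(sheet) {
  stopifnot(is.data.frame(sheet))
  miss <- setdiff(c("sample_id", "group"), names(sheet))
  if (length(miss)) stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stop("duplicated sample_id: ",
         paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]), collapse = ", "))
  bad <- setdiff(unique(sheet$group), group_levels())
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  if (is.null(sheet$sex)) sheet$sex <- "unknown"
  sheet$sex[is.na(sheet$sex) | sheet$sex == ""] <- "unknown"
  bad <- setdiff(unique(sheet$sex), c("M", "F", "unknown"))
  if (length(bad)) stop("sex must be M, F or unknown")
  if (is.null(sheet$gestational_age)) sheet$gestational_age <- NA_real_
  sheet
}
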