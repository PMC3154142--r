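#' Prepare a downloaded GSE25966 series matrix for the screen
#'
#' Offline helper for benchmarking against the study's deposited
#' HumanMethylation27 data (GEO accession GSE25966; 27,578 CpG probes).
#' The user downloads the series-matrix file manually; this function
#' parses the `!series_matrix_table_begin` .. `!series_matrix_table_end`
#' block (probe rows, one column per GEO sample, quoted fields and
#' `"null"` cells tolerated), preserves probe order, and joins a curated
#' groups file mapping GEO sample ids to the study groups. Samples absent
#' from the mapping are dropped with a warning naming them. If the group
#' sizes of the triploid comparison differ from the study design
#' (10 diandric / 10 digynic / 10 normal placenta / 6 CHM / 10 maternal
#' blood) a warning reports the difference.
#'
#' @param series_matrix_path path to the (uncompressed) series-matrix
#'   file.
#' @param groups_path path to a CSV/TSV with columns `sample_id`, `group`
#'   (groups from [group_levels()]).
#' @return list with `beta` (a [BetaMatrix]) and `sample_sheet`, ready for
#'   [run_imprint_pipeline()].
#' @export
prepare_gse25966 <- function(series_matrix_path, groups_path) {
  lines <- readLines(series_matrix_path, warn = FALSE)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) == 1 && length(end) == 0)
    stop("parse error: series matrix table is truncated (no end marker)")
  if (length(beg) == 1 && length(end) == 1) {
    if (end <= beg + 1) stop("parse error: empty series matrix table")
    tbl <- lines[(beg + 1):(end - 1)]
  } else if (length(beg) == 0) {
    tbl <- lines[!grepl("^!", lines)]   # plain TSV fallback
    if (length(tbl) < 2) stop("parse error: no data rows found")
  } else {
    stop("parse error: multiple series matrix tables")
  }
  strip <- function(x) gsub('^"|"$', "", x)
  header <- strip(strsplit(tbl[1], "\t", fixed = TRUE)[[1]])
  cells <- strsplit(tbl[-1], "\t", fixed = TRUE)
  nc <- length(header)
  if (any(lengths(cells) != nc)) stop("parse error: ragged table rows")
  mat <- matrix(strip(unlist(cells)), ncol = nc, byrow = TRUE)
  ids <- mat[, 1]
  if (anyDuplicated(ids)) stop("duplicated probe row(s) in series matrix")
  vals <- suppressWarnings(
    matrix(as.numeric(ifelse(mat[, -1, drop = FALSE] %in% c("null", "NA", ""),
                             NA, mat[, -1, drop = FALSE])),
           nrow = nrow(mat),
           dimnames = list(ids, header[-1])))
  sheet <- read_sample_sheet(groups_path)
  unmapped <- setdiff(colnames(vals), sheet$sample_id)
  if (length(unmapped)) {
    warning("sample(s) without a group mapping dropped: ",
            paste(unmapped, collapse = ", "))
    vals <- vals[, setdiff(colnames(vals), unmapped), drop = FALSE]
  }
  sheet <- sheet[sheet$sample_id %in% colnames(vals), , drop = FALSE]
  design <- c(diandric = 10, digynic = 10, normal_placenta = 10, chm = 6,
              maternal_blood = 10)
  have <- table(factor(sheet$group, levels = names(design)))
  if (any(have != design)) {
    diff <- paste(sprintf("%s: %d (expected %d)", names(design),
                          as.integer(have), design)[have != design],
                  collapse = "; ")
    warning("group sizes differ from the study design - ", diff)
  }
  list(beta = BetaMatrix(vals), sample_sheet = sheet)
}
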