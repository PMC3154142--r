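#' Per-group mean methylation profiles
#'
#' Arithmetic mean beta per probe within each sample group; missing cells
#' are excluded from that probe's mean.
#'
#' @param bm a [BetaMatrix].
#' @param sheet sample sheet (data.frame with `sample_id`, `group`)
#'   covering every sample in `bm`.
#' @param groups groups to profile (default: all groups present).
#' @return numeric matrix, probes x groups.
#' @export
group_means <- function(bm, sheet, groups = NULL) {
  stopifnot(inherits(bm, "BetaMatrix"))
  sheet <- validate_sample_sheet(sheet)
  samples <- colnames(bm$beta)
  unassigned <- setdiff(samples, sheet$sample_id)
  if (length(unassigned))
    stop("sample(s) without a group assignment: ",
         paste(utils::head(unassigned, 5), collapse = ", "))
  grp <- sheet$group[match(samples, sheet$sample_id)]
  if (is.null(groups)) groups <- unique(grp)
  out <- matrix(NA_real_, nrow(bm$beta), length(groups),
                dimnames = list(rownames(bm$beta), groups))
  for (g in groups) {
    cols <- samples[grp == g]
    if (length(cols) == 0) stop("empty group: ", g)
    out[, g] <- rowMeans(bm$beta[, cols, drop = FALSE], na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  out
}

#' Pearson correlation between two beta vectors
#'
#' Pairwise-complete product-moment correlation, requiring at least three
#' complete pairs and nonzero variance in both vectors.
#'
#' @param x,y numeric vectors of equal length.
#' @return correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) stop("fewer than 3 complete pairs")
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance")
  stats::cor(x, y)
}

#' Hierarchical clustering of samples on 1 - r distance
#'
#' Agglomerative clustering of samples using the correlation distance
#' d(i, j) = 1 - Pearson r between the beta profiles of samples i and j
#' (pairwise-complete), with average linkage by default. The column order
#' of the distance matrix is fixed by sorting sample ids, so the result is
#' deterministic regardless of input column order.
#'
#' @param bm a [BetaMatrix] with >= 2 samples.
#' @param linkage linkage method, `"average"` (default) or `"complete"`.
#' @return an object of class `hclust` (merge heights are 1 - r distances).
#' @export
cluster_samples <- function(bm, linkage = c("average", "complete")) {
  stopifnot(inherits(bm, "BetaMatrix"))
  linkage <- match.arg(linkage)
  X <- bm$beta[, order(colnames(bm$beta)), drop = FALSE]
  if (ncol(X) < 2) stop("need at least 2 samples to cluster")
  r <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
  npairs <- crossprod(!is.na(X))
  bad <- which((is.na(r) | npairs < 3) & upper.tri(r), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    pairs <- apply(bad, 1, function(i)
      paste(colnames(X)[i[1]], colnames(X)[i[2]], sep = "/"))
    stop("undefined correlation for sample pair(s): ",
         paste(utils::head(pairs, 5), collapse = ", "))
  }
  d <- stats::as.dist(1 - r)
  stats::hclust(d, method = linkage)
}

#' Export a dendrogram in Newick format
#'
#' @param hc an `hclust` object (e.g. from [cluster_samples()]).
#' @param path optional output path; when NULL the Newick string is
#'   returned instead of written.
#' @return the Newick string, invisibly when written to `path`.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Pairwise 1 - r distance table between samples
#'
#' @param bm a [BetaMatrix].
#' @return data.frame with columns `sample_a`, `sample_b`, `distance`.
#' @export
correlation_distances <- function(bm) {
  stopifnot(inherits(bm, "BetaMatrix"))
  r <- suppressWarnings(stats::cor(bm$beta, use = "pairwise.complete.obs"))
  idx <- which(upper.tri(r), arr.ind = TRUE)
  data.frame(sample_a = colnames(r)[idx[, 1]],
             sample_b = colnames(r)[idx[, 2]],
             distance = 1 - r[idx],
             stringsAsFactors = FALSE)
}

#' Per-probe two-sample t-test census
#'
#' Welch (default) or pooled-variance two-sample t-test at every probe
#' between two groups, returning the p-value vector and the count of
#' probes below `alpha` (the paper-style census of nominally significant
#' probes, compared against the chance expectation `alpha * n_probes`).
#' Probes that are constant within and across both groups yield p = 1;
#' probes with zero variance but different means yield p = 0.
#'
#' @param bm a [BetaMatrix].
#' @param sheet sample sheet covering the samples of `bm`.
#' @param group_a,group_b the two group labels to compare (each >= 2
#'   samples).
#' @param alpha census threshold (default 0.01).
#' @param var_equal pool the variances (classical Student) instead of the
#'   Welch unequal-variance form.
#' @return list with `p` (named numeric), `n_significant`, `alpha`,
#'   `expected` (= alpha * number of testable probes).
#' @export
ttest_census <- function(bm, sheet, group_a, group_b, alpha = 0.01,
                         var_equal = FALSE) {
  stopifnot(inherits(bm, "BetaMatrix"))
  sheet <- validate_sample_sheet(sheet)
  grp <- sheet$group[match(colnames(bm$beta), sheet$sample_id)]
  ia <- which(grp == group_a); ib <- which(grp == group_b)
  if (length(ia) < 2 || length(ib) < 2)
    stop("both groups need at least 2 samples")
  A <- bm$beta[, ia, drop = FALSE]; B <- bm$beta[, ib, drop = FALSE]
  na <- rowSums(!is.na(A)); nb <- rowSums(!is.na(B))
  ma <- rowMeans(A, na.rm = TRUE); mb <- rowMeans(B, na.rm = TRUE)
  va <- .row_var(A, ma); vb <- .row_var(B, mb)
  p <- rep(NA_real_, nrow(A)); names(p) <- rownames(bm$beta)
  ok <- na >= 2 & nb >= 2
  if (var_equal) {
    df <- na + nb - 2
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
    se2 <- sp2 * (1 / na + 1 / nb)
  } else {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tt <- (ma - mb) / sqrt(se2)
  pv <- 2 * stats::pt(-abs(tt), df)
  # degenerate variance: equal means -> no evidence (p = 1); unequal -> p = 0
  degen <- ok & se2 == 0
  pv[degen & ma == mb] <- 1
  pv[degen & ma != mb] <- 0
  p[ok] <- pv[ok]
  n_sig <- sum(p < alpha, na.rm = TRUE)
  list(p = p, n_significant = n_sig, alpha = alpha,
       expected = alpha * sum(ok))
}

.row_var <- function(X, m = rowMeans(X, na.rm = TRUE)) {
  n <- rowSums(!is.na(X))
  rowSums((X - m)^2, na.rm = TRUE) / pmax(n - 1, 1)
}
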