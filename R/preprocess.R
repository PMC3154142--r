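#' Compute beta values from two-channel intensities
#'
#' beta = methylated / (methylated + unmethylated + offset). The default
#' offset is 0, i.e. the plain methylated-signal fraction; platform
#' conventions sometimes add a positive stabilizing offset (e.g. 100),
#' available through `offset`.
#'
#' @param methylated,unmethylated non-negative fluorescence intensities
#'   (vectors are recycled in the usual way).
#' @param offset non-negative scalar added to the denominator (default 0).
#' @param zero_as_na if TRUE, cells with zero total signal and zero offset
#'   become NA instead of raising an error.
#' @return beta values in \[0,1\].
#' @examples
#' beta_from_intensities(300, 100)  # 0.75
#' @export
beta_from_intensities <- function(methylated, unmethylated, offset = 0,
                                  zero_as_na = FALSE) {
  if (length(offset) != 1 || is.na(offset) || offset < 0)
    stop("offset must be a non-negative scalar")
  if (any(methylated < 0, na.rm = TRUE) || any(unmethylated < 0, na.rm = TRUE))
    stop("intensities must be non-negative")
  denom <- methylated + unmethylated + offset
  zero <- !is.na(denom) & denom == 0
  if (any(zero) && !zero_as_na)
    stop("undefined beta: both signals zero with zero offset")
  beta <- methylated / denom
  beta[zero] <- NA_real_
  beta
}

#' Probe-level detection quality filter
#'
#' Removes every probe whose detection p-value exceeds `alpha` in any
#' sample (all-samples-strict), keeping the sample set unchanged. Missing
#' detection p-values count as failures. The ids of removed probes are
#' attached to the result as attribute `"removed_probes"`.
#'
#' @param bm a [BetaMatrix] carrying detection p-values.
#' @param alpha detection significance threshold in (0, 1\]; default 0.05.
#' @param allow_missing if TRUE and `bm` has no detection p-values, return
#'   `bm` unchanged instead of raising a configuration error.
#' @return filtered `BetaMatrix` (idempotent).
#' @export
filter_by_detection <- function(bm, alpha = 0.05, allow_missing = FALSE) {
  stopifnot(inherits(bm, "BetaMatrix"))
  if (length(alpha) != 1 || is.na(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]")
  if (is.null(bm$detection_p)) {
    if (allow_missing) {
      attr(bm, "removed_probes") <- character(0)
      return(bm)
    }
    stop("no detection p-values present; pass allow_missing = TRUE to skip filtering")
  }
  ok <- apply(bm$detection_p, 1, function(p) all(!is.na(p) & p <= alpha))
  removed <- rownames(bm$beta)[!ok]
  out <- BetaMatrix(bm$beta[ok, , drop = FALSE],
                    bm$detection_p[ok, , drop = FALSE])
  attr(out, "removed_probes") <- removed
  out
}
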