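#' Configuration for the SAM permutation screen
#'
#' Settings for the moderated difference statistic d = r / (s + s0) and
#' its permutation-based false discovery rate.
#'
#' @param n_permutations number of label permutations (default 1000). When
#'   it reaches the number of distinct label assignments the permutation
#'   set is enumerated exhaustively instead of sampled.
#' @param fdr_target q-value cutoff defining the called set (default
#'   0.001, i.e. the <0.1 percent FDR used throughout the screen).
#' @param s0_method fudge-factor selection: `"tusher_cv_minimization"`
#'   (coefficient-of-variation minimization over s-quantile candidates;
#'   falls back to the fixed percentile when fewer than 100 probes) or
#'   `"fixed_percentile"`.
#' @param s0_percentile quantile of s used by the fixed-percentile method
#'   (default 0.05).
#' @param seed integer seed controlling the permutation draw; identical
#'   configurations reproduce identical results.
#' @param delta_grid number of rows reported in the delta table
#'   (default 50).
#' @param fdr_summary how the per-threshold false-positive count is
#'   summarized across permutations: `"mean"` (default, the expected
#'   number of false positives) or `"median"`.
#' @return an object of class `SamConfig`.
#' @export
sam_config <- function(n_permutations = 1000, fdr_target = 0.001,
                       s0_method = c("tusher_cv_minimization", "fixed_percentile"),
                       s0_percentile = 0.05, seed = 1, delta_grid = 50,
                       fdr_summary = c("mean", "median")) {
  s0_method <- match.arg(s0_method)
  fdr_summary <- match.arg(fdr_summary)
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  if (fdr_target <= 0 || fdr_target >= 1) stop("fdr_target must lie in (0,1)")
  structure(list(n_permutations = as.integer(n_permutations),
                 fdr_target = fdr_target, s0_method = s0_method,
                 s0_percentile = s0_percentile, seed = as.integer(seed),
                 delta_grid = as.integer(delta_grid),
                 fdr_summary = fdr_summary),
            class = "SamConfig")
}

# ---- internal helpers -------------------------------------------------------

.sam_matrix <- function(bm) {
  X <- if (inherits(bm, "BetaMatrix")) bm$beta else as.matrix(bm)
  if (is.null(rownames(X))) rownames(X) <- paste0("p", seq_len(nrow(X)))
  complete <- stats::complete.cases(X)
  if (!all(complete)) {
    warning(sprintf("dropping %d probe(s) with missing values", sum(!complete)))
    X <- X[complete, , drop = FALSE]
  }
  X
}

.safe_div <- function(num, den) {
  out <- num / den
  out[den == 0] <- ifelse(num[den == 0] == 0, 0,
                          sign(num[den == 0]) * Inf)
  out
}

# Tusher-style fudge factor: candidates are quantiles of s; pick the one
# minimizing the coefficient of variation of the windowed MADs of d.
.select_s0 <- function(r, s, cfg) {
  m <- length(s)
  if (cfg$s0_method == "fixed_percentile" || m < 100) {
    if (cfg$s0_method != "fixed_percentile")
      message("fewer than 100 probes: using fixed-percentile s0")
    return(unname(stats::quantile(s, cfg$s0_percentile)))
  }
  alphas <- seq(0, 1, by = 0.05)
  cand <- unname(stats::quantile(s, alphas))
  cand[1] <- 0
  nbin <- min(100L, max(10L, m %/% 25L))
  br <- unique(stats::quantile(s, seq(0, 1, length.out = nbin + 1)))
  grp <- cut(s, br, include.lowest = TRUE)
  cv <- vapply(cand, function(s0) {
    d <- .safe_div(r, s + s0)
    v <- tapply(d, grp, stats::mad)
    v <- v[is.finite(v)]
    if (length(v) < 2 || mean(v) == 0) return(Inf)
    stats::sd(v) / mean(v)
  }, numeric(1))
  unname(cand[which.min(cv)])
}

# run fn with a locally seeded RNG, restoring the caller's stream
.with_seed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# FDR machinery shared by the two-class and multiclass statistics.
# abs_d: observed |d|; perm_counter: function(thr) returning a list with
#   false_summary (per-threshold summarized false count) and quartiles of
#   the permuted statistic used for pi0.
.sam_fdr <- function(d, abs_d, perm_stats, cfg, signed = TRUE) {
  m <- length(abs_d)
  thr <- sort(abs_d)                       # ascending candidate cutoffs
  ncalled <- m + 1L - match(thr, thr)      # #{|d| >= thr}, tie-safe
  B <- ncol(perm_stats)
  false_counts <- matrix(0, length(thr), 0)
  false_sum <- numeric(length(thr))
  keep_all <- cfg$fdr_summary == "median"
  if (keep_all) false_counts <- matrix(0L, length(thr), B)
  q25 <- q75 <- numeric(B)
  for (b in seq_len(B)) {
    v <- perm_stats[, b]
    # for the signed statistic the permutation null is symmetric by
    # exchangeability; reflecting enforces that symmetry exactly so that
    # pi0 is invariant under group relabeling (d -> -d)
    qq <- stats::quantile(if (signed) c(v, -v) else v, c(0.25, 0.75),
                          names = FALSE)
    q25[b] <- qq[1]; q75[b] <- qq[2]
    sa <- sort(abs(v))
    cnt <- m - findInterval(thr, sa)       # #{|d*| > thr} (ties negligible)
    if (keep_all) false_counts[, b] <- cnt
    false_sum <- false_sum + cnt
  }
  false_summary <- if (keep_all) apply(false_counts, 1, stats::median)
                   else false_sum / B
  lo <- stats::median(q25); hi <- stats::median(q75)
  pi0 <- min(1, (sum(d >= lo & d <= hi) / m) / 0.5)
  fdr <- pmin(1, pi0 * false_summary / pmax(ncalled, 1))
  q_at_thr <- cummin(fdr)                  # q = best FDR among cutoffs <= |d|
  q <- numeric(m)
  q[order(abs_d)] <- q_at_thr
  names(q) <- names(abs_d)
  grid <- if (length(thr) > cfg$delta_grid)
    unique(round(seq(1, length(thr), length.out = cfg$delta_grid))) else seq_along(thr)
  delta_table <- data.frame(delta = thr[grid], n_called = ncalled[grid],
                            false_positives = false_summary[grid],
                            fdr = fdr[grid])
  list(q = q, pi0 = pi0, delta_table = delta_table)
}

.new_sam_result <- function(statistic, d, s, s0, fdrbits, cfg, groups, n_perm,
                            exhaustive) {
  # a probe with d exactly 0 carries no evidence and is never callable,
  # whatever its formal q at the degenerate delta = 0 cutoff
  structure(list(statistic = statistic, d = d, s = s, s0 = s0,
                 pi0 = fdrbits$pi0, q = fdrbits$q,
                 called = names(fdrbits$q)[fdrbits$q <= cfg$fdr_target &
                                             abs(d) > 0],
                 delta_table = fdrbits$delta_table, groups = groups,
                 n_permutations = n_perm, exhaustive = exhaustive,
                 config = cfg),
            class = "SamResult")
}

#' @export
print.SamResult <- function(x, ...) {
  cat(sprintf("SamResult (%s): %d probes, %d permutations%s\n",
              x$statistic, length(x$d), x$n_permutations,
              if (x$exhaustive) " (exhaustive)" else ""))
  cat(sprintf("  s0 = %.4g, pi0 = %.3f, called at q <= %g: %d probe(s)\n",
              x$s0, x$pi0, x$config$fdr_target, length(x$called)))
  invisible(x)
}

# ---- two-class --------------------------------------------------------------

#' Two-class unpaired SAM
#'
#' The moderated difference statistic d_i = (mean_1 - mean_2) / (s_i + s0),
#' where s_i is the pooled two-sample standard error and s0 a fudge factor
#' stabilizing low-variance probes, with a permutation-estimated false
#' discovery rate: for each candidate cutoff delta (every observed |d|),
#' FDR(delta) = pi0 * (summarized count of permuted |d*| >= delta) /
#' (number of observed |d| >= delta), and each probe's q-value is the
#' smallest FDR at any cutoff that calls it. Group order is the sorted
#' order of the two labels. Permutations are canonical sample subsets of
#' the smaller group size, so the result is invariant under relabeling of
#' the two groups (up to the sign of d).
#'
#' @param bm a [BetaMatrix] or plain probes x samples matrix. Probes with
#'   missing values are dropped with a warning.
#' @param labels character/factor vector over the samples (columns) with
#'   exactly two levels, each with >= 2 samples.
#' @param cfg a [sam_config()].
#' @return a `SamResult`: statistic vector `d` (signed), standard errors
#'   `s`, fudge factor `s0`, null proportion `pi0`, q-values `q`, the
#'   `called` probe set at `cfg$fdr_target`, and a `delta_table` of
#'   (delta, n_called, false_positives, fdr) rows.
#' @examples
#' sim <- simulate_dataset(sim_config(n_background = 60, n_maternal_dmr = 4,
#'   n_paternal_dmr = 4, samples_per_group = c(diandric = 5, digynic = 5),
#'   seed = 7))
#' labs <- sim$sample_sheet$group
#' res <- sam_two_class(sim$beta, labs, sam_config(n_permutations = 50, seed = 7))
#' res
#' @export
sam_two_class <- function(bm, labels, cfg = sam_config()) {
  stopifnot(inherits(cfg, "SamConfig"))
  X <- .sam_matrix(bm)
  labels <- as.character(labels)
  if (length(labels) != ncol(X)) stop("labels must cover every sample")
  lev <- sort(unique(labels))
  if (length(lev) != 2) stop("two-class SAM needs exactly 2 groups")
  i1 <- which(labels == lev[1]); i2 <- which(labels == lev[2])
  n1 <- length(i1); n2 <- length(i2); n <- n1 + n2
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 samples")
  m <- nrow(X)

  m1 <- rowMeans(X[, i1, drop = FALSE]); m2 <- rowMeans(X[, i2, drop = FALSE])
  ss <- rowSums((X[, i1, drop = FALSE] - m1)^2) +
        rowSums((X[, i2, drop = FALSE] - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) / (n - 2) * ss)
  r <- m1 - m2
  s0 <- .select_s0(r, s, cfg)
  d <- .safe_div(r, s + s0)
  names(d) <- names(s) <- rownames(X)

  # canonical permutation scheme: random subsets of the smaller group size
  nmin <- min(n1, n2)
  n_distinct <- choose(n, nmin)
  exhaustive <- cfg$n_permutations >= n_distinct
  subsets <- .with_seed(cfg$seed, function() {
    if (exhaustive) {
      message(sprintf(
        "requested %d permutations >= %d distinct assignments: enumerating exhaustively",
        cfg$n_permutations, n_distinct))
      utils::combn(n, nmin)
    } else {
      vapply(seq_len(cfg$n_permutations), function(b) sort(sample.int(n, nmin)),
             integer(nmin))
    }
  })
  B <- ncol(subsets)

  tot <- rowSums(X); tot2 <- rowSums(X^2)
  perm_stats <- matrix(0, m, B)
  chunk <- 200L
  for (off in seq(1L, B, by = chunk)) {
    idx <- off:min(off + chunk - 1L, B)
    Z <- matrix(0, n, length(idx))
    Z[cbind(as.vector(subsets[, idx, drop = FALSE]),
            rep(seq_along(idx), each = nmin))] <- 1
    S1 <- X %*% Z; Q1 <- (X * X) %*% Z
    mm1 <- S1 / nmin; mm2 <- (tot - S1) / (n - nmin)
    ss1 <- pmax(Q1 - S1^2 / nmin, 0)
    ss2 <- pmax((tot2 - Q1) - (tot - S1)^2 / (n - nmin), 0)
    sstar <- sqrt((1 / nmin + 1 / (n - nmin)) / (n - 2) * (ss1 + ss2))
    perm_stats[, idx] <- .safe_div(mm1 - mm2, sstar + s0)
  }

  fdrbits <- .sam_fdr(d, abs(d), perm_stats, cfg)
  .new_sam_result("two_class", d, s, s0, fdrbits, cfg, lev, B, exhaustive)
}

# ---- multiclass -------------------------------------------------------------

# distinct arrangements of a label multiset; enumerate when small enough
.n_multiset_perms <- function(counts) {
  exp(lgamma(sum(counts) + 1) - sum(lgamma(counts + 1)))
}

.enumerate_assignments <- function(labels) {
  # all distinct arrangements of `labels` (returned as integer class codes)
  lev <- sort(unique(labels))
  rec <- function(counts) {
    if (sum(counts) == 0) return(matrix(integer(0), nrow = 1, ncol = 0))
    out <- NULL
    for (k in seq_along(counts)) {
      if (counts[k] == 0) next
      cc <- counts; cc[k] <- cc[k] - 1L
      sub <- rec(cc)
      out <- rbind(out, cbind(k, sub))
    }
    out
  }
  counts <- as.integer(table(factor(labels, levels = lev)))
  t(rec(counts))   # n x P -> transpose to P rows? keep columns = assignments
}

#' Multiclass SAM
#'
#' F-like moderated statistic for k >= 2 groups:
#' d_i = sqrt( (sum_k 1/n_k) * sum_k n_k (mean_ik - mean_i)^2 ) / (s_i + s0)
#' with s_i = sqrt( (sum_k 1/n_k) * SSW_i / (n - k) ) the pooled
#' within-group error. For k = 2 the statistic reduces exactly to the
#' absolute two-class d (given the same s0). The permutation FDR uses
#' uniform random shuffles of the label vector (exhaustive enumeration of
#' the distinct assignments when feasible).
#'
#' @inheritParams sam_two_class
#' @param labels group labels over samples, k >= 2 levels, each with >= 2
#'   samples.
#' @return a `SamResult` (statistic `d` is non-negative).
#' @export
sam_multiclass <- function(bm, labels, cfg = sam_config()) {
  stopifnot(inherits(cfg, "SamConfig"))
  X <- .sam_matrix(bm)
  labels <- as.character(labels)
  if (length(labels) != ncol(X)) stop("labels must cover every sample")
  lev <- sort(unique(labels))
  K <- length(lev)
  if (K < 2) stop("multiclass SAM needs at least 2 groups")
  code <- match(labels, lev)
  nk <- tabulate(code, K)
  if (any(nk < 2)) stop("each group needs at least 2 samples")
  n <- ncol(X); m <- nrow(X)
  csum <- sum(1 / nk)
  tot <- rowSums(X); tot2 <- rowSums(X^2)
  gmean <- tot / n

  stat_for <- function(code_vec, s0 = NULL) {
    SSB <- numeric(m); SSW <- numeric(m)
    Z <- matrix(0, n, K)
    Z[cbind(seq_len(n), code_vec)] <- 1
    S <- X %*% Z          # per-class sums
    Q <- (X * X) %*% Z
    Mk <- sweep(S, 2, nk, "/")
    SSB <- rowSums(sweep((Mk - gmean)^2, 2, nk, "*"))
    SSW <- pmax(rowSums(Q - sweep(S^2, 2, nk, "/")), 0)
    r <- sqrt(csum * SSB)
    s <- sqrt(csum * SSW / (n - K))
    list(r = r, s = s)
  }

  obs <- stat_for(code)
  s0 <- .select_s0(obs$r, obs$s, cfg)
  d <- .safe_div(obs$r, obs$s + s0)
  names(d) <- names(obs$s) <- rownames(X)

  n_distinct <- .n_multiset_perms(nk)
  exhaustive <- is.finite(n_distinct) && cfg$n_permutations >= n_distinct &&
    n_distinct <= 20000
  perm_codes <- .with_seed(cfg$seed, function() {
    if (exhaustive) {
      message(sprintf(
        "requested %d permutations >= %d distinct assignments: enumerating exhaustively",
        cfg$n_permutations, round(n_distinct)))
      .enumerate_assignments(labels)
    } else {
      vapply(seq_len(cfg$n_permutations), function(b) code[sample.int(n)],
             integer(n))
    }
  })
  B <- ncol(perm_codes)
  perm_stats <- matrix(0, m, B)
  for (b in seq_len(B)) {
    p <- stat_for(perm_codes[, b])
    perm_stats[, b] <- .safe_div(p$r, p$s + s0)
  }

  fdrbits <- .sam_fdr(d, d, perm_stats, cfg, signed = FALSE)
  .new_sam_result("multiclass", d, obs$s, s0, fdrbits, cfg, lev, B, exhaustive)
}
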