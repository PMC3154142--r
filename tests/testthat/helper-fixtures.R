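# Small programmatic fixtures shared across test files.

# probes x samples matrix with generated dimnames
make_beta <- function(nprobe, nsample, fill = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vals <- if (length(fill) == 1 && is.na(fill)) stats::runif(nprobe * nsample)
          else fill
  matrix(vals, nprobe, nsample,
         dimnames = list(sprintf("cg%03d", seq_len(nprobe)),
                         sprintf("s%02d", seq_len(nsample))))
}

make_sheet <- function(groups) {
  # groups: named vector group -> count
  ids <- unlist(lapply(names(groups), function(g)
    sprintf("%s_%02d", g, seq_len(groups[[g]]))), use.names = FALSE)
  data.frame(sample_id = ids, group = rep(names(groups), groups),
             stringsAsFactors = FALSE)
}

# minimal SamResult stand-in for screen-threshold tests
fake_sam <- function(probe_ids, q, d = rep(1, length(probe_ids))) {
  names(q) <- names(d) <- probe_ids
  structure(list(q = q, d = d, statistic = "two_class"), class = "SamResult")
}

make_calls <- function(probe_id, origin, A, G, N = (A + G) / 2,
                       C = A + 0.05 * sign(A - G), delta = A - G,
                       q = 1e-4) {
  n <- length(probe_id)
  data.frame(probe_id = probe_id, origin = origin,
             mean_diandric = A, mean_digynic = G, mean_normal = N,
             mean_chm = C, delta_beta = delta,
             q_value = rep_len(q, n),
             consistent = rep(NA, n), elimination_reason = rep("", n),
             cnv_overlap = rep(NA, n), stringsAsFactors = FALSE)
}

make_annotation <- function(probe_id, gene = probe_id,
                            chromosome = "1",
                            position = seq(1000, by = 1000,
                                           length.out = length(probe_id))) {
  data.frame(probe_id = probe_id, gene_symbol = gene,
             chromosome = rep_len(chromosome, length(probe_id)),
             position = position, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
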