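make_profiles <- function(probes, A, G, N = (A + G) / 2, C = NULL) {
  if (is.null(C)) C <- ifelse(A > G, A + 0.02, A - 0.02)
  m <- cbind(diandric = A, digynic = G, normal_placenta = N, chm = C)
  rownames(m) <- probes
  m
}

test_that("candidate screen applies both thresholds strictly and assigns origin", {
  probes <- c("keep_pat", "small_delta", "weak_q", "keep_mat")
  sam <- fake_sam(probes, q = c(5e-4, 5e-4, 0.05, 5e-4))
  prof <- make_profiles(probes,
                        A = c(0.60, 0.50, 0.70, 0.20),
                        G = c(0.40, 0.36, 0.40, 0.55))
  calls <- call_candidate_dml(sam, prof, 0.001, 0.15)
  expect_setequal(calls$probe_id, c("keep_pat", "keep_mat"))
  expect_equal(calls$origin[calls$probe_id == "keep_pat"], "paternal")
  expect_equal(calls$origin[calls$probe_id == "keep_mat"], "maternal")
  expect_equal(calls$delta_beta[calls$probe_id == "keep_pat"], 0.2)
  # |delta| = 0.14 misses the strict > 0.15 cutoff even at tiny q
  expect_false("small_delta" %in% calls$probe_id)
  expect_error(call_candidate_dml(sam, prof, 1.5, 0.15), "thresholds")
})

test_that("parental origin follows the sign of the diandric-digynic difference", {
  expect_equal(assign_parental_origin(0.60, 0.30), "paternal")
  expect_equal(assign_parental_origin(0.20, 0.55), "maternal")
  expect_error(assign_parental_origin(0.40, 0.40), "undefined")
})

test_that("consistency filter enforces both reference clauses with reasons", {
  # case 7 uses dyadic values so the CHM-distance tie is float-exact
  cases <- data.frame(
    A = c(0.60, 0.60, 0.60, 0.60, 0.60, 0.60, 0.75),
    G = c(0.30, 0.30, 0.30, 0.30, 0.30, 0.30, 0.25),
    N = c(0.45, 0.70, 0.45, 0.20, 0.60, 0.30, 0.50),
    C = c(0.70, 0.62, 0.28, 0.28, 0.70, 0.70, 0.50))
  calls <- make_calls(sprintf("cg%d", 1:7), "paternal",
                      A = cases$A, G = cases$G, N = cases$N, C = cases$C)
  out <- consistency_filter(calls)
  expect_equal(out$consistent,
               c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(out$elimination_reason[2], "normal_not_intermediate")
  expect_equal(out$elimination_reason[3], "chm_not_diandric_like")
  # both clauses violated: the normal clause is reported first
  expect_equal(out$elimination_reason[4], "normal_not_intermediate")
  # boundary: N exactly at an endpoint is "between" (closed interval)
  expect_true(out$consistent[5] && out$consistent[6])
  # tie in CHM distances eliminates (strict "closer to")
  expect_equal(out$elimination_reason[7], "chm_not_diandric_like")

  expect_error(consistency_filter(make_calls("x", "paternal", 0.6, 0.3,
                                             N = NA)), "missing reference")
})

test_that("screen composition order does not change the final set", {
  set.seed(99)
  n <- 60
  probes <- sprintf("cg%03d", 1:n)
  sam <- fake_sam(probes, q = runif(n, 0, 0.01))
  A <- runif(n); G <- runif(n)
  A[A == G] <- A[A == G] + 0.01
  prof <- make_profiles(probes, A, G, N = runif(n), C = runif(n))
  # route 1: thresholds then consistency
  r1 <- consistency_filter(call_candidate_dml(sam, prof, 0.001, 0.15))
  set1 <- r1$probe_id[r1$consistent]
  # route 2: consistency on everything, then thresholds
  all_calls <- data.frame(probe_id = probes, origin = "paternal",
                          mean_diandric = A, mean_digynic = G,
                          mean_normal = prof[, "normal_placenta"],
                          mean_chm = prof[, "chm"], delta_beta = A - G,
                          q_value = sam$q, consistent = NA,
                          elimination_reason = "", cnv_overlap = NA,
                          stringsAsFactors = FALSE)
  flagged <- consistency_filter(all_calls)
  set2 <- flagged$probe_id[flagged$consistent & sam$q <= 0.001 &
                             abs(A - G) > 0.15]
  expect_setequal(set1, set2)
})

test_that("DML calls aggregate into DMRs by (gene, origin)", {
  ann <- make_annotation(sprintf("cg%d", 1:6),
                         gene = c("G1", "G1", "G1", "DUAL", "DUAL", ""),
                         position = c(100, 300, 200, 5000, 5100, 900))
  calls <- make_calls(sprintf("cg%d", 1:6),
                      c("maternal", "maternal", "maternal",
                        "maternal", "paternal", "paternal"),
                      A = rep(0.3, 6), G = rep(0.6, 6))
  dmrs <- aggregate_dml_to_dmrs(calls, ann)
  expect_equal(nrow(dmrs), 4)  # G1, DUAL x 2 origins, unannotated singleton
  g1 <- dmrs[dmrs$dmr_id == "G1|maternal", ]
  expect_equal(g1$n_probes, 3)
  expect_equal(c(g1$start, g1$end), c(100, 300))   # 1-based inclusive span
  # the dual-origin gene yields two DMRs from one gene
  expect_setequal(dmrs$dmr_id[dmrs$gene_symbol == "DUAL"],
                  c("DUAL|maternal", "DUAL|paternal"))
  # unannotated probe becomes a singleton keyed by probe id
  solo <- dmrs[dmrs$dmr_id == "cg6|paternal", ]
  expect_equal(solo$gene_symbol, "")
  expect_equal(c(solo$start, solo$end), c(900, 900))

  expect_error(aggregate_dml_to_dmrs(make_calls("nope", "maternal", 0.3, 0.6),
                                     ann), "unannotated")
})

test_that("CNV overlap respects the half-open interval convention", {
  ann <- make_annotation(c("cg1", "cg2", "cg3"), position = c(1000, 1001, 50))
  calls <- make_calls(c("cg1", "cg2", "cg3"), "maternal",
                      A = rep(0.3, 3), G = rep(0.6, 3))
  iv <- data.frame(chromosome = "1", start = 999, end = 1000)
  out <- annotate_cnv_overlap(calls, ann, iv)
  expect_equal(out$cnv_overlap, c(TRUE, FALSE, FALSE))
  # empty interval set: all FALSE
  out0 <- annotate_cnv_overlap(calls, ann, iv[0, ])
  expect_equal(out0$cnv_overlap, rep(FALSE, 3))
  expect_error(annotate_cnv_overlap(calls, ann,
                                    data.frame(chromosome = "1", start = 10,
                                               end = 10)), "malformed")
})
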