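cfg_small <- function(...) sam_config(n_permutations = 200, seed = 42,
                                      s0_method = "fixed_percentile", ...)

test_that("identical groups give d = 0 everywhere and an empty called set", {
  half <- make_beta(20, 4, fill = NA, seed = 1)
  X <- cbind(half, half)   # sample i of group a == sample i of group b
  colnames(X) <- sprintf("s%02d", 1:8)
  labs <- rep(c("a", "b"), each = 4)
  suppressMessages(res <- sam_two_class(X, labs, cfg_small()))
  expect_true(all(res$d == 0))
  expect_length(res$called, 0)
})

test_that("SAM is deterministic given the seed and invariant under relabeling", {
  X <- make_beta(150, 10, fill = NA, seed = 7)
  labs <- rep(c("g1", "g2"), c(4, 6))
  r1 <- sam_two_class(X, labs, cfg_small())
  r2 <- sam_two_class(X, labs, cfg_small())
  expect_identical(r1$q, r2$q)
  expect_identical(r1$called, r2$called)
  expect_identical(r1$delta_table, r2$delta_table)

  # swapping the two group labels flips d, leaves |d|, q and calls unchanged
  swapped <- ifelse(labs == "g1", "g2", "g1")
  r3 <- sam_two_class(X, swapped, cfg_small())
  expect_equal(r3$d, -r1$d)
  expect_identical(r3$q, r1$q)
  expect_identical(r3$called, r1$called)
})

test_that("a per-probe constant shift leaves that probe's statistic unchanged", {
  X <- make_beta(50, 8, fill = NA, seed = 3)
  labs <- rep(c("a", "b"), each = 4)
  r1 <- sam_two_class(X, labs, cfg_small())
  X2 <- X
  X2[5, ] <- X2[5, ] + 0.2
  r2 <- sam_two_class(X2, labs, cfg_small())
  expect_equal(r2$d[5], r1$d[5])
})

test_that("small designs fall back to exhaustive permutation enumeration", {
  X <- make_beta(30, 4, fill = NA, seed = 5)
  labs <- rep(c("a", "b"), each = 2)
  expect_message(res <- sam_two_class(X, labs, cfg_small()), "exhaustively")
  expect_true(res$exhaustive)
  expect_equal(res$n_permutations, choose(4, 2))
})

test_that("spiked probes are recovered with no false calls in a seeded simulation", {
  sim <- simulate_dataset(sim_config(
    n_background = 800, n_maternal_dmr = 10, n_paternal_dmr = 10,
    samples_per_group = c(diandric = 10, digynic = 10), seed = 13))
  res <- sam_two_class(sim$beta, sim$sample_sheet$group,
                       sam_config(n_permutations = 300, seed = 13))
  spiked <- sim$truth$probe_id[sim$truth$class != "background"]
  expect_gte(mean(spiked %in% res$called), 0.95)
  expect_length(setdiff(res$called, spiked), 0)
  # exchangeable-sign statistic: digynic-minus-diandric ordering in sorted
  # group levels means maternal probes (higher in digynic) have d > 0
  mat <- sim$truth$probe_id[sim$truth$class == "maternal_dmr"]
  expect_true(all(res$d[mat] < 0) || all(res$d[mat] > 0))
})

test_that("multiclass SAM reduces to |two-class d| at k = 2 and calls shifted groups", {
  X <- make_beta(200, 12, fill = NA, seed = 11)
  labs <- rep(c("a", "b"), each = 6)
  t2 <- sam_two_class(X, labs, cfg_small())
  tm <- sam_multiclass(X, labs, cfg_small())
  expect_equal(unname(tm$d), unname(abs(t2$d)), tolerance = 1e-12)
  expect_equal(cor(rank(tm$d), rank(t2$d^2)), 1)

  # all groups identical: nothing called
  half <- make_beta(30, 3, fill = NA, seed = 2)
  X3 <- cbind(half, half, half)
  colnames(X3) <- sprintf("t%02d", 1:9)
  suppressMessages(r0 <- sam_multiclass(X3, rep(c("a", "b", "c"), each = 3),
                                        cfg_small()))
  expect_length(r0$called, 0)

  # one group shifted by 0.3 at designated probes is called, nulls are not
  # (groups of 8: a <0.1% permutation FDR needs a permutation space in
  # which near-identity partitions are rare)
  set.seed(17)
  Xs <- matrix(rnorm(300 * 24, 0.5, 0.05), 300, 24,
               dimnames = list(sprintf("cg%03d", 1:300), sprintf("s%02d", 1:24)))
  shift_probes <- 1:10
  Xs[shift_probes, 1:8] <- Xs[shift_probes, 1:8] + 0.3
  labs3 <- rep(c("a", "b", "c"), each = 8)
  rs <- sam_multiclass(Xs, labs3,
    sam_config(n_permutations = 500, seed = 17, s0_method = "fixed_percentile"))
  called_idx <- match(rs$called, rownames(Xs))
  expect_true(all(called_idx %in% shift_probes))
  expect_gte(length(rs$called), 8)
})

test_that("q-values are monotone in |d| and pi0 lies in [0,1]", {
  X <- make_beta(400, 10, fill = NA, seed = 23)
  labs <- rep(c("a", "b"), each = 5)
  res <- sam_two_class(X, labs, cfg_small())
  ord <- order(abs(res$d), decreasing = TRUE)
  expect_true(all(diff(res$q[ord]) >= -1e-12))
  expect_gte(res$pi0, 0)
  expect_lte(res$pi0, 1)
  expect_true(all(res$q >= 0 & res$q <= 1))
})
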