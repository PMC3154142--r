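test_that("group means average within groups and honour the missing-cell policy", {
  m <- make_beta(2, 3, fill = c(0.2, 0.1, 0.4, NA, 0.3, 0.5))
  colnames(m) <- c("diandric_01", "diandric_02", "digynic_01")
  sheet <- make_sheet(c(diandric = 2, digynic = 1))
  gm <- group_means(BetaMatrix(m), sheet)
  expect_equal(gm["cg001", "diandric"], 0.3)           # (0.2 + 0.4)/2
  expect_equal(gm["cg002", "diandric"], 0.1)           # NA cell excluded
  expect_equal(gm["cg001", "digynic"], m["cg001", "digynic_01"])  # group of one

  expect_error(group_means(BetaMatrix(m), sheet, groups = c("diandric", "chm")),
               "empty group: chm")
  expect_error(group_means(BetaMatrix(m), sheet[-1, ]), "without a group")
})

test_that("pearson_r matches closed-form values and rejects degenerate input", {
  x <- c(0.1, 0.2, 0.3)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, 1 - x), -1)
  expect_equal(pearson_r(x, c(0.3, 0.2, 0.1)), -1)
  expect_error(pearson_r(x, rep(0.5, 3)), "zero variance")
  expect_error(pearson_r(c(0.1, 0.2), c(0.2, 0.1)), "3 complete pairs")
  # pairwise-complete: the NA pair is dropped
  expect_equal(pearson_r(c(x, NA), c(0.3, 0.2, 0.1, 0.9)), -1)
})

test_that("1 - r clustering merges identical samples first and separates tissues", {
  # two identical samples merge at height 0
  set.seed(1)
  base <- runif(50)
  m <- cbind(s1 = base, s2 = base, s3 = runif(50))
  rownames(m) <- sprintf("cg%03d", 1:50)
  hc <- cluster_samples(BetaMatrix(m))
  expect_equal(hc$height[1], 0, tolerance = 1e-12)
  first <- hc$labels[-hc$merge[1, ]]
  expect_setequal(first, c("s1", "s2"))

  # brute-force oracle: the pair with the smallest 1 - r distance merges first
  d12 <- 1 - pearson_r(m[, 1], m[, 2])
  d13 <- 1 - pearson_r(m[, 1], m[, 3])
  d23 <- 1 - pearson_r(m[, 2], m[, 3])
  expect_true(d12 == min(d12, d13, d23))

  # simulated blood vs placenta: the top split separates the tissues
  sim <- simulate_dataset(sim_config(
    n_background = 300, n_maternal_dmr = 0, n_paternal_dmr = 0,
    n_tissue_specific = 100, n_blood_divergent = 100,
    samples_per_group = c(normal_placenta = 6, maternal_blood = 6), seed = 9))
  hc2 <- cluster_samples(sim$beta)
  top <- stats::cutree(hc2, k = 2)
  grp <- sim$sample_sheet$group[match(names(top), sim$sample_sheet$sample_id)]
  expect_equal(length(unique(top[grp == "maternal_blood"])), 1)
  expect_equal(length(unique(top[grp == "normal_placenta"])), 1)
  expect_false(top[grp == "maternal_blood"][1] == top[grp == "normal_placenta"][1])

  # Newick export covers every sample
  nwk <- dendrogram_newick(hc2)
  expect_true(all(vapply(sim$sample_sheet$sample_id, grepl, logical(1),
                         x = nwk, fixed = TRUE)))
})

test_that("t-test census is calibrated under the null and detects separation", {
  sim <- simulate_null_dataset(sim_config(
    n_background = 10000, n_maternal_dmr = 0, n_paternal_dmr = 0,
    samples_per_group = c(diandric = 10, digynic = 10), seed = 21))
  cen <- ttest_census(sim$beta, sim$sample_sheet, "diandric", "digynic",
                      alpha = 0.01)
  lo <- qbinom(0.005, 10000, 0.01); hi <- qbinom(0.995, 10000, 0.01)
  expect_gte(cen$n_significant, lo)
  expect_lte(cen$n_significant, hi)
  expect_equal(cen$expected, 100)

  # census is monotone in alpha
  cen05 <- ttest_census(sim$beta, sim$sample_sheet, "diandric", "digynic",
                        alpha = 0.05)
  expect_gte(cen05$n_significant, cen$n_significant)

  # cross-check the vectorized Welch p-values against stats::t.test
  for (probe in rownames(sim$beta$beta)[1:3]) {
    a <- sim$beta$beta[probe, 1:10]; b <- sim$beta$beta[probe, 11:20]
    expect_equal(unname(cen$p[probe]), t.test(a, b)$p.value, tolerance = 1e-12)
  }

  # strongly separated probe: closed-form t is enormous
  m <- rbind(sep = c(rep(0.2, 10), rep(0.8, 10)),
             const = rep(0.5, 20))
  m["sep", ] <- m["sep", ] + rep(c(-0.01, 0.01), 10) * rep(c(1, -1), each = 10)[1:20] * 0.5
  colnames(m) <- colnames(sim$beta$beta)
  cen2 <- ttest_census(BetaMatrix(m), sim$sample_sheet, "diandric", "digynic",
                       alpha = 0.01)
  expect_lt(cen2$p["sep"], 1e-6)
  expect_equal(unname(cen2$p["const"]), 1)   # degenerate-variance policy
  expect_equal(cen2$n_significant, 1)
})
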