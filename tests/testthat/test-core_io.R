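test_that("beta table read/write round-trips and validates its input", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "beta.tsv")
  m <- make_beta(3, 2, fill = c(0.1, 0.5, 0.9, 0.2, 0.6, 0.8))
  df <- data.frame(probe_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)

  bm <- read_beta_table(path)
  expect_s3_class(bm, "BetaMatrix")
  expect_equal(dim(bm), c(3L, 2L))
  expect_equal(bm$beta, m)

  # out-of-range cell names the probe and sample
  bad <- df; bad[2, "s01"] <- "1.2"
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_beta_table(path), "cg002.*s01")

  # duplicated probe row lists the duplicate id
  dup <- rbind(df, df[1, ])
  write.table(dup, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_beta_table(path), "cg001")

  # duplicated sample column
  writeLines(c("probe_id\ts01\ts01", "cg001\t0.1\t0.2"), path)
  expect_error(read_beta_table(path), "duplicated sample")

  # missing probe-id column
  writeLines(c("id\ts01", "cg001\t0.1"), path)
  expect_error(read_beta_table(path), "probe_id")

  # non-numeric cell becomes NA with a warning
  odd <- df; odd[3, "s02"] <- "oops"
  write.table(odd, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(bm2 <- read_beta_table(path), "non-numeric")
  expect_true(is.na(bm2$beta["cg003", "s02"]))
})

test_that("DML table writer is deterministic and round-trips at full precision", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "dml.tsv")

  # header-only file for an empty call set
  empty <- make_calls(character(0), character(0), numeric(0), numeric(0))
  write_dml_table(empty, path)
  expect_length(readLines(path), 1L)
  expect_equal(nrow(read_dml_table(path)), 0L)

  set.seed(42)
  calls <- make_calls(sprintf("cg%04d", 1:7),
                      sample(c("maternal", "paternal"), 7, TRUE),
                      A = runif(7), G = runif(7), N = runif(7), C = runif(7),
                      q = runif(7, 0, 1e-3))
  calls$delta_beta <- calls$mean_diandric - calls$mean_digynic
  calls$consistent <- c(TRUE, TRUE, FALSE, TRUE, NA, TRUE, FALSE)
  calls$elimination_reason <- ifelse(isFALSE(calls$consistent), "normal_not_intermediate", "")
  write_dml_table(calls, path)
  back <- read_dml_table(path)
  expect_identical(back$probe_id, calls$probe_id)
  expect_identical(back$mean_diandric, calls$mean_diandric)  # full double precision
  expect_identical(back$q_value, calls$q_value)
  expect_identical(back$consistent, calls$consistent)
})

test_that("DMR BED output uses 0-based half-open intervals, sorted by genome order", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "dmrs.bed")
  dmrs <- data.frame(
    dmr_id = c("GNASL|maternal", "GNASL|paternal", "ABC|maternal"),
    gene_symbol = c("GNASL", "GNASL", "ABC"),
    origin = c("maternal", "paternal", "maternal"),
    chromosome = c("7", "7", "1"),
    start = c(1000, 5000, 200), end = c(1000, 5200, 200),
    mean_delta_beta = c(-0.3, 0.25, -0.2), stringsAsFactors = FALSE)
  write_dmr_bed(dmrs, path)
  bed <- read.delim(path, header = FALSE, colClasses = c(V1 = "character"))
  # chr1 line first, then the two chr7 lines
  expect_equal(bed$V1, c("1", "7", "7"))
  # single-probe DMR at 1-based p -> [p-1, p)
  expect_equal(bed$V2[1], 199); expect_equal(bed$V3[1], 200)
  # a dual-origin gene yields two distinct lines
  expect_setequal(bed$V4[bed$V1 == "7"], c("GNASL|maternal", "GNASL|paternal"))
  expect_equal(bed$V5[1], 200)  # round(1000 * 0.2)

  # coordinate conversion is invertible: 1-based start == BED start + 1
  parsed <- read_bed(path)
  expect_equal(sort(parsed$start + 1), sort(dmrs$start))
  expect_equal(sort(parsed$end), sort(dmrs$end))
})

test_that("annotation and sample-sheet validation enforce the closed vocabularies", {
  ann <- make_annotation(c("cg1", "cg2"), chromosome = c("1", "X"))
  expect_silent(validate_probe_annotation(ann))
  bad <- ann; bad$chromosome[2] <- "chr99"
  expect_error(validate_probe_annotation(bad), "chromosome")
  bad <- ann; bad$position[1] <- 0
  expect_error(validate_probe_annotation(bad), "position")
  bad <- ann; bad$probe_id[2] <- "cg1"
  expect_error(validate_probe_annotation(bad), "duplicated")

  sheet <- make_sheet(c(diandric = 2, digynic = 2))
  expect_silent(validate_sample_sheet(sheet))
  bad <- sheet; bad$group[1] <- "placenta"
  expect_error(validate_sample_sheet(bad), "unknown group")
  bad <- sheet; bad$sample_id[2] <- bad$sample_id[1]
  expect_error(validate_sample_sheet(bad), "duplicated")
})

test_that("BetaMatrix construction rejects bad keys and off-range values", {
  m <- make_beta(2, 2, fill = c(0.1, 0.2, 0.3, 0.4))
  expect_s3_class(BetaMatrix(m), "BetaMatrix")
  m2 <- m; m2[1, 1] <- 1.5
  expect_error(BetaMatrix(m2), "out of \\[0,1\\]")
  m3 <- m; rownames(m3) <- NULL
  expect_error(BetaMatrix(m3), "rownames")
  dp <- m; dp[] <- 0.01
  expect_s3_class(BetaMatrix(m, dp), "BetaMatrix")
  expect_error(BetaMatrix(m, dp[1, , drop = FALSE]), "same shape")
})
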