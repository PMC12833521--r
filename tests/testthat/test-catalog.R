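test_that("read_catalog round-trips a toy catalog and enforces integrity", {
  ds <- rbindlist(list(ds_row("P1", "PROFILE"), ds_row("D1", "DIFFERENTIAL")))
  obs <- rbindlist(list(obs_row("PROT1", "S", 10, "P1"),
                        obs_row("PROT1", "S", 10, "D1", 2.0, 0.01)))
  dir <- withr::local_tempdir()
  op <- file.path(dir, "obs.tsv"); dp <- file.path(dir, "ds.tsv")
  fwrite(obs, op, sep = "\t", na = "", quote = FALSE)
  fwrite(ds, dp, sep = "\t", na = "", quote = FALSE)
  catalog <- read_catalog(op, dp)
  expect_s3_class(catalog, "phospho_catalog")
  expect_equal(nrow(catalog$observations), 2L)
  expect_equal(nrow(catalog$datasets), 2L)

  # write -> read -> write is byte-identical
  op2 <- file.path(dir, "obs2.tsv"); dp2 <- file.path(dir, "ds2.tsv")
  write_catalog(catalog, op2, dp2)
  cat2 <- read_catalog(op2, dp2)
  op3 <- file.path(dir, "obs3.tsv"); dp3 <- file.path(dir, "ds3.tsv")
  write_catalog(cat2, op3, dp3)
  expect_identical(readLines(op2), readLines(op3))
  expect_identical(readLines(dp2), readLines(dp3))

  # referential integrity: undeclared dataset id
  obs_bad <- rbindlist(list(obs, obs_row("PROT1", "S", 10, "D99", 2, 0.01)))
  fwrite(obs_bad, op, sep = "\t", na = "", quote = FALSE)
  expect_error(read_catalog(op, dp), "undeclared dataset.*D99")

  # schema error names the missing column
  fwrite(obs[, !"window"], op, sep = "\t", na = "", quote = FALSE)
  expect_error(suppressWarnings(read_catalog(op, dp)),
               "missing column.*window")
})

test_that("malformed rows are rejected with diagnostics, not fatal", {
  ds <- list(ds_row("D1", "DIFFERENTIAL"))
  obs <- list(obs_row("PROT1", "S", 10, "D1", 2, 0.01),
              obs_row("PROT1", "X", 11, "D1", 2, 0.01),   # bad residue
              obs_row("PROT1", "S", -4, "D1", 2, 0.01),   # bad position
              obs_row("PROT1", "S", 12, "D1", -1, 0.01),  # bad fold change
              obs_row("PROT1", "S", 13, "D1", 2, 0.01,
                      window = "AAAAAAASAAAAAA"))         # 14-mer
  catalog <- suppressMessages(make_catalog(obs, ds))
  expect_equal(nrow(catalog$observations), 1L)
  expect_equal(nrow(catalog$rejected), 4L)
  expect_setequal(catalog$rejected$reason,
                  c("invalid residue", "invalid position",
                    "non-positive fold change", "window length != 15"))
})

test_that("is_class1 applies the inclusive/strict boundaries with OR", {
  cfg <- threshold_config()
  expect_true(is_class1(0.75, NA, cfg))       # loc prob boundary inclusive
  expect_false(is_class1(0.50, 13, cfg))      # A-score boundary strict
  expect_true(is_class1(NA, 13.01, cfg))
  expect_false(is_class1(NA, NA, cfg))        # unclassifiable, not an error
  expect_true(is_class1(0.2, 20, cfg))        # either criterion suffices
})

test_that("Class-1 filtering is monotone in min_loc_prob", {
  set.seed(1)
  lp <- ifelse(runif(200) < 0.2, NA, runif(200))
  as_ <- ifelse(runif(200) < 0.5, NA, runif(200, 0, 30))
  kept_prev <- which(is_class1(lp, as_, threshold_config(min_loc_prob = 0.5)))
  for (thr in c(0.6, 0.75, 0.9, 1.0)) {
    kept <- which(is_class1(lp, as_, threshold_config(min_loc_prob = thr)))
    expect_true(all(kept %in% kept_prev))
    kept_prev <- kept
  }
})

test_that("classify_regulation boundaries and partition", {
  expect_equal(classify_regulation(1.3, 0.01), "UP")       # inclusive
  expect_equal(classify_regulation(0.76, 0.049), "DOWN")   # inclusive
  expect_equal(classify_regulation(2.0, 0.05), "UNREGULATED")  # p strict
  expect_equal(classify_regulation(1.29, 0.001), "UNREGULATED")
  expect_error(classify_regulation(-2, 0.01), "positive")

  set.seed(2)
  fc <- exp(rnorm(500)); p <- runif(500)
  calls <- classify_regulation(fc, p)
  expect_true(all(calls %in% c("UP", "DOWN", "UNREGULATED")))
  # thresholds partition: recompute membership independently
  expect_equal(calls == "UP", fc >= 1.3 & p < 0.05)
  expect_equal(calls == "DOWN", fc <= 0.76 & p < 0.05)
})

test_that("log-scale fold changes are converted on load", {
  ds <- rbindlist(list(ds_row("D1", "DIFFERENTIAL")))
  obs <- obs_row("PROT1", "S", 10, "D1", 1.0, 0.01)  # log2 fc = 1 -> 2.0
  dir <- withr::local_tempdir()
  op <- file.path(dir, "o.tsv"); dp <- file.path(dir, "d.tsv")
  fwrite(obs, op, sep = "\t", na = ""); fwrite(ds, dp, sep = "\t", na = "")
  catalog <- read_catalog(op, dp, log_fc = TRUE)
  expect_equal(catalog$observations$fold_change, 2.0)
})

test_that("validate_window checks the reference-centred 15-mer with padding", {
  ref <- c(TOY = "ABCDEFGSABCDEFG")   # S at position 8 of a 15-mer
  sites <- data.table(accession = "TOY", residue = "S", position = 8L,
                      window = "ABCDEFGSABCDEFG")
  expect_true(validate_window(sites, ref))

  # centre mismatch vs reference
  sites_bad <- data.table(accession = "TOY", residue = "S", position = 3L,
                          window = "_____ABSDEFGSAB")
  expect_false(validate_window(sites_bad, ref))

  # N-terminal site at position 3: 5 leading pads, suffix must match
  ref2 <- c(NTERM = "MKSDEFGHIJKLMNOP")
  w <- paste0("_____", substr(ref2, 1, 10))
  sites_n <- data.table(accession = "NTERM", residue = "S", position = 3L,
                        window = w)
  expect_true(validate_window(sites_n, ref2))

  # absent accession -> NA with warning, and filter_validated keeps the row
  sites_na <- data.table(accession = "GHOST", residue = "S", position = 3L,
                         window = w)
  expect_warning(res <- validate_window(sites_na, ref2), "no reference")
  expect_true(is.na(res))

  ds <- list(ds_row("D1", "DIFFERENTIAL"))
  obs <- list(obs_row("NTERM", "S", 3, "D1", 2, 0.01, window = w),
              obs_row("NTERM", "S", 4, "D1", 2, 0.01, window = w))
  catalog <- make_catalog(obs, ds)
  filtered <- filter_validated(catalog, ref2)
  expect_equal(nrow(filtered$observations), 1L)
  expect_equal(filtered$rejected$reason, "window mismatch vs reference")
})
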