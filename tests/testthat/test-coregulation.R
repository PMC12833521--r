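test_that("categorize_pair produces the nine mutually exclusive cells", {
  ds <- sprintf("D%02d", 1:10)
  anchor <- setNames(rep("UP", 4), ds[1:4])
  other <- setNames(rep("UP", 3), ds[1:3])
  cnt <- categorize_pair(anchor, other, ds)
  expect_s3_class(cnt, "coreg_counts")
  expect_equal(cnt[["n_UcUo"]], 3L)
  expect_equal(cnt[["n_Uc0"]], 1L)
  expect_equal(cnt[["n_0c0o"]], 6L)
  expect_equal(sum(cnt[phoscoreg:::CELL_NAMES]), cnt[["n_total"]])
  cells <- contingency_cells(cnt)
  expect_equal(unname(cells), c(6L, 1L, 0L, 3L))

  # self-comparison: no discordance, b counts nothing paired
  self <- categorize_pair(anchor, anchor, ds)
  expect_equal(contingency_cells(self)[["c"]], 0L)
  expect_equal(contingency_cells(self)[["b"]], 0L)

  # all absent: a = n_total
  none <- categorize_pair(setNames(character(), character()),
                          setNames(character(), character()), ds)
  expect_equal(none[["n_0c0o"]], 10L)

  # stray dataset id is a consistency error
  expect_error(categorize_pair(setNames("UP", "ZZZ"), other, ds),
               "outside dataset_ids")
})

test_that("fet_pvalue matches frozen oracle values", {
  # (3,1,1,3) POSITIVE: full enumeration over margins (4,4)/(4,4) gives
  # [C(4,3)C(4,1) + C(4,4)C(4,0)] / C(8,4) = 17/70
  expect_equal(fet_pvalue(list(a = 3, b = 1, c = 1, d = 3), "POSITIVE"),
               17 / 70, tolerance = 1e-12)
  expect_equal(oracle_fet(3, 1, 1, 3, "POSITIVE"), 17 / 70, tolerance = 1e-12)

  # d = 0: the POSITIVE tail spans the entire support
  expect_equal(fet_pvalue(list(a = 5, b = 3, c = 4, d = 0), "POSITIVE"), 1)

  # spot value frozen from the independent brute-force oracle
  p_impl <- fet_pvalue(list(a = 10, b = 5, c = 1, d = 4), "POSITIVE")
  expect_equal(p_impl, oracle_fet(10, 5, 1, 4, "POSITIVE"), tolerance = 1e-12)
  expect_equal(p_impl, 1512 / 15504, tolerance = 1e-12)

  expect_error(fet_pvalue(list(a = 0, b = 0, c = 0, d = 0)), "empty contingency")
})

test_that("fet_pvalue agrees with fisher.test on random tables", {
  set.seed(4)
  for (i in 1:1000) {
    tb <- as.list(setNames(rpois(4, sample(c(1, 3, 8), 1)), c("a", "b", "c", "d")))
    if (sum(unlist(tb)) == 0) next
    m <- matrix(unlist(tb), 2, byrow = TRUE)
    expect_equal(fet_pvalue(tb, "POSITIVE"),
                 stats::fisher.test(m, alternative = "greater")$p.value,
                 tolerance = 1e-10)
    expect_equal(fet_pvalue(tb, "NEGATIVE"),
                 stats::fisher.test(m, alternative = "less")$p.value,
                 tolerance = 1e-10)
  }
})

test_that("moving a dataset from c to d never increases the POSITIVE p", {
  set.seed(5)
  for (i in 1:200) {
    tb <- rpois(4, 5); a <- tb[1]; b <- tb[2]; cc <- tb[3] + 1; d <- tb[4]
    p0 <- fet_pvalue(list(a = a, b = b, c = cc, d = d), "POSITIVE")
    p1 <- fet_pvalue(list(a = a, b = b, c = cc - 1, d = d + 1), "POSITIVE")
    expect_lte(p1, p0 * (1 + 1e-12))
  }
})

test_that("UP/DOWN relabeling of both sites leaves c, d and p unchanged", {
  set.seed(6)
  ds <- sprintf("D%02d", 1:30)
  flip <- c(UP = "DOWN", DOWN = "UP")
  for (i in 1:50) {
    a_raw <- sample(c("UP", "DOWN", NA), 30, replace = TRUE)
    o_raw <- sample(c("UP", "DOWN", NA), 30, replace = TRUE)
    av <- setNames(a_raw[!is.na(a_raw)], ds[!is.na(a_raw)])
    ov <- setNames(o_raw[!is.na(o_raw)], ds[!is.na(o_raw)])
    c1 <- contingency_cells(categorize_pair(av, ov, ds))
    c2 <- contingency_cells(categorize_pair(setNames(flip[av], names(av)),
                                            setNames(flip[ov], names(ov)), ds))
    expect_equal(c1[c("c", "d")], c2[c("c", "d")])
    if (sum(c1) > 0) {
      expect_equal(fet_pvalue(as.list(c1), "POSITIVE"),
                   fet_pvalue(as.list(c2), "POSITIVE"), tolerance = 1e-12)
    }
  }
})

test_that("coregulation_ratio arithmetic and sentinels", {
  expect_equal(coregulation_ratio(list(a = 0, b = 0, c = 2, d = 48), "POSITIVE"), 24)
  expect_equal(coregulation_ratio(list(a = 0, b = 0, c = 5, d = 0), "POSITIVE"), 0)
  expect_equal(coregulation_ratio(list(a = 0, b = 0, c = 0, d = 7), "POSITIVE"), Inf)
  expect_equal(coregulation_ratio(list(a = 0, b = 0, c = 2, d = 48), "NEGATIVE"), 1 / 24)
})

test_that("apply_confidence_filters enforces all four criteria", {
  cfg <- confidence_config()
  base <- list(p = 6.98e-11, ratio = 24, pmid_count = 6L, expcode_count = 6L)
  # anchor differential frequency 108 -> ratio threshold 10.8
  expect_true(apply_confidence_filters(base, 108L, cfg))
  expect_false(apply_confidence_filters(modifyList(base, list(pmid_count = 1L)),
                                        108L, cfg))
  expect_false(apply_confidence_filters(modifyList(base, list(p = 0.05)),
                                        108L, cfg))
  expect_false(apply_confidence_filters(modifyList(base, list(ratio = 10.7)),
                                        108L, cfg))
  expect_false(apply_confidence_filters(modifyList(base, list(expcode_count = 1L)),
                                        108L, cfg))
  # absolute override replaces the fraction rule
  cfg_abs <- confidence_config(ratio_absolute = 30)
  expect_false(apply_confidence_filters(base, 108L, cfg_abs))
})

test_that("run_coregulation on synthetic data keeps cell conservation", {
  b <- small_bundle()
  catalog <- bundle_catalog(b)
  ps <- run_coregulation(catalog, b$truth$anchor)
  n_total <- catalog$datasets[kind == "DIFFERENTIAL", .N]
  expect_true(all(ps$a + ps$b + ps$c + ps$d == n_total))
  expect_true(all(ps$p > 0 & ps$p <= 1))
  expect_true(all(ps$coreg_frequency ==
                    ifelse(ps$sign == "POSITIVE", ps$d, ps$c)))
  expect_false(is.unsorted(ps$p))
  # PsOPs are on other proteins only
  expect_false(any(grepl("^ANCH_", ps$psop)))
  summ <- attr(ps, "summary")
  expect_equal(summ$n_high_confidence_positive,
               ps[, sum(high_confidence & sign == "POSITIVE")])
})

test_that("run_coregulation error and degenerate cases", {
  # anchor never regulated -> error
  ds <- list(ds_row("D1", "DIFFERENTIAL"))
  obs <- list(obs_row("PROT1", "S", 10, "D1", 1.0, 0.9),
              obs_row("PROT2", "S", 5, "D1", 2.0, 0.01))
  catalog <- make_catalog(obs, ds)
  expect_error(run_coregulation(catalog, "PROT1_S10"), "never differentially")

  # single-dataset catalog: no PsOP can be high-confidence (PMID filter)
  obs2 <- list(obs_row("PROT1", "S", 10, "D1", 2.0, 0.01),
               obs_row("PROT2", "S", 5, "D1", 2.0, 0.01))
  cat2 <- make_catalog(obs2, ds)
  ps <- run_coregulation(cat2, "PROT1_S10")
  expect_false(any(ps$high_confidence))
})

test_that("unregulated='detected' moves unregulated detections into b", {
  ds <- lapply(sprintf("D%d", 1:6), ds_row, kind = "DIFFERENTIAL")
  obs <- list(
    obs_row("PROT1", "S", 10, "D1", 2.0, 0.01),
    obs_row("PROT2", "S", 5, "D1", 2.0, 0.01),   # co-regulated (d)
    obs_row("PROT1", "S", 10, "D2", 2.0, 0.01),  # anchor only (b)
    obs_row("PROT2", "S", 5, "D3", 1.0, 0.80),   # other detected, unregulated
    obs_row("PROT1", "S", 10, "D4", 1.0, 0.80)   # anchor detected, unregulated
  )
  catalog <- make_catalog(obs, ds)
  ps_abs <- run_coregulation(catalog, "PROT1_S10", confidence_config())
  ps_det <- run_coregulation(catalog, "PROT1_S10",
                             confidence_config(unregulated = "detected"))
  expect_equal(ps_abs[, c(a, b, c, d)], c(4L, 1L, 0L, 1L))
  expect_equal(ps_det[, c(a, b, c, d)], c(2L, 3L, 0L, 1L))
})
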