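test_that("state calls dichotomize betas at the configured cutoffs", {
  expect_equal(call_state(c(0.10, 0.80, 0.30)),
               c("unmethylated", "methylated", "indeterminate"))
  th <- call_thresholds()
  expect_equal(call_state(th$beta_unmeth_max), "unmethylated")
  expect_equal(call_state(th$beta_meth_min), "methylated")
  expect_error(call_state(1.2), "\\[0, 1\\]")
  expect_error(call_thresholds(beta_unmeth_max = 0.5, beta_meth_min = 0.4),
               "beta_unmeth_max")
  expect_error(call_thresholds(absent_freq_max = 0.3), "absent_freq_max")
})

test_that("methylation frequency counts methylated calls over the subset", {
  expect_equal(methylation_frequency(rep(0.1, 51)), 0)
  # 13 methylated of 51 = 25.49%, just above the 25% frequent-marker floor
  expect_equal(methylation_frequency(c(rep(0.8, 13), rep(0.1, 38))),
               100 * 13 / 51)
  # indeterminate calls dilute the denominator only
  expect_equal(methylation_frequency(c(0.8, 0.3, 0.1, 0.1)), 25)
  expect_error(methylation_frequency(numeric(0)), "empty")
})

test_that("gene classification follows the four category clauses in order", {
  expect_equal(classify_gene("unmethylated", 0.30, 0.00), "high_meth_marker")
  expect_equal(classify_gene("methylated", 1.00, 1.00), "normally_methylated")
  expect_equal(classify_gene("unmethylated", 0.00, 0.00), "unmethylated")
  expect_equal(classify_gene("unmethylated", 0.50, 0.50),
               "commonly_methylated")
  # frequencies between the rule boundaries are unclassified
  expect_equal(classify_gene("unmethylated", 0.10, 0.10), "unclassified")
  # indeterminate normals never classify
  expect_equal(classify_gene("indeterminate", 0.30, 0.00), "unclassified")
  # methylated normals with a subgroup gap stay unclassified
  expect_equal(classify_gene("methylated", 1.00, 0.50), "unclassified")
})

test_that("marker table agrees with scalar classification on every gene", {
  b <- simulate_cohort(tiny_config(seed = 51))
  fit <- tiny_fit(b)
  mt <- fit$marker_table
  th <- fit$control$thresholds
  for (i in sample(nrow(mt), 20)) {
    expect_equal(mt$category[i],
                 classify_gene(mt$normal_state[i], mt$freq_high[i] / 100,
                               mt$freq_low[i] / 100, th))
  }
  expect_true(all(mt$freq_high >= 0 & mt$freq_high <= 100))
  # every analyzed gene gets exactly one category
  expect_equal(nrow(mt), length(fit$analyzed_genes))
})

test_that("noise-free bundles recover planted categories exactly", {
  for (s in c(61, 62)) {
    b <- simulate_cohort(tiny_config(seed = s, beta_noise_sd = 0,
                                     calib_noise_sd = 0))
    fit <- tiny_fit(b)
    cfg_counts <- b$config$n_genes_by_category
    cc <- fit$category_counts
    for (cat in c("unmethylated", "high_meth_marker", "commonly_methylated",
                  "normally_methylated"))
      expect_equal(as.integer(cc[[cat]]), unname(cfg_counts[[cat]]))
    expect_equal(as.integer(cc[["unclassified"]]), 0L)
    # per-gene identity, not just counts
    cat_truth <- b$truth$gene_category[fit$marker_table$gene]
    expect_equal(unname(fit$marker_table$category), unname(cat_truth))
  }
})

test_that("raising the methylated cutoff never increases a frequency", {
  b <- simulate_cohort(tiny_config(seed = 52))
  fit_lo <- tiny_fit(b, control = epitype_control(
    thresholds = call_thresholds(beta_meth_min = 0.35)))
  fit_hi <- tiny_fit(b, control = epitype_control(
    thresholds = call_thresholds(beta_meth_min = 0.6)))
  common <- intersect(fit_lo$marker_table$gene, fit_hi$marker_table$gene)
  lo <- fit_lo$marker_table[match(common, fit_lo$marker_table$gene), ]
  hi <- fit_hi$marker_table[match(common, fit_hi$marker_table$gene), ]
  expect_true(all(hi$freq_all <= lo$freq_all + 1e-9))
  expect_true(all(hi$freq_high <= lo$freq_high + 1e-9))
})

test_that("frequent-marker ranking filters, sorts and intersects", {
  mt <- data.frame(gene = c("A", "B", "C", "D"),
                   category = c("high_meth_marker", "high_meth_marker",
                                "unmethylated", "high_meth_marker"),
                   freq_high = c(90, 70, 0, 60),
                   freq_low = c(0, 0, 0, 0),
                   freq_all = c(33, 22, 0, 28),
                   normal_state = "unmethylated")
  rk <- rank_frequent_markers(mt, freq_floor = 25)
  expect_equal(rk$gene, c("A", "D"))
  expect_equal(rank_frequent_markers(mt[mt$category == "unmethylated", ])$gene,
               character(0))
  # two-cohort intersection keeps genes above the floor in both
  mt2 <- mt
  mt2$freq_all <- c(33, 30, 0, 10)
  both <- rank_frequent_markers(mt, freq_floor = 25, second_table = mt2)
  expect_equal(both$gene, "A")
  expect_equal(both$freq_all_2, 33)
})
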