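test_that("generator configuration is validated", {
  expect_s3_class(tiny_config(), "cohort_config")
  expect_error(tiny_config(n_high = 18L), "n_high")
  expect_error(tiny_config(marker_freq_range = c(0.5, 0.2)), "interval")
  expect_error(tiny_config(frac_bad_probes = 1), "frac_bad_probes")
  expect_error(cohort_config(n_genes_by_category = c(unmethylated = 5)),
               "n_genes_by_category")
})

test_that("minimal manifest has one row per probe and full-length promoters", {
  cfg <- cohort_config(seed = 3, n_tumors = 4, n_high = 1,
                       n_genes_by_category = c(unmethylated = 0,
                                               high_meth_marker = 1,
                                               commonly_methylated = 0,
                                               normally_methylated = 0,
                                               filler_low_cpg = 0),
                       max_probes_per_gene = 1L)
  man <- generate_manifest(cfg)
  expect_equal(nrow(man$manifest), 1L)
  expect_equal(length(man$sequences), 1L)
  expect_equal(Biostrings::width(man$sequences), 2000L)
})

test_that("TFPI2 exemplar carries the maximum probe count, nearest 15 bp upstream", {
  cfg <- tiny_config(seed = 2)
  man <- generate_manifest(cfg)
  tf <- man$manifest[man$manifest$gene == "TFPI2", ]
  expect_equal(nrow(tf), cfg$max_probes_per_gene)
  d <- signed_tss_distance(tf$position, tf$tss, tf$strand)
  expect_equal(d[which.min(abs(d))], -15L)
  expect_true(all(abs(d[d != -15L]) > 15L))
})

test_that("identical config and seed give byte-identical bundles", {
  b1 <- simulate_cohort(tiny_config(seed = 11))
  b2 <- simulate_cohort(tiny_config(seed = 11))
  expect_identical(b1$manifest, b2$manifest)
  expect_identical(as.character(b1$sequences), as.character(b2$sequences))
  expect_identical(b1$betas, b2$betas)
  expect_identical(b1$calibration, b2$calibration)
  expect_identical(b1$clinical, b2$clinical)
  expect_identical(b1$truth, b2$truth)
  b3 <- simulate_cohort(tiny_config(seed = 12))
  expect_false(identical(b1$betas, b3$betas))
  expect_identical(dim(b1$betas), dim(b3$betas))
})

test_that("promoter sequences land in the class their category requires", {
  b <- simulate_cohort(tiny_config(seed = 4))
  ann <- annotate_promoters(b$manifest, b$sequences,
                            control = epitype_control(window = c(-450, 450)))
  cls <- setNames(ann$promoter_class, ann$gene)
  cat <- b$truth$gene_category[names(cls)]
  expect_true(all(cls[cat == "filler_low_cpg"] == "LCP"))
  expect_true(all(cls[cat != "filler_low_cpg"] %in% c("HCP", "ICP")))
  expect_true(all(cls[cat %in% c("unmethylated", "high_meth_marker",
                                 "commonly_methylated")] == "HCP"))
})

test_that("noise-free betas sit exactly at the planted base levels", {
  cfg <- tiny_config(seed = 5, beta_noise_sd = 0, frac_bad_probes = 0)
  b <- simulate_cohort(cfg)
  cat <- b$truth$gene_category[b$manifest$gene]
  unm_rows <- b$manifest$probe_id[cat == "unmethylated"]
  expect_true(all(b$betas[unm_rows, ] == cfg$beta_unmeth))
  nrm_rows <- b$manifest$probe_id[cat == "normally_methylated"]
  expect_true(all(b$betas[nrm_rows, ] == cfg$beta_meth))
  # marker genes are methylated only in columns of true high epigenotype
  hi <- names(b$truth$epigenotype)[b$truth$epigenotype == "high"]
  mk_rows <- b$manifest$probe_id[cat == "high_meth_marker"]
  meth_cols <- which(b$betas[mk_rows, , drop = FALSE] == cfg$beta_meth,
                     arr.ind = TRUE)
  expect_true(all(colnames(b$betas)[meth_cols[, 2]] %in% hi))
})

test_that("planted marker frequencies fall inside the configured window", {
  b <- simulate_cohort(cohort_config(seed = 6,
    n_genes_by_category = c(unmethylated = 50, high_meth_marker = 27,
                            commonly_methylated = 5, normally_methylated = 10,
                            filler_low_cpg = 10),
    max_probes_per_gene = 3L, promoter_length = 400L))
  expect_true(all(b$truth$marker_freq >= 0.22 & b$truth$marker_freq <= 0.33))
  expect_equal(b$truth$marker_freq[["TFPI2"]], max(b$truth$marker_freq))
  # frequencies realized in the betas match the planted ones (read off a
  # well-behaved probe of each marker; planted-bad probes are corrupted)
  good <- b$manifest[!b$manifest$probe_id %in% b$truth$bad_probes$probe_id, ]
  mt <- good[match(names(b$truth$marker_freq), good$gene), ]
  tum <- names(b$sample_roles)[b$sample_roles == "tumor"]
  realized <- rowMeans(b$betas[mt$probe_id, tum, drop = FALSE] >= 0.4)
  expect_equal(unname(realized), unname(b$truth$marker_freq), tolerance = 0.06)
})

test_that("calibration series is exact at zero noise and flags planted bad probes", {
  cfg <- tiny_config(seed = 7, calib_noise_sd = 0)
  man <- generate_manifest(cfg)
  cal <- generate_calibration_betas(cfg, man$manifest)
  err <- tapply(abs(cal$measured_beta - cal$expected_fraction),
                cal$probe_id, max)
  bad <- names(err)[err > 0]
  good_one <- setdiff(unique(cal$probe_id), bad)[1]
  expect_equal(cal$measured_beta[cal$probe_id == good_one],
               c(0, 0.25, 0.5, 0.75, 1))
  n_bad_expected <- round(cfg$frac_bad_probes * nrow(man$manifest))
  expect_lte(abs(length(bad) - n_bad_expected), 1L)
})

test_that("every gene keeps at least one well-behaved probe", {
  b <- simulate_cohort(tiny_config(seed = 8, frac_bad_probes = 0.4))
  bad <- b$truth$bad_probes$probe_id
  good_per_gene <- tapply(!b$manifest$probe_id %in% bad, b$manifest$gene, any)
  expect_true(all(good_per_gene))
})

test_that("clinical covariates follow the configured subgroup distributions", {
  cfg <- cohort_config(seed = 9,
                       thickness_params = list(high = c(mean = 8.3, sd = 0),
                                               low = c(mean = 4.5, sd = 0),
                                               floor = 0.1))
  epi <- setNames(rep(c("high", "low"), c(17, 34)), sprintf("MM%02d", 1:51))
  cl <- generate_clinical_table(cfg, epi)
  expect_true(all(cl$thickness_mm[epi == "high"] == 8.3))
  expect_true(all(cl$thickness_mm[epi == "low"] == 4.5))
  expect_true(all(cl$stage %in% 1:4))
  expect_true(all(cl$event %in% 0:1))
  expect_true(all(cl$braf + cl$nras <= 1))
  # BRAF prevalence near its binomial expectation of 51 * 18/77 = 11.9
  braf_counts <- vapply(1:20, function(s)
    sum(generate_clinical_table(cohort_config(seed = s), epi)$braf),
    numeric(1))
  expect_gt(mean(braf_counts), 11.9 - 2.5)
  expect_lt(mean(braf_counts), 11.9 + 2.5)
})

test_that("equal subgroup hazards give a null log-rank distribution", {
  cfg <- cohort_config(seed = 1,
                       survival_params = list(hazard_high = log(2) / 1000,
                                              hazard_low = log(2) / 1000,
                                              censor_rate = 0.4))
  epi <- setNames(rep(c("high", "low"), c(17, 34)), sprintf("MM%02d", 1:51))
  p <- vapply(1:20, function(s) {
    cl <- generate_clinical_table(cohort_config(seed = s,
      survival_params = cfg$survival_params), epi)
    logrank_test(cl$os_days, cl$event, epi)$p_value
  }, numeric(1))
  expect_lte(sum(p < 0.05), 4L)
})

test_that("bundle round-trips through its on-disk representation", {
  b <- simulate_cohort(tiny_config(seed = 10))
  dir <- withr::local_tempdir()
  write_cohort(b, dir)
  expect_setequal(list.files(dir),
                  c("manifest.tsv", "promoters.fasta", "betas.tsv",
                    "calibration.tsv", "clinical.tsv", "prc_targets.gmt",
                    "truth.json"))
  rb <- read_cohort(dir)
  expect_equal(rb$manifest, b$manifest)
  expect_equal(rb$betas, b$betas, tolerance = 1e-12)
  expect_equal(unname(as.character(rb$sequences)),
               unname(as.character(b$sequences)))
  expect_equal(rb$truth$epigenotype, b$truth$epigenotype)
  expect_equal(sort(rb$prc$PRC_TARGETS_ES), sort(b$prc$PRC_TARGETS_ES))
  expect_equal(rb$sample_roles, b$sample_roles)
})
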