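test_that("Fisher p-values match enumeration on worked examples", {
  # empty outcome column: only one table possible
  expect_equal(fisher_exact(matrix(c(0, 5, 0, 5), 2, byrow = TRUE))$p_value, 1)
  # all 5 tables with margins (4,4,4,4) enumerated by hand:
  # P(a)=C(4,a)^2/C(8,4): 1/70, 16/70, 36/70, 16/70, 1/70 -> two-sided p for
  # a=3 sums all but the central table: 34/70
  expect_equal(fisher_exact(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))$p_value,
               34 / 70)
  # extreme 10/0/0/10 table: 2 / C(20,10)
  expect_equal(fisher_exact(matrix(c(10, 0, 0, 10), 2, byrow = TRUE))$p_value,
               2 / choose(20, 10))
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("Fisher matches stats::fisher.test on random tables", {
  set.seed(71)
  for (i in 1:300) {
    tab <- matrix(rpois(4, 5), 2, 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact(tab)$p_value, fisher.test(tab)$p.value,
                 tolerance = 1e-10)
  }
})

test_that("Welch t matches the closed form and stats::t.test", {
  r <- welch_t(c(1, 2, 3), c(1, 2, 3) + 1e-8)
  expect_equal(r$statistic, 0, tolerance = 1e-6)
  expect_equal(r$p_value, 1, tolerance = 1e-6)

  r <- welch_t(c(1, 2, 3), c(4, 5, 6))
  # direct formula: t = -3/sqrt(2/3), df = 4
  expect_equal(r$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r$df, 4)
  expect_equal(r$p_value, 2 * pt(-abs(r$statistic), 4))
  ref <- t.test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, unname(ref$statistic))
  expect_equal(r$p_value, ref$p.value)
  expect_equal(r$mean_x, 2)
  expect_equal(r$sd_x, 1)
  expect_error(welch_t(c(1, 1), c(2, 3)), "zero variance")
  expect_error(welch_t(1, c(2, 3)), "n >= 2")
})

test_that("Kaplan-Meier estimator reproduces hand-computed curves", {
  # no events: flat at 1
  km <- km_estimate(c(3, 6, 9), c(0, 0, 0))
  expect_true(all(km$curve$surv == 1))
  expect_true(is.na(km$median))
  # one death among four: S(10) = 3/4
  km <- km_estimate(c(10, 12, 14, 16), c(1, 0, 0, 0))
  expect_equal(km$curve$surv[1], 3 / 4)
  # hand product-limit: deaths at 5,10,20 with a censor at 15
  km <- km_estimate(c(5, 10, 15, 20), c(1, 1, 0, 1))
  expect_equal(km$curve$surv, c(3 / 4, 1 / 2, 1 / 2, 0))
  expect_equal(km$curve$n_risk, c(4, 3, 2, 1))
  expect_equal(km$median, 10)
  expect_error(km_estimate(-1, 1), "non-negative")
})

test_that("Kaplan-Meier matches survival::survfit and the empirical survivor", {
  set.seed(72)
  time <- round(rexp(40, 1 / 50), 1)
  event <- rbinom(40, 1, 0.7)
  km <- km_estimate(time, event)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  expect_equal(km$curve$surv, unname(summary(sf, times = km$curve$time)$surv),
               tolerance = 1e-12)
  # with no censoring the product-limit equals the empirical survivor
  km2 <- km_estimate(time, rep(1, 40))
  ecdf_surv <- vapply(km2$curve$time, function(t0) mean(time > t0), numeric(1))
  expect_equal(km2$curve$surv, ecdf_surv, tolerance = 1e-12)
})

test_that("log-rank statistic matches a hand risk-set tabulation", {
  # A events at 1,2; B events at 3,4; no censoring
  time <- c(1, 2, 3, 4); event <- rep(1, 4)
  group <- c("A", "A", "B", "B")
  # risk sets: t=1 n=4 n_A=2; t=2 n=3 n_A=1; t=3 n=2 n_A=0; t=4 n=1 n_A=0
  E <- 2 / 4 + 1 / 3
  V <- (2 / 4) * (1 - 2 / 4) * 1 + (1 / 3) * (2 / 3) * 1
  stat_hand <- (2 - E)^2 / V
  r <- logrank_test(time, event, group)
  expect_equal(r$statistic, stat_hand, tolerance = 1e-12)
  expect_equal(r$p_value, pchisq(stat_hand, 1, lower.tail = FALSE))
  # identical survival in both groups
  r0 <- logrank_test(c(1, 2, 1, 2), c(0, 0, 0, 0), c("A", "A", "B", "B"))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  expect_error(logrank_test(1:4, rep(1, 4), rep("A", 4)), "two groups")
})

test_that("log-rank agrees with survival::survdiff and is scale invariant", {
  set.seed(73)
  for (i in 1:20) {
    n <- 30
    time <- rexp(n, 1 / 100)
    event <- rbinom(n, 1, 0.7)
    group <- sample(c("A", "B"), n, replace = TRUE)
    if (length(unique(group)) < 2 || sum(event) == 0) next
    r <- logrank_test(time, event, group)
    sd_ref <- survival::survdiff(survival::Surv(time, event) ~ group)
    expect_equal(r$statistic, sd_ref$chisq, tolerance = 1e-9)
    r_scaled <- logrank_test(time * 365.25, event, group)
    expect_equal(r$statistic, r_scaled$statistic, tolerance = 1e-12)
  }
})

test_that("quartile grouping takes floor(n/4) from each tail", {
  v <- c(10, 20, 30, 40, 50, 60, 70, 80)
  g <- quartile_groups(v)
  expect_equal(sum(g == "high"), 2)
  expect_equal(sum(g == "low"), 2)
  expect_equal(sum(g == "excluded"), 4)
  expect_true(all(v[g == "high"] > max(v[g == "excluded"])))
  expect_true(all(v[g == "low"] < min(v[g == "excluded"])))
  # tie resolution by first occurrence keeps the group sizes exact
  g2 <- quartile_groups(rep(c(1, 2, 3), c(4, 4, 4)))
  expect_equal(sum(g2 == "high"), 3)
  expect_equal(sum(g2 == "low"), 3)
  # 342 samples: floor(342/4) = 85 per tail group
  g3 <- quartile_groups(seq_len(342))
  expect_equal(sum(g3 == "high"), 85)
  expect_equal(sum(g3 == "low"), 85)
  expect_error(quartile_groups(1:3), "at least 4")
  expect_error(quartile_groups(rep(1, 8)), "all values are equal")
})

test_that("PRC enrichment builds the right tables and respects symmetry", {
  mt <- data.frame(
    gene = c(sprintf("M%02d", 1:20), sprintf("U%03d", 1:200),
             sprintf("N%03d", 1:50)),
    category = rep(c("high_meth_marker", "unmethylated",
                     "normally_methylated"), c(20, 200, 50)))
  mt$freq_high <- 0; mt$freq_low <- 0; mt$freq_all <- 0
  mt$normal_state <- "unmethylated"
  # planted enrichment: 60% of markers, 10% of background are PRC targets
  prc <- c(sprintf("M%02d", 1:12), sprintf("U%03d", 1:20),
           sprintf("N%03d", 1:5))
  enr <- prc_enrichment(mt, prc)
  expect_equal(enr$prc_marker, c(12, 12))
  expect_equal(enr$prc_ref, c(20, 5))
  # hypergeometric tail at these counts is well below 0.05
  expect_true(all(enr$p_value < 0.05))
  expect_equal(enr$p_value[1],
               fisher_exact(matrix(c(12, 8, 20, 180), 2, byrow = TRUE))$p_value)
  # disjoint gene set: both tests are null
  enr0 <- prc_enrichment(mt, c("ZZZ1", "ZZZ2"))
  expect_true(all(enr0$p_value == 1))
  # swapping the comparison rows leaves Fisher's p unchanged
  p_swap <- fisher_exact(matrix(c(20, 180, 12, 8), 2, byrow = TRUE))$p_value
  expect_equal(enr$p_value[1], p_swap)
})

test_that("association report tests each factor with the right method", {
  b <- simulate_cohort(tiny_config(seed = 74))
  fit <- tiny_fit(b)
  rep <- fit$association
  expect_setequal(rep$factor,
                  c("stage_3_4", "thickness_gt_4mm", "age_above_median",
                    "braf_mutant", "nras_mutant", "acral_site", "ulceration",
                    "thickness_mm", "overall_survival"))
  expect_equal(rep$test[rep$factor == "thickness_mm"], "welch_t")
  expect_equal(rep$test[rep$factor == "overall_survival"], "logrank")
  expect_true(all(rep$p_value >= 0 & rep$p_value <= 1))
  expect_equal(rep$significant, rep$p_value < 0.05)
  expect_true(all(rep$p_adj_BH >= rep$p_value - 1e-12))
  expect_error(association_report(fit$labels, b$clinical[, -2]),
               "lacks columns")
})

test_that("separated thickness distributions are flagged, null factors mostly not", {
  # planted separation with tiny SDs: Welch test must fire
  cfg <- tiny_config(seed = 75,
                     thickness_params = list(high = c(mean = 8.3, sd = 0.1),
                                             low = c(mean = 4.5, sd = 0.1),
                                             floor = 0.1))
  b <- simulate_cohort(cfg)
  fit <- tiny_fit(b)
  expect_true(fit$association$significant[
    fit$association$factor == "thickness_mm"])
  # epigenotype-independent factors stay null in most seeds
  hits <- vapply(1:10, function(s) {
    b <- simulate_cohort(tiny_config(seed = 200 + s))
    fit <- tiny_fit(b)
    a <- fit$association
    sum(a$significant[a$factor %in% c("braf_mutant", "nras_mutant",
                                      "acral_site", "ulceration")])
  }, numeric(1))
  expect_lte(mean(hits > 0), 0.4)
})
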