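# Relative expression and group statistics.

make_qpcr_rows <- function(sample, group, ct_target, ct_hk) {
  data.frame(sample = rep(sample, 2), group = rep(group, 2),
             gene = c("Nppb", "Gapdh"), ct = c(ct_target, ct_hk))
}

test_that("ddct reproduces the hand-worked example", {
  # control samples with dCt 3; test sample Ct 20 target / 18 housekeeping:
  # dCt 2, ddCt -1, fold 2
  tab <- rbind(make_qpcr_rows("c1", "CTRL", 21, 18),
               make_qpcr_rows("c2", "CTRL", 23, 20),
               make_qpcr_rows("t1", "HF", 20, 18))
  dd <- ddct(tab, housekeeping = "Gapdh", control = "CTRL")
  expect_equal(dd$fold[dd$sample == "t1"], 2)
  # control group geometric mean fold is exactly 1
  ctl <- dd$fold[dd$group == "CTRL"]
  expect_equal(exp(mean(log(ctl))), 1, tolerance = 1e-12)
  # a sample whose dCt equals the control mean has fold 1
  tab2 <- rbind(tab, make_qpcr_rows("t2", "HF", 22, 19))
  dd2 <- ddct(tab2)
  expect_equal(dd2$fold[dd2$sample == "t2"], 1)
  # ddCt of -2 means fold 4
  tab3 <- rbind(tab, make_qpcr_rows("t3", "HF", 19, 18))
  dd3 <- ddct(tab3)
  expect_equal(dd3$fold[dd3$sample == "t3"], 4)
})

test_that("ddct is invariant to plate-wide Ct shifts, equivariant to target shifts", {
  q <- simulate_qpcr(seed = 5, ct_sd = 0.2)
  dd <- ddct(q$table)
  shifted <- q$table
  shifted$ct <- shifted$ct + 1.7   # both genes shift: dCt cancels
  dd2 <- ddct(shifted)
  expect_equal(dd2$fold, dd$fold, tolerance = 1e-12)
  tshift <- q$table
  tshift$ct[tshift$gene == "Nppb"] <- tshift$ct[tshift$gene == "Nppb"] + 1
  dd3 <- ddct(tshift)
  # shifting only target Ct shifts every dCt equally, so folds (centered on
  # the control) are unchanged
  expect_equal(dd3$fold, dd$fold, tolerance = 1e-12)
  miss <- q$table[!(q$table$sample == "CTRL_01" & q$table$gene == "Gapdh"), ]
  expect_error(ddct(miss), "CTRL_01")
})

test_that("normalization to control maps control mean to 100 and is idempotent", {
  tab <- data.frame(group = c("CTRL", "CTRL", "CTRL", "HF"),
                    value = c(2, 2, 2, 3))
  nz <- normalize_to_control(tab, control = "CTRL")
  expect_equal(nz$value[4], 150)
  expect_equal(mean(nz$value[1:3]), 100)
  expect_equal(normalize_to_control(nz, control = "CTRL")$value, nz$value)
  expect_error(normalize_to_control(data.frame(group = "CTRL", value = 0)),
               "zero")
})

test_that("two identical groups give t = 0 and p = 1", {
  tab <- data.frame(group = rep(c("A", "B"), each = 4),
                    value = rep(c(1, 2, 3, 4), 2))
  r <- compare_groups(tab, design = "t-test")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
})

test_that("Dunn test matches an independently computed oracle", {
  # z and p values computed independently with scipy rank machinery
  vals <- c(3.1, 2.8, 3.5, 3.0, 4.9, 5.2, 4.7, 5.5, 2.9, 3.2, 3.3)
  grp <- factor(c("A", "A", "A", "A", "B", "B", "B", "B", "C", "C", "C"))
  d <- dunn_test(vals, grp, adjust = "holm")
  expect_equal(d$z[d$pair == "A-B"], -2.4518082381, tolerance = 1e-9)
  expect_equal(d$z[d$pair == "A-C"], -0.2302830932, tolerance = 1e-9)
  expect_equal(d$z[d$pair == "B-C"], 2.0396502544, tolerance = 1e-9)
  expect_equal(d$p_unadjusted[d$pair == "A-B"], 0.0142140389, tolerance = 1e-8)
  expect_equal(d$p_adjusted[d$pair == "A-B"], 0.0426421166, tolerance = 1e-8)
  expect_equal(d$p_adjusted[d$pair == "A-C"], 0.8178717973, tolerance = 1e-8)
  expect_equal(d$p_adjusted[d$pair == "B-C"], 0.0827703458, tolerance = 1e-8)
  kw <- compare_groups(data.frame(group = grp, value = vals),
                       design = "nonparametric")
  expect_equal(kw$statistic, 7.0530303030, tolerance = 1e-8)
  expect_equal(kw$p_value, 0.0294072172, tolerance = 1e-8)
})

test_that("p-values are invariant to relabeling and the right transformations", {
  set.seed(split_seed(3, "invariance"))
  tab <- data.frame(group = rep(c("A", "B", "C"), each = 8),
                    value = rnorm(24))
  r1 <- compare_groups(tab, design = "one-way")
  relab <- tab
  relab$group <- c(A = "Z", B = "Y", C = "X")[tab$group]
  r2 <- compare_groups(relab, design = "one-way")
  expect_equal(r2$p_value, r1$p_value, tolerance = 1e-12)
  aff <- tab
  aff$value <- -2.5 * tab$value + 7
  r3 <- compare_groups(aff, design = "one-way")
  expect_equal(r3$p_value, r1$p_value, tolerance = 1e-9)
  k1 <- compare_groups(tab, design = "nonparametric")
  mono <- tab
  mono$value <- exp(tab$value)
  k2 <- compare_groups(mono, design = "nonparametric")
  expect_equal(k2$p_value, k1$p_value, tolerance = 1e-12)
  expect_equal(k2$pairwise$p_adjusted, k1$pairwise$p_adjusted,
               tolerance = 1e-12)
})

test_that("Tukey-adjusted p is never below the unadjusted pairwise p", {
  set.seed(split_seed(4, "tukey"))
  for (i in 1:5) {
    tab <- data.frame(group = rep(c("A", "B", "C"), each = 7),
                      value = rnorm(21, mean = rep(c(0, 0.5, 1), each = 7)))
    r <- compare_groups(tab, design = "one-way")
    fit <- aov(value ~ group, data = tab)
    mse <- sum(residuals(fit)^2) / fit$df.residual
    for (p in seq_len(nrow(r$pairwise))) {
      gs <- strsplit(r$pairwise$pair[p], "-")[[1]]
      v1 <- tab$value[tab$group == gs[1]]
      v2 <- tab$value[tab$group == gs[2]]
      se <- sqrt(mse * (1 / length(v1) + 1 / length(v2)))
      p_unadj <- 2 * pt(-abs(mean(v1) - mean(v2)) / se, fit$df.residual)
      expect_gte(r$pairwise$p_adjusted[p], p_unadj - 1e-12)
    }
  }
})

test_that("two-way design reports the group effect with within-level Tukey", {
  set.seed(split_seed(5, "twoway"))
  tab <- expand.grid(rep_i = 1:6, group = c("CTRL", "HF", "HF_CBD"),
                     factor2 = c(0.5, 1, 2))
  tab$value <- rnorm(nrow(tab)) +
    ifelse(tab$group == "HF", -2, 0) + as.numeric(tab$factor2)
  r <- compare_groups(tab[, c("group", "factor2", "value")],
                      design = "two-way")
  expect_lt(r$p_value, 0.001)
  expect_equal(nrow(r$pairwise), 9)  # 3 pairs x 3 frequency levels
  expect_true(all(grepl("factor2=", r$pairwise$pair)))
})

test_that("auto design screens normality and falls back to Kruskal-Wallis", {
  set.seed(split_seed(6, "auto"))
  norm_tab <- data.frame(group = rep(c("A", "B"), each = 12),
                         value = rnorm(24))
  r1 <- compare_groups(norm_tab, design = "auto")
  expect_equal(r1$design, "t-test")
  skew <- data.frame(group = rep(c("A", "B", "C"), each = 12),
                     value = exp(rnorm(36, sd = 2)))
  r2 <- compare_groups(skew, design = "auto")
  expect_equal(r2$design, "nonparametric")
  expect_error(compare_groups(data.frame(group = c("A", "B"), value = 1:2)),
               "fewer than 2")
})
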