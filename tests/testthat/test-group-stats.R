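test_that("Box-Cox lambda recovers the generating transform", {
  set.seed(31)
  x <- exp(rnorm(500))
  bc <- box_cox_transform(x)
  expect_gte(bc$lambda_hat, -0.2)
  expect_lte(bc$lambda_hat, 0.2)
  # agrees with the profile-likelihood maximiser in MASS
  mb <- MASS::boxcox(x ~ 1, lambda = seq(-1, 1, 0.01), plotit = FALSE)
  expect_lt(abs(bc$lambda_hat - mb$x[which.max(mb$y)]), 0.02)

  y <- rnorm(500, 10, 1)
  bcy <- box_cox_transform(y)
  expect_gte(bcy$lambda_hat, 0.5)
  expect_lte(bcy$lambda_hat, 1.5)

  expect_error(box_cox_transform(rep(3, 50)), "constant")
  # profile is maximised at lambda_hat on the grid
  prof <- bc$loglik_profile
  expect_lt(abs(prof$lambda[which.max(prof$loglik)] - bc$lambda_hat), 0.011)
  # non-positive data are shifted, and the shift reported
  bs <- box_cox_transform(c(-1, 0.5, 1, 2, 3, 4))
  expect_gt(bs$shift, 1)
})

test_that("effect-size classifier uses the 0.04/0.25/0.64 thresholds", {
  expect_equal(as.character(classify_effect(c(0.03, 0.11, 0.30, 0.90))),
               c("negligible", "small", "moderate", "large"))
  expect_equal(as.character(classify_effect(c(0.04, 0.25, 0.64))),
               c("small", "moderate", "large"))
  expect_error(classify_effect(1.2))
})

hand_cohort <- function() {
  data.frame(
    subject_id = paste0("s", 1:8),
    group = rep(c("g1", "g2"), each = 2, times = 2),
    voi = rep(c("A", "B"), each = 4),
    val = c(1, 2, 3, 4, 5, 6, 7, 8))
}

test_that("two-way ANOVA reproduces hand-computed sums of squares", {
  tab <- hand_cohort()
  res <- two_way_anova_eta(tab, "val", transform = "none")
  ss <- stats::setNames(res$ss, res$factor)
  expect_equal(ss[["lesion_compartment"]], 32)
  expect_equal(ss[["group"]], 8)
  expect_equal(ss[["interaction"]], 0)
  expect_equal(attr(res, "ss_error"), 2)
  eta <- res$partial_eta_sq[res$factor == "group"]
  expect_equal(eta, 8 / 10)
  expect_equal(res$size_class[res$factor == "group"], "large")

  # independent cell-mean oracle and exact SS decomposition
  o <- ss_twoway_oracle(tab$val, factor(tab$voi), factor(tab$group))
  expect_equal(o$ss1, 32); expect_equal(o$ss2, 8)
  expect_equal(o$ss_int + o$ss1 + o$ss2 + o$ss_error, o$ss_total,
               tolerance = 1e-9)
  expect_equal(sum(res$ss) + attr(res, "ss_error"), o$ss_total,
               tolerance = 1e-9)

  # response differing by region only -> zero group effect
  tab2 <- tab; tab2$val <- c(1, 2, 1, 2, 5, 6, 5, 6)
  res2 <- two_way_anova_eta(tab2, "val", transform = "none")
  expect_equal(res2$partial_eta_sq[res2$factor == "group"], 0)

  # empty cell reported by name
  tab3 <- tab[!(tab$voi == "B" & tab$group == "g2"), ]
  expect_error(two_way_anova_eta(tab3, "val", transform = "none"),
               "empty cell")
})

test_that("partial eta-squared is invariant under affine response maps", {
  set.seed(32)
  tab <- hand_cohort()
  tab$val <- rnorm(8)
  r1 <- two_way_anova_eta(tab, "val", transform = "none")
  tab$val <- 3.2 * tab$val - 7
  r2 <- two_way_anova_eta(tab, "val", transform = "none")
  expect_equal(r1$partial_eta_sq, r2$partial_eta_sq, tolerance = 1e-9)
})

test_that("group F-test is calibrated and null effects stay small", {
  set.seed(33)
  n_sub <- 32; n_rep <- 200
  p_group <- numeric(n_rep)
  eta_group <- numeric(n_rep)
  base <- data.frame(
    subject_id = rep(paste0("s", 1:n_sub), each = 2),
    group = rep(rep(c("M1", "M1_ICA"), each = n_sub / 2), each = 2),
    voi = rep(c("dwi_lesion", "tar"), times = n_sub))
  for (i in seq_len(n_rep)) {
    base$val <- rnorm(2 * n_sub)
    r <- two_way_anova_eta(base, "val", transform = "none")
    p_group[i] <- r$p_value[r$factor == "group"]
    eta_group[i] <- r$partial_eta_sq[r$factor == "group"]
  }
  # permutation-null behaviour: p approximately uniform, eta small
  expect_lt(abs(mean(p_group < 0.05) - 0.05), 0.05)
  expect_gt(mean(p_group > 0.5), 0.3)
  expect_lt(median(eta_group), 0.05)
})

test_that("a CBV-only group offset is detected on CBV before any other parameter", {
  set.seed(34)
  n_sub <- 32
  delta <- 0.703  # group offset in SD units giving partial eta^2 ~ 0.11
  params <- c("adc_median", "tmax_median", "cbf_median", "cbv_median",
              "mtt_median")
  rejections <- stats::setNames(numeric(5), params)
  for (i in 1:100) {
    tab <- data.frame(
      subject_id = rep(paste0("s", 1:n_sub), each = 2),
      group = rep(rep(c("M1", "M1_ICA"), each = n_sub / 2), each = 2),
      voi = rep(c("dwi_lesion", "tar"), times = n_sub))
    for (p in params) tab[[p]] <- rnorm(2 * n_sub)
    shift <- rep(rep(c(0, delta), each = n_sub / 2), each = 2)
    tab$cbv_median <- tab$cbv_median + shift
    for (p in params) {
      r <- two_way_anova_eta(tab, p, transform = "none")
      rejections[p] <- rejections[p] +
        (r$p_value[r$factor == "group"] < 0.05)
    }
  }
  expect_true(all(rejections["cbv_median"] > rejections[params != "cbv_median"]))
  expect_gt(rejections[["cbv_median"]] / 100, 0.5)
})

test_that("baseline tests dispatch and match exact references", {
  # identical groups, balanced 2x2 table -> Fisher p = 1
  vals <- factor(rep(c("f", "m"), times = 8))
  grp <- rep(c("a", "b"), each = 8)
  expect_equal(baseline_tests(vals, grp, type = "nominal")$p_value, 1)

  # 3/13 vs 13/3 gender split: exact hypergeometric enumeration oracle
  vals2 <- factor(c(rep("f", 3), rep("m", 13), rep("f", 13), rep("m", 3)))
  grp2 <- rep(c("M1_ICA", "M1"), each = 16)
  ft <- baseline_tests(vals2, grp2, type = "nominal")
  expect_equal(ft$test, "fisher_exact")
  expect_lt(ft$p_value, 0.01)
  probs <- dhyper(0:16, 16, 16, 16)
  p_enum <- sum(probs[probs <= dhyper(3, 16, 16, 16) * (1 + 1e-7)])
  expect_equal(ft$p_value, p_enum, tolerance = 1e-9)

  # Mann-Whitney on fully separated triplets: exact two-sided p = 0.1
  mw <- baseline_tests(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3),
                       type = "interval_nonnormal")
  expect_equal(mw$test, "mann_whitney_u")
  expect_equal(mw$p_value, 0.1)

  # t-test route
  set.seed(35)
  tt <- baseline_tests(c(rnorm(20), rnorm(20, 3)),
                       rep(c("a", "b"), each = 20),
                       type = "interval_normal")
  expect_equal(tt$test, "t")
  expect_lt(tt$p_value, 0.001)
})

test_that("stats report stacks parameters and writes JSON", {
  set.seed(36)
  n_sub <- 12
  tab <- data.frame(
    subject_id = rep(paste0("s", 1:n_sub), each = 2),
    group = rep(rep(c("M1", "M1_ICA"), each = n_sub / 2), each = 2),
    voi = rep(c("dwi_lesion", "tar"), times = n_sub))
  for (p in c("adc_median", "tmax_median", "cbf_median", "cbv_median",
              "mtt_median"))
    tab[[p]] <- abs(rnorm(2 * n_sub, 10, 2))
  rep_ <- stats_report(tab)
  expect_equal(nrow(rep_$effects), 15)   # 5 parameters x 3 factors
  expect_true(all(rep_$effects$partial_eta_sq >= 0 &
                    rep_$effects$partial_eta_sq <= 1))
  expect_false(is.null(rep_$pillai))
  path <- withr::local_tempfile(fileext = ".json")
  write_stats_report(rep_, path)
  back <- jsonlite::read_json(path)
  expect_equal(length(back$effects), 15)
  ft <- format_effect_table(rep_)
  expect_equal(nrow(ft), 5)
  expect_match(ft$group[1], "eta2")
})
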