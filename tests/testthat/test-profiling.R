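test_that("community profiles report counts, percentages and original-scale summaries", {
  co <- tiny_cohort()
  part <- c(1, 1, 1, 2, 2, 2)               # members 1-3: IBS, IBS, HC
  prof <- community_profiles(co, part)
  expect_equal(prof$n, c(3, 3))
  expect_equal(prof$pct_ibs[1], 66.7, tolerance = 0.05)
  expect_equal(prof$n_ibs + prof$n_hc, prof$n)
  expect_equal(sum(prof$n), nrow(co))
  # IBS-SSS summarized over IBS members only
  expect_equal(prof$sss_mean[1], mean(c(210, 180)))
  expect_equal(prof$rbans_mean[1], mean(c(101, 95, 99)))

  # printed composition: 15 IBS / 8 HC -> 65.2% IBS
  expect_equal(round(100 * 15 / 23, 1), 65.2)

  # size-1 community: SD absent, not zero
  prof1 <- community_profiles(co, c(1, 1, 1, 1, 1, 2))
  expect_true(is.na(prof1$age_sd[2]))
})

test_that("feature mean z-scores are zero for the whole-cohort community and size-balance to zero", {
  co <- standardize_features(impute_missing(generate_cohort(ibs_cohort_spec(seed = 41))))
  mz_all <- community_feature_z(co, rep(1, nrow(co)))
  expect_lt(max(abs(mz_all$mean_z)), 1e-10)

  part <- planted_partition(co)
  mz <- community_feature_z(co, part)
  sizes <- as.integer(table(part))
  balance <- mz |>
    dplyr::group_by(feature) |>
    dplyr::summarise(w = sum(mean_z * sizes[community]) / sum(sizes))
  expect_lt(max(abs(balance$w)), 1e-10)
})

test_that("omnibus tests combine Kruskal-Wallis with eta-squared and chi-square", {
  # closed-form effect size
  expect_equal(psntools:::kw_eta_squared(7, 4, 78), 4 / 74)
  expect_warning(e0 <- psntools:::kw_eta_squared(1, 4, 78), "clamped")
  expect_equal(e0, 0)

  co <- generate_cohort(ibs_cohort_spec(seed = 43))
  part <- planted_partition(co)
  out <- omnibus_tests(co, part)
  expect_setequal(out$variable, c("age", "ibs_sss", "rbans_total", "diagnosis"))
  kw <- out[out$test == "kruskal_wallis", ]
  expect_true(all(kw$eta_sq >= 0 & kw$eta_sq <= 1))
  # eta^2 is consistent with the reported H, k and n
  age <- kw[kw$variable == "age", ]
  expect_equal(age$eta_sq, (age$statistic - 4 + 1) / (78 - 4))
  # the preset's age separation (community 1 oldest) is detectable
  expect_lt(age$p_value, 0.01)

  cs <- out[out$test == "chi_square", ]
  expect_equal(cs$df, 3L)
  tab <- contingency_table(part, co$diagnosis)
  expect_equal(cs$statistic, chisq_oracle(tab), tolerance = 1e-10)
})

test_that("chi-square on the printed composition is non-significant", {
  tab <- matrix(c(15, 8, 9, 3, 10, 13, 15, 5), ncol = 2, byrow = TRUE)
  x2 <- chisq_oracle(tab)
  expect_equal(x2, 5.77, tolerance = 0.005)
  p <- stats::pchisq(x2, df = 3, lower.tail = FALSE)
  expect_equal(round(p, 2), 0.12)
  expect_gt(p, 0.05)
})

test_that("post hoc pairwise comparisons use exact rank-sum tests with a Bonferroni cap", {
  co <- generate_cohort(ibs_cohort_spec(seed = 44))
  out <- posthoc_pairwise(co, planted_partition(co), "age")
  expect_equal(nrow(out), choose(4, 2))
  expect_true(all(out$p_bonferroni <= 1))
  expect_true(all(out$p_bonferroni >= out$p_value))
  expect_equal(out$p_bonferroni, pmin(1, out$p_value * 6))

  # {1,2} vs {3,4}: U = 0, exact two-sided p = 1/3
  co4 <- tiny_cohort()[1:4, ] |> as_cohort()
  co4$age <- c(1, 2, 3, 4)
  pp <- posthoc_pairwise(co4, c(1, 1, 2, 2), "age")
  expect_equal(pp$statistic_u, 0)
  expect_equal(pp$p_value, 1 / 3)
})

test_that("distinguishing features surface planted shifts with category tags", {
  spec <- ibs_cohort_spec(effect_size = 0)
  for (s in 1:3) {
    co <- generate_cohort(spec, seed = s)
    pl <- planted_partition(co)
    co$CC_Posterior[pl == 2] <- co$CC_Posterior[pl == 2] + 2
    out <- distinguishing_features(co, pl, n_top = 3)
    up2 <- out[out$community == 2 & out$direction == "elevated", ]
    expect_true("CC_Posterior" %in% up2$feature)
    expect_equal(nrow(out), 4 * 6)
  }

  co <- generate_cohort(ibs_cohort_spec(seed = 4))
  out <- distinguishing_features(co, planted_partition(co), n_top = 3)
  expect_true(all(out$direction %in% c("elevated", "reduced")))
  expect_true(all(out$category %in% c("morphometric", "cognitive")))
  # elevated ranks decrease in mean z, reduced ranks increase
  for (cc in unique(out$community)) {
    up <- out[out$community == cc & out$direction == "elevated", ]
    dn <- out[out$community == cc & out$direction == "reduced", ]
    expect_true(all(diff(up$mean_z) <= 1e-12))
    expect_true(all(diff(dn$mean_z) >= -1e-12))
    expect_true(min(up$mean_z) >= max(dn$mean_z))
  }
  expect_error(distinguishing_features(co, planted_partition(co), n_top = 30),
               "2 \\* n_top")
})
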