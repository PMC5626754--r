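# Split-plot ANOVA engine, Fisher LSD, Cohen's d, full analysis bundle.

anova_row <- function(an, effect) {
  d <- as.data.frame(an)
  d[d$effect == effect, ]
}

test_that("mixed ANOVA matches the brute-force SS oracle on random designs", {
  set.seed(50)
  for (r in 1:25) {
    npg <- sample(2:6, 3, replace = TRUE)
    dat <- random_split_plot_data(n_per_group = npg,
                                  n_region = sample(2:3, 1),
                                  n_component = sample(2:4, 1))
    an <- mixed_anova(dat)
    or <- oracle_split_plot(dat)
    for (eff in c("group", "region", "component", "region:component")) {
      key <- if (grepl(":", eff)) "region:component" else eff
      row <- anova_row(an, eff)
      expect_equal(row$F, or[[key]]$F, tolerance = 1e-8)
      expect_equal(c(row$df, anova_row(an, if (eff == "group")
        "subjects(group)" else paste0(key, ":subjects(group)"))$df),
        c(or[[key]]$df[1], or[[key]]$df[2]), ignore_attr = TRUE)
    }
    for (eff in c("region", "component", "region:component")) {
      row <- anova_row(an, paste0("group:", eff))
      expect_equal(row$F, or[[paste0("group:", eff)]]$F, tolerance = 1e-8)
    }
  }
})

test_that("single-within-cell model reduces to the classical one-way ANOVA", {
  set.seed(51)
  x <- rnorm(12)
  g <- rep(c("a", "b", "c"), c(5, 4, 3))
  dat <- data.frame(subject_id = sprintf("S%02d", 1:12), group = g, amplitude = x)
  an <- mixed_anova(dat, within = character(0))
  or <- oracle_oneway_F(x, g)
  row <- anova_row(an, "group")
  expect_equal(row$F, or$F, tolerance = 1e-12)
  expect_equal(row$df, or$df1, ignore_attr = TRUE)
  expect_equal(row$p, or$p, tolerance = 1e-12)
})

test_that("group F is exactly 0 when group means are literally identical", {
  # subject offsets form the same set in every group, so group means are
  # equal by construction while subjects still vary
  dat <- expand.grid(subject_id = sprintf("S%02d", 1:9),
                     region = c("R1", "R2"), component = c("C1", "C2"),
                     stringsAsFactors = FALSE)
  dat$group <- rep(c("a", "b", "c"), each = 3)[match(dat$subject_id,
                                                     sprintf("S%02d", 1:9))]
  set.seed(52)
  cellfx <- rnorm(4)
  offsets <- rep(c(-1, 0, 1), 3) # subjects S01..S09 in group blocks a,a,a,b..
  dat$amplitude <- cellfx[as.integer(interaction(dat$region, dat$component))] +
    offsets[match(dat$subject_id, sprintf("S%02d", 1:9))]
  an <- mixed_anova(dat)
  g <- anova_row(an, "group")
  expect_equal(g$ss, 0, tolerance = 1e-20)
  expect_equal(g$F, 0, tolerance = 1e-20)
  expect_gt(anova_row(an, "subjects(group)")$ss, 0)
})

test_that("degrees of freedom follow the split-plot structure", {
  # 3 groups, 40 subjects -> N - k = 37; 2 regions x 4 components
  set.seed(53)
  dat <- random_split_plot_data(n_per_group = c(14, 18, 8))
  an <- mixed_anova(dat)
  expect_identical(anova_row(an, "group")$df, 2L)
  expect_identical(anova_row(an, "subjects(group)")$df, 37L)
  rc <- anova_row(an, "region:component")
  expect_identical(rc$df, 3L)
  expect_identical(anova_row(an, "region:component:subjects(group)")$df, 111L)
})

test_that("ANOVA rejects malformed designs", {
  set.seed(54)
  dat <- random_split_plot_data()
  expect_error(mixed_anova(dat[-1, ]), "exactly one observation")
  one <- dat[dat$group == "A", ]
  expect_error(mixed_anova(one), ">= 2 levels")
  single <- dat[dat$group != "A" | dat$subject_id == "S01", ]
  expect_error(mixed_anova(single), ">= 2 subjects")
})

test_that("F, p and d are invariant to shift and positive scaling", {
  set.seed(55)
  dat <- random_split_plot_data()
  an1 <- as.data.frame(mixed_anova(dat))
  dat2 <- dat; dat2$amplitude <- 5 + 3 * dat$amplitude
  an2 <- as.data.frame(mixed_anova(dat2))
  expect_equal(an1$F, an2$F, tolerance = 1e-10)
  expect_equal(an1$p, an2$p, tolerance = 1e-10)
  x <- rnorm(10); y <- rnorm(12)
  expect_equal(cohens_d(x, y), cohens_d(5 + 3 * x, 5 + 3 * y), tolerance = 1e-12)
})

test_that("Fisher LSD reproduces hand-computed values", {
  # integer fixture, n_i = n_j = 3: means 2 and 5; within SS = 2 + 2 = 4,
  # error df = 4, MSe = 1 -> t = 3 / sqrt(1 * (1/3 + 1/3)) = 3 / sqrt(2/3)
  x <- c(1, 2, 3, 4, 5, 6)
  g <- rep(c("lo", "hi"), each = 3)
  out <- fisher_lsd(x, g)
  expect_identical(nrow(out), 1L)
  expect_equal(out$t, 3 / sqrt(2 / 3), tolerance = 1e-12) # group_i = "hi"
  expect_identical(out$df, 4L)
  expect_equal(out$p, 2 * pt(3 / sqrt(2 / 3), 4, lower.tail = FALSE),
               tolerance = 1e-12)
  # identical group means -> t = 0, p = 1
  out2 <- fisher_lsd(c(1, 2, 1, 2), rep(c("a", "b"), each = 2))
  expect_equal(out2$t, 0)
  expect_equal(out2$p, 1)
  # three groups -> 3 pairwise rows
  out3 <- fisher_lsd(rnorm(9), rep(c("a", "b", "c"), 3))
  expect_identical(nrow(out3), 3L)
})

test_that("Cohen's d basics and Monte-Carlo recovery", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(cohens_d(c(0, 0), c(1, 1)), "pooled")
  expect_error(cohens_d(1, c(1, 2)), "n >= 2")
  set.seed(56)
  d <- replicate(2000, cohens_d(rnorm(14, 0.9, 1), rnorm(18, 0, 1)))
  expect_lt(abs(mean(d) - 0.9), 0.05)
})

test_that("full analysis bundle has the expected structure and gating", {
  f0 <- fake_features()
  res <- run_group_analysis(f0)
  expect_s3_class(res, "ffr_results")
  expect_identical(anova_row(res$global, "region:component")$df, 3L)
  expect_named(res$per_feature,
               c("consonant_f0", "consonant_mean_h", "vowel_f0", "vowel_f1",
                 "vowel_non_f1"))
  # consonant model: 2 components -> component df 1; vowel: 3 -> df 2
  expect_identical(anova_row(res$consonant, "component")$df, 1L)
  expect_identical(anova_row(res$vowel, "component")$df, 2L)
  # strong vowel F1 shift is detected and gates its post-hoc table
  f1 <- fake_features(f1_shift = c(0.4, 0, 0.4), seed = 3)
  res1 <- run_group_analysis(f1)
  expect_lt(anova_row(res1$per_feature$vowel_f1, "group")$p, 0.05)
  expect_true("vowel_f1" %in% names(res1$posthoc))
  expect_identical(nrow(res1$posthoc$vowel_f1), 3L)
  expect_true(all(c("t", "p", "cohens_d") %in% names(res1$posthoc$vowel_f1)))
  # posthoc = "always" emits a table per model
  res2 <- run_group_analysis(f0, posthoc = "always")
  expect_true(all(c("global", "vowel_f1") %in% names(res2$posthoc)))
  # single group errors
  expect_error(run_group_analysis(f0[f0$group == "g1", ]), ">= 2 groups")
})

test_that("results bundle serializes to JSON", {
  res <- run_group_analysis(fake_features())
  js <- results_to_json(res)
  doc <- jsonlite::fromJSON(js)
  expect_true(all(c("global", "consonant", "vowel", "per_feature") %in% names(doc)))
  expect_true("F" %in% names(doc$global))
})

test_that("LSD on the mixed model group effect uses the subject stratum", {
  set.seed(57)
  dat <- random_split_plot_data(n_per_group = c(5, 5, 5))
  an <- mixed_anova(dat)
  lsd <- ffrpipe:::lsd_for_group_effect(an)
  # independent check: one-way LSD on subject means must agree
  m <- tapply(dat$amplitude, dat$subject_id, mean)
  g <- factor(tapply(as.character(dat$group), dat$subject_id, unique))
  ref <- fisher_lsd(as.numeric(m), g)
  expect_equal(lsd$t, ref$t, tolerance = 1e-10)
  expect_equal(lsd$p, ref$p, tolerance = 1e-10)
})
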