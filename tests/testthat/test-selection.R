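test_that("difference profiles compute signed differences and direction agreement", {
  panel <- group_panel(c(0.9, 0.5, 0.3), c(0.1, 0.1, 0.3), c(0.2, 0.9, 0.3))
  prof <- difference_profiles(panel)
  expect_equal(prof$d_we, c(0.8, 0.4, 0.0))
  expect_equal(prof$d_wa, c(0.7, -0.4, 0.0))
  expect_equal(prof$same_direction, c(TRUE, FALSE, FALSE))  # zero has no sign
  expect_equal(prof$mean_abs_diff, c(0.75, NA, NA))
  expect_equal(prof$category, c("HIGHEST", "NONE", "NONE"))
})

test_that("missing group frequencies flag the profile unusable", {
  panel <- group_panel(c(0.9, NA), c(0.1, 0.2), c(0.2, 0.3))
  expect_warning(prof <- difference_profiles(panel), "unusable")
  expect_false(prof$usable[2])
  expect_equal(prof$category[2], "NONE")
})

test_that("category boundaries follow the closed-lower / open-upper convention", {
  expect_equal(categorize(0.75, 0.75), "HIGHEST")
  expect_equal(categorize(0.70, 0.70), "HIGHEST")
  expect_equal(categorize(0.60, 0.60), "HIGH")       # 0.60 exactly -> HIGH
  expect_equal(categorize(0.699, 0.699), "HIGH")
  expect_equal(categorize(0.40, 0.40), "MODERATE")
  expect_equal(categorize(0.399, 0.399), "NONE")
  # one comparison extreme, the other low, opposite directions
  expect_equal(categorize(0.72, -0.35), "HIGHEST_LOW")
  expect_equal(categorize(-0.72, 0.1), "HIGHEST_LOW")
  # same-direction categories take precedence for same-direction SNPs
  expect_equal(categorize(0.72, 0.35), "MODERATE")   # mean 0.535
  expect_equal(categorize(0.70, 0.05), "HIGHEST_LOW")# mean 0.375, falls through
})

test_that("categorize matches a scalar decision-list oracle on a dense grid", {
  d <- seq(-1, 1, by = 0.01)
  grid <- expand.grid(d_we = d, d_wa = d)
  got <- categorize(grid$d_we, grid$d_wa)
  want <- mapply(categorize_oracle, grid$d_we, grid$d_wa)
  expect_identical(got, unname(want))
})

test_that("category assignment is invariant under reference-allele relabeling", {
  set.seed(11)
  fw <- runif(500); fe <- runif(500); fa <- runif(500)
  cat1 <- difference_profiles(group_panel(fw, fe, fa))$category
  cat2 <- difference_profiles(group_panel(1 - fw, 1 - fe, 1 - fa))$category
  expect_identical(cat1, cat2)
})

test_that("select_candidates recovers constructed per-category counts", {
  # 5 HIGHEST, 3 HIGH, 2 MODERATE, 4 HIGHEST_LOW, 3 NONE by construction
  fw <- c(rep(0.90, 5), rep(0.80, 3), rep(0.70, 2), rep(0.85, 4), rep(0.50, 3))
  fe <- c(rep(0.10, 5), rep(0.15, 3), rep(0.25, 2), rep(0.10, 4), rep(0.45, 3))
  fa <- c(rep(0.15, 5), rep(0.15, 3), rep(0.25, 2), rep(0.95, 4), rep(0.55, 3))
  sel <- select_candidates(group_panel(fw, fe, fa))
  expect_equal(attr(sel, "category_counts"),
               c(HIGHEST = 5L, HIGH = 3L, MODERATE = 2L, HIGHEST_LOW = 4L))
  expect_true(all(sel$category != "NONE"))
  # undifferentiated panel selects nothing
  empty <- select_candidates(group_panel(c(0.5, 0.4), c(0.5, 0.42), c(0.5, 0.41)))
  expect_equal(nrow(empty), 0)
})

test_that("category thresholds divide the subgroup alpha by the SNP count", {
  th <- category_thresholds(c(HIGHEST = 38, HIGH = 266, MODERATE = 2883,
                              HIGHEST_LOW = 774))
  tab <- th$table
  expect_equal(tab$signif_3[tab$category == "HIGHEST"], 3.29e-4)
  expect_equal(tab$signif_3[tab$category == "HIGH"], 4.70e-5)
  expect_equal(tab$signif_3[tab$category == "MODERATE"], 4.34e-6)
  expect_equal(tab$signif_3[tab$category == "HIGHEST_LOW"], 1.61e-5)
  # thresholds spend exactly the study alpha: sum over categories of n x t
  expect_equal(sum(tab$threshold * tab$n_snps), 0.05)
  expect_equal(category_thresholds(c(HIGHEST = 1))$table$threshold, 0.0125)
  empty <- category_thresholds(c(HIGHEST = 0, HIGH = 10))
  expect_true(is.na(empty$table$threshold[empty$table$category == "HIGHEST"]))
  expect_error(category_thresholds(c(HIGHEST = -1)), "non-negative")
})
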