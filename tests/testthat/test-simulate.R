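test_that("cohort marginals reproduce the configured MoCA moments", {
  cfg <- sim_config(seed = 11, n_train = 9000, n_val = 1000)
  cohort <- generate_cohort(cfg)
  expect_equal(nrow(cohort), 10000L)
  se <- sd(cohort$moca) / sqrt(nrow(cohort))
  expect_lt(abs(mean(cohort$moca) - 24.13), 3 * se)
  expect_lt(abs(sd(cohort$moca) - 4.93), 0.2)
})

test_that("all generated scores respect catalogue ranges", {
  cat <- score_catalog()
  cohort <- generate_cohort(sim_config(seed = 3, n_train = 400, n_val = 100))
  for (i in seq_len(nrow(cat))) {
    x <- cohort[[cat$score[i]]]
    expect_true(all(x >= cat$range_min[i] & x <= cat$range_max[i]),
                label = paste(cat$score[i], "within range"))
  }
})

test_that("zero-sd configuration gives exactly the mean for every patient", {
  sp <- default_score_params()
  sp$sd <- 0
  cfg <- sim_config(seed = 5, n_train = 5, n_val = 5, score_params = sp,
                    age_sd = 0)
  cohort <- generate_cohort(cfg)
  expect_true(all(cohort$moca == 24.13))
  expect_true(all(cohort$had_d == 4.54))
  expect_true(all(cohort$age == 65.44))
})

test_that("cohort generation is bit-reproducible and names missing params", {
  cfg <- quick_sim(seed = 8)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  bad <- cfg
  bad$score_params <- bad$score_params[bad$score_params$score != "ist", ]
  expect_error(generate_cohort(bad), "ist")
})

test_that("pseudorandomized split balances main scores within tolerance", {
  cohort <- generate_cohort(sim_config(seed = 2))
  split <- split_cohort(cohort, 187, 50, seed = 4, tolerance = 0.1)
  expect_equal(sum(split$role == "train"), 187L)
  expect_equal(sum(split$role == "validation"), 50L)
  bal <- attr(split, "balance")
  expect_true(bal$converged)
  expect_lte(bal$max_smd, 0.1)
  # recompute the SMDs independently
  for (sc in main_scores()) {
    a <- split[[sc]][split$role == "train"]
    b <- split[[sc]][split$role == "validation"]
    smd <- abs(mean(a) - mean(b)) / sqrt((var(a) + var(b)) / 2)
    expect_lte(smd, 0.1 + 1e-12)
  }
})

test_that("infinite tolerance accepts the first split; identical patients trivially balance", {
  cohort <- generate_cohort(quick_sim(seed = 9))
  s <- split_cohort(cohort, 30, 20, seed = 1, tolerance = Inf)
  expect_equal(attr(s, "balance")$attempts, 1L)
  expect_error(split_cohort(cohort, 10, 10, seed = 1), "must equal")

  sp <- default_score_params(); sp$sd <- 0
  flat <- generate_cohort(sim_config(seed = 1, n_train = 12, n_val = 8,
                                     score_params = sp))
  s0 <- split_cohort(flat, 12, 8, seed = 1, tolerance = 0)
  expect_equal(attr(s0, "balance")$max_smd, 0)
  expect_true(attr(s0, "balance")$converged)
})

test_that("unreachable tolerance warns and returns the best split found", {
  cohort <- generate_cohort(quick_sim(seed = 10))
  expect_warning(
    s <- split_cohort(cohort, 30, 20, seed = 2, tolerance = 1e-8,
                      max_attempts = 5),
    "tolerance"
  )
  expect_false(attr(s, "balance")$converged)
  expect_equal(sum(s$role == "validation"), 20L)
})

test_that("recipe match is Jaccard similarity with binary validation", {
  r <- c(rep(1, 4), rep(0, 13))
  expect_equal(recipe_match(r, r), 1.0)
  disj <- c(rep(0, 4), rep(1, 4), rep(0, 9))
  expect_equal(recipe_match(disj, r), 0.0)
  f <- c(1, 1, rep(0, 15))
  expect_equal(recipe_match(f, r), 0.5)  # 2 of 4 recipe bits, no extras
  expect_equal(recipe_match(rep(0, 17), rep(0, 17)), 0)
  expect_error(recipe_match(c(rep(1, 16), 0.5), r), "binary")
  expect_error(recipe_match(rep(1, 16), r), "length 17")
})

test_that("planted recipes are nonempty, sized like reported combinations, and seeded", {
  rec <- plant_recipes(seed = 123)
  expect_equal(rec$feature, morpho_features()$feature)
  for (d in c("motor", "cognitive", "emotional")) {
    v <- recipe_vector(rec, d)
    expect_gte(sum(v), 3)
    expect_lte(sum(v), 8)
    expect_gte(sum(v[1:9]), 2)   # inputs
    expect_gte(sum(v[10:17]), 1) # methods
  }
  expect_identical(rec, plant_recipes(seed = 123))
})

test_that("submission accuracy follows the match-to-correlation law", {
  # with r_base == r_max the law is flat: every submission hits r = 0.8
  # regardless of features, so R^2 ~= 0.64 on a large validation set
  cfg <- sim_config(seed = 21, n_train = 10, n_val = 5000,
                    r_base = 0.8, r_max = 0.8, n_teams = 2,
                    n_submissions = 3)
  cohort <- generate_cohort(cfg)
  cohort <- split_cohort(cohort, 10, 5000, seed = 1, tolerance = Inf)
  subs <- generate_submissions(cohort, plant_recipes(1), cfg)
  truth <- cohort[cohort$role == "validation", ]
  mc_se <- 2 * 0.8 * (1 - 0.64) / sqrt(5000)
  for (sid in subs$features$submission_id) {
    p <- subs$predictions[subs$predictions$submission_id == sid &
                            subs$predictions$score == "ist", ]
    r2 <- cor(p$predicted, truth$ist[match(p$patient_id,
                                           truth$patient_id)])^2
    expect_lt(abs(r2 - 0.64), 3 * mc_se)
  }
})

test_that("noiseless limit r = 1 reproduces the truth exactly", {
  cfg <- sim_config(seed = 22, n_train = 5, n_val = 200,
                    r_base = 1, r_max = 1, n_teams = 1, n_submissions = 1)
  cohort <- split_cohort(generate_cohort(cfg), 5, 200, seed = 1,
                         tolerance = Inf)
  subs <- generate_submissions(cohort, plant_recipes(1), cfg)
  truth <- cohort[cohort$role == "validation", ]
  p <- subs$predictions[subs$predictions$score == "ist", ]
  expect_equal(p$predicted, truth$ist[match(p$patient_id,
                                            truth$patient_id)],
               tolerance = 1e-10)
})

test_that("expected accuracy increases with recipe match", {
  cfg <- sim_config(seed = 30, n_train = 10, n_val = 1000,
                    n_teams = 15, n_submissions = 24)
  cohort <- split_cohort(generate_cohort(cfg), 10, 1000, seed = 1,
                         tolerance = Inf)
  recipes <- plant_recipes(30)
  subs <- generate_submissions(cohort, recipes, cfg)
  truth <- cohort[cohort$role == "validation", ]
  rec <- recipe_vector(recipes, "cognitive")
  fm <- build_feature_matrix(subs)
  match <- apply(fm, 1, recipe_match, recipe = rec)
  r2 <- vapply(rownames(fm), function(sid) {
    p <- subs$predictions[subs$predictions$submission_id == sid &
                            subs$predictions$score == "moca", ]
    cor(p$predicted, truth$moca[match(p$patient_id, truth$patient_id)])^2
  }, numeric(1))
  expect_gt(cor(match, r2, method = "spearman"), 0.7)
})

test_that("submission generation is seeded and validates its inputs", {
  cfg <- quick_sim(seed = 40, n_teams = 3, n_submissions = 5)
  cohort <- split_cohort(generate_cohort(cfg), 30, 20, seed = 1,
                         tolerance = Inf)
  s1 <- generate_submissions(cohort, plant_recipes(1), cfg)
  s2 <- generate_submissions(cohort, plant_recipes(1), cfg)
  expect_identical(s1$features, s2$features)
  expect_identical(s1$predictions, s2$predictions)
  expect_equal(nrow(s1$features), 5L)
  expect_equal(length(unique(s1$features$team_id)), 3L)
  # feature sampling ranges: 0-8 inputs, 1-5 methods
  fm <- build_feature_matrix(s1)
  expect_true(all(rowSums(fm[, 1:9, drop = FALSE]) <= 8))
  expect_true(all(rowSums(fm[, 10:17, drop = FALSE]) >= 1))
  expect_true(all(rowSums(fm[, 10:17, drop = FALSE]) <= 5))
  noval <- cohort; noval$role <- "train"
  expect_error(generate_submissions(noval, plant_recipes(1), cfg),
               "validation")
})
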