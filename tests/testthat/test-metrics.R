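test_that("worked metric examples evaluate exactly", {
  expect_equal(as.numeric(score_r2(c(1, 2, 3, 4), c(1, 2, 2, 4))),
               4.5^2 / (5 * 4.75), tolerance = 1e-12)
  expect_equal(score_mse(c(0, 0), c(1, 3)), 5.0)
  expect_equal(score_mae(c(0, 0), c(1, 3)), 2.0)
  expect_equal(score_auc(c(1, 2, 3, 4), c(TRUE, FALSE, TRUE, FALSE),
                         "low_is_poor"), 0.75)
})

test_that("R2 is affine-invariant, identity gives 1, constants degrade to 0", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(as.numeric(score_r2(x, x)), 1.0)
  expect_equal(as.numeric(score_r2(2 * x + 7, x)), 1.0)
  r <- score_r2(rep(1, 5), c(1, 2, 3, 4, 5))
  expect_equal(as.numeric(r), 0)
  expect_true(attr(r, "degenerate"))
})

test_that("MSE/MAE translation invariance and scaling; MAE <= sqrt(MSE)", {
  set.seed(1)
  for (i in 1:20) {
    p <- rnorm(15); t <- rnorm(15); c0 <- rnorm(1); s <- runif(1, 0.5, 3)
    expect_equal(score_mse(p + c0, t + c0), score_mse(p, t))
    expect_equal(score_mae(p + c0, t + c0), score_mae(p, t))
    expect_equal(score_mse(s * p, s * t), s^2 * score_mse(p, t))
    expect_equal(score_mae(s * p, s * t), s * score_mae(p, t))
    expect_lte(score_mae(p, t), sqrt(score_mse(p, t)) + 1e-12)
  }
})

test_that("metrics agree with brute-force oracles on random pairs", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    p <- rnorm(n); t <- rnorm(n)
    expect_equal(as.numeric(score_r2(p, t)), oracle_r2(p, t),
                 tolerance = 1e-10)
    expect_equal(score_mse(p, t), oracle_mse(p, t), tolerance = 1e-10)
    expect_equal(score_mae(p, t), oracle_mae(p, t), tolerance = 1e-10)
    poor <- as.logical(rbinom(n, 1, 0.4))
    if (any(poor) && any(!poor)) {
      pr <- round(p, 1)  # induce ties
      dirn <- sample(c("low_is_poor", "high_is_poor"), 1)
      expect_equal(score_auc(pr, poor, dirn), oracle_auc(pr, poor, dirn),
                   tolerance = 1e-10)
    }
  }
})

test_that("AUC properties: perfect separation, all ties, label flip, pROC agreement", {
  expect_equal(score_auc(c(1, 2, 10, 11), c(TRUE, TRUE, FALSE, FALSE),
                         "low_is_poor"), 1.0)
  expect_equal(score_auc(rep(5, 6), rep(c(TRUE, FALSE), 3),
                         "low_is_poor"), 0.5)
  set.seed(7)
  p <- rnorm(30); poor <- as.logical(rbinom(30, 1, 0.5))
  expect_equal(score_auc(p, poor, "high_is_poor"),
               1 - score_auc(p, !poor, "high_is_poor"))
  # rank formulation equals trapezoidal ROC integration on tie-free data
  skip_if_not_installed("pROC")
  roc <- pROC::roc(response = poor, predictor = p, quiet = TRUE,
                   levels = c(FALSE, TRUE), direction = "<")
  expect_equal(score_auc(p, poor, "high_is_poor"),
               as.numeric(pROC::auc(roc)), tolerance = 1e-10)
  expect_warning(a <- score_auc(p, rep(TRUE, 30), "high_is_poor"),
                 "one outcome class")
  expect_true(is.na(a))
})

test_that("evaluation fills all metrics and a noiseless submission is perfect", {
  cfg <- quick_sim(seed = 50)
  cohort <- split_cohort(generate_cohort(cfg), 30, 20, seed = 1,
                         tolerance = Inf)
  truth <- cohort[cohort$role == "validation", ]
  cat <- score_catalog()
  preds <- tidyr::pivot_longer(truth[, c("patient_id", cat$score)],
                               -"patient_id", names_to = "score",
                               values_to = "predicted")
  preds$submission_id <- "perfect"
  ev <- evaluate_submissions(preds, cohort)
  expect_equal(nrow(ev), 13L)
  expect_equal(ev$r2, rep(1, 13), tolerance = 1e-12)
  expect_true(all(ev$mse == 0))
  expect_true(all(ev$mae == 0))
  # AUC is attempted exactly for the thresholded tests and defined for
  # those with both outcome classes in this validation sample (FM total is
  # ceilinged far above its threshold, so it has no poor patients here)
  expect_true(all(ev$score[!is.na(ev$auc)] %in%
                    c("fm_total", "moca", "ist", "had_a", "had_d")))
  expect_setequal(ev$score[!is.na(ev$auc)],
                  c("moca", "ist", "had_a", "had_d"))
  expect_true(all(ev$auc[!is.na(ev$auc)] == 1))
  rk <- rank_submissions(ev)
  expect_equal(rk$mean_r2_main, 1)
})

test_that("predictions independent of truth score near zero mean R2", {
  cfg <- sim_config(seed = 51, n_train = 10, n_val = 2000)
  cohort <- split_cohort(generate_cohort(cfg), 10, 2000, seed = 1,
                         tolerance = Inf)
  truth <- cohort[cohort$role == "validation", ]
  cat <- score_catalog()
  shuffle <- sample(nrow(truth))  # fixed by the config seed
  preds <- purrr::map_dfr(cat$score, function(sc) {
    tibble::tibble(submission_id = "shuffled",
                   patient_id = truth$patient_id,
                   score = sc, predicted = truth[[sc]][shuffle])
  })
  ev <- evaluate_submissions(preds, cohort)
  expect_lt(rank_submissions(ev)$mean_r2_main, 0.02)
})

test_that("partial submissions average over the main scores present", {
  cfg <- quick_sim(seed = 52)
  cohort <- split_cohort(generate_cohort(cfg), 30, 20, seed = 1,
                         tolerance = Inf)
  truth <- cohort[cohort$role == "validation", ]
  main6 <- main_scores()
  preds <- purrr::map_dfr(main6, function(sc) {
    tibble::tibble(submission_id = "main_only",
                   patient_id = truth$patient_id,
                   score = sc, predicted = truth[[sc]] + rnorm(20))
  })
  ev <- evaluate_submissions(preds, cohort)
  expect_equal(nrow(ev), 6L)
  rk <- rank_submissions(ev)
  expect_equal(rk$n_main, 6L)
  expect_false(is.na(rk$mean_r2_main))
  # dropping one main score triggers the coverage warning
  ev5 <- ev[ev$score != "moca", ]
  expect_warning(rk5 <- rank_submissions(ev5), "main scores")
  expect_equal(rk5$n_main, 5L)
})

test_that("ranking is by mean R2, ties broken by MSE then id", {
  mk <- function(id, r2, mse) {
    tibble::tibble(submission_id = id, score = main_scores(),
                   n = 50, r2 = r2, degenerate = FALSE,
                   mse = mse, mae = sqrt(mse), auc = NA_real_)
  }
  rec <- dplyr::bind_rows(mk("teamB", 0.238, 10), mk("teamC", 0.182, 10),
                          mk("teamA", 0.311, 10))
  rk <- rank_submissions(rec)
  expect_equal(rk$submission_id, c("teamA", "teamB", "teamC"))
  expect_equal(rk$mean_r2_main, c(0.311, 0.238, 0.182))

  tie <- dplyr::bind_rows(mk("s2", 0.3, 5), mk("s1", 0.3, 9))
  expect_equal(rank_submissions(tie)$submission_id, c("s2", "s1"))
  tie2 <- dplyr::bind_rows(mk("s2", 0.3, 5), mk("s1", 0.3, 5))
  expect_equal(rank_submissions(tie2)$submission_id, c("s1", "s2"))
})
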