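#' Squared Pearson correlation between predictions and truth
#'
#' The primary ranking metric: the square of the Pearson correlation
#' coefficient (not the coefficient of determination - the two differ for
#' biased predictions; see the methods vignette). Constant predictions or
#' truth yield 0 with a `degenerate` attribute instead of an error, so
#' ranking never crashes on trivial submissions.
#'
#' @param pred,truth Numeric vectors of equal length (>= 3).
#' @return A number in `[0, 1]`; `attr(, "degenerate")` is `TRUE` when either
#'   vector is constant.
#' @examples
#' score_r2(c(1, 2, 3, 4), c(1, 2, 2, 4))
#' @export
score_r2 <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), length(pred) >= 3L)
  if (stats::sd(pred) == 0 || stats::sd(truth) == 0) {
    return(structure(0, degenerate = TRUE))
  }
  structure(stats::cor(pred, truth)^2, degenerate = FALSE)
}

#' Mean squared error
#'
#' @param pred,truth Numeric vectors of equal, nonzero length.
#' @return Mean of squared differences (squared score units).
#' @export
score_mse <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), length(pred) >= 1L)
  mean((pred - truth)^2)
}

#' Mean absolute error
#'
#' @param pred,truth Numeric vectors of equal, nonzero length.
#' @return Mean of absolute differences (score units).
#' @export
score_mae <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), length(pred) >= 1L)
  mean(abs(pred - truth))
}

#' Area under the ROC curve for poor-outcome discrimination
#'
#' Mann-Whitney formulation: the probability that a randomly chosen poor
#' case receives a more poor-leaning prediction than a randomly chosen good
#' case, ties counted 1/2. Predictions are oriented by `direction` before
#' ranking - for `low_is_poor` scores a *lower* prediction leans poor.
#'
#' @param pred Numeric predictions.
#' @param poor Logical (or 0/1) vector: is the true outcome poor?
#' @param direction `"low_is_poor"` or `"high_is_poor"`.
#' @return AUC in `[0, 1]`, or `NA` with a warning if only one class is
#'   present in the truth.
#' @examples
#' score_auc(c(1, 2, 3, 4), c(TRUE, FALSE, TRUE, FALSE), "low_is_poor")
#' @export
score_auc <- function(pred, poor, direction = c("low_is_poor", "high_is_poor")) {
  direction <- match.arg(direction)
  stopifnot(length(pred) == length(poor))
  poor <- as.logical(poor)
  n1 <- sum(poor); n0 <- sum(!poor)
  if (n1 == 0L || n0 == 0L) {
    warning("AUC undefined: only one outcome class present", call. = FALSE)
    return(NA_real_)
  }
  s <- if (direction == "low_is_poor") -pred else pred
  r <- rank(s)  # midranks handle ties as 1/2
  (sum(r[poor]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate submissions against validation truth
#'
#' Computes, for every submission and every score it predicts: squared
#' Pearson R2, MSE, MAE, and - for the five scores with clinical poor-outcome
#' thresholds - the AUC for discriminating truly poor from good outcomes.
#'
#' @param submissions A `submission_set` (see [generate_submissions()]) or a
#'   long predictions tibble (`submission_id`, `patient_id`, `score`,
#'   `predicted`).
#' @param truth A cohort tibble; if it has a `role` column, only
#'   `"validation"` rows are used as ground truth.
#' @param catalog A score catalogue.
#' @return A tibble with one row per submission x score: `submission_id`,
#'   `score`, `n`, `r2`, `degenerate`, `mse`, `mae`, `auc` (`NA` for
#'   unthresholded scores).
#' @export
evaluate_submissions <- function(submissions, truth,
                                 catalog = score_catalog()) {
  preds <- if (inherits(submissions, "submission_set")) {
    submissions$predictions
  } else {
    submissions
  }
  stopifnot(all(c("submission_id", "patient_id", "score", "predicted")
                %in% names(preds)))
  if ("role" %in% names(truth) && any(truth$role == "validation",
                                      na.rm = TRUE)) {
    truth <- truth[!is.na(truth$role) & truth$role == "validation", ]
  }
  unknown <- setdiff(unique(preds$score), catalog$score)
  if (length(unknown) > 0L) {
    stop("Predictions contain unknown scores: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  truth_long <- tidyr::pivot_longer(
    truth[, c("patient_id", intersect(catalog$score, names(truth)))],
    -"patient_id", names_to = "score", values_to = "truth"
  )
  joined <- dplyr::inner_join(preds, truth_long,
                              by = c("patient_id", "score"))
  if (nrow(joined) == 0L) {
    stop("No overlap between predicted and truth patients/scores",
         call. = FALSE)
  }

  eval_one <- function(df, sc) {
    row <- catalog[catalog$score == sc, ]
    r2 <- score_r2(df$predicted, df$truth)
    auc <- NA_real_
    if (!is.na(row$poor_threshold)) {
      poor <- classify_poor(sc, df$truth, catalog) == "poor"
      if (sum(poor) > 0L && sum(!poor) > 0L) {
        auc <- score_auc(df$predicted, poor, row$poor_direction)
      }
    }
    tibble::tibble(
      n = nrow(df),
      r2 = as.numeric(r2),
      degenerate = isTRUE(attr(r2, "degenerate")),
      mse = score_mse(df$predicted, df$truth),
      mae = score_mae(df$predicted, df$truth),
      auc = auc
    )
  }

  joined |>
    dplyr::group_by(.data$submission_id, .data$score) |>
    dplyr::group_modify(~ eval_one(.x, .y$score)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$submission_id,
                   match(.data$score, catalog$score))
}

#' Rank submissions by mean R2 over the main scores
#'
#' The primary leaderboard: submissions ordered by descending arithmetic
#' mean of R2 over the six main scores, ties broken by lower mean MSE over
#' the same scores, then by submission id. Submissions missing some main
#' scores are averaged over the main scores they did predict, with a warning
#' and `n_main` recording the coverage.
#'
#' @param records An evaluation tibble from [evaluate_submissions()].
#' @param catalog A score catalogue.
#' @return A tibble: `rank`, `submission_id`, `mean_r2_main`,
#'   `mean_mse_main`, `n_main`.
#' @export
rank_submissions <- function(records, catalog = score_catalog()) {
  stopifnot(nrow(records) > 0L)
  main <- main_scores(catalog)
  out <- records |>
    dplyr::filter(.data$score %in% main) |>
    dplyr::group_by(.data$submission_id) |>
    dplyr::summarise(
      mean_r2_main = mean(.data$r2),
      mean_mse_main = mean(.data$mse),
      n_main = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$mean_r2_main), .data$mean_mse_main,
                   .data$submission_id) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1L)
  if (any(out$n_main < length(main))) {
    warning("Some submissions predicted only ",
            min(out$n_main), "/", length(main),
            " main scores; their means cover the scores present",
            call. = FALSE)
  }
  out
}
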