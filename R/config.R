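#' Default marginal parameters for simulated outcome scores
#'
#' Means and standard deviations of the training-cohort score marginals the
#' synthetic generator reproduces. For FM total, MoCA, IST, HAD-A and HAD-D
#' these are the published training-cohort values of the stroke benchmark the
#' generator emulates; the FM motor subscale and the MoCA subscores have no
#' published marginals, so field-realistic one-year values are used (mild
#' residual impairment, ceiling-leaning subscores).
#'
#' @return A tibble with columns `score`, `mean`, `sd` covering all 13
#'   catalogue scores.
#' @export
default_score_params <- function() {
  tibble::tribble(
    ~score,              ~mean,  ~sd,
    "fm_total",          224.93, 30.43,
    "fm_motor",          92.5,   12.5,
    "moca",              24.13,  4.93,
    "moca_attention",    5.0,    1.2,
    "moca_visuospatial", 4.0,    1.2,
    "moca_denomination", 2.8,    0.5,
    "moca_language",     2.4,    0.8,
    "moca_abstraction",  1.6,    0.6,
    "moca_orientation",  5.7,    0.7,
    "moca_recall",       3.0,    1.5,
    "ist",               30.48,  6.41,
    "had_a",             6.07,   3.80,
    "had_d",             4.54,   3.98
  )
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic cohort and submission generator. The
#' defaults reproduce the study conditions of the benchmark the package
#' emulates: a 237-patient cohort pseudorandomized into 187 training and 50
#' validation patients, and 24 prediction submissions from 15 teams whose
#' per-score accuracy is a monotone function of how closely their declared
#' feature combination matches a planted per-domain "optimal recipe".
#'
#' The accuracy law is `r(match) = r_base + (r_max - r_base) * match^match_exponent`
#' where `match` is the Jaccard similarity between a submission's 17-bit
#' feature vector and the recipe of the score's domain, and `r` is the target
#' Pearson correlation between predictions and truth.
#'
#' @param seed Integer seed for cohort generation (stage seeds for splitting
#'   and submission generation are derived from it by small offsets).
#' @param n_train,n_val Cohort split sizes.
#' @param score_params Tibble (`score`, `mean`, `sd`) of marginal parameters
#'   covering every catalogue score.
#' @param age_mean,age_sd,sex_p Demographics: age marginal (years, truncated
#'   to 18-100) and probability of `sex == 1`.
#' @param n_teams,n_submissions Number of teams and total submissions
#'   (`n_submissions >= n_teams`; every team submits at least once).
#' @param r_max Maximum attainable prediction-truth correlation, in `[0, 1]`.
#' @param r_base Baseline correlation for a feature vector disjoint from the
#'   recipe, in `[0, r_max]`.
#' @param match_exponent Positive exponent shaping the match-to-accuracy
#'   curve; 1 (default) is linear.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 7, n_train = 40, n_val = 20)
#' @export
sim_config <- function(seed = 42L,
                       n_train = 187L,
                       n_val = 50L,
                       score_params = default_score_params(),
                       age_mean = 65.44, age_sd = 13.48, sex_p = 0.4,
                       n_teams = 15L,
                       n_submissions = 24L,
                       r_max = 0.8,
                       r_base = 0.2,
                       match_exponent = 1) {
  stopifnot(
    is.numeric(seed), length(seed) == 1L,
    n_train >= 1L, n_val >= 1L,
    is.data.frame(score_params),
    all(c("score", "mean", "sd") %in% names(score_params)),
    all(score_params$sd >= 0),
    n_teams >= 1L, n_submissions >= n_teams,
    r_base >= 0, r_base <= r_max, r_max <= 1,
    match_exponent > 0
  )
  structure(
    list(seed = as.integer(seed),
         n_train = as.integer(n_train), n_val = as.integer(n_val),
         score_params = tibble::as_tibble(score_params),
         age_mean = age_mean, age_sd = age_sd, sex_p = sex_p,
         n_teams = as.integer(n_teams),
         n_submissions = as.integer(n_submissions),
         r_max = r_max, r_base = r_base,
         match_exponent = match_exponent),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed", x$seed,
      "| cohort", x$n_train, "+", x$n_val,
      "| submissions", x$n_submissions, "from", x$n_teams, "teams",
      "| r in [", x$r_base, ",", x$r_max, "] exponent", x$match_exponent, "\n")
  invisible(x)
}
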