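#' @importFrom stats optim rnorm rbinom sd var cor setNames
NULL

# Parent (mu, sigma) of a truncated normal on [lo, hi] whose *truncated*
# mean/sd best match the targets (least squares). For scores far from their
# bounds this is essentially exact; for ceilinged marginals (e.g. a mean
# within one SD of the maximum) no truncated normal attains the printed
# moments and the closest member of the family is used instead.
match_truncnorm_params <- function(m, s, lo, hi) {
  if (m < lo || m > hi) {
    stop("Target mean ", m, " lies outside the range [", lo, ", ", hi, "]",
         call. = FALSE)
  }
  if (s == 0) return(c(mu = m, sigma = 0))
  obj <- function(p) {
    mu <- p[1]; sig <- exp(p[2])
    (truncnorm::etruncnorm(lo, hi, mu, sig) - m)^2 +
      (sqrt(truncnorm::vtruncnorm(lo, hi, mu, sig)) - s)^2
  }
  fit <- stats::optim(c(m, log(s)), obj,
                      control = list(reltol = 1e-14, maxit = 5000))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

draw_truncated_score <- function(n, m, s, lo, hi) {
  if (s == 0) return(rep(m, n))
  p <- match_truncnorm_params(m, s, lo, hi)
  truncnorm::rtruncnorm(n, a = lo, b = hi, mean = p["mu"], sd = p["sigma"])
}

#' Generate a synthetic patient cohort
#'
#' Draws `n_train + n_val` patients with age, sex, and all 13 catalogue
#' outcome scores. Each score is drawn from a truncated normal confined to
#' its valid range whose parameters are moment-matched so the simulated
#' marginal reproduces the configured mean and SD (exactly where feasible;
#' otherwise, for strongly ceilinged marginals, as closely as the family
#' allows). Generation is bit-reproducible given `config$seed`. Roles are
#' unassigned until [split_cohort()] is applied.
#'
#' @param config A [sim_config()].
#' @param catalog A score catalogue, see [score_catalog()].
#' @return A tibble with columns `patient_id`, `age`, `sex`, `role`
#'   (all `NA` at this stage) and one column per catalogue score.
#' @examples
#' cohort <- generate_cohort(sim_config(seed = 1, n_train = 20, n_val = 10))
#' @export
generate_cohort <- function(config, catalog = score_catalog()) {
  stopifnot(inherits(config, "sim_config"))
  missing <- setdiff(catalog$score, config$score_params$score)
  if (length(missing) > 0L) {
    stop("score_params is missing entries for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  set.seed(config$seed)
  n <- config$n_train + config$n_val
  out <- tibble::tibble(
    patient_id = sprintf("P%04d", seq_len(n)),
    age = draw_truncated_score(n, config$age_mean, config$age_sd, 18, 100),
    sex = stats::rbinom(n, 1L, config$sex_p),
    role = NA_character_
  )
  for (i in seq_len(nrow(catalog))) {
    sc <- catalog$score[i]
    pr <- config$score_params[config$score_params$score == sc, ]
    out[[sc]] <- draw_truncated_score(n, pr$mean, pr$sd,
                                      catalog$range_min[i],
                                      catalog$range_max[i])
  }
  out
}

max_main_smd <- function(cohort, val_idx, scores) {
  smd <- vapply(scores, function(sc) {
    x <- cohort[[sc]]
    a <- x[-val_idx]; b <- x[val_idx]
    sp <- sqrt((stats::var(a) + stats::var(b)) / 2)
    if (!is.finite(sp) || sp == 0) return(0)
    abs(mean(a) - mean(b)) / sp
  }, numeric(1))
  max(smd)
}

#' Pseudorandomize a cohort into training and validation roles
#'
#' Emulates pseudorandomization "to ensure comparable distribution of the
#' outcome scores": among up to `max_attempts` seeded random splits, the one
#' minimizing the maximum absolute standardized mean difference (SMD) over
#' the six main scores is kept; the search stops early once a split meets
#' `tolerance`. If no split meets the tolerance, the best split found is
#' returned with a warning and `attr(, "balance")$converged == FALSE`.
#'
#' @param cohort A cohort tibble from [generate_cohort()] (or read from CSV).
#' @param n_train,n_val Role counts; must sum to `nrow(cohort)`.
#' @param seed Integer seed for the split search.
#' @param tolerance Maximum tolerated SMD (standardized units); `Inf`
#'   accepts the first random split.
#' @param max_attempts Number of candidate splits to try (default 1000).
#' @param catalog A score catalogue.
#' @return The cohort with `role` filled (`"train"`/`"validation"`), with a
#'   `balance` attribute (list: `max_smd`, `attempts`, `converged`).
#' @export
split_cohort <- function(cohort, n_train = 187L, n_val = 50L, seed = 1L,
                         tolerance = 0.1, max_attempts = 1000L,
                         catalog = score_catalog()) {
  n <- nrow(cohort)
  if (n_train + n_val != n) {
    stop("n_train + n_val (", n_train + n_val,
         ") must equal the number of rows (", n, ")", call. = FALSE)
  }
  scores <- main_scores(catalog)
  set.seed(seed)
  best_idx <- NULL
  best_smd <- Inf
  attempts <- 0L
  for (k in seq_len(max_attempts)) {
    attempts <- k
    idx <- sample.int(n, n_val)
    smd <- max_main_smd(cohort, idx, scores)
    if (smd < best_smd) {
      best_smd <- smd
      best_idx <- idx
    }
    if (best_smd <= tolerance) break
  }
  converged <- best_smd <= tolerance
  if (!converged) {
    warning("No split reached SMD tolerance ", tolerance, " after ",
            max_attempts, " attempts; best attained ",
            signif(best_smd, 3), call. = FALSE)
  }
  cohort$role <- "train"
  cohort$role[best_idx] <- "validation"
  attr(cohort, "balance") <- list(max_smd = best_smd, attempts = attempts,
                                  converged = converged)
  cohort
}

check_binary17 <- function(x, what) {
  if (length(x) != n_features()) {
    stop(what, " must have length ", n_features(), call. = FALSE)
  }
  if (!all(x %in% c(0, 1))) {
    stop(what, " must be binary (0/1)", call. = FALSE)
  }
  as.numeric(x)
}

#' Jaccard match between a feature vector and a recipe
#'
#' Quantifies how closely a submission's declared 17-bit feature combination
#' matches an optimal recipe: the Jaccard similarity
#' `|features AND recipe| / |features OR recipe|`, defined as 0 when both
#' vectors are empty.
#'
#' @param features,recipe Binary vectors of length 17 in canonical feature
#'   order ([morpho_features()]).
#' @return A number in `[0, 1]`.
#' @examples
#' r <- c(rep(1, 4), rep(0, 13))
#' f <- c(1, 1, rep(0, 15))
#' recipe_match(f, r) # 2/4
#' @export
recipe_match <- function(features, recipe) {
  f <- check_binary17(features, "features")
  r <- check_binary17(recipe, "recipe")
  u <- sum(f + r > 0)
  if (u == 0) return(0)
  sum(f * r) / u
}

#' Plant per-domain optimal recipes
#'
#' Samples one 17-bit recipe per outcome domain: 2-5 inputs and 1-3 methods
#' drawn uniformly without replacement, giving recipes of 3-8 features,
#' the size range of optimal combinations reported for this kind of
#' benchmark. Used as the ground truth the synthetic accuracy law rewards.
#'
#' @param seed Integer seed.
#' @return A tibble in recipe-table layout: `feature` (17 canonical rows) and
#'   one 0/1 column per domain (`motor`, `cognitive`, `emotional`).
#' @export
plant_recipes <- function(seed = 42L) {
  set.seed(seed)
  feats <- feature_names()
  out <- tibble::tibble(feature = feats)
  for (dom in c("motor", "cognitive", "emotional")) {
    v <- numeric(n_features())
    n_in <- sample(2:5, 1L)
    n_me <- sample(1:3, 1L)
    v[sample.int(9L, n_in)] <- 1
    v[9L + sample.int(8L, n_me)] <- 1
    out[[dom]] <- v
  }
  out
}

#' Extract one domain's recipe vector from a recipe table
#'
#' @param recipes A recipe table (`feature` column plus domain columns), as
#'   returned by [plant_recipes()] or [aggregate_domain_recipes()].
#' @param domain Domain name.
#' @return Named binary vector of length 17 in canonical order.
#' @export
recipe_vector <- function(recipes, domain) {
  stopifnot(domain %in% names(recipes))
  v <- recipes[[domain]][match(feature_names(), recipes$feature)]
  stats::setNames(as.numeric(v), feature_names())
}

#' Hamming distance between two 17-bit feature vectors
#'
#' @param x,y Binary vectors of length 17.
#' @return Integer number of disagreeing features.
#' @export
feature_hamming <- function(x, y) {
  as.integer(sum(abs(check_binary17(x, "x") - check_binary17(y, "y"))))
}

sample_feature_vector <- function() {
  v <- numeric(n_features())
  n_in <- sample(0:8, 1L)
  n_me <- sample(1:5, 1L)
  if (n_in > 0) v[sample.int(9L, n_in)] <- 1
  v[9L + sample.int(8L, n_me)] <- 1
  v
}

#' Generate synthetic prediction submissions
#'
#' Each of `config$n_submissions` submissions (spread over `config$n_teams`
#' teams, every team contributing at least one) declares a random feature
#' combination - between none and eight inputs with one to five methods -
#' and predicts every catalogue score for every validation patient. The
#' target prediction-truth Pearson correlation for a score is
#' `r = r_base + (r_max - r_base) * match^match_exponent`, where `match` is
#' the Jaccard similarity between the submission's features and the recipe
#' of the score's domain. Predictions are `r * z(truth) + sqrt(1 - r^2) * noise`,
#' rescaled to the truth's mean/SD and clipped to the score range.
#'
#' @param cohort A cohort with roles assigned; only `role == "validation"`
#'   rows are predicted.
#' @param recipes A recipe table ([plant_recipes()]).
#' @param config A [sim_config()].
#' @param catalog A score catalogue.
#' @param seed Seed for feature sampling and prediction noise; defaults to
#'   `config$seed + 2`.
#' @return An object of class `submission_set`: a list with `features`
#'   (tibble: `submission_id`, `team_id`, 17 binary feature columns) and
#'   `predictions` (long tibble: `submission_id`, `patient_id`, `score`,
#'   `predicted`).
#' @export
generate_submissions <- function(cohort, recipes, config,
                                 catalog = score_catalog(),
                                 seed = config$seed + 2L) {
  stopifnot(inherits(config, "sim_config"))
  val <- cohort[!is.na(cohort$role) & cohort$role == "validation", ]
  if (nrow(val) == 0L) {
    stop("Cohort has no validation rows; run split_cohort() first",
         call. = FALSE)
  }
  set.seed(seed)
  n_sub <- config$n_submissions
  teams <- c(seq_len(config$n_teams),
             sample.int(config$n_teams, n_sub - config$n_teams,
                        replace = TRUE))
  teams <- sprintf("team%02d", teams)
  sub_ids <- sprintf("sub%02d", seq_len(n_sub))

  fmat <- t(vapply(seq_len(n_sub), function(i) sample_feature_vector(),
                   numeric(n_features())))
  colnames(fmat) <- feature_names()
  features <- dplyr::bind_cols(
    tibble::tibble(submission_id = sub_ids, team_id = teams),
    tibble::as_tibble(fmat)
  )

  domain_recipe <- lapply(
    stats::setNames(unique(catalog$domain), unique(catalog$domain)),
    function(d) recipe_vector(recipes, d)
  )

  n_val <- nrow(val)
  preds <- vector("list", n_sub * nrow(catalog))
  k <- 0L
  for (i in seq_len(n_sub)) {
    for (j in seq_len(nrow(catalog))) {
      sc <- catalog$score[j]
      truth <- val[[sc]]
      m <- mean(truth); s <- stats::sd(truth)
      match <- recipe_match(fmat[i, ], domain_recipe[[catalog$domain[j]]])
      r <- config$r_base +
        (config$r_max - config$r_base) * match^config$match_exponent
      z <- if (s > 0) (truth - m) / s else rep(0, n_val)
      pz <- r * z + sqrt(1 - r^2) * stats::rnorm(n_val)
      p <- m + s * pz
      p <- pmin(pmax(p, catalog$range_min[j]), catalog$range_max[j])
      k <- k + 1L
      preds[[k]] <- tibble::tibble(submission_id = sub_ids[i],
                                   patient_id = val$patient_id,
                                   score = sc, predicted = p)
    }
  }
  structure(
    list(features = features, predictions = dplyr::bind_rows(preds)),
    class = "submission_set"
  )
}

#' @export
print.submission_set <- function(x, ...) {
  cat("<submission_set>", nrow(x$features), "submissions,",
      length(unique(x$predictions$score)), "scores,",
      length(unique(x$predictions$patient_id)), "validation patients\n")
  invisible(x)
}
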