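#' Catalogue of clinical outcome scores
#'
#' The benchmark evaluates predictions of 13 one-year post-stroke outcome
#' scores grouped into three domains: motor (Fugl-Meyer total and motor
#' subscale), cognitive (MoCA, its seven subscores, and the Isaacs Set Test of
#' categorical verbal fluency), and emotional (the HADS anxiety and depression
#' subscales). Six scores are flagged "main" and drive the primary ranking
#' metric; five carry clinically validated poor-outcome thresholds
#' (FM total <= 100, MoCA <= 25, IST <= 28, HAD-A >= 8, HAD-D >= 8).
#'
#' @return A tibble with one row per score and columns `score`, `label`,
#'   `domain` (`"motor"`, `"cognitive"`, `"emotional"`), `range_min`,
#'   `range_max`, `poor_threshold` (`NA` where no clinical threshold exists),
#'   `poor_direction` (`"low_is_poor"` or `"high_is_poor"`), and `is_main`.
#' @examples
#' score_catalog()
#' @export
score_catalog <- function() {
  tibble::tribble(
    ~score,               ~label,             ~domain,     ~range_min, ~range_max, ~poor_threshold, ~poor_direction, ~is_main,
    "fm_total",           "FM total",         "motor",     0,          242,        100,             "low_is_poor",   TRUE,
    "fm_motor",           "FM motor",         "motor",     0,          100,        NA,              NA,              TRUE,
    "moca",               "MoCA",             "cognitive", 0,          30,         25,              "low_is_poor",   TRUE,
    "moca_attention",     "MoCA attention",   "cognitive", 0,          6,          NA,              NA,              FALSE,
    "moca_visuospatial",  "MoCA visuospatial","cognitive", 0,          5,          NA,              NA,              FALSE,
    "moca_denomination",  "MoCA denomination","cognitive", 0,          3,          NA,              NA,              FALSE,
    "moca_language",      "MoCA language",    "cognitive", 0,          3,          NA,              NA,              FALSE,
    "moca_abstraction",   "MoCA abstraction", "cognitive", 0,          2,          NA,              NA,              FALSE,
    "moca_orientation",   "MoCA orientation", "cognitive", 0,          6,          NA,              NA,              FALSE,
    "moca_recall",        "MoCA recall",      "cognitive", 0,          5,          NA,              NA,              FALSE,
    "ist",                "IST",              "cognitive", 0,          60,         28,              "low_is_poor",   TRUE,
    "had_a",              "HAD-A",            "emotional", 0,          21,         8,               "high_is_poor",  TRUE,
    "had_d",              "HAD-D",            "emotional", 0,          21,         8,               "high_is_poor",  TRUE
  )
}

#' Names of the six main scores
#'
#' @param catalog A score catalogue, see [score_catalog()].
#' @return Character vector of the main score names.
#' @export
main_scores <- function(catalog = score_catalog()) {
  catalog$score[catalog$is_main]
}

#' Classify outcome values as poor or good
#'
#' Applies the clinically validated poor-outcome thresholds: for scores where
#' low values indicate a poor outcome (FM total, MoCA, IST), a value less than
#' or equal to the threshold is poor; for scores where high values do
#' (HAD-A, HAD-D), a value greater than or equal to the threshold is poor.
#'
#' @param score Name of a thresholded score (a `score` entry of the catalogue).
#' @param value Numeric vector of observed or predicted score values.
#' @param catalog A score catalogue.
#' @return Character vector (`"poor"`/`"good"`) of the same length as `value`.
#' @examples
#' classify_poor("fm_total", c(100, 101))
#' classify_poor("had_a", c(7, 8))
#' @export
classify_poor <- function(score, value, catalog = score_catalog()) {
  stopifnot(length(score) == 1L)
  row <- catalog[catalog$score == score, ]
  if (nrow(row) == 0L) {
    stop("Unknown score '", score, "'. Valid scores: ",
         paste(catalog$score, collapse = ", "), call. = FALSE)
  }
  if (is.na(row$poor_threshold)) {
    stop("Score '", score, "' has no clinical poor-outcome threshold.",
         call. = FALSE)
  }
  poor <- if (row$poor_direction == "low_is_poor") {
    value <= row$poor_threshold
  } else {
    value >= row$poor_threshold
  }
  ifelse(poor, "poor", "good")
}

#' Canonical feature taxonomy of the morphospace
#'
#' Submissions declare which of 9 inputs (age, gender, DWI, T1, segmented
#' lesion, FLAIR, white-matter tracts, parcellation atlases, disconnectome)
#' and 8 method classes (clustering, artificial neural networks, regression,
#' feature selection, dimensionality reduction, parcellation/segmentation,
#' cross-validation, bootstrap) they combined. The column order of every
#' 17-bit feature vector in the package follows this table and is immutable.
#'
#' @return A tibble with columns `feature`, `class` (`"input"`/`"method"`)
#'   and `index` (1-based canonical position).
#' @export
morpho_features <- function() {
  tibble::tibble(
    feature = c("age", "gender", "dwi", "t1", "lesion", "flair", "tracts",
                "atlases", "disconnectome",
                "clustering", "ann", "regression", "feature_selection",
                "dim_reduction", "parcellation", "cross_validation",
                "bootstrap"),
    class = rep(c("input", "method"), c(9L, 8L)),
    index = 1:17
  )
}

# canonical feature names, in order
feature_names <- function() morpho_features()$feature

n_features <- function() 17L
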