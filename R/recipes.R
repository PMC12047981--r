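#' Invert the morphospace into per-feature fields
#'
#' Maps the center of every grid cell back to a continuous 17-dimensional
#' feature vector with the inverse transform ([morpho_inverse()]), giving
#' one grid_size x grid_size field per feature (3600 values each on the
#' default 60 x 60 grid), then binarizes each field at `threshold`
#' (values >= threshold count as feature present; the boundary is included).
#'
#' @param space A discretized `morphospace`.
#' @param threshold Binarization threshold in `[0, 1]` (default 0.5).
#' @return An object of class `feature_fields`: list with `continuous` and
#'   `binary` (grid_size x grid_size x 17 arrays, `[gx + 1, gy + 1, feature]`
#'   indexing, canonical feature order), `threshold`, `features`,
#'   `grid_size`.
#' @export
inverse_feature_maps <- function(space, threshold = 0.5) {
  stopifnot(inherits(space, "morphospace"))
  if (is.null(space$bounds)) {
    stop("Morphospace has not been discretized", call. = FALSE)
  }
  g <- space$grid_size
  cells <- grid_cells_xy(g)
  centers <- grid_cell_centers(space, cbind(cells$gx, cells$gy))
  cont <- morpho_inverse(space, centers)
  stopifnot(all(is.finite(cont)))
  continuous <- array(cont, dim = c(g, g, n_features()),
                      dimnames = list(NULL, NULL, feature_names()))
  structure(
    list(continuous = continuous,
         binary = (continuous >= threshold) * 1,
         threshold = threshold,
         features = feature_names(),
         grid_size = g),
    class = "feature_fields"
  )
}

#' @export
print.feature_fields <- function(x, ...) {
  cat("<feature_fields>", x$grid_size, "x", x$grid_size, "x",
      length(x$features), "fields, binarized at", x$threshold, "\n")
  invisible(x)
}

#' Read the optimal recipe at a grid coordinate
#'
#' Reads the 17 binarized feature values at one cell of the inverted
#' morphospace: the estimated combination of inputs and methods ("recipe")
#' associated with that location.
#'
#' @param stack A `feature_fields` object.
#' @param cell Integer length-2 vector `(gx, gy)`, 0-based.
#' @param score_name,cluster_id Optional labels carried into the result.
#' @return A one-row tibble: `score`, `cluster`, `gx`, `gy`, `n_features`
#'   (0 flags an empty recipe), then the 17 binary feature columns.
#' @export
recipe_at <- function(stack, cell, score_name = NA_character_,
                      cluster_id = NA_integer_) {
  stopifnot(inherits(stack, "feature_fields"))
  g <- stack$grid_size
  cell <- as.integer(cell)
  if (length(cell) != 2L || any(cell < 0L) || any(cell > g - 1L)) {
    stop("cell must be a 0-based (gx, gy) coordinate within the ",
         g, " x ", g, " grid", call. = FALSE)
  }
  bits <- as.integer(stack$binary[cell[1] + 1L, cell[2] + 1L, ])
  dplyr::bind_cols(
    tibble::tibble(score = score_name, cluster = as.integer(cluster_id),
                   gx = cell[1], gy = cell[2], n_features = sum(bits)),
    tibble::as_tibble(as.list(stats::setNames(bits, stack$features)))
  )
}

#' Recipes at the significant local maxima of a statmap
#'
#' One recipe per significant cluster, read at the cluster's local maximum.
#' Different clusters of the same score may yield different recipes - more
#' than one combination can predict an outcome comparably well.
#'
#' @param statmap A `statmap`.
#' @param stack A `feature_fields` from the same morphospace.
#' @return A tibble of recipes (one row per cluster, with `t` of the
#'   maximum); zero rows when the map has no significant cells.
#' @export
recipes_for_score <- function(statmap, stack) {
  stopifnot(inherits(statmap, "statmap"), inherits(stack, "feature_fields"))
  if (statmap$grid_size != stack$grid_size) {
    stop("Grid size mismatch: statmap ", statmap$grid_size,
         " vs feature fields ", stack$grid_size, call. = FALSE)
  }
  mx <- statmap$maxima
  if (nrow(mx) == 0L) {
    empty <- recipe_at(stack, c(0L, 0L))[0, ]
    empty$t <- numeric(0)
    return(empty)
  }
  purrr::map2_dfr(seq_len(nrow(mx)), mx$t, function(i, tval) {
    r <- recipe_at(stack, c(mx$gx[i], mx$gy[i]),
                   score_name = statmap$score_name,
                   cluster_id = mx$cluster[i])
    r$t <- tval
    r
  })
}

#' Aggregate per-score recipes into a per-domain recipe table
#'
#' For each outcome domain (motor, cognitive, emotional), picks the recipe
#' of the highest-t significant local maximum among that domain's scores and
#' emits a 17-row by 3-column binary table (features x domains). Domains
#' with no significant recipe get a zero column and are listed in
#' `attr(, "absent_domains")`.
#'
#' @param recipes A tibble of recipes from [recipes_for_score()] (rows from
#'   several scores bound together), with `score` and `t` columns.
#' @param catalog A score catalogue (maps scores to domains).
#' @return A tibble: `feature` (17 canonical rows) plus `motor`,
#'   `cognitive`, `emotional` 0/1 columns. Attributes: `absent_domains`
#'   (character) and `sources` (tibble of the chosen score/cluster/cell/t
#'   per domain).
#' @export
aggregate_domain_recipes <- function(recipes, catalog = score_catalog()) {
  domains <- c("motor", "cognitive", "emotional")
  out <- tibble::tibble(feature = feature_names())
  absent <- character()
  sources <- list()
  rec <- recipes
  if (nrow(rec) > 0L) {
    rec$domain <- catalog$domain[match(rec$score, catalog$score)]
    if (anyNA(rec$domain)) {
      stop("Recipes contain scores not in the catalogue: ",
           paste(unique(rec$score[is.na(rec$domain)]), collapse = ", "),
           call. = FALSE)
    }
  }
  for (dom in domains) {
    sub <- if (nrow(rec) > 0L) rec[rec$domain == dom, ] else rec
    if (nrow(sub) == 0L) {
      out[[dom]] <- 0
      absent <- c(absent, dom)
    } else {
      sub <- sub[order(-sub$t, sub$score, sub$cluster), ]
      best <- sub[1, ]
      out[[dom]] <- as.numeric(best[, feature_names()])
      sources[[dom]] <- tibble::tibble(
        domain = dom, score = best$score, cluster = best$cluster,
        gx = best$gx, gy = best$gy, t = best$t
      )
    }
  }
  attr(out, "absent_domains") <- absent
  attr(out, "sources") <- dplyr::bind_rows(sources)
  out
}
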