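#' Build the canonical submission-by-feature matrix
#'
#' @param x A `submission_set`, a tibble containing the 17 canonical feature
#'   columns (plus optional `submission_id`/`team_id`), or a numeric matrix
#'   with 17 columns.
#' @return A numeric 0/1 matrix, one row per submission, columns in the
#'   immutable canonical order of [morpho_features()], rownames set to
#'   submission ids when available.
#' @examples
#' tb <- tibble::tibble(submission_id = "s1",
#'                      !!!stats::setNames(as.list(rep(1, 17)),
#'                                         morpho_features()$feature))
#' build_feature_matrix(tb)
#' @export
build_feature_matrix <- function(x) {
  feats <- feature_names()
  if (inherits(x, "submission_set")) x <- x$features
  if (is.matrix(x)) {
    if (ncol(x) != n_features()) {
      stop("Feature matrix must have ", n_features(), " columns", call. = FALSE)
    }
    if (is.null(colnames(x))) colnames(x) <- feats
    x <- tibble::as_tibble(x)
  }
  stopifnot(is.data.frame(x), nrow(x) > 0L)
  id_cols <- intersect(c("submission_id", "team_id"), names(x))
  other <- setdiff(names(x), c(id_cols, feats))
  if (length(other) > 0L) {
    stop("Unknown feature columns: ", paste(other, collapse = ", "),
         ". Valid features: ", paste(feats, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(feats, names(x))
  if (length(missing) > 0L) {
    stop("Missing feature columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(x[, feats])
  if (!all(m %in% c(0, 1))) stop("Features must be binary 0/1", call. = FALSE)
  storage.mode(m) <- "numeric"
  rownames(m) <- if ("submission_id" %in% id_cols) x$submission_id
                 else sprintf("sub%02d", seq_len(nrow(m)))
  m
}

#' Embed submissions into a discretized 2-D morphospace
#'
#' Runs UMAP on the binary feature matrix (Hamming metric by default, so
#' proximity reflects shared design choices) and discretizes the layout onto
#' a square grid with [discretize_morphospace()]. The embedding is
#' deterministic given `seed`. The fitted UMAP model is retained for
#' forward transforms of new feature vectors; the inverse transform back to
#' feature space is an inverse-distance-weighted average of the `k_inverse`
#' nearest training rows in embedding space (see [morpho_inverse()]), whose
#' fidelity is covered by the round-trip conformance tests.
#'
#' @param x Submissions in any form accepted by [build_feature_matrix()].
#' @param grid_size Number of cells per axis (default 60).
#' @param n_neighbors UMAP neighborhood size; auto-shrunk (with a warning)
#'   to `n - 1` for small inputs.
#' @param min_dist UMAP minimum distance (default 0.1).
#' @param metric Distance between binary rows: `"hamming"` (default),
#'   `"manhattan"`, `"euclidean"` or `"cosine"`.
#' @param seed Integer seed.
#' @param k_inverse Neighbors used by the inverse transform (default 5).
#' @return An object of class `morphospace`: list with `embedding` (n x 2),
#'   `features` (n x 17), `coords` (n x 2 integer cells, 0-based), `bounds`,
#'   `grid_size`, the UMAP `model`, and the parameters used.
#' @export
embed_morphospace <- function(x, grid_size = 60L, n_neighbors = 15L,
                              min_dist = 0.1,
                              metric = c("hamming", "manhattan",
                                         "euclidean", "cosine"),
                              seed = 42L, k_inverse = 5L) {
  metric <- match.arg(metric)
  X <- build_feature_matrix(x)
  n <- nrow(X)
  if (nrow(unique(X)) < 4L) {
    stop("Need at least 4 distinct feature rows to embed", call. = FALSE)
  }
  nn <- n_neighbors
  if (nn > n - 1L) {
    nn <- n - 1L
    warning("n_neighbors reduced to ", nn, " for ", n, " submissions",
            call. = FALSE)
  }
  set.seed(seed)
  model <- uwot::umap(X, n_neighbors = nn, min_dist = min_dist,
                      metric = metric, n_threads = 1, n_sgd_threads = 0,
                      ret_model = TRUE)
  emb <- model$embedding
  rownames(emb) <- rownames(X)
  colnames(emb) <- c("x", "y")
  space <- structure(
    list(embedding = emb, features = X, grid_size = as.integer(grid_size),
         coords = NULL, bounds = NULL, model = model,
         n_neighbors = nn, min_dist = min_dist, metric = metric,
         seed = as.integer(seed), k_inverse = as.integer(k_inverse)),
    class = "morphospace"
  )
  discretize_morphospace(space, grid_size)
}

#' Discretize a morphospace onto a square grid
#'
#' Min-max scales each embedding axis onto `[0, grid_size - 1]` and rounds
#' half-up to the nearest integer cell. The axis bounds are stored so any
#' grid cell can be mapped back to continuous embedding coordinates (its
#' cell center) by [grid_cell_centers()]. A degenerate axis (max == min)
#' puts every point at the middle cell `floor((grid_size - 1) / 2)` with a
#' warning.
#'
#' @param space A `morphospace`.
#' @param grid_size Cells per axis.
#' @return The morphospace with `coords` (0-based integer cells, columns
#'   `gx`, `gy`) and `bounds` filled.
#' @export
discretize_morphospace <- function(space, grid_size = space$grid_size) {
  stopifnot(inherits(space, "morphospace"))
  g <- as.integer(grid_size)
  emb <- space$embedding
  bounds <- apply(emb, 2, range)  # 2 x 2: rows min/max, cols axes
  coords <- matrix(0L, nrow(emb), 2L, dimnames = list(rownames(emb),
                                                      c("gx", "gy")))
  for (a in 1:2) {
    lo <- bounds[1, a]; hi <- bounds[2, a]
    if (hi == lo) {
      warning("Embedding axis ", a, " is degenerate; all points at cell ",
              (g - 1L) %/% 2L, call. = FALSE)
      coords[, a] <- (g - 1L) %/% 2L
    } else {
      coords[, a] <- as.integer(floor((emb[, a] - lo) / (hi - lo) *
                                        (g - 1L) + 0.5))
    }
  }
  space$coords <- coords
  space$bounds <- bounds
  space$grid_size <- g
  space
}

#' Continuous embedding coordinates of grid cell centers
#'
#' @param space A discretized `morphospace`.
#' @param cells Integer matrix (m x 2) of 0-based cells (`gx`, `gy`).
#' @return An m x 2 matrix of continuous embedding coordinates.
#' @export
grid_cell_centers <- function(space, cells) {
  stopifnot(inherits(space, "morphospace"), !is.null(space$bounds))
  cells <- matrix(as.numeric(cells), ncol = 2L)
  g <- space$grid_size
  out <- cells
  for (a in 1:2) {
    lo <- space$bounds[1, a]; hi <- space$bounds[2, a]
    out[, a] <- if (hi == lo) lo else lo + cells[, a] / (g - 1) * (hi - lo)
  }
  out
}

#' Inverse transform: embedding coordinates to continuous feature vectors
#'
#' Maps points in the 2-D embedding back to 17-dimensional continuous
#' feature space as the inverse-distance-weighted (1/d) average of the
#' `k` nearest training submissions in embedding space. At or very near a
#' training point the weights are dominated by that point, so the inverse
#' reproduces its feature row; between clusters it interpolates.
#'
#' @param space A `morphospace`.
#' @param points Numeric m x 2 matrix of continuous embedding coordinates.
#' @param k Number of neighbors (default the space's `k_inverse`).
#' @return An m x 17 matrix of continuous feature values in `[0, 1]`.
#' @export
morpho_inverse <- function(space, points, k = space$k_inverse) {
  stopifnot(inherits(space, "morphospace"))
  points <- matrix(as.numeric(points), ncol = 2L)
  emb <- space$embedding
  k <- min(k, nrow(emb))
  out <- matrix(NA_real_, nrow(points), n_features(),
                dimnames = list(NULL, feature_names()))
  for (i in seq_len(nrow(points))) {
    d <- sqrt((emb[, 1] - points[i, 1])^2 + (emb[, 2] - points[i, 2])^2)
    idx <- order(d)[seq_len(k)]
    w <- 1 / pmax(d[idx], 1e-8)
    w <- w / sum(w)
    out[i, ] <- as.numeric(w %*% space$features[idx, , drop = FALSE])
  }
  out
}

#' Forward transform new feature vectors into an existing morphospace
#'
#' @param space A `morphospace` retaining its fitted model.
#' @param x New submissions in any form accepted by
#'   [build_feature_matrix()].
#' @return An m x 2 matrix of embedding coordinates.
#' @export
morpho_transform <- function(space, x) {
  stopifnot(inherits(space, "morphospace"), !is.null(space$model))
  X <- build_feature_matrix(x)
  uwot::umap_transform(X, space$model, n_threads = 1)
}

#' @export
print.morphospace <- function(x, ...) {
  cat("<morphospace>", nrow(x$embedding), "submissions on a",
      x$grid_size, "x", x$grid_size, "grid (", x$metric,
      "metric, seed", x$seed, ")\n")
  invisible(x)
}

#' Tidy a morphospace into a per-submission tibble
#'
#' @param x A `morphospace`.
#' @param ... Unused.
#' @return Tibble: `submission_id`, continuous `x`, `y`, grid cells
#'   `gx`, `gy`.
#' @method tidy morphospace
#' @export
tidy.morphospace <- function(x, ...) {
  emb <- x$embedding
  coords <- x$coords
  tibble::tibble(
    submission_id = rownames(emb),
    x = emb[, 1], y = emb[, 2],
    gx = coords[, 1], gy = coords[, 2]
  )
}

#' One-row summary of a morphospace
#'
#' @param x A `morphospace`.
#' @param ... Unused.
#' @return Tibble: `n`, `grid_size`, `n_cells_occupied`, `metric`, `seed`.
#' @method glance morphospace
#' @export
glance.morphospace <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$embedding),
    grid_size = x$grid_size,
    n_cells_occupied = nrow(unique(as.data.frame(x$coords))),
    metric = x$metric,
    seed = x$seed
  )
}
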