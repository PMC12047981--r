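grid_cells_xy <- function(g) {
  # linear ordering: gx fastest, then gy (matrix(v, g, g)[gx + 1, gy + 1])
  list(gx = rep(0:(g - 1L), times = g),
       gy = rep(0:(g - 1L), each = g))
}

#' Per-submission presence maps on the morphospace grid
#'
#' For each submission, a Gaussian bump of width `sigma` (in cells) centered
#' at its grid cell, normalized to unit peak amplitude. These presence maps
#' are the regressors of the permutation t-map: at each cell, predictive
#' performance is regressed on how strongly each submission is "present"
#' there. `sigma <= 0` degenerates to a delta map (1 at the submission's own
#' cell, 0 elsewhere).
#'
#' @param coords Integer n x 2 matrix of 0-based grid cells (`gx`, `gy`),
#'   e.g. `space$coords`.
#' @param grid_size Cells per axis.
#' @param sigma Gaussian kernel width in cell units (default 2).
#' @return An n x grid_size^2 matrix (cells ordered x-fastest), with
#'   attributes `grid_size` and `sigma`.
#' @export
build_signal_maps <- function(coords, grid_size = 60L, sigma = 2) {
  coords <- matrix(as.numeric(coords), ncol = 2L)
  g <- as.integer(grid_size)
  cells <- grid_cells_xy(g)
  n <- nrow(coords)
  maps <- matrix(0, n, g * g)
  for (i in seq_len(n)) {
    d2 <- (cells$gx - coords[i, 1])^2 + (cells$gy - coords[i, 2])^2
    maps[i, ] <- if (sigma > 0) exp(-d2 / (2 * sigma^2)) else as.numeric(d2 == 0)
  }
  # compact support: negligible kernel tails are exactly zero, so far-away
  # cells do not pick up underflow-level presence variance
  maps[maps < 1e-12] <- 0
  structure(maps, grid_size = g, sigma = sigma)
}

#' Permutation t-statistic map over the morphospace
#'
#' A randomise-style nonparametric association map: at every grid cell the
#' t-statistic of the slope from the simple linear regression of the
#' submissions' R2 values on their presence values at that cell. The null
#' distribution is built by permuting the R2 values across submissions
#' (`n_perm` seeded draws); family-wise error across the grid is controlled
#' with the maximum-statistic method (each cell's corrected p-value is the
#' proportion of permutations whose grid-wide maximum t reaches the
#' observed cell t, with the add-one convention, so p >= 1/(n_perm + 1)).
#' Inference is one-sided for positive association (high R2). Cells with
#' zero presence variance get t = 0 and p = 1. Significant cells
#' (p <= alpha) are segmented into 8-connected clusters, each with its
#' local maximum.
#'
#' @param maps Presence matrix from [build_signal_maps()].
#' @param r2_values Numeric vector of per-submission R2, aligned with the
#'   rows of `maps`; must not be constant (n >= 5).
#' @param n_perm Number of permutations (default 5000).
#' @param alpha Family-wise significance level (default 0.05).
#' @param seed Integer seed for the permutations.
#' @param score_name Optional label stored in the result.
#' @return An object of class `statmap`: list with `t`, `p`, `sig`
#'   (grid_size x grid_size matrices, `[gx + 1, gy + 1]` indexing),
#'   `clusters` and `maxima` tibbles, `null_max` (sorted permutation
#'   distribution of the grid maximum), and the parameters.
#' @export
permutation_tmap <- function(maps, r2_values, n_perm = 5000L, alpha = 0.05,
                             seed = 42L, score_name = NULL) {
  n <- nrow(maps)
  stopifnot(n >= 5L, length(r2_values) == n)
  if (stats::sd(r2_values) == 0) {
    stop("r2_values are constant; no association to test", call. = FALSE)
  }
  g <- attr(maps, "grid_size")
  if (is.null(g)) g <- as.integer(sqrt(ncol(maps)))
  m <- ncol(maps)

  sds <- matrixStats::colSds(maps)
  valid <- sds > 0
  Z <- maps[, valid, drop = FALSE]
  Z <- sweep(Z, 2L, colMeans(Z), "-")
  Z <- sweep(Z, 2L, sds[valid], "/")
  ys <- as.numeric(scale(r2_values))

  t_from_r <- function(r) {
    r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
    r * sqrt((n - 2) / (1 - r^2))
  }
  t_valid <- t_from_r(as.numeric(crossprod(Z, ys)) / (n - 1))

  set.seed(seed)
  null_max <- numeric(n_perm)
  chunk <- 500L
  done <- 0L
  while (done < n_perm) {
    b <- min(chunk, n_perm - done)
    Y <- vapply(seq_len(b),
                function(j) as.numeric(scale(sample(r2_values))),
                numeric(n))
    Tm <- t_from_r(crossprod(Z, Y) / (n - 1))
    null_max[done + seq_len(b)] <- matrixStats::colMaxs(Tm)
    done <- done + b
  }
  sorted_max <- sort(null_max)
  # count of permutation maxima >= t, add-one corrected
  exceed <- n_perm - findInterval(t_valid, sorted_max, left.open = TRUE)
  p_valid <- (1 + exceed) / (n_perm + 1)

  t_grid <- matrix(0, g, g)
  p_grid <- matrix(1, g, g)
  t_grid[valid] <- t_valid
  p_grid[valid] <- p_valid
  sig <- p_grid <= alpha

  clusters <- find_clusters(sig)
  maxima <- find_local_maxima(t_grid, clusters)

  structure(
    list(score_name = score_name, grid_size = g,
         t = t_grid, p = p_grid, sig = sig,
         clusters = clusters, maxima = maxima,
         null_max = sorted_max, n_perm = as.integer(n_perm),
         alpha = alpha, seed = as.integer(seed)),
    class = "statmap"
  )
}

#' Connected clusters of significant cells
#'
#' Labels the 8-connected components (edge- or corner-touching) of a binary
#' significance mask. Clusters are numbered by descending size; ties broken
#' by the scan-order (increasing `gy`, then `gx`) position of their first
#' cell.
#'
#' @param sig_mask Logical grid matrix (`[gx + 1, gy + 1]` indexing).
#' @return Tibble with columns `cluster`, `gx`, `gy` (0-based), one row per
#'   significant cell; zero rows if the mask is empty.
#' @export
find_clusters <- function(sig_mask) {
  g1 <- nrow(sig_mask); g2 <- ncol(sig_mask)
  lab <- matrix(0L, g1, g2)
  nxt <- 0L
  queue <- integer(g1 * g2)  # linear indices, preallocated
  # scan in reading order: increasing gy (columns), then gx (rows)
  for (iy in seq_len(g2)) {
    for (ix in seq_len(g1)) {
      if (sig_mask[ix, iy] && lab[ix, iy] == 0L) {
        nxt <- nxt + 1L
        head <- 1L; tail <- 1L
        queue[1L] <- ix + (iy - 1L) * g1
        lab[ix, iy] <- nxt
        while (head <= tail) {
          cur <- queue[head]; head <- head + 1L
          cx <- ((cur - 1L) %% g1) + 1L
          cy <- ((cur - 1L) %/% g1) + 1L
          for (dx in -1:1) for (dy in -1:1) {
            nx <- cx + dx; ny <- cy + dy
            if (nx >= 1L && nx <= g1 && ny >= 1L && ny <= g2 &&
                sig_mask[nx, ny] && lab[nx, ny] == 0L) {
              lab[nx, ny] <- nxt
              tail <- tail + 1L
              queue[tail] <- nx + (ny - 1L) * g1
            }
          }
        }
      }
    }
  }
  if (nxt == 0L) {
    return(tibble::tibble(cluster = integer(), gx = integer(),
                          gy = integer()))
  }
  idx <- which(lab > 0L, arr.ind = TRUE)
  df <- tibble::tibble(raw = lab[idx], gx = idx[, 1] - 1L,
                       gy = idx[, 2] - 1L)
  df <- df[order(df$gy, df$gx), ]
  sizes <- table(df$raw)
  first_pos <- tapply(seq_len(nrow(df)), df$raw, min)
  ord <- order(-as.integer(sizes), first_pos)
  relabel <- stats::setNames(seq_along(ord), names(sizes)[ord])
  df$cluster <- as.integer(relabel[as.character(df$raw)])
  df <- df[order(df$cluster, df$gy, df$gx), ]
  tibble::tibble(cluster = df$cluster, gx = df$gx, gy = df$gy)
}

#' Local maximum of each significant cluster
#'
#' @param t_grid Grid matrix of t-statistics.
#' @param clusters Cluster tibble from [find_clusters()].
#' @return Tibble `cluster`, `gx`, `gy`, `t`: the in-cluster cell with the
#'   highest t (ties broken by scan order, increasing `gy` then `gx`); zero
#'   rows for an empty cluster list.
#' @export
find_local_maxima <- function(t_grid, clusters) {
  if (nrow(clusters) == 0L) {
    return(tibble::tibble(cluster = integer(), gx = integer(),
                          gy = integer(), t = numeric()))
  }
  clusters$t <- t_grid[cbind(clusters$gx + 1L, clusters$gy + 1L)]
  clusters |>
    dplyr::arrange(.data$cluster, dplyr::desc(.data$t), .data$gy, .data$gx) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
}

#' @export
print.statmap <- function(x, ...) {
  nc <- if (nrow(x$clusters)) max(x$clusters$cluster) else 0L
  cat("<statmap", if (!is.null(x$score_name)) x$score_name else "", ">",
      x$grid_size, "x", x$grid_size, "grid,", x$n_perm, "permutations,",
      sum(x$sig), "significant cells in", nc, "cluster(s)\n")
  invisible(x)
}

#' Tidy a statmap into a per-cell tibble
#'
#' @param x A `statmap`.
#' @param ... Unused.
#' @return Tibble: `gx`, `gy`, `t`, `p`, `sig`, `cluster` (`NA` outside
#'   significant clusters), plus `score` when the map is labelled.
#' @method tidy statmap
#' @export
tidy.statmap <- function(x, ...) {
  g <- x$grid_size
  cells <- grid_cells_xy(g)
  out <- tibble::tibble(
    gx = cells$gx, gy = cells$gy,
    t = as.vector(x$t), p = as.vector(x$p), sig = as.vector(x$sig)
  )
  out$cluster <- NA_integer_
  if (nrow(x$clusters)) {
    lin <- x$clusters$gx + x$clusters$gy * g + 1L
    out$cluster[lin] <- x$clusters$cluster
  }
  if (!is.null(x$score_name)) {
    out <- dplyr::mutate(out, score = x$score_name, .before = 1L)
  }
  out
}

#' One-row summary of a statmap
#'
#' @param x A `statmap`.
#' @param ... Unused.
#' @return Tibble: `score`, `max_t`, `min_p`, `n_sig_cells`, `n_clusters`,
#'   `n_perm`, `alpha`.
#' @method glance statmap
#' @export
glance.statmap <- function(x, ...) {
  tibble::tibble(
    score = if (is.null(x$score_name)) NA_character_ else x$score_name,
    max_t = max(x$t),
    min_p = min(x$p),
    n_sig_cells = sum(x$sig),
    n_clusters = if (nrow(x$clusters)) max(x$clusters$cluster) else 0L,
    n_perm = x$n_perm,
    alpha = x$alpha
  )
}
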