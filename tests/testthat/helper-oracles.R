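# Independent brute-force oracles: written directly from the metric
# definitions, never reusing the package's code paths.

oracle_r2 <- function(pred, truth) {
  n <- length(pred)
  sxy <- sum((pred - sum(pred) / n) * (truth - sum(truth) / n))
  sxx <- sum((pred - sum(pred) / n)^2)
  syy <- sum((truth - sum(truth) / n)^2)
  sxy^2 / (sxx * syy)
}

oracle_mse <- function(pred, truth) sum((pred - truth)^2) / length(pred)

oracle_mae <- function(pred, truth) sum(abs(pred - truth)) / length(pred)

# Pairwise Mann-Whitney: P(poor case leans more poor), ties 1/2
oracle_auc <- function(pred, poor, direction) {
  s <- if (direction == "low_is_poor") -pred else pred
  ip <- which(poor); ig <- which(!poor)
  tot <- 0
  for (i in ip) for (j in ig) {
    tot <- tot + if (s[i] > s[j]) 1 else if (s[i] == s[j]) 0.5 else 0
  }
  tot / (length(ip) * length(ig))
}

# 8-connected components through igraph, as an independent labelling route
oracle_cluster_partition <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(list())
  n <- nrow(idx)
  edges <- c()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && max(abs(idx[i, ] - idx[j, ])) <= 1L) {
      edges <- c(edges, i, j)
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  cells <- paste(idx[, 1], idx[, 2])
  unname(lapply(split(cells, comp), sort))
}

# Block-structured binary designs: n_blocks far-apart prototypes, each
# repeated with `flips` random bit flips per row.
make_block_features <- function(n_blocks = 4, per_block = 6, flips = 1,
                                min_sep = 8, seed = 1) {
  set.seed(seed)
  repeat {
    protos <- matrix(rbinom(n_blocks * 17, 1, 0.5), n_blocks, 17)
    d <- as.matrix(stats::dist(protos, method = "manhattan"))
    if (min(d[upper.tri(d)]) >= min_sep) break
  }
  rows <- lapply(seq_len(n_blocks), function(b) {
    t(vapply(seq_len(per_block), function(i) {
      v <- protos[b, ]
      if (flips > 0) {
        fl <- sample.int(17, flips)
        v[fl] <- 1 - v[fl]
      }
      v
    }, numeric(17)))
  })
  X <- do.call(rbind, rows)
  colnames(X) <- morpho_features()$feature
  rownames(X) <- sprintf("sub%02d", seq_len(nrow(X)))
  list(features = X, block = rep(seq_len(n_blocks), each = per_block),
       prototypes = protos)
}

# small simulation configs used across tests
quick_sim <- function(seed = 1, n_train = 30, n_val = 20, ...) {
  sim_config(seed = seed, n_train = n_train, n_val = n_val, ...)
}
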