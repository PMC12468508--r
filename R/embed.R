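# Exact t-SNE (no tree approximation): suitable for cohort-sized inputs
# (n of order 100). Pairwise affinities with per-point bandwidths calibrated
# to the target perplexity by bisection; KL divergence minimized by gradient
# descent with momentum and early exaggeration. Initialization is the first
# two principal components scaled to 1e-4 (stable layouts across runs) plus
# a small seed-dependent jitter, so results are deterministic given the seed.
tsne_exact <- function(X, perplexity = 30, seed = 1, n_iter = 1000,
                       eta = 50, exaggeration = 4) {
  n <- nrow(X)
  set.seed(as.integer(seed %% 2147483647L))
  D2 <- as.matrix(stats::dist(X))^2
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (it in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { beta <- beta / 2; next }
      H <- log(sw) + beta * sum(di * w) / sw
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2
                                          else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2
                                 else beta / 2 }
    }
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  pc <- stats::prcomp(X)$x
  pc <- cbind(pc, matrix(0, n, 2))[, 1:2, drop = FALSE]
  s1 <- stats::sd(pc[, 1])
  Y <- (if (s1 > 0) pc / s1 else pc) * 1e-4 +
    matrix(stats::rnorm(n * 2, sd = 1e-6), n, 2)
  inc <- matrix(0, n, 2)
  for (iter in seq_len(n_iter)) {
    Pe <- if (iter <= 250) P * exaggeration else P
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    mom <- if (iter <= 250) 0.5 else 0.8
    inc <- mom * inc - eta * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

# z-score feature columns (constant columns map to 0) so that metrics on
# different scales contribute comparably to the pairwise distances.
standardize_columns <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  scale(X, mu, sdv)
}

new_embedding <- function(coords, scope, perplexity, seed, ids) {
  rownames(coords) <- ids
  colnames(coords) <- c("dim1", "dim2")
  structure(list(coordinates = coords, scope = scope,
                 perplexity = perplexity, seed = seed),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("<embedding> scope %s: %d x 2, perplexity %g, seed %s\n",
              x$scope, nrow(x$coordinates), x$perplexity, format(x$seed)))
  invisible(x)
}

#' t-SNE embedding of one channel's features
#'
#' Embeds the subjects in 2-D from the three metric values (RE, TE, LZC) of a
#' single channel, using exact t-SNE. Coordinates are deterministic given
#' `seed` and do not depend on the group labels. Perplexity is capped at
#' `(n - 1) / 3`.
#'
#' @param features Feature table.
#' @param channel Channel as ordinal alias (`"C15"`) or electrode label
#'   (`"Pz"`).
#' @param perplexity t-SNE perplexity.
#' @param seed Integer seed.
#' @return An `embedding` object; `coordinates` is an `n x 2` matrix with
#'   subject ids as row names.
#' @export
embed_channel <- function(features, channel, perplexity = 30, seed = 1) {
  ords <- channel_ordinals()
  ord <- if (channel %in% ords) channel
         else if (channel %in% names(ords)) ords[[channel]]
         else stop("unknown channel: ", channel)
  cols <- paste0(c("RE_", "TE_", "LZC_"), ord)
  if (!all(cols %in% names(features)))
    stop("feature table lacks columns for channel ", channel)
  X <- standardize_columns(as.matrix(features[, cols]))
  perplexity <- min(perplexity, (nrow(X) - 1) / 3)
  Y <- tsne_exact(X, perplexity = perplexity, seed = seed)
  new_embedding(Y, ord, perplexity, seed, features$subject_id)
}

#' t-SNE embedding of the concatenated 57-feature vectors
#'
#' @inheritParams embed_channel
#' @return An `embedding` object over all feature columns.
#' @export
embed_concat <- function(features, perplexity = 30, seed = 1) {
  cols <- setdiff(names(features), c("subject_id", "group"))
  X <- standardize_columns(as.matrix(features[, cols]))
  perplexity <- min(perplexity, (nrow(X) - 1) / 3)
  Y <- tsne_exact(X, perplexity = perplexity, seed = seed)
  new_embedding(Y, "all", perplexity, seed, features$subject_id)
}

#' Silhouette-based cluster-separation score
#'
#' Mean silhouette width of the embedded coordinates under the given labels
#' (Euclidean distance): near 1 for tight well-separated group clusters, near
#' 0 when groups are intermixed. Convention: singleton clusters and points
#' with `max(a, b) == 0` (e.g. all-identical coordinates) score 0.
#'
#' @param embedding An `embedding`, or an `n x d` coordinate matrix.
#' @param labels Cluster labels (>= 2 distinct values present).
#' @return Mean silhouette in `[-1, 1]`.
#' @export
separation_score <- function(embedding, labels) {
  coords <- if (inherits(embedding, "embedding")) embedding$coordinates
            else as.matrix(embedding)
  labels <- as.character(labels)
  stopifnot(nrow(coords) == length(labels))
  if (length(unique(labels)) < 2) stop("need >= 2 labels")
  D <- as.matrix(stats::dist(coords))
  s <- vapply(seq_along(labels), function(i) {
    own <- labels == labels[i]
    if (sum(own) == 1) return(0)
    a <- mean(D[i, own & seq_along(labels) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(D[i, labels == l]), 0))
    if (max(a, b) == 0) return(0)
    (b - a) / max(a, b)
  }, 0)
  mean(s)
}
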