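# Shannon entropy in bits of a class-count vector.
entropy_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

# Entropy in bits of a label vector.
label_entropy <- function(labels) entropy_bits(table(labels))

#' Supervised MDLP discretization (Fayyad-Irani)
#'
#' Finds cut points for a continuous attribute by recursively choosing the
#' boundary that minimizes the class-label entropy, accepting a split only if
#' its information gain exceeds the minimum-description-length criterion
#' `(log2(N - 1) + log2(3^k - 2) - (k H(S) - k1 H(S1) - k2 H(S2))) / N`.
#' An attribute with no accepted cut is left as a single bin.
#'
#' @param values Numeric attribute values (>= 2 distinct values for any cut
#'   to be possible).
#' @param labels Class labels, same length.
#' @return Sorted numeric vector of cut points (possibly empty).
#' @export
#' @examples
#' discretize(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))
discretize <- function(values, labels) {
  stopifnot(length(values) == length(labels))
  ord <- order(values)
  mdlp_rec(values[ord], as.character(labels)[ord])
}

# Recursive MDLP on values sorted ascending.
mdlp_rec <- function(v, y) {
  n <- length(v)
  uv <- unique(v)
  if (n < 2 || length(uv) < 2) return(numeric())
  # candidate cuts: midpoints between adjacent distinct values
  mids <- (uv[-1] + uv[-length(uv)]) / 2
  base_counts <- table(y)
  ent_s <- entropy_bits(base_counts)
  best <- NULL
  best_e <- Inf
  for (cut in mids) {
    left <- y[v <= cut]
    right <- y[v > cut]
    e <- (length(left) * entropy_bits(table(left)) +
          length(right) * entropy_bits(table(right))) / n
    if (e < best_e) {
      best_e <- e
      best <- cut
    }
  }
  left <- y[v <= best]
  right <- y[v > best]
  gain <- ent_s - best_e
  k <- length(base_counts)
  k1 <- length(unique(left))
  k2 <- length(unique(right))
  delta <- log2(3^k - 2) -
    (k * ent_s - k1 * entropy_bits(table(left)) -
       k2 * entropy_bits(table(right)))
  if (gain <= (log2(n - 1) + delta) / n) return(numeric())
  sort(c(mdlp_rec(v[v <= best], left), best, mdlp_rec(v[v > best], right)))
}

# Discretized attribute as a factor of bin indices.
bin_attribute <- function(values, cuts) {
  findInterval(values, sort(cuts)) + 1L
}

# Core scorer: per-attribute MDLP bins, IG and split entropy H(A) in bits.
score_attributes <- function(features, labels) {
  if (is.null(labels)) {
    if (!"group" %in% names(features))
      stop("labels missing and no 'group' column present")
    labels <- features$group
    features <- features[, setdiff(names(features),
                                   c("subject_id", "group")), drop = FALSE]
  }
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("need >= 2 classes")
  hy <- label_entropy(labels)
  n <- length(labels)
  res <- lapply(names(features), function(a) {
    bins <- bin_attribute(features[[a]], discretize(features[[a]], labels))
    tab <- table(bins, labels)
    sizes <- rowSums(tab)
    cond <- sum(sizes / n * apply(tab, 1, entropy_bits))
    data.frame(attribute = a, info_gain = hy - cond,
               split_entropy = entropy_bits(sizes), n_bins = nrow(tab))
  })
  do.call(rbind, res)
}

#' Attribute ranking by information gain
#'
#' Scores every attribute by `IG(A) = H(Y) - H(Y | A)` in bits, with the
#' attribute first discretized by supervised MDLP ([discretize()]); an
#' attribute with no accepted cut has a single bin and `IG = 0`. Attributes
#' are ranked in descending score order, ties broken by column order.
#'
#' @param features A feature table (with `subject_id`/`group` columns), or a
#'   data frame of attribute columns when `labels` is given.
#' @param labels Optional class-label vector (defaults to the table's `group`
#'   column).
#' @return A `data.frame` with `attribute`, `info_gain`, and `rank`, sorted by
#'   descending score.
#' @export
info_gain <- function(features, labels = NULL) {
  sc <- score_attributes(features, labels)
  ord <- order(-sc$info_gain)
  out <- sc[ord, c("attribute", "info_gain")]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Attribute ranking by gain ratio
#'
#' Scores every attribute by `GR(A) = IG(A) / H(A)`, the information gain
#' normalized by the split entropy of the MDLP-discretized attribute.
#' Attributes whose discretization yields a single bin (`H(A) = 0`) are
#' excluded from the ranking.
#'
#' @inheritParams info_gain
#' @return A `data.frame` with `attribute`, `info_gain`, `gain_ratio`, `rank`.
#' @export
gain_ratio <- function(features, labels = NULL) {
  sc <- score_attributes(features, labels)
  sc <- sc[sc$split_entropy > 0, , drop = FALSE]
  sc$gain_ratio <- sc$info_gain / sc$split_entropy
  ord <- order(-sc$gain_ratio)
  out <- sc[ord, c("attribute", "info_gain", "gain_ratio")]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Top-k attribute subsets
#'
#' Builds the nested attribute subsets used for the four training setups:
#' all 57 attributes, top 15, top 10 and top 5 by rank.
#'
#' @param scores A ranking from [gain_ratio()] or [info_gain()].
#' @param k_list Subset sizes.
#' @return Named list of character vectors of attribute names.
#' @export
top_k_subsets <- function(scores, k_list = c(57, 15, 10, 5)) {
  if (any(k_list > nrow(scores)))
    stop("k exceeds the number of ranked attributes (", nrow(scores), ")")
  out <- lapply(k_list, function(k) scores$attribute[seq_len(k)])
  names(out) <- paste0("top", k_list)
  out
}
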