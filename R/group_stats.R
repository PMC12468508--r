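# Split a feature table into the two group label values, erroring if either
# group is empty.
split_groups <- function(features) {
  g <- features$group
  lv <- unique(g)
  if (length(lv) < 2) stop("both groups must be nonempty")
  lv
}

#' Channel-wise Mann-Whitney U tests between groups
#'
#' Runs a two-sided Mann-Whitney (Wilcoxon rank-sum) test per channel on the
#' selected metric's columns of a feature table. The exact null distribution
#' is enumerated when both groups have at most 8 subjects (and no ties);
#' otherwise the normal approximation with continuity and tie correction is
#' used — appropriate at the 39/49 group sizes this analysis targets.
#'
#' @param features Feature table from [extract_feature_table()] (columns
#'   `subject_id`, `group`, then `<metric>_C<k>`).
#' @param metric `"RE"`, `"TE"` or `"LZC"`.
#' @param alpha Family significance level before correction.
#' @param correct_m Number of comparisons for the Bonferroni correction
#'   (defaults to the number of channels tested).
#' @return A `data.frame` with one row per channel: `channel`, `U`, `p_value`,
#'   `significant` (at the Bonferroni-corrected level, carried in attribute
#'   `corrected_level`).
#' @export
mwu_per_channel <- function(features, metric = c("RE", "TE", "LZC"),
                            alpha = 0.05, correct_m = NULL) {
  metric <- match.arg(metric)
  lv <- split_groups(features)
  cols <- grep(paste0("^", metric, "_C[0-9]+$"), names(features), value = TRUE)
  if (length(cols) == 0) stop("no columns found for metric ", metric)
  if (is.null(correct_m)) correct_m <- length(cols)
  level <- bonferroni_level(alpha, correct_m)
  res <- lapply(cols, function(cl) {
    x <- features[[cl]][features$group == lv[1]]
    y <- features[[cl]][features$group == lv[2]]
    exact <- length(x) <= 8 && length(y) <= 8
    wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                              exact = exact, correct = TRUE))
    data.frame(channel = sub(paste0("^", metric, "_"), "", cl),
               U = unname(wt$statistic), p_value = wt$p.value)
  })
  out <- do.call(rbind, res)
  out$significant <- out$p_value < level
  attr(out, "corrected_level") <- level
  attr(out, "groups") <- lv
  out
}

#' Bonferroni-corrected significance level
#'
#' Divides the family level by the number of comparisons; for the 19-channel
#' montage at `alpha = 0.05` this is `0.05 / 19 = 0.0026` (4 d.p.).
#'
#' @param alpha Significance level in (0, 1).
#' @param m Number of comparisons, >= 1.
#' @return The corrected level `alpha / m`, with the 4-decimal rounding
#'   carried in attribute `rounded`.
#' @export
#' @examples
#' bonferroni_level(0.05, 19)
bonferroni_level <- function(alpha, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (!is.numeric(m) || m < 1) stop("m must be >= 1")
  structure(alpha / m, rounded = round(alpha / m, 4))
}

#' Entropic-index sensitivity grid
#'
#' Recomputes the Tsallis features at each entropic index `q` of a grid and
#' runs [mwu_per_channel()] at each, assembling a q x channel matrix of
#' p-values with significance flags at the Bonferroni-corrected level. The
#' default grid is `q = -2, -1.9, ..., 2` excluding 1 (40 values).
#'
#' @param cohort_features_fn Either an `eeg_cohort` (Tsallis features are
#'   recomputed internally at each `q`) or a function `f(q)` returning a
#'   feature table with `TE_C*` columns.
#' @param q_grid Numeric grid of entropic indices; must not contain 1.
#' @param alpha Family significance level.
#' @param n_bins Histogram bins for the internal Tsallis recomputation.
#' @return Object of class `sensitivity_grid`: list with `q_values`,
#'   `channels`, `p_matrix` (q x channel), `significant` (logical matrix) and
#'   `corrected_level`.
#' @export
q_sensitivity <- function(cohort_features_fn,
                          q_grid = setdiff(round(seq(-2, 2, by = 0.1), 1), 1),
                          alpha = 0.05, n_bins = 100L) {
  q_grid <- round(as.numeric(q_grid), 10)
  if (any(q_grid == 1)) stop("q grid must exclude 1")
  feat_fn <- if (inherits(cohort_features_fn, "eeg_cohort")) {
    cohort <- cohort_features_fn
    sig <- lapply(cohort$recordings, function(r) r$data[montage_1020(), ,
                                                        drop = FALSE])
    grp <- vapply(cohort$recordings, `[[`, "", "group")
    function(q) {
      tp <- tsallis_params(q = q, n_bins = n_bins)
      te <- t(vapply(sig, function(m) apply(m, 1, tsallis_entropy, params = tp),
                     numeric(19)))
      colnames(te) <- paste0("TE_C", 1:19)
      data.frame(subject_id = vapply(cohort$recordings, `[[`, "", "subject_id"),
                 group = grp, te, check.names = FALSE)
    }
  } else {
    stopifnot(is.function(cohort_features_fn))
    cohort_features_fn
  }
  rows <- lapply(q_grid, function(q) {
    mwu_per_channel(feat_fn(q), metric = "TE", alpha = alpha)
  })
  channels <- rows[[1]]$channel
  p <- do.call(rbind, lapply(rows, `[[`, "p_value"))
  dimnames(p) <- list(sprintf("q=%g", q_grid), channels)
  level <- attr(rows[[1]], "corrected_level")
  structure(list(q_values = q_grid, channels = channels, p_matrix = p,
                 significant = p < level,
                 corrected_level = as.numeric(level)),
            class = "sensitivity_grid")
}

#' @export
print.sensitivity_grid <- function(x, ...) {
  cat(sprintf("<sensitivity_grid> %d q-values x %d channels; corrected level %.4g\n",
              length(x$q_values), length(x$channels), x$corrected_level))
  invisible(x)
}
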