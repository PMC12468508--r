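#' Matthews correlation coefficient from confusion counts
#'
#' `MCC = (tp * tn - fp * fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, with the
#' convention that the value is 0 whenever any factor of the denominator is 0.
#'
#' @param tp,fp,tn,fn Nonnegative confusion counts.
#' @return A value in `[-1, 1]`.
#' @export
#' @examples
#' compute_mcc(10, 0, 10, 0)  # 1
compute_mcc <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  d <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (d == 0) return(0)
  (tp * tn - fp * fn) / sqrt(d)
}

# Trapezoidal ROC area from scores for the positive class.
roc_area_trapezoid <- function(truth, score, positive) {
  ord <- order(score, decreasing = TRUE)
  y <- truth[ord] == positive
  s <- score[ord]
  # group tied scores so the curve is threshold-wise
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / sum(y))
  fpr <- c(0, fp[last] / sum(!y))
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

# Trapezoidal precision-recall area, starting the curve at recall 0 with the
# precision of the highest-score threshold group.
prc_area_trapezoid <- function(truth, score, positive) {
  ord <- order(score, decreasing = TRUE)
  y <- truth[ord] == positive
  s <- score[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); n_pred <- seq_along(y)
  last <- !duplicated(grp, fromLast = TRUE)
  rec <- tp[last] / sum(y)
  prec <- tp[last] / n_pred[last]
  rec <- c(0, rec); prec <- c(prec[1], prec)
  sum(diff(rec) * (prec[-1] + prec[-length(prec)]) / 2)
}

#' Evaluation report from pooled predictions
#'
#' Builds the per-class and weighted-average table of TP rate, FP rate,
#' precision, recall, F-measure, MCC, ROC area and PRC area from pooled
#' cross-validated predictions, plus overall accuracy. All metrics are
#' computed here (areas by the trapezoidal rule on pooled scores).
#'
#' @param truth Factor or character vector of true classes.
#' @param pred Predicted classes.
#' @param score Numeric score (probability) for `positive`.
#' @param positive Class whose probability `score` carries.
#' @param model,subset Identifiers stored in the report.
#' @return Object of class `evaluation_report`: a 3-row data frame
#'   (one row per class plus `Weighted Avg.`) with attributes `accuracy`,
#'   `confusion`, `model`, `subset`.
#' @export
evaluation_report <- function(truth, pred, score, positive = "ASD",
                              model = NA_character_, subset = NA_character_) {
  truth <- as.character(truth); pred <- as.character(pred)
  classes <- sort(unique(truth))
  stopifnot(length(classes) == 2, positive %in% classes)
  rows <- lapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    fp <- sum(truth != cl & pred == cl)
    tn <- sum(truth != cl & pred != cl)
    sc <- if (cl == positive) score else 1 - score
    data.frame(
      class = cl,
      tp_rate = if (tp + fn > 0) tp / (tp + fn) else 0,
      fp_rate = if (fp + tn > 0) fp / (fp + tn) else 0,
      precision = if (tp + fp > 0) tp / (tp + fp) else 0,
      recall = if (tp + fn > 0) tp / (tp + fn) else 0,
      f_measure = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0,
      mcc = compute_mcc(tp, fp, tn, fn),
      roc_area = roc_area_trapezoid(truth, sc, cl),
      prc_area = prc_area_trapezoid(truth, sc, cl))
  })
  tab <- do.call(rbind, rows)
  support <- vapply(classes, function(cl) sum(truth == cl), 0)
  w <- support / sum(support)
  wavg <- data.frame(class = "Weighted Avg.",
                     t(colSums(w * as.matrix(tab[, -1]))))
  names(wavg) <- names(tab)
  out <- rbind(tab, wavg)
  rownames(out) <- NULL
  structure(out,
            accuracy = mean(truth == pred),
            confusion = table(truth = truth, pred = pred),
            model = model, subset = subset,
            class = c("evaluation_report", "data.frame"))
}

#' @export
print.evaluation_report <- function(x, digits = 3, ...) {
  cat(sprintf("<evaluation_report> model %s, subset %s, accuracy %.3f\n",
              attr(x, "model"), attr(x, "subset"), attr(x, "accuracy")))
  print.data.frame(cbind(x[1], round(x[-1], digits)), row.names = FALSE)
  invisible(x)
}

# ---- model adapters ---------------------------------------------------------

# Each adapter fits on (x: data.frame, y: factor) and predicts
# list(class, score) on newdata; score is P(positive class = last level).
fit_predict <- function(model, x, y, newx, hp) {
  pos <- levels(y)[2]
  switch(model,
    random_forest = {
      fit <- randomForest::randomForest(x = x, y = y, ntree = hp$ntree)
      p <- stats::predict(fit, newx, type = "prob")[, pos]
      list(class = as.character(stats::predict(fit, newx)), score = p)
    },
    pruned_tree = {
      d <- data.frame(.y = y, x, check.names = FALSE)
      fit <- rpart::rpart(.y ~ ., data = d, method = "class",
                          control = rpart::rpart.control(cp = 0, xval = 10,
                                                         minsplit = 5))
      cp <- fit$cptable
      fit <- rpart::prune(fit, cp = cp[which.min(cp[, "xerror"]), "CP"])
      p <- stats::predict(fit, newx, type = "prob")[, pos]
      list(class = as.character(stats::predict(fit, newx, type = "class")),
           score = p)
    },
    rep_tree = {
      fit <- rep_tree_fit(x, y, grow_frac = hp$grow_frac)
      p <- stats::predict(fit, newx, type = "prob")[, pos]
      list(class = as.character(stats::predict(fit, newx, type = "class")),
           score = p)
    },
    svm = {
      fit <- e1071::svm(x = as.matrix(x), y = y, kernel = "radial",
                        probability = TRUE)
      pr <- stats::predict(fit, as.matrix(newx), probability = TRUE)
      p <- attr(pr, "probabilities")[, pos]
      list(class = as.character(pr), score = p)
    },
    mlp = {
      mu <- colMeans(x); sdv <- pmax(apply(x, 2, stats::sd), 1e-12)
      xs <- scale(x, mu, sdv)
      fit <- nnet::nnet(xs, as.numeric(y) - 1, size = hp$mlp_size,
                        decay = hp$mlp_decay, maxit = hp$mlp_maxit,
                        entropy = TRUE, trace = FALSE, MaxNWts = 10000)
      p <- as.numeric(stats::predict(fit, scale(newx, mu, sdv)))
      list(class = ifelse(p >= 0.5, pos, levels(y)[1]), score = p)
    },
    stop("unknown model: ", model))
}

# Reduced-error pruning analogue of a fast decision tree: grow an unpruned
# tree on a grow set (3:1 split), then bottom-up snip every internal node
# whose replacement by a leaf does not increase error on the prune set.
rep_tree_fit <- function(x, y, grow_frac = 0.75) {
  n <- length(y)
  idx <- unlist(lapply(split(seq_len(n), y), function(i)
    i[seq_len(max(1L, round(grow_frac * length(i))))]))
  grow <- sort(idx)
  prune_set <- setdiff(seq_len(n), grow)
  if (length(prune_set) == 0) prune_set <- grow
  d <- data.frame(.y = y, x, check.names = FALSE)
  fit <- rpart::rpart(.y ~ ., data = d[grow, ], method = "class",
                      control = rpart::rpart.control(cp = 0, xval = 0,
                                                     minsplit = 5))
  perr <- function(f)
    sum(stats::predict(f, d[prune_set, ], type = "class") != y[prune_set])
  nodes <- as.integer(rownames(fit$frame))[fit$frame$var != "<leaf>"]
  for (nd in sort(nodes, decreasing = TRUE)) {
    if (!nd %in% as.integer(rownames(fit$frame))) next  # already snipped away
    if (fit$frame$var[rownames(fit$frame) == as.character(nd)] == "<leaf>")
      next
    cand <- rpart::snip.rpart(fit, toss = nd)
    if (perr(cand) <= perr(fit)) fit <- cand
  }
  fit
}

#' Cross-validated classification suite
#'
#' Trains the five-model suite (random forest, cost-complexity pruned tree,
#' reduced-error-pruning tree, RBF SVM, single-hidden-layer MLP) on each
#' attribute subset under stratified k-fold cross-validation, pooling the
#' held-out fold predictions into one [evaluation_report()] per
#' (model, subset) pair. Deterministic given `seed`; fold assignment is shared
#' across models and subsets for comparability.
#'
#' @param features Feature table with `group` labels.
#' @param subsets Named list of attribute-name subsets (default: one subset
#'   with all feature columns).
#' @param models Models to run.
#' @param folds Number of folds; every class needs at least `folds` members.
#' @param seed Integer seed.
#' @param hyperparams List of pinned hyperparameters; see defaults.
#' @return Named list (`model.subset`) of `evaluation_report` objects; each
#'   carries its pooled predictions in attribute `predictions`.
#' @export
run_suite <- function(features, subsets = NULL,
                      models = c("random_forest", "pruned_tree", "rep_tree",
                                 "svm", "mlp"),
                      folds = 10, seed = 1,
                      hyperparams = list(ntree = 100, mlp_size = 20,
                                         mlp_decay = 0.01, mlp_maxit = 200,
                                         grow_frac = 0.75)) {
  y <- factor(features$group)
  if (nlevels(y) != 2) stop("need exactly two classes")
  if (any(table(y) < folds))
    stop("class with fewer than ", folds,
         " members; reduce the number of folds")
  xcols <- setdiff(names(features), c("subject_id", "group"))
  if (is.null(subsets)) subsets <- list(all = xcols)
  # stratified fold assignment
  set.seed(as.integer(seed %% 2147483647L))
  fold_id <- integer(length(y))
  for (cl in levels(y)) {
    i <- which(y == cl)
    fold_id[i] <- sample(rep_len(seq_len(folds), length(i)))
  }
  reports <- list()
  for (sn in names(subsets)) {
    cols <- subsets[[sn]]
    stopifnot(all(cols %in% xcols))
    x <- features[, cols, drop = FALSE]
    for (m in models) {
      pred <- character(length(y)); score <- numeric(length(y))
      for (f in seq_len(folds)) {
        tr <- fold_id != f; te <- !tr
        set.seed(as.integer((seed * 131 + f * 17 + match(m, models)) %%
                              2147483647))
        fp <- fit_predict(m, x[tr, , drop = FALSE], droplevels(y[tr]),
                          x[te, , drop = FALSE], hyperparams)
        pred[te] <- fp$class; score[te] <- fp$score
      }
      rep <- evaluation_report(as.character(y), pred, score,
                               positive = levels(y)[2], model = m,
                               subset = sn)
      attr(rep, "predictions") <- data.frame(truth = as.character(y),
                                             pred = pred, score = score,
                                             fold = fold_id)
      reports[[paste(m, sn, sep = ".")]] <- rep
    }
  }
  reports
}

#' Fit a single interpretable decision tree on the full table
#'
#' Convenience fit of a cost-complexity pruned `rpart` tree on all rows of a
#' feature table, for rule extraction with [extract_tree_rules()].
#'
#' @inheritParams run_suite
#' @param attributes Attribute subset to use (default all).
#' @param minsplit Minimum node size before a split is attempted.
#' @return An `rpart` fit.
#' @export
fit_decision_tree <- function(features, attributes = NULL, seed = 1,
                              minsplit = 5) {
  xcols <- setdiff(names(features), c("subject_id", "group"))
  if (is.null(attributes)) attributes <- xcols
  d <- data.frame(.y = factor(features$group),
                  features[, attributes, drop = FALSE], check.names = FALSE)
  set.seed(as.integer(seed %% 2147483647L))
  fit <- rpart::rpart(.y ~ ., data = d, method = "class",
                      control = rpart::rpart.control(cp = 0, xval = 10,
                                                     minsplit = minsplit))
  cp <- fit$cptable
  rpart::prune(fit, cp = cp[which.min(cp[, "xerror"]), "CP"])
}

#' Extract root-to-leaf decision rules from a fitted tree
#'
#' Converts each leaf of an `rpart` classification tree into a rule: the
#' ordered (feature, comparator, threshold) conditions on the path from the
#' root, the predicted class, and the training support. Rules like
#' `LZC_C15 < 0.2173 -> ASD` are directly usable as neurofeedback targets.
#'
#' @param tree A fitted `rpart` classification tree.
#' @return Object of class `tree_rules`: list of rules, each a list with
#'   `path` (data frame `feature`, `comparator`, `threshold`), `class`,
#'   `support`.
#' @export
extract_tree_rules <- function(tree) {
  if (!inherits(tree, "rpart")) stop("not a tree model (need an rpart fit)")
  frame <- tree$frame
  leaves <- as.integer(rownames(frame))[frame$var == "<leaf>"]
  ylev <- attr(tree, "ylevels")
  paths <- rpart::path.rpart(tree, nodes = leaves, print.it = FALSE)
  rules <- lapply(seq_along(leaves), function(i) {
    steps <- setdiff(paths[[i]], "root")
    path <- if (length(steps) == 0) {
      data.frame(feature = character(), comparator = character(),
                 threshold = numeric())
    } else {
      m <- regmatches(steps, regexec("^(.*?)(>=|<=|<|>)(.*)$", steps))
      data.frame(feature = vapply(m, `[`, "", 2),
                 comparator = vapply(m, `[`, "", 3),
                 threshold = as.numeric(vapply(m, `[`, "", 4)))
    }
    row <- which(rownames(frame) == as.character(leaves[i]))
    list(path = path, class = ylev[frame$yval[row]], support = frame$n[row])
  })
  structure(rules, class = "tree_rules")
}

#' @export
format.tree_rules <- function(x, digits = 4, ...) {
  vapply(x, function(r) {
    cond <- if (nrow(r$path) == 0) "TRUE"
      else paste(sprintf("%s %s %.*g", r$path$feature, r$path$comparator,
                         digits, r$path$threshold), collapse = " & ")
    sprintf("%s -> %s (n = %d)", cond, r$class, r$support)
  }, "")
}

#' @export
print.tree_rules <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}
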