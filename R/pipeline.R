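#' Pipeline configuration
#'
#' Bundles every stage's parameters behind one object with one global seed.
#' Defaults reflect the analysis conditions this package emulates: 19 channels
#' at 250 Hz, Renyi `alpha = 2`, Tsallis `q = 1.5` with 100 bins, normalized
#' LZ76 complexity, Bonferroni-corrected Mann-Whitney tests, gain-ratio
#' subsets of sizes 57/15/10/5, five models under stratified 10-fold
#' cross-validation, and t-SNE embeddings.
#'
#' @param n_td,n_asd Synthetic group sizes (study design: 39 TD, 49 ASD).
#' @param config A [recording_config()].
#' @param effect A [group_effect()].
#' @param rules A [rejection_rules()].
#' @param renyi,tsallis,lzc Metric parameter objects.
#' @param alpha Family significance level for the group tests.
#' @param sensitivity Run the entropic-index sensitivity grid (adds
#'   considerable compute).
#' @param k_list Attribute-subset sizes for the training setups.
#' @param models Classifier identifiers for [run_suite()].
#' @param folds Cross-validation folds.
#' @param perplexity t-SNE perplexity.
#' @param seed Global integer seed governing all randomness.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_td = 39, n_asd = 49,
                            config = recording_config(duration = 60),
                            effect = group_effect("ASD", delta = 0.3,
                                                  effect_channels =
                                                    montage_1020()),
                            rules = rejection_rules(),
                            renyi = renyi_params(),
                            tsallis = tsallis_params(),
                            lzc = lzc_params(),
                            alpha = 0.05, sensitivity = FALSE,
                            k_list = c(57, 15, 10, 5),
                            models = c("random_forest", "pruned_tree",
                                       "rep_tree", "svm", "mlp"),
                            folds = 10, perplexity = 30, seed = 1) {
  structure(list(n_td = n_td, n_asd = n_asd, config = config, effect = effect,
                 rules = rules, renyi = renyi, tsallis = tsallis, lzc = lzc,
                 alpha = alpha, sensitivity = sensitivity, k_list = k_list,
                 models = models, folds = folds, perplexity = perplexity,
                 seed = seed),
            class = "pipeline_config")
}

# Attribute subsets for the training setups: the full set plus gain-ratio
# top-k subsets for every k not exceeding the number of ranked attributes.
build_subsets <- function(features, ranking, k_list) {
  xcols <- setdiff(names(features), c("subject_id", "group"))
  subsets <- list()
  for (k in sort(k_list, decreasing = TRUE)) {
    subsets[[paste0("top", k)]] <-
      if (k >= length(xcols)) xcols
      else ranking$attribute[seq_len(min(k, nrow(ranking)))]
  }
  subsets
}

#' Run the full analysis pipeline
#'
#' simulate (or ingest) -> preprocess -> extract features -> group statistics
#' (optionally the q-sensitivity grid) -> attribute ranking -> cross-validated
#' classification with rule extraction -> t-SNE embedding with separation
#' score. All randomness derives from `cfg$seed`. If `out_dir` is given, every
#' stage's outputs plus the effective configuration are serialized (CSV for
#' tables, JSON for nested reports).
#'
#' @param cfg A [pipeline_config()].
#' @param cohort Optionally, an existing `eeg_cohort` to analyse instead of
#'   simulating one.
#' @param out_dir Optional output directory.
#' @param verbose Print stage progress.
#' @return A report bundle: list with `cohort`, `features`, `stats`,
#'   `sensitivity`, `ranking_ig`, `ranking_gr`, `subsets`, `reports`,
#'   `rules`, `embedding`, `silhouette`, `config`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), cohort = NULL,
                         out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(...) if (verbose)
    message(format(Sys.time(), "%H:%M:%S"), " [", ..., "]")
  stage <- function(name, expr) {
    say(name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (is.null(cohort))
    cohort <- stage("simulate",
                    generate_cohort(cfg$n_td, cfg$n_asd, cfg$config,
                                    cfg$effect, cfg$seed))
  cohort <- stage("preprocess", preprocess_cohort(cohort, cfg$rules))
  features <- stage("extract",
                    extract_feature_table(cohort, renyi = cfg$renyi,
                                          tsallis = cfg$tsallis,
                                          lzc = cfg$lzc))
  stats <- stage("stats", lapply(
    stats::setNames(nm = c("RE", "TE", "LZC")),
    function(m) mwu_per_channel(features, metric = m, alpha = cfg$alpha)))
  sens <- if (cfg$sensitivity)
    stage("sensitivity", q_sensitivity(cohort, alpha = cfg$alpha,
                                       n_bins = cfg$tsallis$n_bins))
  ig <- stage("rank", info_gain(features))
  gr <- gain_ratio(features)
  subsets <- build_subsets(features, gr, cfg$k_list)
  reports <- stage("classify",
                   run_suite(features, subsets = subsets,
                             models = cfg$models, folds = cfg$folds,
                             seed = cfg$seed))
  tree <- stage("rules", fit_decision_tree(features, seed = cfg$seed))
  rules <- extract_tree_rules(tree)
  emb <- stage("embed", embed_concat(features, perplexity = cfg$perplexity,
                                     seed = cfg$seed))
  sil <- separation_score(emb, features$group)
  bundle <- list(cohort = cohort, features = features, stats = stats,
                 sensitivity = sens, ranking_ig = ig, ranking_gr = gr,
                 subsets = subsets, reports = reports, rules = rules,
                 embedding = emb, silhouette = sil, config = cfg)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

# Serialize a pipeline bundle: CSV tables, JSON reports, config echo.
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(bundle$features, file.path(out_dir, "features.csv"))
  for (m in names(bundle$stats))
    utils::write.csv(bundle$stats[[m]],
                     file.path(out_dir, paste0("stats_", m, ".csv")),
                     row.names = FALSE)
  if (!is.null(bundle$sensitivity))
    utils::write.csv(
      data.frame(q = bundle$sensitivity$q_values, bundle$sensitivity$p_matrix,
                 check.names = FALSE),
      file.path(out_dir, "sensitivity.csv"), row.names = FALSE)
  utils::write.csv(bundle$ranking_ig, file.path(out_dir, "ranking_ig.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$ranking_gr, file.path(out_dir, "ranking_gr.csv"),
                   row.names = FALSE)
  reports <- lapply(bundle$reports, function(r)
    list(model = attr(r, "model"), subset = attr(r, "subset"),
         accuracy = attr(r, "accuracy"),
         table = as.data.frame(r)))
  jsonlite::write_json(reports, file.path(out_dir, "reports.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(format(bundle$rules), file.path(out_dir, "rules.txt"))
  utils::write.csv(
    data.frame(subject_id = rownames(bundle$embedding$coordinates),
               bundle$embedding$coordinates,
               group = bundle$features$group),
    file.path(out_dir, "embedding.csv"), row.names = FALSE)
  cfg <- bundle$config
  cfg_plain <- rapply(unclass(cfg), unclass, how = "replace")
  jsonlite::write_json(list(config = cfg_plain,
                            silhouette = bundle$silhouette),
                       file.path(out_dir, "config_echo.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}
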