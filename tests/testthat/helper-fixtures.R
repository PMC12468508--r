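# Shared fixtures, built once per test run and memoized (cohort generation and
# feature extraction dominate the suite's runtime).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures))
    assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

# a short clean recording (19 channels, 2 s)
small_recording <- function() fixture("small_recording",
  generate_recording(recording_config(duration = 2), group_effect("TD"),
                     seed = 11))

# study-condition cohort at reduced scale: group effect on all 19 channels
planted_features <- function() fixture("planted_features", {
  coh <- generate_cohort(20, 20, recording_config(duration = 10),
                         group_effect("ASD", delta = 0.3,
                                      effect_channels = montage_1020()),
                         seed = 101)
  extract_feature_table(coh)
})

# zero-effect cohort of the same shape
null_features <- function() fixture("null_features", {
  coh <- generate_cohort(20, 20, recording_config(duration = 10),
                         group_effect("ASD", delta = 0), seed = 202)
  extract_feature_table(coh)
})

# synthetic feature-level table: `informative` columns get a group mean shift
synth_feature_table <- function(n_per_group = 20, informative = character(),
                                shift = 2.5, seed = 1) {
  set.seed(seed)
  cols <- feature_names()
  n <- 2 * n_per_group
  grp <- rep(c("TD", "ASD"), each = n_per_group)
  tab <- as.data.frame(matrix(stats::rnorm(n * length(cols)), n,
                              dimnames = list(NULL, cols)))
  for (cl in informative)
    tab[[cl]] <- tab[[cl]] + shift * (grp == "ASD")
  data.frame(subject_id = sprintf("S%02d", seq_len(n)), group = grp, tab,
             check.names = FALSE)
}

# independent brute-force LZ76 oracle: string-based novelty scan
lz76_oracle <- function(bits) {
  s <- paste(bits, collapse = "")
  n <- nchar(s)
  pos <- 1L
  count <- 0L
  while (pos <= n) {
    len <- 1L
    repeat {
      word <- substr(s, pos, pos + len - 1L)
      prefix <- substr(s, 1L, pos + len - 2L)
      if (!grepl(word, prefix, fixed = TRUE)) break       # novel word
      if (pos + len - 1L == n) break                      # terminal word
      len <- len + 1L
    }
    count <- count + 1L
    pos <- pos + len
  }
  count
}

# independent brute-force silhouette oracle (plain loops)
silhouette_oracle <- function(coords, labels) {
  D <- as.matrix(stats::dist(coords))
  vals <- numeric(nrow(coords))
  for (i in seq_len(nrow(coords))) {
    same <- which(labels == labels[i] & seq_along(labels) != i)
    if (length(same) == 0) { vals[i] <- 0; next }
    a <- mean(D[i, same])
    b <- Inf
    for (l in unique(labels[labels != labels[i]]))
      b <- min(b, mean(D[i, labels == l]))
    vals[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(vals)
}
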