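#' Parameter objects for the complexity metrics
#'
#' Constructors for the tunable parameters of the three per-channel metrics.
#' Defaults follow the analysis this package implements: Renyi order
#' `alpha = 2` (emphasis on frequent amplitude patterns rather than rare
#' events), Tsallis entropic index `q = 1.5` with a 100-bin equal-width
#' histogram on the per-channel data range, and normalized Lempel-Ziv
#' complexity under LZ76 parsing.
#'
#' @param alpha Renyi order, `> 0` and `!= 1`.
#' @param resolution Maximum number of quadrature subdivisions.
#' @return A parameter object (`renyi_params`, `tsallis_params` or
#'   `lzc_params`).
#' @export
renyi_params <- function(alpha = 2, resolution = 1000L) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha == 1)
    stop("alpha must be > 0 and != 1")
  structure(list(alpha = alpha, resolution = as.integer(resolution)),
            class = "renyi_params")
}

#' @rdname renyi_params
#' @param q Tsallis entropic index, `!= 1`.
#' @param n_bins Number of equal-width histogram bins (>= 2).
#' @export
tsallis_params <- function(q = 1.5, n_bins = 100L) {
  if (!is.numeric(q) || q == 1) stop("q must not equal 1")
  if (n_bins < 2) stop("n_bins must be >= 2")
  structure(list(q = q, n_bins = as.integer(n_bins)), class = "tsallis_params")
}

#' @rdname renyi_params
#' @param normalized Report `c(n) * log2(n) / n` instead of the raw word
#'   count `c(n)`.
#' @export
lzc_params <- function(normalized = TRUE) {
  structure(list(normalized = isTRUE(normalized), variant = "LZ76"),
            class = "lzc_params")
}

#' Gaussian kernel density estimate of an amplitude distribution
#'
#' Estimates the probability density of a signal's amplitude values with a
#' Gaussian kernel and Silverman's rule-of-thumb bandwidth
#' ([stats::bw.nrd0()]). The estimate is the exact kernel mixture (not a
#' binned approximation), evaluable at arbitrary points, with support taken
#' as `[min - 4h, max + 4h]`.
#'
#' @param signal Numeric amplitude series, length >= 1, nonzero variance
#'   (length-1 signals use `h = 1`).
#' @param bandwidth Either `"silverman"` or a positive number.
#' @return Object of class `density_estimate` with fields `data`, `h`,
#'   `support`; evaluate it with [pdf_eval()].
#' @export
#' @examples
#' de <- estimate_pdf(rnorm(500))
#' pdf_eval(de, 0)
estimate_pdf <- function(signal, bandwidth = "silverman") {
  signal <- as.numeric(signal)
  if (length(signal) < 1) stop("signal must be nonempty")
  if (length(signal) >= 2 && stats::sd(signal) == 0)
    stop("degenerate density: constant signal")
  h <- if (identical(bandwidth, "silverman")) {
    if (length(signal) == 1) 1 else stats::bw.nrd0(signal)
  } else {
    stopifnot(is.numeric(bandwidth), bandwidth > 0)
    bandwidth
  }
  structure(list(data = signal, h = h,
                 support = c(min(signal) - 4 * h, max(signal) + 4 * h)),
            class = "density_estimate")
}

#' @rdname estimate_pdf
#' @param de A `density_estimate`.
#' @param x Query points.
#' @return `pdf_eval()` returns the nonnegative density values at `x`.
#' @export
pdf_eval <- function(de, x) {
  # chunked kernel-mixture evaluation to bound the m x n workspace
  n <- length(de$data)
  out <- numeric(length(x))
  chunk <- max(1L, floor(5e6 / n))
  for (i0 in seq(1L, length(x), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, length(x))
    m <- outer(x[i0:i1], de$data, function(a, b) stats::dnorm(a - b, sd = de$h))
    out[i0:i1] <- rowMeans(m)
  }
  out
}

#' Renyi entropy of a continuous signal via kernel density estimation
#'
#' Computes the order-`alpha` Renyi entropy
#' `H_a = log(integral f(x)^a dx) / (1 - a)` (natural log, nats) of the
#' amplitude distribution, with `f` the Gaussian KDE of [estimate_pdf()] and
#' the integral evaluated by adaptive quadrature over the KDE support. This
#' avoids discretizing the amplitudes into bins. `alpha > 1` emphasizes
#' frequent amplitude patterns; `alpha -> 1` recovers Shannon entropy (not an
#' admissible value here).
#'
#' @param signal Numeric amplitude series (length >= 1, nonzero variance).
#' @param params A [renyi_params()].
#' @param bandwidth Passed to [estimate_pdf()].
#' @return Entropy in nats.
#' @export
#' @examples
#' renyi_entropy(rnorm(1000))  # close to 0.5 * log(4 * pi) for N(0, 1)
renyi_entropy <- function(signal, params = renyi_params(),
                          bandwidth = "silverman") {
  stopifnot(inherits(params, "renyi_params"))
  de <- estimate_pdf(signal, bandwidth)
  a <- params$alpha
  I <- stats::integrate(function(x) pdf_eval(de, x)^a,
                        lower = de$support[1], upper = de$support[2],
                        subdivisions = params$resolution,
                        rel.tol = 1e-9)$value
  log(I) / (1 - a)
}

#' @rdname renyi_entropy
#' @details `renyi_entropy_closed2()` is the exact closed form for
#'   `alpha = 2`: the integral of the squared kernel mixture is a double sum
#'   of Gaussian convolutions,
#'   `(1/n^2) * sum_ij dnorm(x_i - x_j, sd = sqrt(2) h)`. It is `O(n^2)` and
#'   intended as a cross-check of the quadrature path.
#' @export
renyi_entropy_closed2 <- function(signal, bandwidth = "silverman") {
  de <- estimate_pdf(signal, bandwidth)
  d <- outer(de$data, de$data, "-")
  I <- mean(stats::dnorm(d, sd = sqrt(2) * de$h))
  -log(I)
}

#' Tsallis entropy of a discretized amplitude distribution
#'
#' Computes `S_q = (1 - sum_i p_i^q) / (q - 1)` with probabilities `p_i` from
#' an equal-width histogram over `[min(signal), max(signal)]`. The sum runs
#' over nonzero-probability bins only, which keeps `p^q` finite for `q < 0`.
#' `q -> 1` recovers the Shannon entropy of the same histogram (in nats);
#' a constant signal puts all mass in a single bin and returns 0.
#'
#' @param signal Numeric amplitude series, length >= 2.
#' @param params A [tsallis_params()].
#' @return Dimensionless entropy.
#' @export
#' @examples
#' tsallis_entropy(c(1, 2, 3, 4), tsallis_params(q = 2, n_bins = 4))  # 0.75
tsallis_entropy <- function(signal, params = tsallis_params()) {
  stopifnot(inherits(params, "tsallis_params"))
  signal <- as.numeric(signal)
  if (length(signal) < 2) stop("signal must have length >= 2")
  q <- params$q
  rng <- range(signal)
  if (rng[1] == rng[2]) return(0)  # single-bin convention
  breaks <- seq(rng[1], rng[2], length.out = params$n_bins + 1L)
  idx <- findInterval(signal, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(idx, nbins = params$n_bins)
  p <- counts[counts > 0] / length(signal)
  (1 - sum(p^q)) / (q - 1)
}

#' Binarize a signal at its mean amplitude
#'
#' Maps each sample to 1 where the amplitude is greater than or equal to the
#' signal mean and to 0 below it (ties at the threshold map to 1). This is the
#' symbolization step feeding the Lempel-Ziv complexity.
#'
#' @param signal Numeric amplitude series, nonempty.
#' @return Object of class `binary_seq`: integer 0/1 vector with attribute
#'   `threshold` (the mean, in signal units).
#' @export
#' @examples
#' binarize(c(1, 2, 3, 4))  # 0 0 1 1
binarize <- function(signal) {
  signal <- as.numeric(signal)
  if (length(signal) == 0) stop("signal must be nonempty")
  thr <- mean(signal)
  structure(as.integer(signal >= thr), threshold = thr, class = "binary_seq")
}

# Coerce 0/1 input (binary_seq, numeric vector, or a single string like
# "0110") to an integer 0/1 vector.
as_bits <- function(seq) {
  if (inherits(seq, "binary_seq")) return(as.integer(unclass(seq)))
  if (is.character(seq) && length(seq) == 1)
    seq <- if (nzchar(seq)) strsplit(seq, "")[[1]] else character()
  bits <- suppressWarnings(as.integer(seq))
  if (length(bits) && (anyNA(bits) || any(bits != 0 & bits != 1)))
    stop("sequence contains non-binary symbols")
  bits
}

#' LZ76 parse of a binary sequence
#'
#' Scans the sequence left to right, growing the current word while it still
#' occurs as a substring of the already-scanned prefix (overlap allowed), and
#' emitting it at first novelty; a terminal partial word is counted. The
#' number of emitted words is the Lempel-Ziv complexity `c(n)`. For example,
#' `"011001011110"` parses into 6 words.
#'
#' @param seq A `binary_seq`, a 0/1 vector, or a single string of 0/1
#'   characters.
#' @return Character vector of the parsed words, in order.
#' @export
#' @examples
#' lz_parse("011001011110")  # 6 words
lz_parse <- function(seq) {
  bits <- as_bits(seq)
  if (length(bits) == 0) return(character())
  lens <- .lz76_word_lengths(bits)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  s <- paste(bits, collapse = "")
  substring(s, starts, ends)
}

#' Lempel-Ziv complexity
#'
#' Raw complexity is the LZ76 word count `c(n)` of [lz_parse()]; the
#' normalized value is `c(n) * log2(n) / n`, which tends to 1 for an i.i.d.
#' fair-coin sequence and is small for periodic sequences. Normalized values
#' are on the scale of interpretable decision thresholds such as
#' `LZC_C15 <= 0.2173`.
#'
#' @inheritParams lz_parse
#' @param params An [lzc_params()].
#' @return Raw word count, or the normalized complexity.
#' @export
#' @examples
#' lz_complexity("011001011110", lzc_params(normalized = FALSE))  # 6
lz_complexity <- function(seq, params = lzc_params()) {
  stopifnot(inherits(params, "lzc_params"))
  bits <- as_bits(seq)
  cn <- length(.lz76_word_lengths(bits))
  if (!params$normalized) return(cn)
  n <- length(bits)
  if (n < 2) stop("normalized LZC needs length >= 2")
  cn * log2(n) / n
}

#' Count distinct overlapping k-grams
#'
#' Number of distinct length-`k` substrings of the binary sequence, counted
#' with overlap. The alternating sequence `"0101..."` has exactly two distinct
#' bigrams, `01` and `10`.
#'
#' @inheritParams lz_parse
#' @param k Substring length, `1 <= k <= length(seq)`.
#' @return Integer count.
#' @export
#' @examples
#' distinct_kgrams("010101010101", 2)  # 2
distinct_kgrams <- function(seq, k) {
  bits <- as_bits(seq)
  n <- length(bits)
  if (k < 1 || k > n) stop("k must be in [1, length(seq)]")
  s <- paste(bits, collapse = "")
  length(unique(substring(s, 1:(n - k + 1L), k:n)))
}

#' Extract the 57-value feature vector of a recording
#'
#' Computes, per channel, the KDE-based Renyi entropy, the Tsallis entropy and
#' the (normalized) Lempel-Ziv complexity of the mean-binarized signal, and
#' assembles them in the fixed order RE over channels C1..C19, then TE, then
#' LZC — `3 * 19 = 57` attributes for the standard montage.
#'
#' @param recording An `eeg_recording` whose channels match the 10/20 montage
#'   of [montage_1020()].
#' @param renyi,tsallis,lzc Parameter objects.
#' @return Named numeric vector of length `3 * n_channels` (class
#'   `feature_vector`) with attributes `subject_id` and `group`.
#' @export
extract_features <- function(recording, renyi = renyi_params(),
                             tsallis = tsallis_params(), lzc = lzc_params()) {
  labs <- recording$config$channel_labels
  ref <- montage_1020()
  missing <- setdiff(ref, labs)
  if (length(missing) > 0 || length(labs) != length(ref))
    stop("recording does not match the 19-channel montage; missing: ",
         if (length(missing)) paste(missing, collapse = ", ") else "none",
         "; extra: ", paste(setdiff(labs, ref), collapse = ", "))
  data <- recording$data[ref, , drop = FALSE]  # normalize channel order
  re <- apply(data, 1, renyi_entropy, params = renyi)
  te <- apply(data, 1, tsallis_entropy, params = tsallis)
  lz <- apply(data, 1, function(x) lz_complexity(binarize(x), params = lzc))
  out <- c(re, te, lz)
  names(out) <- feature_names(ref)
  structure(out, subject_id = recording$subject_id, group = recording$group,
            class = "feature_vector")
}

#' Feature table of a cohort
#'
#' Applies [extract_features()] to every recording and binds the results into
#' a subjects x features data frame with `subject_id` and `group` columns
#' followed by the 57 feature columns.
#'
#' @param cohort An `eeg_cohort` of trimmed recordings.
#' @inheritParams extract_features
#' @return A `data.frame` with `n_subjects` rows.
#' @export
extract_feature_table <- function(cohort, renyi = renyi_params(),
                                  tsallis = tsallis_params(),
                                  lzc = lzc_params()) {
  fvs <- lapply(cohort$recordings, extract_features,
                renyi = renyi, tsallis = tsallis, lzc = lzc)
  tab <- as.data.frame(do.call(rbind, lapply(fvs, unclass)))
  data.frame(subject_id = vapply(fvs, attr, "", "subject_id"),
             group = vapply(fvs, attr, "", "group"),
             tab, row.names = NULL, check.names = FALSE)
}
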