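test_that("kernel density estimate matches analytic values and normalizes", {
  set.seed(4)
  x <- rnorm(1000)
  de <- estimate_pdf(x)
  expect_equal(pdf_eval(de, 0), stats::dnorm(0), tolerance = 0.05 / 0.3989)
  I <- stats::integrate(function(q) pdf_eval(de, q), de$support[1],
                        de$support[2], rel.tol = 1e-9)$value
  expect_equal(I, 1, tolerance = 1e-3)
  expect_error(estimate_pdf(rep(3, 50)), "degenerate")
})

test_that("Renyi entropy: closed forms, quadrature agreement, monotonicity", {
  # one-sample KDE is a single Gaussian of width h: H_2 = 0.5 log(4 pi h^2)
  expect_equal(renyi_entropy(0, renyi_params(alpha = 2)),
               0.5 * log(4 * pi), tolerance = 1e-6)

  # Gaussian signal: H_2 -> 0.5 log(4 pi sigma^2)
  set.seed(7)
  x <- rnorm(5000)
  expect_equal(renyi_entropy(x), 0.5 * log(4 * pi), tolerance = 0.05)

  # quadrature vs exact pairwise-kernel closed form at alpha = 2
  for (s in 1:5) {
    set.seed(100 + s)
    y <- rnorm(200) * runif(1, 0.5, 3) + runif(1, -5, 5)
    expect_equal(renyi_entropy(y), renyi_entropy_closed2(y),
                 tolerance = 1e-6)
  }

  # order-monotonicity: H_alpha non-increasing in alpha
  set.seed(8)
  z <- rnorm(500)
  h <- vapply(c(0.5, 2, 5),
              function(a) renyi_entropy(z, renyi_params(alpha = a)), 0)
  expect_true(all(diff(h) <= 1e-9))

  expect_error(renyi_params(alpha = 1), "alpha")
  expect_error(renyi_params(alpha = -2), "alpha")
})

test_that("Renyi entropy is shift-invariant and log-covariant in scale", {
  set.seed(9)
  x <- rnorm(2000)
  expect_equal(renyi_entropy(x + 100), renyi_entropy(x), tolerance = 1e-6)
  for (s in c(2, 10))
    expect_equal(renyi_entropy(s * x) - renyi_entropy(x), log(s),
                 tolerance = 0.05)
})

test_that("Tsallis entropy matches analytic cases and the Shannon limit", {
  # uniform mass over 4 bins at q = 2: (1 - 4/16) / 1 = 0.75
  expect_equal(tsallis_entropy(c(1, 2, 3, 4),
                               tsallis_params(q = 2, n_bins = 4)), 0.75)
  # all mass in one bin
  expect_equal(tsallis_entropy(rep(5, 10), tsallis_params(q = 2)), 0)
  expect_equal(tsallis_entropy(c(1, 1, 1, 1.0000001),
                               tsallis_params(q = -1, n_bins = 2)),
               tsallis_entropy(c(2, 2, 2, 2.0000001),
                               tsallis_params(q = -1, n_bins = 2)))

  # q -> 1 recovers the Shannon entropy of the same histogram (nats)
  set.seed(10)
  x <- rnorm(3000)
  breaks <- seq(min(x), max(x), length.out = 101)
  counts <- table(cut(x, breaks, include.lowest = TRUE))
  p <- counts[counts > 0] / length(x)
  shannon <- -sum(p * log(p))
  for (q in c(1 - 1e-4, 1 + 1e-4))
    expect_equal(tsallis_entropy(x, tsallis_params(q = q)), shannon,
                 tolerance = 1e-3)

  # uniform closed form (1 - n^(1-q)) / (q - 1), exact over occupied bins
  u <- rep(seq_len(10), 7)
  for (q in c(-1, 0.5, 2, 3))
    expect_equal(tsallis_entropy(u, tsallis_params(q = q, n_bins = 10)),
                 (1 - 10^(1 - q)) / (q - 1), tolerance = 1e-12)

  expect_error(tsallis_params(q = 1), "q")
  expect_error(tsallis_entropy(5, tsallis_params()), "length")
})

test_that("binarization thresholds at the mean with ties mapping to 1", {
  expect_equal(as.integer(binarize(c(1, 2, 3, 4))), c(0, 0, 1, 1))
  expect_equal(as.integer(binarize(rep(2, 5))), rep(1L, 5))
  # one full sine period sampled at 12 points: six above, six below the mean
  s <- sin(2 * pi * (0:11) / 12 + 0.1)
  expect_equal(sum(binarize(s) == 1), 6)
  expect_error(binarize(numeric()), "nonempty")
})

test_that("LZ76 parsing reproduces hand counts", {
  expect_length(lz_parse("011001011110"), 6)
  expect_equal(paste(lz_parse("011001011110"), collapse = ""),
               "011001011110")  # words tile the sequence
  expect_length(lz_parse(""), 0)
  expect_length(lz_parse(strrep("0", 100)), 2)
  expect_length(lz_parse("010101010101"), 3)
  expect_error(lz_parse("0120"), "non-binary")
})

test_that("LZ76 parse count equals the brute-force novelty-scan oracle", {
  for (len in 1:10) {
    for (v in 0:(2^len - 1)) {
      bits <- as.integer(intToBits(v))[seq_len(len)]
      expect_equal(lz_complexity(bits, lzc_params(normalized = FALSE)),
                   lz76_oracle(bits),
                   info = paste(bits, collapse = ""))
    }
  }
})

test_that("normalized LZC separates periodic from random sequences", {
  expect_equal(lz_complexity("011001011110", lzc_params(normalized = FALSE)),
               6)
  set.seed(12)
  shuffled <- sample(rep(0:1, 500))
  periodic <- rep(0:1, 500)
  expect_gt(lz_complexity(shuffled), lz_complexity(periodic))
  coin <- sample(0:1, 1e4, replace = TRUE)
  expect_gt(lz_complexity(coin), 0.8)
  expect_lt(lz_complexity(coin), 1.2)
  expect_error(lz_complexity("1"), "length >= 2")
})

test_that("distinct k-gram counting is exact", {
  expect_equal(distinct_kgrams("010101010101", 2), 2)
  expect_equal(distinct_kgrams("011001011110", 1), 2)
  expect_equal(distinct_kgrams("0110", 2), 3)  # {01, 11, 10}
  expect_error(distinct_kgrams("0110", 5), "k must be")
  expect_error(distinct_kgrams("0110", 0), "k must be")
})

test_that("feature extraction yields the ordered 57-vector", {
  fv <- extract_features(small_recording())
  expect_length(fv, 57)
  expect_equal(names(fv)[c(1, 20, 39, 57)],
               c("RE_C1", "TE_C1", "LZC_C1", "LZC_C19"))
  expect_true(all(is.finite(fv)))
  expect_identical(attr(fv, "group"), "TD")

  broken <- small_recording()
  broken$data <- broken$data[-19, ]
  broken$config$channel_labels <- broken$config$channel_labels[-19]
  broken$config$n_channels <- 18L
  expect_error(extract_features(broken), "O2")
})

test_that("features are invariant to a constant amplitude offset", {
  rec <- small_recording()
  shifted <- rec
  shifted$data <- shifted$data + 10
  f0 <- extract_features(rec)
  f1 <- extract_features(shifted)
  expect_equal(unclass(f1)[1:19], unclass(f0)[1:19], tolerance = 1e-6)
  expect_equal(unclass(f1)[20:57], unclass(f0)[20:57], tolerance = 1e-9)
})
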