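test_that("generation is deterministic and dimensionally exact", {
  cfg <- recording_config(duration = 2)
  eff <- group_effect("TD")
  r1 <- generate_recording(cfg, eff, seed = 5)
  r2 <- generate_recording(cfg, eff, seed = 5)
  expect_identical(r1$data, r2$data)
  expect_false(identical(r1$data,
                         generate_recording(cfg, eff, seed = 6)$data))

  r43 <- generate_recording(recording_config(duration = 43),
                            group_effect("TD"), seed = 1)
  expect_identical(dim(r43$data), c(19L, 10750L))
  expect_true(all(is.finite(r43$data)))
})

test_that("amplitudes stay in a physiologic range", {
  r <- small_recording()
  expect_equal(unname(apply(r$data, 1, sd)), rep(10, 19), tolerance = 1e-9)
  expect_lt(max(abs(r$data)), 80)
})

test_that("configuration invariants are enforced", {
  expect_error(recording_config(duration = 0), "duration")
  expect_error(recording_config(fs = -1), "fs")
  expect_error(recording_config(n_channels = 5), "channel_labels")
  expect_error(group_effect("TD", noise_mix = 1.2), "noise_mix")
})

test_that("cohort generation yields labelled, distinct subjects", {
  cfg <- recording_config(duration = 1)
  coh <- generate_cohort(39, 49, cfg, group_effect(), seed = 3)
  expect_length(coh$recordings, 88)
  grp <- vapply(coh$recordings, `[[`, "", "group")
  expect_equal(sum(grp == "TD"), 39)
  expect_equal(sum(grp == "ASD"), 49)
  # per-subject seeds distinct: no two subjects identical
  first_rows <- t(vapply(coh$recordings, function(r) r$data[1, 1:50],
                         numeric(50)))
  expect_equal(nrow(unique(first_rows)), 88)
  expect_error(generate_cohort(0, 5, cfg, group_effect(), 1), ">= 1")
})

test_that("injected artifacts exceed their thresholds and stay local", {
  rec <- generate_recording(recording_config(duration = 6),
                            group_effect("TD"), seed = 5)
  fs <- rec$config$fs
  ep3 <- 501:750

  spiked <- inject_artifacts(rec, "spike", epoch_index = 3)
  expect_gt(max(abs(spiked$data[1, ep3])), 100)
  # locality: all other samples and channels untouched
  expect_identical(spiked$data[1, -ep3], rec$data[1, -ep3])
  expect_identical(spiked$data[-1, ], rec$data[-1, ])

  # band-filter oracle: 20-35 Hz amplitude of the contaminated epoch > 35 uV
  fast <- inject_artifacts(rec, "fast", epoch_index = 3)
  bf <- signal::butter(4, c(20, 35) / (fs / 2), type = "pass")
  filt <- as.numeric(signal::filtfilt(bf, fast$data[1, ]))
  expect_gt(diff(range(filt[ep3])) / 2, 35)

  expect_error(inject_artifacts(rec, "spike", epoch_index = 99), "outside")
  expect_error(inject_artifacts(rec, "wobble", 1))
})

test_that("with no group effect, metric distributions are exchangeable", {
  cfg <- recording_config(n_channels = 1, channel_labels = "Cz",
                          fs = 250, duration = 2)
  eff <- group_effect("ASD", delta = 0)
  te_of <- function(group, seeds) vapply(seeds, function(s) {
    e <- eff; e$group <- group
    tsallis_entropy(generate_recording(cfg, e, seed = s)$data[1, ])
  }, 0)
  td <- te_of("TD", 1:30)
  asd <- te_of("ASD", 31:60)
  expect_gt(stats::ks.test(td, asd)$p.value, 0.05)
})

test_that("metrics increase monotonically with the broadband share", {
  cfg <- recording_config(n_channels = 1, channel_labels = "Cz",
                          fs = 250, duration = 4)
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  means <- sapply(grid, function(m) {
    vals <- sapply(1:20, function(r) {
      eff <- group_effect("TD", noise_mix = m, subject_sd = 0)
      x <- generate_recording(cfg, eff, seed = 9000 + 37 * r)$data[1, ]
      c(re = renyi_entropy(x), te = tsallis_entropy(x),
        lzc = lz_complexity(binarize(x)))
    })
    rowMeans(vals)
  })
  for (metric in rownames(means))
    expect_true(all(diff(means[metric, ]) > 0),
                info = paste("non-monotone:", metric))
})
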