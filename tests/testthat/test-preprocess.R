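make_mask <- function(keep, len = 250L) {
  n <- length(keep)
  structure(list(keep = keep,
                 channel_keep = matrix(keep, nrow = 1),
                 boundaries = cbind(start = (seq_len(n) - 1L) * len,
                                    end = seq_len(n) * len),
                 epoch_len = 1),
            class = "epoch_mask")
}

test_that("rejection rules flag exactly the contaminated epochs", {
  rec <- generate_recording(recording_config(duration = 6),
                            group_effect("TD"), seed = 5)
  expect_true(all(reject_epochs(rec)$keep))  # clean low-amplitude recording

  spiked <- inject_artifacts(rec, "spike", epoch_index = 3)
  keep <- reject_epochs(spiked)$keep
  expect_false(keep[3])
  expect_true(all(keep[-3]))

  # a 40 uV 25 Hz sinusoid added to one epoch trips the fast rule; the
  # band-filter oracle confirms its 20-35 Hz amplitude exceeds 35 uV
  fs <- rec$config$fs
  fast <- rec
  idx <- 501:750
  t <- (seq_along(idx) - 1) / fs
  fast$data[1, idx] <- fast$data[1, idx] + 40 * sin(2 * pi * 25 * t)
  expect_false(reject_epochs(fast)$keep[3])
  bf <- signal::butter(4, c(20, 35) / (fs / 2), type = "pass")
  filt <- as.numeric(signal::filtfilt(bf, fast$data[1, ]))
  expect_gt(diff(range(filt[idx])) / 2, 35)
  expect_lt(max(abs(fast$data[1, idx])), 100)  # amp rule not the trigger

  # slow rule in isolation: 60 uV at 0.5 Hz across the whole recording
  # stays under the 100 uV amplitude rule but exceeds the 50 uV slow rule
  slow <- rec
  tt <- (seq_len(ncol(rec$data)) - 1) / fs
  slow$data[1, ] <- slow$data[1, ] + 60 * sin(2 * pi * 0.5 * tt)
  expect_lt(max(abs(slow$data[1, ])), 100)
  expect_true(all(!reject_epochs(slow)$keep))

  expect_error(reject_epochs(rec, rejection_rules(epoch_len = 0)))
  expect_error(reject_epochs(small_recording(),
                             rejection_rules(epoch_len = 10)), "duration")
})

test_that("rejection is monotone under added amplitude", {
  rec <- generate_recording(recording_config(duration = 6),
                            group_effect("TD"), seed = 5)
  r1 <- inject_artifacts(rec, "spike", epoch_index = 2)
  r2 <- inject_artifacts(r1, "spike", epoch_index = 2)  # even larger transient
  k1 <- reject_epochs(r1)$keep
  k2 <- reject_epochs(r2)$keep
  expect_false(k1[2])
  expect_false(k2[2])
  expect_true(all(which(!k1) %in% which(!k2)))
})

test_that("longest clean segment follows the stated tie-breaks", {
  # runs of kept epochs: 1-2 and 4-6; the longer (4-6) wins
  seg <- longest_clean_segment(make_mask(c(TRUE, TRUE, FALSE, TRUE, TRUE,
                                           TRUE)))
  expect_equal(seg$start, 3 * 250)
  expect_equal(seg$end, 6 * 250)

  # all kept: whole recording
  seg <- longest_clean_segment(make_mask(rep(TRUE, 4)))
  expect_equal(c(seg$start, seg$end), c(0, 1000))

  # two equal runs: the earlier one is returned
  seg <- longest_clean_segment(make_mask(c(TRUE, TRUE, FALSE, TRUE, TRUE)))
  expect_equal(c(seg$start, seg$end), c(0, 500))

  # all rejected: empty interval
  seg <- longest_clean_segment(make_mask(rep(FALSE, 3)))
  expect_equal(c(seg$start, seg$end), c(0, 0))
})

test_that("trimming cuts every subject to the common length and is idempotent", {
  cfg_for <- function(d) recording_config(duration = d)
  recs <- Map(function(d, s) generate_recording(cfg_for(d), group_effect(),
                                                seed = s, subject_id =
                                                  paste0("S", s)),
              c(50, 43, 60), 1:3)
  coh <- structure(list(recordings = recs, seed = 1), class = "eeg_cohort")
  trimmed <- trim_to_common_length(coh)
  lens <- vapply(trimmed$recordings, function(r) ncol(r$data), 0L)
  expect_equal(lens, rep(10750L, 3))  # 43 s at 250 Hz
  expect_equal(vapply(trimmed$recordings, function(r) length(r$data), 0L),
               rep(204250L, 3))       # 19 channels x 10750 samples
  again <- trim_to_common_length(trimmed)
  expect_identical(vapply(again$recordings, function(r) ncol(r$data), 0L),
                   lens)
})

test_that("cohort preprocessing selects clean segments end to end", {
  cfg <- recording_config(duration = 6)
  recs <- lapply(1:3, function(s)
    generate_recording(cfg, group_effect(), seed = 40 + s,
                       subject_id = paste0("S", s)))
  recs[[2]] <- inject_artifacts(recs[[2]], "spike", epoch_index = 2)
  coh <- structure(list(recordings = recs, seed = 1), class = "eeg_cohort")
  out <- preprocess_cohort(coh)
  lens <- vapply(out$recordings, function(r) ncol(r$data), 0L)
  # subject 2 loses epoch 2; its longest clean run (epochs 3-6, 4 s) caps
  # the whole cohort
  expect_equal(lens, rep(1000L, 3))
})
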