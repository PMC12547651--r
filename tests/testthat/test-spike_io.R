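test_that("spike tables parse into sessions with sorted per-unit timestamps", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("well_id,unit_id,timestamp_s",
               "A,u1,12.5", "A,u1,10.0", "A,u2,3.0"), path)
  s <- read_spike_table(path, "treated", c(0, 300), c(300, 600))
  expect_s3_class(s, "mea_session")
  expect_equal(nrow(session_units(s)), 2)
  expect_equal(s$spikes$timestamp_s[s$spikes$unit_id == "u1"], c(10, 12.5))
})

test_that("an empty spike file with a valid header yields zero units and a warning", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("well_id,unit_id,timestamp_s", path)
  expect_warning(s <- read_spike_table(path), "no spikes")
  expect_equal(nrow(session_units(s)), 0)
})

test_that("malformed spike tables are rejected with informative errors", {
  bad_col <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("well,unit_id,timestamp_s", "A,u1,1"), bad_col)
  expect_error(read_spike_table(bad_col), "missing required column")

  bad_num <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("well_id,unit_id,timestamp_s", "A,u1,1.0", "A,u1,abc"),
             bad_num)
  expect_error(read_spike_table(bad_num), "non-numeric timestamp.*row\\(s\\) 2")

  dup <- tibble::tibble(well_id = "A", unit_id = "u1",
                        timestamp_s = c(1, 1))
  expect_error(mea_session(dup), "duplicate timestamps")

  expect_error(mea_session(tibble::tibble(well_id = "A", unit_id = "u1",
                                          timestamp_s = -2)),
               "negative timestamp")
})

test_that("out-of-window rows error in strict mode and drop loudly otherwise", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("well_id,unit_id,timestamp_s",
               "A,u1,10.0", "A,u1,650.0"), path)
  expect_error(read_spike_table(path, baseline_window = c(0, 300),
                                treatment_window = c(300, 600)),
               "outside recording interval.*row\\(s\\) 2")
  expect_warning(
    s <- read_spike_table(path, baseline_window = c(0, 300),
                          treatment_window = c(300, 600),
                          out_of_window = "drop"),
    "dropping 1 spike")
  expect_equal(nrow(s$spikes), 1)
})

test_that("session windows must tile the recording", {
  sp <- tibble::tibble(well_id = "A", unit_id = "u1", timestamp_s = 5)
  expect_error(mea_session(sp, baseline_window = c(0, 300),
                           treatment_window = c(310, 600)),
               "exactly where")
  # a spike exactly at treatment time belongs to the treatment window
  s <- mea_session(tibble::tibble(well_id = "A", unit_id = "u1",
                                  timestamp_s = 300), "treated")
  d <- response_deltas(s)
  expect_equal(d$delta_mfr_hz, 1 / 30)
})

test_that("label, feature and spike tables round-trip losslessly", {
  lab <- tibble::tibble(
    well_id = c("A", "A", "B"), unit_id = c("u1", "u2", "u1"),
    delta_mfr_hz = c(0.123456789012345, -1 / 3, 2.5),
    kde_density = c(1e-21, 0.987654321098765, 0.5),
    label = c("nociceptor", "non-nociceptor", "nociceptor"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_labels(lab, path)
  back <- read_labels(path)
  expect_equal(as.data.frame(back), as.data.frame(lab), tolerance = 1e-12)
  # well grouping order of rows is preserved
  expect_equal(back$well_id, c("A", "A", "B"))

  ft <- tibble::tibble(
    well_id = "A", unit_id = c("u1", "u2"),
    mfr_hz = c(1.23456789, 2 / 7), isicv = c(0.5, 1.5),
    sync_median = c(0.25, 0.75), sync_skewness = c(-0.1, 0.3),
    label = c("nociceptor", "non-nociceptor"))
  fpath <- withr::local_tempfile(fileext = ".csv")
  write_features(ft, fpath)
  expect_equal(as.data.frame(read_features(fpath)), as.data.frame(ft),
               tolerance = 1e-12)
  expect_error(write_labels(ft, path), "missing column")
})

test_that("unlabeled feature tables read back with an explicit marker", {
  ft <- tibble::tibble(well_id = "A", unit_id = "u1", mfr_hz = 1,
                       isicv = 1, sync_median = 0.2, sync_skewness = 0)
  path <- withr::local_tempfile(fileext = ".csv")
  write_features(ft, path)
  expect_equal(read_features(path)$label, "unlabeled")
})

test_that("metric documents re-parse to identical values", {
  metrics <- list(accuracy = 0.8123456789012345,
                  f1 = list(nociceptor = 0.75, non_nociceptor = 1 / 3),
                  auc = 0.8766,
                  roc = data.frame(fpr = c(0, 0.5, 1), tpr = c(0, 0.9, 1)))
  path <- withr::local_tempfile(fileext = ".json")
  write_metrics(metrics, path)
  back <- read_metrics(path)
  expect_equal(back$accuracy, metrics$accuracy, tolerance = 0)
  expect_equal(back$f1$non_nociceptor, 1 / 3, tolerance = 0)
  expect_equal(back$roc$tpr, metrics$roc$tpr, tolerance = 0)
})
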