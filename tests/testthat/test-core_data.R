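test_that("native format round-trips signal, header, and duration", {
  sig <- matrix(rnorm(2000), 2)
  rec <- bb_recording(sig, fs = 1000, labels = c("C3", "C4"), t0 = 5)
  path <- tempfile("rec")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(rec_duration(back), 1.0)
  expect_equal(back$labels, c("C3", "C4"))
  expect_equal(back$fs, 1000)
  expect_equal(back$t0, 5)
  expect_equal(back$signal, rec$signal, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("recording validation rejects bad headers and bad samples", {
  expect_error(bb_recording(matrix(1, 2, 10), fs = 0), "fs")
  expect_error(bb_recording(matrix(1, 2, 10), fs = 1000,
                            labels = c("a", "a")), "duplicate")
  expect_error(bb_recording(matrix(1, 2, 10), fs = 1000,
                            labels = "a"), "labels")
  sig <- matrix(1, 2, 10); sig[2, 4] <- NaN
  expect_error(bb_recording(sig, fs = 100, labels = c("A", "B")),
               "'B'.*index 3")
  # fs = 0 in a file header is also rejected
  path <- tempfile("rec")
  write.table(matrix(rnorm(20), 2), path, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(fs = 0, labels = c("a", "b")),
                       paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(read_recording(path), "fs")
})

test_that("EDF round-trip preserves the signal within 16-bit precision", {
  sig <- matrix(sin(seq(0, 20, length.out = 500)) + rnorm(1000, sd = .1),
                2, byrow = TRUE)
  rec <- bb_recording(sig, fs = 250, labels = c("Cz", "Pz"))
  path <- tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_recording(path, dialect = "edf")
  expect_equal(back$fs, 250)
  expect_equal(back$labels, c("Cz", "Pz"))
  tol <- (max(sig) - min(sig)) / 65534 * 1.01
  expect_lt(max(abs(back$signal - rec$signal)), tol)
})

test_that("read_events sorts, deduplicates, and reports parse errors", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("0.5", "0.2", "0.2"), path)
  ev <- read_events(path)
  expect_equal(ev$times, c(0.2, 0.5))
  expect_equal(ev$n_duplicates_dropped, 1L)

  writeLines(character(0), path)
  expect_length(read_events(path)$times, 0)

  writeLines(c("0.5", "oops", "0.9"), path)
  expect_error(read_events(path), "line 2")

  set.seed(1)
  tt <- runif(1000, 0, 3600)
  writeLines(format(tt, digits = 12), path)
  out <- read_events(path)$times
  expect_true(all(diff(out) > 0))

  # header dialect with app labels carried through
  writeLines(c("time_s,app_label", "1.5,maps", "0.5,chat"), path)
  ev <- read_events(path)
  expect_equal(ev$times, c(0.5, 1.5))
  expect_equal(ev$app_label, c("chat", "maps"))
})

test_that("inactive segment rule removes exactly the doubly-distant stretch", {
  m <- inactive_segment_mask(c(10, 100), span = c(0, 110), threshold_s = 30)
  expect_equal(m$removed, matrix(c(40, 70), 1), ignore_attr = TRUE)
  expect_equal(m$keep, rbind(c(0, 40), c(70, 110)), ignore_attr = TRUE)

  # dense events: no gap exceeds the threshold
  m2 <- inactive_segment_mask(seq(0, 100, by = 5), c(0, 100), 30)
  expect_equal(m2$keep, matrix(c(0, 100), 1), ignore_attr = TRUE)

  # no events: everything removed, with a warning
  expect_warning(m3 <- inactive_segment_mask(numeric(0), c(0, 100), 30))
  expect_equal(nrow(m3$keep), 0L)
})

test_that("inactive mask agrees with per-sample brute force on random trains", {
  set.seed(42)
  for (rep in 1:20) {
    span <- c(0, 200)
    ev <- sort(runif(sample(1:6, 1), 0, 200))
    thr <- runif(1, 5, 60)
    m <- inactive_segment_mask(ev, span, thr)
    tt <- seq(0.137, 199.9, by = 0.731)   # probe points off boundaries
    prev_d <- sapply(tt, function(t) {
      e <- ev[ev <= t]; if (length(e)) t - max(e) else Inf
    })
    next_d <- sapply(tt, function(t) {
      e <- ev[ev >= t]; if (length(e)) min(e) - t else Inf
    })
    removed_ref <- prev_d > thr & next_d > thr
    in_keep <- sapply(tt, function(t)
      any(t >= m$keep[, 1] & t < m$keep[, 2]))
    expect_equal(!in_keep, removed_ref)
  }
})

test_that("inactive mask is idempotent and conserves duration", {
  ev <- c(10, 100, 150)
  m <- inactive_segment_mask(ev, c(0, 300), 30)
  kept <- sum(m$keep[, 2] - m$keep[, 1])
  removed <- sum(m$removed[, 2] - m$removed[, 1])
  expect_equal(kept + removed, 300)
  # applying the rule again inside each kept interval removes nothing:
  # all kept time is within threshold of an event on at least one side
  for (i in seq_len(nrow(m$keep))) {
    tt <- seq(m$keep[i, 1] + 1e-6, m$keep[i, 2] - 1e-6, length.out = 50)
    prev_d <- sapply(tt, function(t) {
      e <- ev[ev <= t]; if (length(e)) t - max(e) else Inf
    })
    next_d <- sapply(tt, function(t) {
      e <- ev[ev >= t]; if (length(e)) min(e) - t else Inf
    })
    expect_false(any(prev_d > 30 & next_d > 30))
  }
})

test_that("apply_mask concatenates kept runs and maps times both ways", {
  rec <- bb_recording(matrix(seq_len(30), 1), fs = 10)
  mask <- structure(list(keep = rbind(c(0, 1), c(2, 3)),
                         removed = rbind(c(1, 2)), span = c(0, 3)),
                    class = "bb_mask")
  out <- apply_mask(rec, mask)
  expect_equal(ncol(out$recording$signal), 20L)
  expect_equal(out$seams, 10L)
  # samples: 1..10 then 21..30 of the original
  expect_equal(as.numeric(out$recording$signal),
               c(1:10, 21:30))
  # original t = 2.5 lies in the second run -> masked t = 1.5
  expect_equal(to_masked_time(2.5, out$map, 10), 1.5)
  expect_true(is.na(to_masked_time(1.5, out$map, 10)))
  # masked -> original is the inverse on kept samples
  expect_equal(to_original_time(1.5, out$map, 10), 2.5)
  expect_equal(to_original_time(to_masked_time(0.31, out$map, 10),
                                out$map, 10), 0.31, tolerance = 1e-9)
  # full-span mask is the identity
  id <- apply_mask(rec, full_mask(c(0, 3)))
  expect_equal(id$recording$signal, rec$signal)
  expect_length(id$seams, 0)
  expect_error(apply_mask(rec, structure(
    list(keep = matrix(numeric(0), 0, 2), removed = rbind(c(0, 3)),
         span = c(0, 3)), class = "bb_mask")), "nothing")
})

test_that("mask serialization round-trips kept intervals", {
  m <- inactive_segment_mask(c(10, 100), c(0, 110), 30)
  path <- tempfile()
  write_mask(m, path)
  back <- read_mask(path, span = c(0, 110))
  expect_equal(back$keep, m$keep)
})
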