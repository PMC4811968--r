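test_that("band-pass frequency response meets the design targets", {
  fs <- 500
  cfg <- preproc_config()
  sec <- erpdistract:::butter_sections(cfg, fs)
  # two-pass (zero-phase) magnitude response of the designed filter
  Hmag2 <- function(f) {
    z <- exp(-1i * 2 * pi * f / fs)
    h <- 1
    for (s in sec)
      h <- h * sum(s$b * z^(0:(length(s$b) - 1))) /
        sum(s$a * z^(0:(length(s$a) - 1)))
    abs(h)^2
  }
  expect_lt(Hmag2(0), 1e-3)
  expect_gte(Hmag2(10), 0.95)
  expect_lte(Hmag2(10), 1.0)
  expect_gt(-20 * log10(Hmag2(60)), 12)  # attenuation in dB
  # empirical check on sinusoids, away from the edges
  tt <- seq(0, 10, by = 1 / fs)
  mid <- 2000:3000
  s10 <- erpdistract:::filt_zerophase(sin(2 * pi * 10 * tt), sec, fs, 0.1)
  expect_gt(max(abs(s10[mid])), 0.95)
  s60 <- erpdistract:::filt_zerophase(sin(2 * pi * 60 * tt), sec, fs, 0.1)
  expect_lt(max(abs(s60[mid])), 10^(-12 / 20))
  expect_error(bandpass_filter(render_recording("Young", 1,
                                                task = small_task(4),
                                                noise = quiet_noise()),
                               preproc_config(band = c(0.1, 300))),
               "Nyquist")
})

test_that("zero-phase filtering leaves a mid-band peak latency unchanged", {
  fs <- 500
  cfg <- preproc_config()
  sec <- erpdistract:::butter_sections(cfg, fs)
  tt <- seq(0, 4, by = 1 / fs)
  v <- erpdistract:::hann_kernel(tt * 1000, 2000, 55)
  f <- erpdistract:::filt_zerophase(v, sec, fs, 0.1)
  expect_equal(which.max(f), which.max(v))
})

test_that("epoching keeps only Go-paired epochs with the documented time axis", {
  rec <- render_recording("Young", 13, task = task_config(n_pairs = 60),
                          noise = quiet_noise())
  ep <- epoch_recording(rec)
  tl <- rec$timeline
  expect_equal(dim(ep$data)[1], sum(tl$visual_type %in% c("number", "letter")))
  expect_lt(dim(ep$data)[1], nrow(tl))  # NoGo pairs contribute nothing
  expect_equal(dim(ep$data)[3], 726)    # [-150, 1300] ms at 500 Hz, inclusive
  expect_equal(ep$times[1], -150)
  expect_equal(ep$times[726], 1300)
  expect_true(0 %in% ep$times)
  expect_equal(diff(ep$times[1:2]), 2)
  expect_setequal(unique(ep$condition), c("Standard", "Deviant", "Novel"))
})

test_that("epochs at the recording edge are dropped with a message", {
  rec <- render_recording("Young", 13, task = task_config(n_pairs = 6,
                                                          lead_in = 1000),
                          noise = quiet_noise())
  rec$timeline$auditory_onset <- rec$timeline$auditory_onset - 950
  rec$timeline$visual_onset <- rec$timeline$visual_onset - 950
  rec$timeline$visual_type <- "number"  # all Go, so the edge pair counts
  expect_message(epoch_recording(rec), "dropped")
})

test_that("baseline correction zeroes the pre-stimulus mean and ignores offsets", {
  rec <- render_recording("Old", 17, task = small_task(10),
                          noise = noise_config(rms = 5, alpha_amplitude = 2,
                                               blink_rate = 0,
                                               eog_noise_rms = 1))
  ep <- baseline_correct(epoch_recording(rec))
  sel <- ep$times >= -150 & ep$times < 0
  bl <- apply(ep$data[, , sel, drop = FALSE], c(1, 2), mean)
  expect_lt(max(abs(bl)), 1e-10)
  # adding a constant leaves the corrected epochs unchanged
  rec2 <- rec
  rec2$data["Cz", ] <- rec2$data["Cz", ] + 7
  ep2 <- baseline_correct(epoch_recording(rec2))
  expect_equal(ep2$data, ep$data, tolerance = 1e-12)
  # a linear drift is not removed, only its baseline mean: a ramp through
  # the epoch keeps exactly its analytic drift-minus-baseline-mean residual
  rec3 <- rec
  slope <- 0.01  # uV per sample
  rec3$data["Pz", ] <- seq_len(ncol(rec3$data)) * slope
  ep3 <- baseline_correct(epoch_recording(rec3))
  resid <- ep3$data[1, which(ep$channels == "Pz"), ]
  k <- seq_along(ep$times)
  expected <- slope * (k - mean(k[sel]))
  expect_equal(unname(resid), expected, tolerance = 1e-10)
})

test_that("rejection removes exactly the threshold-violating and initial epochs", {
  rec <- render_recording("Young", 23, task = task_config(n_pairs = 30,
                                                          n_blocks = 2),
                          noise = quiet_noise())
  ep <- baseline_correct(epoch_recording(rec))
  # inject a 150-uV spike into the first kept-range epoch on one scalp
  # channel, and a large EOG excursion into another epoch (must NOT reject)
  cz <- which(ep$channels == "Cz")
  veog <- which(ep$channels == "VEOGU")
  mid <- which(ep$pair > 5 & ep$pair < 16)  # kept range of block 1
  target <- mid[1]
  eog_only <- mid[2]
  ep$data[target, cz, 300] <- 150
  ep$data[eog_only, veog, 300] <- 400
  ep <- reject_epochs(ep)
  expect_false(ep$kept[target])
  expect_equal(ep$reason[target], "amplitude")
  expect_true(ep$kept[eog_only])
  # first five pairs of each block are out, regardless of condition
  expect_true(all(!ep$kept[ep$pair %in% c(1:5, 16:20)]))
  expect_true(all(ep$reason[ep$pair %in% c(1:5, 16:20)] == "initial"))
  # everything else is kept
  others <- !(ep$pair %in% c(1:5, 16:20)) & seq_along(ep$kept) != target
  expect_true(all(ep$kept[others]))
  # rejection never modifies data
  expect_equal(unname(ep$data[target, cz, 300]), 150)
})

test_that("averaging and differencing are exact arithmetic", {
  rec <- render_recording("Young", 29, task = small_task(20),
                          noise = quiet_noise())
  pp <- preprocess_subject(rec, filter = FALSE)
  # identical epochs average to any one of them: clean standard epochs are
  # identical by construction
  ep <- pp$epochs
  std <- which(ep$condition == "Standard" & ep$kept)
  expect_equal(pp$evoked$Standard$data["Cz", ],
               ep$data[std[1], which(ep$channels == "Cz"), ],
               tolerance = 1e-12)
  # D-S of identical evokeds is zero
  dd <- difference_wave(structure(list(condition = "Deviant",
                                       data = pp$evoked$Standard$data,
                                       times = pp$evoked$Standard$times,
                                       sample_rate = 500),
                                  class = "erp_evoked"),
                        pp$evoked$Standard)
  expect_true(all(dd$data == 0))
  expect_error(average_epochs(ep, "Bogus"), "no kept epochs")
})

test_that("noiseless subject difference waves equal the rendered ground truth", {
  rec <- render_recording("MiddleAged", 31, task = task_config(n_pairs = 60),
                          noise = quiet_noise())
  pp <- preprocess_subject(rec, filter = FALSE)
  for (ct in c("NS", "DS")) {
    truth <- render_difference_wave("MiddleAged", ct, times = pp[[ct]]$times)
    expect_lt(max(abs(pp[[ct]]$data - truth$data)), 1e-12)
  }
})

test_that("ocular regression removes injected blinks and is benign without them", {
  task <- small_task(20)
  blinky <- noise_config(rms = 0, alpha_amplitude = 0, blink_rate = 20,
                         blink_amplitude = 150, eog_noise_rms = 0)
  rec <- render_recording("Young", 37, task = task, noise = blinky)
  clean <- render_recording("Young", 37, task = task, noise = quiet_noise())
  corrected <- correct_ocular(rec)
  injected <- rec$data["Fz", ] - clean$data["Fz", ]
  residual <- corrected$data["Fz", ] - clean$data["Fz", ]
  expect_gt(stats::sd(injected), 1)  # blinks really were injected
  expect_lt(stats::sd(residual), 0.05 * stats::sd(injected))
  # EOG channels are untouched
  expect_identical(corrected$data["VEOGU", ], rec$data["VEOGU", ])
  # idempotence
  twice <- correct_ocular(corrected)
  expect_lt(max(abs(twice$data - corrected$data)), 1e-6)
  # blink-free recording passes through essentially unchanged
  cc <- correct_ocular(clean)
  expect_lt(max(abs(cc$data - clean$data)), 1e-8)
  # method = none is the identity; missing EOG errors
  expect_identical(correct_ocular(rec, preproc_config(ocular = "none")), rec)
  rec2 <- rec
  rec2$montage$eog_labels <- character()
  expect_error(correct_ocular(rec2), "EOG")
})
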