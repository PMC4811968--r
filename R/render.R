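#' @title Waveform rendering for the synthetic generator
#' @description Components are rendered as raised-cosine (Hann) bumps with
#'   compact support, scaled per channel by a scalp topography interpolated
#'   from the Fz/Cz/Pz anchor amplitudes. The compact support (half-width
#'   55 ms by default) guarantees that no kernel contributes signal at
#'   another kernel's peak for the default parameter table, which makes
#'   parameter recovery by peak measurement exact rather than approximate.
#' @name rendering
NULL

# Raised-cosine bump: 1 at t = latency, 0 outside [latency +- halfwidth].
hann_kernel <- function(times, latency, halfwidth) {
  x <- (times - latency) / halfwidth
  ifelse(abs(x) < 1, 0.5 * (1 + cos(pi * x)), 0)
}

# Per-channel topography from anchor values at Fz/Cz/Pz: inverse great-circle
# distance interpolation between the anchors, multiplied by a cosine taper
# that is 1 out to the anchor ring and decays to 0 at a 90 degree arc from
# Cz. Anchor electrodes reproduce their anchor values exactly. EOG channels
# carry no ERP signal.
topography_weights <- function(montage, anchors) {
  pos <- montage$positions
  scalp <- montage$labels
  apos <- pos[c("Fz", "Cz", "Pz"), , drop = FALSE]
  ang <- arc_angle(pos[scalp, , drop = FALSE], apos)  # n x 3, radians
  val <- numeric(length(scalp))
  names(val) <- scalp
  for (i in seq_along(scalp)) {
    hit <- which(ang[i, ] < 1e-9)
    if (length(hit)) {
      val[i] <- anchors[hit[1]]
    } else {
      w <- 1 / ang[i, ]^2
      val[i] <- sum(w * anchors) / sum(w)
    }
  }
  theta <- arc_angle(pos[scalp, , drop = FALSE],
                     pos["Cz", , drop = FALSE])[, 1]
  theta0 <- max(arc_angle(apos, pos["Cz", , drop = FALSE]))
  taper <- ifelse(theta <= theta0, 1,
                  pmax(0, cos((pi / 2) * (theta - theta0) / (pi / 2 - theta0))))
  out <- numeric(n_channels(montage))
  names(out) <- all_channel_labels(montage)
  out[scalp] <- val * taper
  out
}

#' Render a clean (noiseless) difference waveform
#'
#' Sums the four component kernels, each scaled by its scalp topography, on
#' an arbitrary time axis. The default axis is a 1-ms grid from -150 to
#' 1300 ms, on which every latency of the default parameter table falls on
#' a sample, so window-constrained peak measurement recovers the table
#' exactly. Rendering is linear in the template amplitudes, and noise-free
#' by construction.
#'
#' @param group one of "Young", "MiddleAged", "Old".
#' @param contrast "NS" (novel minus standard) or "DS" (deviant minus standard).
#' @param templates a component parameter table ([component_templates()] or a
#'   subject-perturbed copy).
#' @param montage an [montage()] object.
#' @param times numeric time axis in ms (relative to auditory onset).
#' @param halfwidth kernel half-width, ms.
#' @param check_overlap if TRUE (default), error when any kernel would
#'   contribute nonzero signal at another kernel's peak latency.
#' @return An object of class `erp_difference_wave`: channels x samples
#'   matrix `data` (uV, rownames = channel labels), `times`, `contrast`,
#'   `group`.
#' @export
render_difference_wave <- function(group, contrast,
                                   templates = component_templates(),
                                   montage = standard_1010_montage(),
                                   times = seq(-150, 1300, by = 1),
                                   halfwidth = 55, check_overlap = TRUE) {
  anc <- anchor_amplitudes(templates, group, contrast)
  lats <- template_latencies(templates, group, contrast)
  if (check_overlap) {
    gaps <- abs(outer(lats, lats, "-"))
    diag(gaps) <- Inf
    if (any(gaps <= halfwidth))
      stop("kernel overlap violation: component peaks closer than the ",
           "kernel half-width (", halfwidth, " ms)")
  }
  data <- matrix(0, nrow = n_channels(montage), ncol = length(times),
                 dimnames = list(all_channel_labels(montage), NULL))
  for (cp in rownames(anc)) {
    topo <- topography_weights(montage, anc[cp, ])
    data <- data + outer(topo, hann_kernel(times, lats[[cp]], halfwidth))
  }
  structure(list(data = data, times = times, contrast = contrast,
                 group = group, sample_rate = 1000 / diff(times[1:2])),
            class = "erp_difference_wave")
}

#' @export
print.erp_difference_wave <- function(x, ...) {
  cat("<erp_difference_wave> ", x$contrast,
      if (!is.null(x$group)) paste0(" (", x$group, ")"), ", ",
      nrow(x$data), " channels x ", length(x$times), " samples [",
      min(x$times), ", ", max(x$times), "] ms\n", sep = "")
  invisible(x)
}

#' Noise model configuration
#'
#' Parameters of the synthetic EEG background: a spatially correlated 1/f
#' ("pink") process, a posterior-dominant alpha oscillation, and stereotyped
#' eye blinks projected with a frontal gradient. With all amplitudes zero
#' the rendered EEG equals the clean ERP signal exactly.
#'
#' @param rms background RMS per scalp channel, uV.
#' @param exponent spectral exponent of the 1/f background.
#' @param alpha_amplitude,alpha_freq alpha oscillation amplitude (uV, at the
#'   posterior maximum) and frequency (Hz).
#' @param spatial_corr_deg correlation length of the background across the
#'   scalp, degrees of arc.
#' @param blink_rate blinks per minute; `blink_amplitude` is the deflection
#'   at the upper vertical EOG electrode, uV.
#' @param eog_noise_rms white-noise RMS added to the EOG channels, uV.
#' @return A list of class `erp_noise_config`.
#' @export
noise_config <- function(rms = 10, exponent = 1, alpha_amplitude = 3,
                         alpha_freq = 10, spatial_corr_deg = 40,
                         blink_rate = 5, blink_amplitude = 150,
                         eog_noise_rms = 5) {
  if (rms < 0) stop("noise RMS must be >= 0")
  structure(as.list(environment()), class = "erp_noise_config")
}

#' Reaction-time model
#'
#' Trial RT = group base mean + condition offset + Gaussian trial noise,
#' truncated at 100 ms. The condition offsets are centered to sum to zero
#' across Standard/Deviant/Novel, so in the noiseless model the mean of the
#' per-condition means equals the group base mean exactly. The default
#' offsets derive from the emulated condition means 556/560/587 ms.
#'
#' @param group_means named base means, ms.
#' @param condition_offsets named zero-sum offsets, ms.
#' @param trial_sd trial-level SD, ms (0 = deterministic).
#' @param miss_prob probability that a Go trial receives no response.
#' @return A list of class `erp_rt_model`.
#' @export
rt_model <- function(group_means = c(Young = 467, MiddleAged = 612, Old = 623),
                     condition_offsets = c(standard = -35 / 3,
                                           deviant = -23 / 3,
                                           novel = 58 / 3),
                     trial_sd = 100, miss_prob = 0.02) {
  if (abs(sum(condition_offsets)) > 1e-9)
    stop("condition offsets must sum to zero")
  if (trial_sd < 0 || miss_prob < 0 || miss_prob > 1)
    stop("invalid RT model parameters")
  structure(as.list(environment()), class = "erp_rt_model")
}

# Truncated-normal draw (lower bound lo); degenerate sd = 0 returns the mean.
rtrunc_norm <- function(n, mean, sd, lo = 100) {
  if (sd == 0) return(rep(mean, length.out = n))
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), 1)
  stats::qnorm(u, mean, sd)
}

#' Simulate behavioral responses for a timeline
#'
#' Fills the `response` and `rt` columns: Go trials (numbers -> left hand,
#' letters -> right hand) receive a truncated-Gaussian RT unless missed;
#' NoGo trials receive no response. Uses the caller-visible RNG stream.
#'
#' @param timeline an `erp_timeline`.
#' @param group_mean subject-level base mean RT, ms.
#' @param rt an [rt_model()].
#' @return The timeline with behavior filled in.
#' @export
simulate_rts <- function(timeline, group_mean, rt = rt_model()) {
  go <- is_go(timeline)
  off <- rt$condition_offsets[timeline$auditory_type[go]]
  val <- rtrunc_norm(sum(go), group_mean + off, rt$trial_sd)
  miss <- stats::runif(sum(go)) < rt$miss_prob
  val[miss] <- NA_real_
  resp <- ifelse(timeline$visual_type[go] == "number", "left", "right")
  resp[miss] <- "none"
  timeline$response[go] <- resp
  timeline$rt[go] <- val
  timeline
}

# Generic auditory and visual evoked responses common to every trial (they
# cancel exactly in the difference waveforms). Latencies in ms from the
# auditory onset; the visual complex sits at the 300-ms SOA.
standard_response_wave <- function(montage, times, halfwidth = 40) {
  kernels <- list(
    list(lat = 100, anchors = c(Fz = -4.8, Cz = -6.0, Pz = -3.0)),  # auditory N1
    list(lat = 190, anchors = c(Fz = 3.5, Cz = 5.0, Pz = 3.0)),     # auditory P2
    list(lat = 410, anchors = c(Fz = 0.8, Cz = 2.0, Pz = 4.0)),     # visual P1
    list(lat = 470, anchors = c(Fz = -1.0, Cz = -2.0, Pz = -3.5))   # visual N1
  )
  data <- matrix(0, nrow = n_channels(montage), ncol = length(times),
                 dimnames = list(all_channel_labels(montage), NULL))
  for (k in kernels) {
    topo <- topography_weights(montage, k$anchors)
    data <- data + outer(topo, hann_kernel(times, k$lat, halfwidth))
  }
  data
}

# Spatially correlated 1/f background, channels x n matrix.
pink_background <- function(montage, n, fs, noise) {
  nch <- n_channels(montage)
  white <- matrix(stats::rnorm(nch * n), nrow = nch)
  freqs <- c(1, seq_len(n - 1))
  freqs <- pmin(freqs, n - freqs)  # two-sided frequency index, DC -> 1
  shape <- freqs^(-noise$exponent / 2)
  shape[1] <- 0  # remove DC
  shaped <- t(apply(white, 1, function(v) Re(stats::fft(stats::fft(v) * shape,
                                                        inverse = TRUE)) / n))
  shaped <- shaped / sqrt(rowSums(shaped^2) / n)  # unit RMS per channel
  ang <- arc_angle(montage$positions, montage$positions)
  K <- exp(-(ang / (noise$spatial_corr_deg * pi / 180))^2)
  L <- chol(K + diag(1e-6, nch))
  noise$rms * crossprod(L, shaped)
}

blink_signal <- function(n, fs, noise) {
  out <- numeric(n)
  dur_min <- n / fs / 60
  n_blinks <- stats::rpois(1, noise$blink_rate * dur_min)
  if (n_blinks == 0) return(out)
  centers <- sort(stats::runif(n_blinks, 0.2, n / fs - 0.2))
  tt <- seq_len(n) / fs
  for (ct in centers) out <- out + hann_kernel(tt, ct, 0.15)
  out * noise$blink_amplitude
}

# Frontal projection of the blink potential onto the scalp channels; the
# upper vertical EOG electrode carries the full deflection and the lower
# one inverts below the eye.
blink_topography <- function(montage) {
  w <- pmax(0, montage$positions[, "y"])^3 * 0.4
  names(w) <- rownames(montage$positions)
  w <- w[all_channel_labels(montage)]
  eog_w <- c(VEOGU = 1, VEOGL = -0.6, HEOGL = 0.15, HEOGR = 0.15)
  for (lab in intersect(names(eog_w), montage$eog_labels)) w[lab] <- eog_w[[lab]]
  w
}

#' Render one subject's continuous recording
#'
#' Builds the continuous multichannel EEG: every trial receives the common
#' auditory+visual evoked response; deviant and novel trials additionally
#' receive the group's D-S / N-S difference-wave composite (optionally with
#' trial-level latency jitter); spatially correlated 1/f background, alpha
#' and blinks are added on top; behavior is simulated into the timeline.
#' Fully deterministic given `subject_seed`.
#'
#' @param group age group label.
#' @param subject_seed integer seed for all subject-level randomness.
#' @param task a [task_config()].
#' @param templates component parameter table (possibly subject-perturbed).
#' @param noise a [noise_config()]; pass `noise_config(rms = 0,
#'   alpha_amplitude = 0, blink_rate = 0, eog_noise_rms = 0)` for a clean
#'   recording.
#' @param rt an [rt_model()].
#' @param montage an [montage()].
#' @param subject_mean_rt subject base mean RT; defaults to the group mean.
#' @param latency_jitter_sd per-trial SD of a common latency shift applied
#'   to the embedded difference components, ms (default 0).
#' @return An object of class `erp_recording`.
#' @export
render_recording <- function(group, subject_seed = 1, task = task_config(),
                             templates = component_templates(),
                             noise = noise_config(), rt = rt_model(),
                             montage = standard_1010_montage(),
                             subject_mean_rt = NULL,
                             latency_jitter_sd = 0) {
  fs <- 500
  with_seed(subject_seed, {
    timeline <- generate_timeline(task, seed = subject_seed)
    if (is.null(subject_mean_rt)) subject_mean_rt <- rt$group_means[[group]]
    timeline <- simulate_rts(timeline, subject_mean_rt, rt)
    dur_ms <- task$lead_in + task$n_pairs * task$inter_pair + 2000
    n <- round(dur_ms * fs / 1000)
    nch <- n_channels(montage)
    data <- matrix(0, nrow = nch, ncol = n,
                   dimnames = list(all_channel_labels(montage), NULL))
    ep_times <- seq(-150, 1300, by = 1000 / fs)
    rel_idx <- round(ep_times * fs / 1000)  # sample offsets around onset
    std_wave <- standard_response_wave(montage, ep_times)
    dwave <- list(
      deviant = render_difference_wave(group, "DS", templates, montage,
                                       times = ep_times)$data,
      novel = render_difference_wave(group, "NS", templates, montage,
                                     times = ep_times)$data
    )
    onset_idx <- round(timeline$auditory_onset * fs / 1000) + 1
    jit <- if (latency_jitter_sd > 0)
      stats::rnorm(nrow(timeline), 0, latency_jitter_sd) else
        numeric(nrow(timeline))
    for (i in seq_len(nrow(timeline))) {
      cols <- onset_idx[i] + rel_idx
      data[, cols] <- data[, cols] + std_wave
      ty <- timeline$auditory_type[i]
      if (ty != "standard") {
        dw <- if (jit[i] != 0)
          shift_wave(dwave[[ty]], round(jit[i] * fs / 1000)) else dwave[[ty]]
        data[, cols] <- data[, cols] + dw
      }
    }
    if (noise$rms > 0)
      data <- data + pink_background(montage, n, fs, noise)
    if (noise$alpha_amplitude > 0) {
      topo <- topography_weights(montage, c(Fz = 0.3, Cz = 0.6, Pz = 1))
      phase <- stats::runif(1, 0, 2 * pi)
      data <- data + noise$alpha_amplitude *
        outer(topo, sin(2 * pi * noise$alpha_freq * seq_len(n) / fs + phase))
    }
    if (noise$blink_rate > 0) {
      b <- blink_signal(n, fs, noise)
      data <- data + outer(blink_topography(montage), b)
    }
    if (noise$eog_noise_rms > 0) {
      eog <- montage$eog_labels
      data[eog, ] <- data[eog, ] +
        matrix(stats::rnorm(length(eog) * n, 0, noise$eog_noise_rms),
               nrow = length(eog))
    }
  })
  structure(list(montage = montage, sample_rate = fs, data = data,
                 timeline = timeline, group = group,
                 subject_seed = subject_seed),
            class = "erp_recording")
}

# Integer-sample circular-free shift of an epoch-shaped wave (zeros shifted in).
shift_wave <- function(w, k) {
  if (k == 0) return(w)
  out <- matrix(0, nrow = nrow(w), ncol = ncol(w), dimnames = dimnames(w))
  if (k > 0) out[, (k + 1):ncol(w)] <- w[, 1:(ncol(w) - k)]
  else out[, 1:(ncol(w) + k)] <- w[, (1 - k):ncol(w)]
  out
}

#' @export
print.erp_recording <- function(x, ...) {
  cat("<erp_recording> ", x$group, ", ", nrow(x$data), " channels x ",
      ncol(x$data), " samples @ ", x$sample_rate, " Hz, ",
      nrow(x$timeline), " A-V pairs\n", sep = "")
  invisible(x)
}

#' Perturb the component parameter table for one subject
#'
#' Draws subject-level amplitudes and latencies around the table means with
#' the table SDs (scaled by `amp_sd_scale` / `lat_sd_scale`). Draws are then
#' constrained to keep the subject renderable and measurable: amplitudes
#' keep their component's polarity (magnitude >= 0.2 uV); latencies stay
#' inside their component's search window (5-ms margin) and successive
#' component peaks stay more than one kernel half-width apart.
#'
#' @param templates the table to perturb.
#' @param amp_sd_scale,lat_sd_scale multipliers on the table SDs (0 = none).
#' @param halfwidth kernel half-width used for the gap constraint, ms.
#' @return A perturbed copy of the table. Uses the caller-visible RNG stream.
#' @export
perturb_templates <- function(templates, amp_sd_scale = 1, lat_sd_scale = 1,
                              halfwidth = 55) {
  out <- templates
  sp <- measurement_specs()
  for (g in unique(out$group)) for (ct in unique(out$contrast)) {
    idx <- which(out$group == g & out$contrast == ct)
    sub <- out[idx, ]
    lat <- numeric(nrow(sp))
    for (k in seq_len(nrow(sp))) {
      cp <- sp$component[k]
      rows <- which(sub$component == cp)
      l0 <- sub$latency[rows[1]]
      l <- l0 + stats::rnorm(1, 0, lat_sd_scale * sub$latency_sd[rows[1]])
      l <- min(max(l, sp$window_lo[k] + 5), sp$window_hi[k] - 5)
      if (k > 1) l <- max(l, lat[k - 1] + halfwidth + 1)
      l <- min(l, sp$window_hi[k] - 5)
      lat[k] <- l
      sub$latency[rows] <- l
      a <- sub$amplitude[rows] +
        stats::rnorm(length(rows), 0, amp_sd_scale * sub$amplitude_sd[rows])
      if (sp$polarity[k] == "negative") a <- pmin(a, -0.2) else a <- pmax(a, 0.2)
      sub$amplitude[rows] <- a
    }
    # backward pass: if clamping at a window top squeezed a gap, pull the
    # earlier peak down; the default windows always leave a feasible order.
    for (k in rev(seq_len(nrow(sp) - 1))) {
      rows <- which(sub$component == sp$component[k])
      lmax <- lat[k + 1] - halfwidth - 1
      if (lat[k] > lmax) {
        lat[k] <- max(sp$window_lo[k] + 5, lmax)
        sub$latency[rows] <- lat[k]
      }
    }
    out[idx, ] <- sub
  }
  out
}

#' Generate a synthetic cohort
#'
#' Produces one recording per subject (18 Young, 20 MiddleAged, 15 Old by
#' default). Subject seeds derive from the master seed by a fixed counter
#' scheme (`master_seed * 1000 + subject index`), so any subject can be
#' regenerated in isolation. Each subject's component parameters are drawn
#' around the table means with the table SDs via [perturb_templates()], and
#' the subject's base RT varies around the group mean with SD
#' `rt_between_sd`.
#'
#' A full-length cohort is large (hundreds of MB); pass `process` to map
#' each recording to a summary as it is generated instead of keeping it.
#'
#' @param n_young,n_middle,n_old group sizes.
#' @param master_seed integer master seed.
#' @param task,templates,noise,rt,montage shared configuration objects.
#' @param between_sd_scale multiplier on the table SDs for subject-level
#'   parameter variation (0 = identical clean signals within a group).
#' @param rt_between_sd named per-group between-subject SD of the base RT.
#' @param latency_jitter_sd trial-level latency jitter SD, ms.
#' @param process optional `function(recording)`; when given, its value is
#'   stored instead of the recording.
#' @return A list with one element per subject (recording or processed
#'   value), with attributes `subjects` (data.frame: subject, group, seed)
#'   and `true_templates` (list of per-subject parameter tables).
#' @export
generate_cohort <- function(n_young = 18, n_middle = 20, n_old = 15,
                            master_seed = 1, task = task_config(),
                            templates = component_templates(),
                            noise = noise_config(), rt = rt_model(),
                            montage = standard_1010_montage(),
                            between_sd_scale = 1,
                            rt_between_sd = c(Young = 58.5, MiddleAged = 62.1,
                                              Old = 73.7),
                            latency_jitter_sd = 0, process = NULL) {
  if (min(n_young, n_middle, n_old) < 1) stop("group sizes must be >= 1")
  groups <- rep(c("Young", "MiddleAged", "Old"), c(n_young, n_middle, n_old))
  n_sub <- length(groups)
  seeds <- (master_seed * 1000 + seq_len(n_sub)) %% .Machine$integer.max
  out <- vector("list", n_sub)
  truth <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    g <- groups[i]
    sub_tpl <- with_seed(seeds[i] + 1, {
      if (between_sd_scale > 0)
        perturb_templates(templates, between_sd_scale, between_sd_scale)
      else templates
    })
    sub_rt_mean <- with_seed(seeds[i] + 2,
      rt$group_means[[g]] +
        if (between_sd_scale > 0)
          stats::rnorm(1, 0, rt_between_sd[[g]]) else 0)
    rec <- render_recording(g, subject_seed = seeds[i], task = task,
                            templates = sub_tpl, noise = noise, rt = rt,
                            montage = montage,
                            subject_mean_rt = sub_rt_mean,
                            latency_jitter_sd = latency_jitter_sd)
    truth[[i]] <- sub_tpl
    out[[i]] <- if (is.null(process)) rec else process(rec)
  }
  attr(out, "subjects") <- data.frame(subject = seq_len(n_sub), group = groups,
                                      seed = seeds, stringsAsFactors = FALSE)
  attr(out, "true_templates") <- truth
  out
}

#' Simulate cohort behavior only (no EEG)
#'
#' Fast path used for behavioral analyses and power checks: generates each
#' subject's timeline and RTs exactly as [generate_cohort()] would (same
#' seed scheme) but skips waveform rendering.
#'
#' @inheritParams generate_cohort
#' @return A long data.frame of trials: subject, group, pair, block,
#'   auditory_type, visual_type, response, rt.
#' @export
simulate_cohort_rts <- function(n_young = 18, n_middle = 20, n_old = 15,
                                master_seed = 1, task = task_config(),
                                rt = rt_model(),
                                rt_between_sd = c(Young = 58.5,
                                                  MiddleAged = 62.1,
                                                  Old = 73.7),
                                between_sd_scale = 1) {
  groups <- rep(c("Young", "MiddleAged", "Old"), c(n_young, n_middle, n_old))
  seeds <- (master_seed * 1000 + seq_along(groups)) %% .Machine$integer.max
  res <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[i]
    sub_rt_mean <- with_seed(seeds[i] + 2,
      rt$group_means[[g]] +
        if (between_sd_scale > 0) stats::rnorm(1, 0, rt_between_sd[[g]]) else 0)
    tl <- with_seed(seeds[i], {
      tl <- generate_timeline(task, seed = seeds[i])
      simulate_rts(tl, sub_rt_mean, rt)
    })
    tl$subject <- i
    tl$group <- g
    res[[i]] <- as.data.frame(tl)
  }
  do.call(rbind, res)
}
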