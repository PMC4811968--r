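#' Window-constrained peak detection on one channel
#'
#' Finds the local extremum of the requested polarity with the largest
#' absolute amplitude inside `window`, optionally restricted to latencies
#' strictly later than `after_ms`. Local extrema are assessed on the full
#' trace, so a window-boundary sample qualifies only when the signal
#' actually turns there rather than being clipped mid-slope by the window.
#' Amplitude is the signed value at the peak sample ("peak to baseline";
#' the baseline is zero after baseline correction). Ties are broken toward
#' the earlier latency. When no local extremum of the requested sign exists
#' in the window the peak is not identifiable.
#'
#' @param values numeric vector, one channel's waveform (uV).
#' @param times time axis, ms.
#' @param window `c(lo, hi)` search window, ms (inclusive).
#' @param polarity `"negative"` or `"positive"`.
#' @param after_ms optional lower latency bound (strict).
#' @return `list(latency, amplitude, identifiable)`.
#' @export
find_window_peak <- function(values, times, window, polarity,
                             after_ms = NULL) {
  polarity <- match.arg(polarity, c("negative", "positive"))
  sel <- which(times >= window[1] & times <= window[2])
  if (!length(sel)) stop("empty search window")
  sgn <- if (polarity == "negative") -1 else 1
  v <- sgn * values  # search maxima of v
  n <- length(v)
  is_max <- logical(n)
  left <- c(-Inf, v[-n])
  right <- c(v[-1], -Inf)
  is_max <- v >= left & v >= right & (v > left | v > right)
  cand <- sel[is_max[sel] & v[sel] > 0]
  if (!is.null(after_ms)) cand <- cand[times[cand] > after_ms]
  if (!length(cand))
    return(list(latency = NA_real_, amplitude = NA_real_,
                identifiable = FALSE))
  best <- cand[which.max(v[cand])]  # which.max takes the earliest on ties
  list(latency = times[best], amplitude = values[best], identifiable = TRUE)
}

#' Measure ERP components on a difference waveform
#'
#' Measures each component of `specs` (in order) on one subject's
#' difference waveform. Latency is taken from the Cz peak for every
#' component. Because the e-P3a (280-400 ms) and l-P3a (350-500 ms)
#' windows overlap, the l-P3a search at every electrode is restricted to
#' latencies strictly later than the e-P3a peak found at Cz — the two P3a
#' phases are consecutive, and without this rule the l-P3a measure would
#' re-detect a late, large e-P3a peak.
#'
#' @param dw an `erp_difference_wave`.
#' @param specs a [measurement_specs()] table.
#' @param subject,group identifiers copied into the output.
#' @return A data.frame of class `erp_component_measures`: one row per
#'   (component, electrode) with `amplitude` (uV, signed, at that
#'   electrode's peak), `latency` (ms, the Cz peak), `identifiable`.
#' @export
measure_components <- function(dw, specs = measurement_specs(),
                               subject = NA, group = dw$group) {
  rows <- list()
  after <- NULL
  ep3a_cz <- NA_real_
  for (k in seq_len(nrow(specs))) {
    cp <- specs$component[k]
    electrodes <- strsplit(specs$electrodes[k], ",")[[1]]
    win <- c(specs$window_lo[k], specs$window_hi[k])
    missing <- setdiff(union(electrodes, specs$latency_electrode[k]),
                       rownames(dw$data))
    if (length(missing))
      stop("difference wave lacks electrode(s): ",
           paste(missing, collapse = ", "))
    constraint <- if (cp == "lP3a" && !is.na(ep3a_cz)) ep3a_cz else NULL
    cz <- find_window_peak(dw$data[specs$latency_electrode[k], ], dw$times,
                           win, specs$polarity[k], after_ms = constraint)
    if (cp == "eP3a") ep3a_cz <- cz$latency
    for (el in electrodes) {
      pk <- if (el == specs$latency_electrode[k]) cz else
        find_window_peak(dw$data[el, ], dw$times, win, specs$polarity[k],
                         after_ms = constraint)
      rows[[length(rows) + 1]] <- data.frame(
        subject = subject, group = if (is.null(group)) NA else group,
        contrast = dw$contrast, component = cp, electrode = el,
        amplitude = pk$amplitude, latency = cz$latency,
        identifiable = pk$identifiable && cz$identifiable,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("erp_component_measures", "data.frame")
  out
}

#' Measure a cohort of difference waveforms
#'
#' Applies [measure_components()] to both contrasts of every subject and
#' marks, per component, the subjects retained for analysis: a subject is
#' included for a component only when every required electrode yields an
#' identifiable peak in both contrasts (mirroring per-component attrition
#' of analysis samples).
#'
#' @param waves a list with one element per subject:
#'   `list(subject =, group =, NS = <difference wave>, DS = <...>)`.
#' @param specs a [measurement_specs()] table.
#' @return A long `erp_component_measures` data.frame with an `included`
#'   column.
#' @export
measure_cohort <- function(waves, specs = measurement_specs()) {
  if (!length(waves)) stop("empty cohort")
  tabs <- lapply(waves, function(w) {
    rbind(measure_components(w$NS, specs, subject = w$subject,
                             group = w$group),
          measure_components(w$DS, specs, subject = w$subject,
                             group = w$group))
  })
  tab <- do.call(rbind, tabs)
  ok <- stats::aggregate(identifiable ~ subject + component, tab, all)
  names(ok)[3] <- "included"
  tab <- merge(tab, ok, by = c("subject", "component"), sort = FALSE)
  class(tab) <- c("erp_component_measures", "data.frame")
  tab
}

#' Group-mean component table
#'
#' Means of amplitude and latency by group x contrast x component x
#' electrode over included subjects, in the layout of the default
#' parameter table.
#'
#' @param measures output of [measure_cohort()] (or of
#'   [measure_components()]; then all rows are used).
#' @return A data.frame of group means with subject counts.
#' @export
group_component_means <- function(measures) {
  m <- measures
  if (!is.null(m$included)) m <- m[m$included, , drop = FALSE]
  agg <- stats::aggregate(cbind(amplitude, latency) ~
                            group + contrast + component + electrode,
                          data = m, FUN = mean)
  n <- stats::aggregate(subject ~ group + contrast + component + electrode,
                        data = m, FUN = function(s) length(unique(s)))
  names(n)[5] <- "n_subjects"
  merge(agg, n, by = c("group", "contrast", "component", "electrode"))
}
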