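#' Plot a difference waveform at the midline electrodes
#'
#' Draws the Fz, Cz and Pz traces of a difference waveform with the
#' component search windows shaded — the layout used for grand-average
#' figures (negative is plotted upward, the ERP convention).
#'
#' @param dw an `erp_difference_wave`.
#' @param electrodes electrodes to draw.
#' @param main title (default built from group/contrast).
#' @return Invisibly, `dw`.
#' @export
plot_difference_wave <- function(dw, electrodes = c("Fz", "Cz", "Pz"),
                                 main = NULL) {
  if (is.null(main))
    main <- paste(c(dw$group, dw$contrast), collapse = " ")
  electrodes <- intersect(electrodes, rownames(dw$data))
  old <- graphics::par(mfrow = c(length(electrodes), 1),
                       mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  sp <- measurement_specs()
  ylim <- rev(range(dw$data[electrodes, ]))  # negative up
  for (el in electrodes) {
    graphics::plot(dw$times, dw$data[el, ], type = "l", ylim = ylim,
                   xlab = "", ylab = paste0(el, " (uV)"),
                   main = if (el == electrodes[1]) main else "")
    graphics::abline(h = 0, v = 0, col = "grey70")
    for (k in seq_len(nrow(sp)))
      graphics::rect(sp$window_lo[k], ylim[1], sp$window_hi[k], ylim[2],
                     border = NA,
                     col = grDevices::adjustcolor(k + 1, alpha.f = 0.06))
  }
  invisible(dw)
}

# PNG wrapper used by run_pipeline.
plot_difference_wave_png <- function(dw, file, width = 800, height = 900) {
  grDevices::png(file, width = width, height = height)
  on.exit(grDevices::dev.off())
  plot_difference_wave(dw)
  invisible(file)
}
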