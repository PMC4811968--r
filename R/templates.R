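#' Default component parameter table
#'
#' Reads the versioned table of group-mean peak amplitudes (per electrode)
#' and peak latencies (at Cz) with their between-subject SDs, for the MMN,
#' e-P3a, l-P3a and RON components in the novel-minus-standard (`NS`) and
#' deviant-minus-standard (`DS`) difference waveforms of three age groups
#' (Young, MiddleAged, Old). This table defines the ground truth the
#' synthetic generator embeds; the generator's calibration property is that
#' the measurement pipeline recovers it exactly from clean renderings.
#'
#' One cell (Old, DS, RON at Cz) is stored with its sign flipped relative to
#' the published value, which contradicts the component's negative polarity;
#' the `flag` column marks it (see the methods vignette).
#'
#' @return A data.frame of class `erp_templates` with columns `component`,
#'   `group`, `contrast`, `electrode`, `amplitude` (uV), `amplitude_sd`,
#'   `latency` (ms), `latency_sd`, `flag`.
#' @export
component_templates <- function() {
  path <- system.file("extdata", "component_templates_default.csv",
                      package = "erpdistract", mustWork = TRUE)
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  class(tab) <- c("erp_templates", "data.frame")
  tab
}

#' Measurement specifications for the four components
#'
#' Encodes the search window, polarity, amplitude electrodes and latency
#' electrode of each component: MMN (negative, 100-250 ms, Cz), e-P3a
#' (positive, 280-400 ms, Fz/Cz/Pz), l-P3a (positive, 350-500 ms, Fz/Cz/Pz)
#' and RON (negative, 400-700 ms, Fz/Cz). Latency is always read at Cz,
#' where the components are maximal. The e-P3a and l-P3a windows overlap;
#' the measurement stage resolves this with a sequential-assignment rule
#' (see [measure_components()]).
#'
#' @return A data.frame with one row per component, in measurement order.
#' @export
measurement_specs <- function() {
  data.frame(
    component = c("MMN", "eP3a", "lP3a", "RON"),
    polarity = c("negative", "positive", "positive", "negative"),
    window_lo = c(100, 280, 350, 400),
    window_hi = c(250, 400, 500, 700),
    electrodes = c("Cz", "Fz,Cz,Pz", "Fz,Cz,Pz", "Fz,Cz"),
    latency_electrode = "Cz",
    stringsAsFactors = FALSE
  )
}

component_polarity <- function(component) {
  sp <- measurement_specs()
  sp$polarity[match(component, sp$component)]
}

# Anchor amplitudes at the three midline sites used to build a component's
# scalp topography. Cells absent from the parameter table (MMN at Fz/Pz,
# RON at Pz) are filled with fixed fractions of the Cz value reflecting the
# components' fronto-central distributions; these synthetic anchors are
# never measured against the table.
.mmn_fz_frac <- 0.85
.mmn_pz_frac <- 0.55
.ron_pz_frac <- 0.40

anchor_amplitudes <- function(templates, group, contrast) {
  sel <- templates[templates$group == group & templates$contrast == contrast, ]
  comps <- measurement_specs()$component
  out <- matrix(NA_real_, nrow = length(comps), ncol = 3,
                dimnames = list(comps, c("Fz", "Cz", "Pz")))
  for (cp in comps) {
    rows <- sel[sel$component == cp, ]
    if (!nrow(rows)) stop("no template rows for ", cp, " ", group, " ", contrast)
    for (el in rows$electrode) out[cp, el] <- rows$amplitude[rows$electrode == el]
  }
  out["MMN", "Fz"] <- .mmn_fz_frac * out["MMN", "Cz"]
  out["MMN", "Pz"] <- .mmn_pz_frac * out["MMN", "Cz"]
  out["RON", "Pz"] <- .ron_pz_frac * out["RON", "Cz"]
  out
}

template_latencies <- function(templates, group, contrast) {
  sel <- templates[templates$group == group & templates$contrast == contrast &
                     templates$electrode == "Cz", ]
  stats::setNames(sel$latency, sel$component)[measurement_specs()$component]
}
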