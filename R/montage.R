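#' Electrode montage
#'
#' A montage holds the scalp electrode labels, their unit-sphere positions
#' (head-centered, nose along +y, vertex at +z), the labels of the four
#' periocular EOG channels, and the reference label. All recordings in this
#' package are referenced to the nose tip, which is retained as a label only
#' (the reference itself carries no data channel).
#'
#' @param labels character vector of scalp electrode names (must contain
#'   Fz, Cz and Pz, the midline sites every component is measured at).
#' @param positions numeric matrix with one row per label (scalp then EOG,
#'   or any superset; matched by rownames) and columns x, y, z. Rows are
#'   re-normalized to unit length.
#' @param eog_labels names of the EOG channels (default none).
#' @param reference_label name of the reference site.
#' @return An object of class `erp_montage`.
#' @export
montage <- function(labels, positions, eog_labels = character(),
                    reference_label = "nose") {
  all_labels <- c(labels, eog_labels)
  if (anyDuplicated(all_labels))
    stop("montage labels must be unique")
  if (!all(c("Fz", "Cz", "Pz") %in% labels))
    stop("montage must contain Fz, Cz and Pz")
  if (is.null(rownames(positions)))
    stop("positions must have labels as rownames")
  missing <- setdiff(all_labels, rownames(positions))
  if (length(missing))
    stop("no position for electrode(s): ", paste(missing, collapse = ", "))
  pos <- positions[all_labels, , drop = FALSE]
  nrm <- sqrt(rowSums(pos^2))
  if (any(nrm == 0)) stop("zero-length electrode position")
  pos <- pos / nrm
  colnames(pos) <- c("x", "y", "z")
  structure(
    list(labels = labels, eog_labels = eog_labels, positions = pos,
         reference_label = reference_label),
    class = "erp_montage"
  )
}

#' Default 49-channel 10-10 scalp montage
#'
#' Returns the package's default montage: 49 scalp electrodes from the
#' international 10-10 system (an interior subset; Fpz is reserved as ground
#' and excluded) plus four periocular EOG channels (VEOGU/VEOGL above and
#' below the right eye, HEOGL/HEOGR at the outer canthi). Positions are
#' idealized unit-sphere coordinates shipped with the package.
#'
#' @return An `erp_montage` with 49 scalp and 4 EOG channels.
#' @export
standard_1010_montage <- function() {
  path <- system.file("extdata", "montage_1010_49.csv",
                      package = "erpdistract", mustWork = TRUE)
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  pos <- as.matrix(tab[, c("x", "y", "z")])
  rownames(pos) <- tab$label
  montage(labels = tab$label[tab$type == "scalp"],
          positions = pos,
          eog_labels = tab$label[tab$type == "eog"],
          reference_label = "nose")
}

#' @export
print.erp_montage <- function(x, ...) {
  cat("<erp_montage> ", length(x$labels), " scalp + ",
      length(x$eog_labels), " EOG channels, reference: ",
      x$reference_label, "\n", sep = "")
  invisible(x)
}

# Number of data channels a recording with this montage carries.
n_channels <- function(montage) length(montage$labels) + length(montage$eog_labels)

all_channel_labels <- function(montage) c(montage$labels, montage$eog_labels)

# Great-circle angle (radians) between unit-sphere points.
# a: n x 3 matrix, b: m x 3 matrix -> n x m matrix of angles.
arc_angle <- function(a, b) {
  cosang <- tcrossprod(a, b)
  cosang[cosang > 1] <- 1
  cosang[cosang < -1] <- -1
  acos(cosang)
}
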