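#' Recording container I/O
#'
#' A recording is stored as a directory:
#' \itemize{
#'   \item `data.bin` — the channels x samples matrix as little-endian
#'     64-bit doubles in column-major (sample-by-sample) order;
#'   \item `meta.json` — sample rate, dimensions, channel order, group;
#'   \item `timeline.csv` — the event table (full-precision numerics);
#'   \item `montage.json` — label -> x,y,z plus EOG/reference labels.
#' }
#' Round trips are bit-exact for the data array and field-exact for the
#' timeline.
#'
#' @param rec an `erp_recording`.
#' @param path directory to write (created if needed).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(path, "data.bin"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.vector(rec$data), con, size = 8, endian = "little")
  jsonlite::write_json(
    list(sample_rate = rec$sample_rate,
         n_channels = nrow(rec$data), n_samples = ncol(rec$data),
         channels = rownames(rec$data),
         group = rec$group, subject_seed = rec$subject_seed,
         byte_order = "little", dtype = "float64"),
    file.path(path, "meta.json"), auto_unbox = TRUE, digits = NA)
  write_timeline_csv(rec$timeline, file.path(path, "timeline.csv"))
  m <- rec$montage
  jsonlite::write_json(
    list(scalp_labels = m$labels, eog_labels = m$eog_labels,
         reference_label = m$reference_label,
         positions = apply(m$positions, 1, function(p)
           list(x = p[[1]], y = p[[2]], z = p[[3]]))),
    file.path(path, "montage.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Full-precision CSV for the timeline (plain write.csv would round RTs).
write_timeline_csv <- function(tl, file) {
  tab <- as.data.frame(tl)
  tab$rt <- ifelse(is.na(tab$rt), "",
                   formatC(tab$rt, digits = 17, format = "g"))
  utils::write.csv(tab, file, row.names = FALSE, quote = FALSE)
}

read_timeline_csv <- function(file) {
  tl <- utils::read.csv(file, stringsAsFactors = FALSE,
                        colClasses = c(rt = "character"))
  tl$rt <- suppressWarnings(as.numeric(tl$rt))
  class(tl) <- c("erp_timeline", "data.frame")
  tl
}

#' @rdname write_recording
#' @return For `read_recording`, the reconstructed `erp_recording`.
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  con <- file(file.path(path, "data.bin"), "rb")
  on.exit(close(con), add = TRUE)
  v <- readBin(con, "double", n = meta$n_channels * meta$n_samples,
               size = 8, endian = "little")
  data <- matrix(v, nrow = meta$n_channels,
                 dimnames = list(meta$channels, NULL))
  mj <- jsonlite::read_json(file.path(path, "montage.json"),
                            simplifyVector = TRUE)
  pos <- t(vapply(mj$positions, function(p) c(p$x, p$y, p$z), numeric(3)))
  rownames(pos) <- names(mj$positions)
  m <- montage(labels = mj$scalp_labels, positions = pos,
               eog_labels = mj$eog_labels,
               reference_label = mj$reference_label)
  missing <- setdiff(all_channel_labels(m), meta$channels)
  if (length(missing))
    stop("recording lacks channel(s) named in montage: ",
         paste(missing, collapse = ", "))
  tl <- read_timeline_csv(file.path(path, "timeline.csv"))
  validate_timeline(tl)
  structure(list(montage = m, sample_rate = as.numeric(meta$sample_rate),
                 data = data,
                 timeline = tl, group = meta$group,
                 subject_seed = meta$subject_seed),
            class = "erp_recording")
}
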