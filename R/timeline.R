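#' Task configuration for the auditory-visual distraction paradigm
#'
#' Defaults reproduce the study design the synthetic generator emulates:
#' 500 auditory-visual pairs in 2 blocks; sounds are 70% standard, 15%
#' deviant, 15% novel; visual stimuli are 33% numbers, 33% letters (Go) and
#' 34% triangles (NoGo, absorbing rounding); each 150-ms sound is followed
#' by a 200-ms visual stimulus at a 300-ms onset-to-onset lag, with 2000 ms
#' between consecutive pair onsets.
#'
#' @param n_pairs number of A-V pairs.
#' @param n_blocks number of blocks (pairs split evenly; remainder to last).
#' @param p_standard,p_deviant,p_novel auditory category proportions (sum 1).
#' @param p_number,p_letter,p_triangle visual category proportions (sum 1).
#' @param sound_dur,visual_dur stimulus durations, ms.
#' @param av_soa auditory-to-visual onset-to-onset lag, ms.
#' @param inter_pair onset-to-onset interval between pairs, ms.
#' @param lead_in recording time before the first auditory onset, ms.
#' @return A list of class `erp_task_config`.
#' @export
task_config <- function(n_pairs = 500, n_blocks = 2,
                        p_standard = 0.70, p_deviant = 0.15, p_novel = 0.15,
                        p_number = 0.33, p_letter = 0.33, p_triangle = 0.34,
                        sound_dur = 150, visual_dur = 200,
                        av_soa = 300, inter_pair = 2000, lead_in = 1000) {
  if (abs(p_standard + p_deviant + p_novel - 1) > 1e-9)
    stop("auditory stimulus probabilities must sum to 1")
  if (abs(p_number + p_letter + p_triangle - 1) > 1e-9)
    stop("visual stimulus probabilities must sum to 1")
  if (n_pairs < 1 || n_blocks < 1) stop("n_pairs and n_blocks must be >= 1")
  structure(as.list(environment()), class = "erp_task_config")
}

# Run expr with a temporary RNG state seeded by `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate an event timeline for one session
#'
#' Category counts are realized exactly (stratified, then shuffled): each
#' auditory category receives `round(p * n_pairs)` events with the standard
#' category absorbing any rounding remainder, and the triangle (NoGo)
#' category absorbs rounding on the visual side. Auditory onsets are evenly
#' spaced at the configured inter-pair interval; every visual onset trails
#' its auditory onset by the configured SOA.
#'
#' @param config an [task_config()] object.
#' @param seed integer seed; the same seed always yields the same timeline.
#' @return A data.frame of class `erp_timeline` with one row per pair:
#'   `pair` (1-based), `block`, `auditory_onset` (ms), `auditory_type`,
#'   `visual_onset` (ms), `visual_type`, `response`, `rt` (ms, NA until
#'   behavior is simulated).
#' @export
generate_timeline <- function(config = task_config(), seed = 1) {
  n <- config$n_pairs
  n_dev <- round(config$p_deviant * n)
  n_nov <- round(config$p_novel * n)
  n_std <- n - n_dev - n_nov
  n_num <- round(config$p_number * n)
  n_let <- round(config$p_letter * n)
  n_tri <- n - n_num - n_let
  if (min(n_std, n_dev, n_nov, n_num, n_let, n_tri) < 0)
    stop("degenerate category counts")
  aud <- rep(c("standard", "deviant", "novel"), c(n_std, n_dev, n_nov))
  vis <- rep(c("number", "letter", "triangle"), c(n_num, n_let, n_tri))
  with_seed(seed, {
    aud <- sample(aud)
    vis <- sample(vis)
  })
  per_block <- rep(n %/% config$n_blocks, config$n_blocks)
  per_block[config$n_blocks] <- per_block[config$n_blocks] + n %% config$n_blocks
  onset <- config$lead_in + (seq_len(n) - 1) * config$inter_pair
  tl <- data.frame(
    pair = seq_len(n),
    block = rep(seq_len(config$n_blocks), per_block),
    auditory_onset = onset,
    auditory_type = aud,
    visual_onset = onset + config$av_soa,
    visual_type = vis,
    response = "none",
    rt = NA_real_,
    stringsAsFactors = FALSE
  )
  class(tl) <- c("erp_timeline", "data.frame")
  attr(tl, "config") <- config
  tl
}

# Validate the structural invariants of a timeline (used on I/O and by the
# epoching stage). Errors on violation, invisibly TRUE otherwise.
validate_timeline <- function(tl, av_soa = NULL, inter_pair = NULL) {
  cfg <- attr(tl, "config")
  if (is.null(av_soa)) av_soa <- if (!is.null(cfg)) cfg$av_soa else 300
  need <- c("pair", "block", "auditory_onset", "auditory_type",
            "visual_onset", "visual_type", "response", "rt")
  miss <- setdiff(need, names(tl))
  if (length(miss)) stop("timeline lacks column(s): ", paste(miss, collapse = ", "))
  if (any(tl$visual_onset - tl$auditory_onset != av_soa))
    stop("visual_onset - auditory_onset must equal the configured SOA (",
         av_soa, " ms) for every pair")
  if (is.unsorted(tl$auditory_onset, strictly = TRUE))
    stop("event times must be strictly increasing")
  if (!is.null(inter_pair) && nrow(tl) > 1 &&
      any(diff(tl$auditory_onset) != inter_pair))
    stop("consecutive pair onsets must differ by the inter-pair interval")
  if (!all(tl$auditory_type %in% c("standard", "deviant", "novel")))
    stop("unknown auditory stimulus type")
  if (!all(tl$visual_type %in% c("number", "letter", "triangle")))
    stop("unknown visual stimulus type")
  invisible(TRUE)
}

# Go pairs are those whose visual stimulus requires a response.
is_go <- function(tl) tl$visual_type %in% c("number", "letter")
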