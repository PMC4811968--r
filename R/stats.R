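#' @title Mixed-design ANOVA with Greenhouse-Geisser correction
#' @description Classical univariate mixed-model analysis for designs with
#'   one between-subject factor (subjects nested in groups) and up to two
#'   fully crossed within-subject factors, as used for RT (Group x
#'   Condition) and component parameters (Group x Difference, Group x
#'   Difference x Electrode). Sums of squares are Type III with unweighted
#'   cell means for the (possibly unbalanced) between factor; each within
#'   effect is tested against its own subject-interaction error stratum;
#'   Greenhouse-Geisser epsilon is estimated from the pooled within-group
#'   covariance of the orthonormal contrast scores and applied to the
#'   degrees of freedom of every within effect with more than two levels.
#' @name mixed-anova
NULL

# Orthonormal contrast matrix (k x k-1) spanning the deviation space.
orthonormal_contrasts <- function(k) {
  cc <- stats::contr.helmert(k)
  sweep(cc, 2, sqrt(colSums(cc^2)), "/")
}

#' Greenhouse-Geisser epsilon
#'
#' Estimates the sphericity correction factor from a k x k covariance
#' matrix of within-subject scores. Equals 1 under compound symmetry and
#' is bounded in `[1/(k-1), 1]`. Invariant to adding a constant to all
#' scores and to the covariance scale.
#'
#' @param S covariance matrix of the k within-cell scores.
#' @return epsilon (scalar).
#' @export
gg_epsilon <- function(S) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S)) stop("covariance matrix must be square")
  k <- nrow(S)
  if (k < 2) stop("need at least 2 within levels")
  if (k == 2) return(1)
  C <- orthonormal_contrasts(k)
  Sc <- crossprod(C, S %*% C)
  if (sum(Sc^2) == 0) return(1)  # degenerate: no contrast variance
  eps <- sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
  min(max(eps, 1 / (k - 1)), 1)
}

# epsilon from an orthonormal contrast-score covariance (q x q), used for
# interaction strata where q = product of (k_i - 1).
gg_epsilon_contrast <- function(Sc) {
  q <- nrow(Sc)
  if (q == 1 || sum(Sc^2) == 0) return(1)
  eps <- sum(diag(Sc))^2 / (q * sum(Sc^2))
  min(max(eps, 1 / q), 1)
}

#' Mixed-design ANOVA
#'
#' @param data long-format data.frame.
#' @param dv name of the dependent-variable column.
#' @param subject name of the subject identifier column.
#' @param between name of the between-subject factor column (or NULL for a
#'   pure one-way between design use `within = NULL` instead).
#' @param within character vector (length 0-2) of within-subject factor
#'   columns; every subject must have exactly one observation per within
#'   cell.
#' @return An `erp_anova` data.frame: one row per effect with `df1`, `df2`
#'   (uncorrected), `F`, `epsilon` (NA for between effects and two-level
#'   within effects, where it is exactly 1), `p` (Greenhouse-Geisser
#'   corrected for within effects with >2 levels), `eta_p2`, and the
#'   effect and error sums of squares.
#' @export
mixed_anova <- function(data, dv, subject, between, within = NULL) {
  data <- as.data.frame(data)
  for (col in c(dv, subject, between, within))
    if (!col %in% names(data)) stop("column not found: ", col)
  g_f <- factor(data[[between]], levels = unique(data[[between]]))
  if (nlevels(g_f) < 2) stop("between factor needs >= 2 levels")
  w_f <- lapply(within, function(w)
    factor(data[[w]], levels = unique(data[[w]])))
  names(w_f) <- within
  subj <- factor(data[[subject]], levels = unique(data[[subject]]))

  if (length(within) == 0) {
    return(one_way_anova(data[[dv]], g_f))
  }
  ks <- vapply(w_f, nlevels, 0L)
  p <- prod(ks)
  # cell index with the first within factor varying fastest (matches the
  # kronecker ordering of the contrast sets below)
  ci <- as.integer(w_f[[1]]) +
    if (length(w_f) == 2) (as.integer(w_f[[2]]) - 1L) * ks[1] else 0L
  # wide matrix Y: subjects x cells
  Y <- matrix(NA_real_, nrow = nlevels(subj), ncol = p)
  Y[cbind(as.integer(subj), ci)] <- data[[dv]]
  if (anyNA(Y)) stop("each subject needs exactly one observation per cell")
  grp <- g_f[match(levels(subj), subj)]
  ng <- table(grp)
  if (any(ng < 2)) stop("need >= 2 subjects per group")
  N <- nrow(Y); g <- nlevels(grp)
  nh <- g / sum(1 / ng)  # harmonic mean group size

  # contrast sets per within effect: columns of p x q matrices built as
  # Kronecker products of orthonormal contrasts / unit means, with the
  # first within factor varying fastest in the cell ordering.
  base <- lapply(ks, function(k) list(u = matrix(1 / sqrt(k), k, 1),
                                      c = orthonormal_contrasts(k)))
  kron_for <- function(use) {
    # use: logical per within factor, TRUE -> contrast space, FALSE -> mean
    M <- matrix(1, 1, 1)
    for (j in rev(seq_along(ks)))  # slowest factor leftmost in kronecker
      M <- kronecker(M, if (use[j]) base[[j]]$c else base[[j]]$u)
    M
  }
  effect_sets <- list()
  for (j in seq_along(within)) {
    use <- seq_along(within) == j
    effect_sets[[within[j]]] <- kron_for(use)
  }
  if (length(within) == 2)
    effect_sets[[paste(within, collapse = ":")]] <- kron_for(c(TRUE, TRUE))

  rows <- list()
  # between-subject stratum
  z0 <- as.vector(Y %*% matrix(1 / sqrt(p), p, 1))
  gm <- tapply(z0, grp, mean)
  ss_g <- sum(ng * (gm - sum(ng * gm) / N)^2)
  ss_es <- sum((z0 - gm[grp])^2)
  Fg <- safe_F(ss_g / (g - 1), ss_es / (N - g))
  rows[[between]] <- data.frame(
    effect = between, df1 = g - 1, df2 = N - g,
    F = Fg, epsilon = NA_real_,
    p = stats::pf(Fg, g - 1, N - g, lower.tail = FALSE),
    eta_p2 = if (ss_g == 0) 0 else ss_g / (ss_g + ss_es),
    ss_effect = ss_g, ss_error = ss_es,
    stringsAsFactors = FALSE)

  # grand-mean centering: within contrasts annihilate constants exactly
  # only in exact arithmetic; centering removes the floating-point residue
  # (all within sums of squares are invariant to a constant shift)
  Yc <- Y - mean(Y)
  for (nm in names(effect_sets)) {
    M <- effect_sets[[nm]]
    q <- ncol(M)
    Z <- Yc %*% M  # subjects x q contrast scores
    zg <- apply(Z, 2, function(col) tapply(col, grp, mean))  # g x q
    zg <- matrix(zg, nrow = g)
    resid <- Z - zg[as.integer(grp), , drop = FALSE]
    ss_err <- sum(resid^2)
    df_err <- (N - g) * q
    # within main effect / pure within interaction: Type III test of the
    # unweighted grand mean of the group means
    zu <- colMeans(zg)
    ss_w <- g * nh * sum(zu^2)
    # group x effect interaction: between-group dispersion of the scores
    zw <- colSums(Z) / N
    ss_gw <- sum(rep(as.vector(ng), q) * (zg - rep(zw, each = g))^2)
    S_pool <- crossprod(resid) / (N - g)
    eps <- gg_epsilon_contrast(S_pool)
    for (ef in c("w", "gw")) {
      ss <- if (ef == "w") ss_w else ss_gw
      df1 <- if (ef == "w") q else (g - 1) * q
      Fv <- safe_F(ss / df1, ss_err / df_err)
      pv <- stats::pf(Fv, df1 * eps, df_err * eps, lower.tail = FALSE)
      lab <- if (ef == "w") nm else paste(between, nm, sep = ":")
      rows[[lab]] <- data.frame(
        effect = lab, df1 = df1, df2 = df_err, F = Fv,
        epsilon = if (q > 1) eps else NA_real_, p = pv,
        eta_p2 = if (ss == 0) 0 else ss / (ss + ss_err),
        ss_effect = ss, ss_error = ss_err,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("erp_anova", "data.frame")
  attr(out, "n_subjects") <- N
  out
}

# An effect with zero sum of squares has F = 0 by convention (covers the
# degenerate all-identical-data case, where the error SS is zero too).
safe_F <- function(ms_effect, ms_error) {
  if (ms_effect == 0) return(0)
  ms_effect / ms_error
}

one_way_anova <- function(y, grp) {
  g <- nlevels(grp); N <- length(y)
  gm <- tapply(y, grp, mean)
  ng <- table(grp)
  ss_g <- sum(ng * (gm - mean(y))^2)
  ss_e <- sum((y - gm[grp])^2)
  Fv <- (ss_g / (g - 1)) / (ss_e / (N - g))
  out <- data.frame(effect = "group", df1 = g - 1, df2 = N - g, F = Fv,
                    epsilon = NA_real_,
                    p = stats::pf(Fv, g - 1, N - g, lower.tail = FALSE),
                    eta_p2 = ss_g / (ss_g + ss_e),
                    ss_effect = ss_g, ss_error = ss_e,
                    stringsAsFactors = FALSE)
  class(out) <- c("erp_anova", "data.frame")
  out
}

#' Cohen's d
#'
#' Between-subject design: `|mean1 - mean2| / sqrt((sd1^2 + sd2^2) / 2)` —
#' the unweighted root-mean-square of the two SDs in the denominator (the
#' two-group convention of common power-analysis software). Within design:
#' `mean1`/`sd1` are the mean and SD of the paired difference scores and
#' d = |mean1| / sd1.
#'
#' @param mean1,sd1,n1 first group (or difference-score) statistics.
#' @param mean2,sd2,n2 second group statistics (between design only).
#' @param design `"between"` or `"within"`.
#' @return d (non-negative scalar).
#' @export
cohens_d <- function(mean1, sd1, n1 = NULL, mean2 = 0, sd2 = NULL,
                     n2 = NULL, design = c("between", "within")) {
  design <- match.arg(design)
  if (design == "within") {
    if (sd1 <= 0) stop("sd must be > 0")
    return(abs(mean1) / sd1)
  }
  if (is.null(sd2)) stop("between design needs both sds")
  if (sd1 <= 0 || sd2 <= 0) stop("sds must be > 0")
  abs(mean1 - mean2) / sqrt((sd1^2 + sd2^2) / 2)
}

#' Bonferroni-corrected pairwise post-hoc comparisons
#'
#' All pairwise comparisons among the levels of one factor. Between-subject
#' factors use two-sample pooled-variance t-tests on subject scores
#' (averaged over any within factors beforehand by the caller); within
#' factors use paired t-tests on the per-subject cell scores. Each p-value
#' is multiplied by the family size (the number of pairs) and capped at 1;
#' Cohen's d follows [cohens_d()] with the matching design.
#'
#' @param data long data.frame with one row per subject x level.
#' @param dv,subject,factor column names.
#' @param design `"between"` or `"within"`.
#' @return A data.frame of class `erp_posthoc`: level pair, mean
#'   difference, t, df, adjusted p, Cohen's d.
#' @export
bonferroni_posthoc <- function(data, dv, subject, factor,
                               design = c("between", "within")) {
  design <- match.arg(design)
  f <- base::factor(data[[factor]], levels = unique(data[[factor]]))
  lev <- levels(f)
  if (length(lev) < 2) stop("post-hoc family needs >= 2 levels")
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  fam <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    if (design == "between") {
      x <- data[[dv]][f == pr[1]]
      y <- data[[dv]][f == pr[2]]
      tt <- safe_t(stats::t.test(x, y, var.equal = TRUE), mean(x) - mean(y),
                   length(x) + length(y) - 2)
      d <- if (stats::sd(x) > 0 && stats::sd(y) > 0)
        cohens_d(mean(x), stats::sd(x), length(x),
                 mean(y), stats::sd(y), length(y), design = "between")
      else NA_real_
      md <- mean(x) - mean(y)
    } else {
      sx <- data[f == pr[1], c(subject, dv)]
      sy <- data[f == pr[2], c(subject, dv)]
      mrg <- merge(sx, sy, by = subject)
      dif <- mrg[[paste0(dv, ".x")]] - mrg[[paste0(dv, ".y")]]
      tt <- safe_t(stats::t.test(dif), mean(dif), length(dif) - 1)
      d <- if (stats::sd(dif) > 0)
        cohens_d(mean(dif), stats::sd(dif), design = "within") else NA_real_
      md <- mean(dif)
    }
    data.frame(level1 = pr[1], level2 = pr[2], mean_diff = md,
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_bonferroni = min(1, tt$p.value * fam),
               cohens_d = d, design = design, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("erp_posthoc", "data.frame")
  out
}

# t.test errors on zero-variance input; degenerate comparisons get the
# limiting values (p = 1 for a zero difference, p = 0 otherwise, d = NA).
safe_t <- function(expr, mean_diff, df) {
  tryCatch(expr, error = function(e) {
    list(statistic = if (mean_diff == 0) 0 else Inf * sign(mean_diff),
         parameter = df, p.value = if (mean_diff == 0) 1 else 0,
         estimate = mean_diff)
  })
}

#' Reaction-time analysis
#'
#' Computes per-subject mean RT per auditory condition over correct Go
#' responses with RT inside the validity window (default 100-1500 ms),
#' then runs the mixed Group x Condition ANOVA and Bonferroni post-hoc
#' comparisons for both factors.
#'
#' @param trials long trial table (as from [simulate_cohort_rts()]):
#'   columns subject, group, auditory_type, visual_type, response, rt.
#' @param rt_window RT validity window, ms.
#' @return A list: `cell_means` (subject x condition mean RTs), `anova`,
#'   `posthoc_group`, `posthoc_condition`.
#' @export
rt_analysis <- function(trials, rt_window = c(100, 1500)) {
  valid <- trials$visual_type %in% c("number", "letter") &
    trials$response != "none" & !is.na(trials$rt) &
    trials$rt >= rt_window[1] & trials$rt <= rt_window[2]
  v <- trials[valid, , drop = FALSE]
  v$condition <- factor(c(standard = "Standard", deviant = "Deviant",
                          novel = "Novel")[v$auditory_type],
                        levels = c("Standard", "Deviant", "Novel"))
  cm <- stats::aggregate(rt ~ subject + group + condition, data = v,
                         FUN = mean)
  counts <- table(cm$subject)
  if (any(counts < 3))
    stop("subject(s) with no valid trials in some condition: ",
         paste(names(counts)[counts < 3], collapse = ", "))
  cm <- cm[order(cm$subject, cm$condition), ]
  an <- mixed_anova(cm, dv = "rt", subject = "subject", between = "group",
                    within = "condition")
  subj_means <- stats::aggregate(rt ~ subject + group, data = cm, FUN = mean)
  list(cell_means = cm, anova = an,
       posthoc_group = bonferroni_posthoc(subj_means, "rt", "subject",
                                          "group", design = "between"),
       posthoc_condition = bonferroni_posthoc(cm, "rt", "subject",
                                              "condition",
                                              design = "within"))
}
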