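# Confidence intervals for QTL location.
#
# The primary method resamples the residuals of the peak-marker genetic
# fit: each simulated trait re-attaches a permutation of the residuals to
# the fitted genetic values, the neighborhood of the peak is rescanned,
# and the argmax positions across simulations form the interval.  A quick
# profile-support method is included for comparison only.

#' Simulation-based QTL location confidence interval
#'
#' For each of `n_sim` simulations, the residuals of the weighted founder
#' fit at the peak marker are randomly permuted (without replacement) and
#' recombined with the fitted genetic values; markers within
#' `neighborhood_mb` of the peak are rescanned and the argmax position
#' recorded.  The level-L interval is the central L% of the argmax
#' distribution (inverse-ECDF quantiles, so endpoints are marker
#' positions), widened to contain the peak.
#'
#' The default recombination is additive (`fitted + permuted residual`).
#' Mode `"multiplicative"` instead forms
#' `permuted residual * exp(fitted)`; this reproduces a published variant
#' of the resampling formula whose exponential factor is dimensionally
#' surprising, and is provided for comparison only (see the methods
#' vignette).
#'
#' @inheritParams marker_fit
#' @param qtl a one-row [call_qtls()] data frame, or a list with
#'   `peak_marker`.
#' @param n_sim number of simulated rescans (>= 100 recommended).
#' @param neighborhood_mb half-width of the rescanned window, Mb (default 5).
#' @param levels confidence levels, percent.
#' @param mode `"additive"` (default) or `"multiplicative"`.
#' @param seed optional integer seed.
#' @return Data frame of class `cc_ci`: one row per level with start/end bp
#'   and width in Mb; attribute `argmax_bp` holds the simulated positions.
#' @export
qtl_ci_sim <- function(line_means, tensor, qtl, n_sim = 1000,
                       neighborhood_mb = 5, levels = c(50, 90, 95),
                       weights = NULL, mode = c("additive", "multiplicative"),
                       seed = NULL, clamp = LOGP_CLAMP) {
  mode <- match.arg(mode)
  stopifnot(n_sim >= 1)
  pm <- if (is.data.frame(qtl)) qtl$peak_marker[1] else qtl$peak_marker
  lm_ <- resolve_means(line_means, weights)
  li <- tensor_lines(tensor, lm_$lines)
  mi <- marker_index(tensor, pm)
  mk <- tensor$markers
  ch <- mk$chrom[mi]
  nb <- which(mk$chrom == ch &
                abs(mk$pos_bp - mk$pos_bp[mi]) <= neighborhood_mb * 1e6)
  if (length(nb) < 3) stop("neighborhood contains fewer than 3 markers")

  fit <- marker_fit(setNames(lm_$y, lm_$lines), tensor, pm,
                    weights = lm_$w, clamp = clamp)
  Xpk <- matrix(tensor$P[li, mi, ], nrow = length(li))
  fitted <- fit$intercept + as.vector(Xpk %*% fit$beta)
  resid <- lm_$y - fitted
  cube <- tensor_cube(tensor, li, nb)
  pos_nb <- mk$pos_bp[nb]

  argmax_bp <- with_seed(seed, {
    vapply(seq_len(n_sim), function(s) {
      r <- resid[sample.int(length(resid))]
      ystar <- if (mode == "additive") fitted + r else r * exp(fitted)
      sc <- scan_wls_cpp(cube, ystar, lm_$w, cc_ref_founder(), clamp)
      pos_nb[which.max(sc$logp)]
    }, numeric(1))
  })

  peak_bp <- mk$pos_bp[mi]
  rows <- lapply(sort(levels), function(L) {
    a <- (1 - L / 100) / 2
    qs <- quantile(argmax_bp, c(a, 1 - a), type = 1, names = FALSE)
    lo <- min(qs[1], peak_bp)
    hi <- max(qs[2], peak_bp)
    data.frame(trait = if (is.data.frame(qtl)) qtl$trait[1] else NA_character_,
               chrom = ch, level = L, start_bp = lo, end_bp = hi,
               width_mb = (hi - lo) / 1e6, method = "simulation",
               n_sim = n_sim, neighborhood_mb = neighborhood_mb,
               seed = seed %||% NA_integer_)
  })
  out <- do.call(rbind, rows)
  # nesting: lower-level intervals sit inside higher-level ones
  for (j in seq_len(nrow(out) - 1)) {
    stopifnot(out$start_bp[j] >= out$start_bp[j + 1],
              out$end_bp[j] <= out$end_bp[j + 1])
  }
  attr(out, "argmax_bp") <- argmax_bp
  class(out) <- c("cc_ci", "data.frame")
  out
}

#' Quick profile-support confidence interval
#'
#' A closed-form comparison interval derived from the scan profile around
#' the peak: using the chi-square approximation for the profile of the
#' association statistic, the level-L interval is the contiguous set of
#' markers around the peak whose logP stays within
#' `qchisq(L/100, 1) / (2 ln 10)` of the peak logP, with endpoints snapped
#' outward to marker positions.  Flagged `method = "li2011"`; intended for
#' cross-checking the simulation intervals, not as the primary method.
#'
#' @param qtl a one-row [call_qtls()] data frame or list with `peak_marker`.
#' @param scan a [scan_haplotypes()] result covering the peak's chromosome.
#' @param levels confidence levels, percent.
#' @return Data frame of class `cc_ci`, one row per level.
#' @export
qtl_ci_li <- function(qtl, scan, levels = c(50, 90, 95)) {
  pm <- if (is.data.frame(qtl)) qtl$peak_marker[1] else qtl$peak_marker
  mi <- if (is.numeric(pm)) as.integer(pm) else
    match(pm, scan$markers$marker_id)
  if (is.na(mi) || mi < 1 || mi > nrow(scan$markers)) {
    stop("peak marker not in scan")
  }
  mk <- scan$markers
  ch <- mk$chrom[mi]
  idx <- which(mk$chrom == ch)
  if (length(idx) < 3) stop("need at least 3 markers on the peak chromosome")
  lp <- scan$logp[idx]
  p0 <- match(mi, idx)
  rows <- lapply(sort(levels), function(L) {
    drop <- qchisq(L / 100, df = 1) / (2 * log(10))
    lo <- p0
    while (lo > 1 && lp[lo - 1] >= lp[p0] - drop) lo <- lo - 1
    hi <- p0
    while (hi < length(idx) && lp[hi + 1] >= lp[p0] - drop) hi <- hi + 1
    data.frame(trait = if (is.data.frame(qtl)) qtl$trait[1] else NA_character_,
               chrom = ch, level = L, start_bp = mk$pos_bp[idx[lo]],
               end_bp = mk$pos_bp[idx[hi]],
               width_mb = (mk$pos_bp[idx[hi]] - mk$pos_bp[idx[lo]]) / 1e6,
               method = "li2011", n_sim = NA_integer_,
               neighborhood_mb = NA_real_, seed = NA_integer_)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cc_ci", "data.frame")
  out
}
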