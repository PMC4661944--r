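# Founder-haplotype association scan.
#
# At each marker the covariate-adjusted line means are regressed (weighted
# by line size) on the founder descent dosages, with the WSB column omitted
# so that the WSB effect is identically 0; the marker's logP is the -log10 P
# of the F test of this genetic model against the weighted-mean null.
# Genome-wide thresholds come from permuting line labels.

# normalise line means input: named vector or cc_line_means data frame
resolve_means <- function(line_means, weights = NULL) {
  if (is.data.frame(line_means)) {
    stopifnot(all(c("line", "mean") %in% names(line_means)))
    y <- setNames(line_means$mean, line_means$line)
    w <- weights %||% (if ("n" %in% names(line_means)) line_means$n else
      rep(1, nrow(line_means)))
  } else {
    if (is.null(names(line_means))) stop("line means must be named by line")
    y <- line_means
    w <- weights %||% rep(1, length(y))
  }
  if (length(w) != length(y)) stop("weights do not match line means")
  if (any(w <= 0)) stop("weights must be positive")
  list(y = as.numeric(y), w = as.numeric(w), lines = names(y))
}

#' Weighted founder-effect fit at a single marker
#'
#' @param line_means adjusted line means: a [adjusted_line_means()] data
#'   frame or a named numeric vector.
#' @param tensor a [cc_tensor()].
#' @param marker marker id or index.
#' @param weights per-line weights; defaults to the line sizes carried by
#'   `line_means` (or 1).
#' @param clamp upper bound on reported logP.
#' @return List with `rss_genetic`, `rss_null`, `f_stat`, `logp`, `rank`,
#'   `beta` (named founder effects, WSB exactly 0) and `intercept`.
#' @export
marker_fit <- function(line_means, tensor, marker, weights = NULL,
                       clamp = LOGP_CLAMP) {
  lm_ <- resolve_means(line_means, weights)
  li <- tensor_lines(tensor, lm_$lines)
  mi <- marker_index(tensor, marker)
  cube <- tensor_cube(tensor, li, mi)
  fit <- scan_wls_cpp(cube, lm_$y, lm_$w, cc_ref_founder(), clamp)
  n <- length(lm_$y)
  rank <- fit$rank[1]
  df1 <- rank - 1
  df2 <- n - rank
  fstat <- if (df1 >= 1 && df2 >= 1 && fit$rss[1] > 0) {
    ((fit$rss_null - fit$rss[1]) / df1) / (fit$rss[1] / df2)
  } else Inf
  beta <- setNames(fit$beta[, 1], cc_founders())
  list(rss_genetic = fit$rss[1], rss_null = fit$rss_null,
       f_stat = fstat, logp = fit$logp[1], rank = rank,
       beta = beta, intercept = fit$intercept[1])
}

#' Genome scan of line means on founder haplotype dosages
#'
#' Applies [marker_fit()] at every marker.  The result is deterministic
#' given its inputs.
#'
#' @inheritParams marker_fit
#' @param trait trait label attached to the result.
#' @return Object of class `cc_scan`: marker map plus per-marker `logp`,
#'   `rss`, `rank` and an 8 x markers founder-effect matrix `beta` (WSB row
#'   identically 0).
#' @export
scan_haplotypes <- function(line_means, tensor, weights = NULL,
                            trait = attr(line_means, "trait") %||% "trait",
                            clamp = LOGP_CLAMP) {
  lm_ <- resolve_means(line_means, weights)
  li <- tensor_lines(tensor, lm_$lines)
  cube <- tensor_cube(tensor, li)
  fit <- scan_wls_cpp(cube, lm_$y, lm_$w, cc_ref_founder(), clamp)
  rownames(fit$beta) <- cc_founders()
  colnames(fit$beta) <- tensor$markers$marker_id
  # genetic RSS can never exceed the null RSS (nested models)
  stopifnot(all(fit$rss <= fit$rss_null + 1e-8 * max(fit$rss_null, 1)))
  structure(list(markers = tensor$markers, logp = as.numeric(fit$logp),
                 beta = fit$beta, rss = as.numeric(fit$rss),
                 rss_null = fit$rss_null, rank = as.integer(fit$rank),
                 trait = trait, lines = lm_$lines, weights = lm_$w,
                 clamp = clamp, ref = cc_founders()[cc_ref_founder()]),
            class = "cc_scan")
}

#' @export
print.cc_scan <- function(x, ...) {
  pk <- which.max(x$logp)
  cat(sprintf("Haplotype scan of %s: %d markers, %d lines\n",
              x$trait, length(x$logp), length(x$lines)))
  cat(sprintf("Peak logP %.2f at %s (chr %s, %.2f Mb)\n", x$logp[pk],
              x$markers$marker_id[pk], x$markers$chrom[pk],
              x$markers$pos_bp[pk] / 1e6))
  invisible(x)
}

#' @export
summary.cc_scan <- function(object, ...) {
  by_chr <- split(seq_along(object$logp), object$markers$chrom)
  rows <- lapply(names(by_chr), function(ch) {
    i <- by_chr[[ch]][which.max(object$logp[by_chr[[ch]]])]
    data.frame(chrom = ch, peak_marker = object$markers$marker_id[i],
               peak_bp = object$markers$pos_bp[i],
               peak_logp = object$logp[i])
  })
  out <- do.call(rbind, rows)
  out[order(match(out$chrom, unique(object$markers$chrom))), ]
}

#' Founder effects at a marker
#' @param object a `cc_scan`.
#' @param marker marker id or index; default the peak marker.
#' @param ... unused.
#' @return Named numeric vector of 8 founder effects (WSB = 0).
#' @export
coef.cc_scan <- function(object, marker = NULL, ...) {
  i <- if (is.null(marker)) which.max(object$logp)
  else if (is.numeric(marker)) as.integer(marker)
  else match(marker, object$markers$marker_id)
  if (is.na(i)) stop("unknown marker")
  object$beta[, i]
}

#' Manhattan-style plot of a haplotype scan
#' @param x a `cc_scan`.
#' @param thresholds optional [perm_thresholds()] result drawn as
#'   horizontal lines.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cc_scan <- function(x, thresholds = NULL, ...) {
  mk <- x$markers
  chrs <- unique(mk$chrom)
  offset <- c(0, cumsum(tapply(mk$pos_bp, factor(mk$chrom, levels = chrs),
                               max)))[seq_along(chrs)]
  gx <- mk$pos_bp + offset[match(mk$chrom, chrs)]
  col <- c("grey30", "steelblue")[1 + match(mk$chrom, chrs) %% 2]
  graphics::plot(gx / 1e6, x$logp, pch = 16, cex = 0.5, col = col,
                 xlab = "genome position (Mb)", ylab = "logP",
                 main = paste("Haplotype scan:", x$trait), ...)
  if (!is.null(thresholds)) {
    th <- if (inherits(thresholds, "cc_thresholds")) thresholds$thresholds
    else thresholds
    graphics::abline(h = th, lty = c(2, 1)[seq_along(th)], col = "red3")
  }
  invisible(x)
}

#' Genome-wide significance thresholds by line permutation
#'
#' Shuffles the line labels of the mean vector (weights travel with the
#' means), rescans the genome, and records the maximum logP of each
#' permutation; thresholds are empirical percentiles of that null maximum
#' distribution.
#'
#' @inheritParams marker_fit
#' @param n_perm number of permutations (>= 20; 200 is the working default).
#' @param percentiles percentiles of the max-logP distribution to report.
#' @param seed optional integer seed.
#' @return Object of class `cc_thresholds`: named `thresholds`, the raw
#'   `max_logp` vector, `n_perm` and `seed`.
#' @export
perm_thresholds <- function(line_means, tensor, n_perm = 200,
                            percentiles = c(95, 99), weights = NULL,
                            seed = NULL, clamp = LOGP_CLAMP) {
  if (n_perm < 20) stop("n_perm < 20: threshold quantiles are unstable")
  stopifnot(all(percentiles > 0), all(percentiles < 100))
  lm_ <- resolve_means(line_means, weights)
  li <- tensor_lines(tensor, lm_$lines)
  cube <- tensor_cube(tensor, li)
  n <- length(lm_$y)
  perms <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
  })
  mx <- as.numeric(perm_max_logp_cpp(cube, lm_$y, lm_$w, perms,
                                     cc_ref_founder(), clamp))
  th <- quantile(mx, percentiles / 100, type = 7, names = FALSE)
  structure(list(thresholds = setNames(th, as.character(percentiles)),
                 max_logp = mx, n_perm = n_perm, percentiles = percentiles,
                 seed = seed), class = "cc_thresholds")
}

#' @export
print.cc_thresholds <- function(x, ...) {
  cat(sprintf("Permutation thresholds (%d permutations):\n", x$n_perm))
  for (nm in names(x$thresholds)) {
    cat(sprintf("  %sth percentile: logP %.2f\n", nm, x$thresholds[[nm]]))
  }
  invisible(x)
}

#' Call QTLs from a scan and its thresholds
#'
#' Contiguous runs of markers at or above the calling threshold are merged
#' into one QTL per run, with the call placed at the run's maximum (ties
#' broken to the lowest bp).  Two runs on the same chromosome are reported
#' as separate proximal QTLs only when the valley between them dips below
#' the `split_level` threshold; otherwise they are merged into one call.
#'
#' @param scan a [scan_haplotypes()] result.
#' @param thresholds a [perm_thresholds()] result, or a named numeric
#'   vector of thresholds by percentile.
#' @param level percentile used for calling (default 99).
#' @param split_level percentile whose threshold a valley must dip below to
#'   split proximal peaks (default 95).
#' @return Data frame of class `cc_qtl` (possibly 0 rows): trait, chrom,
#'   peak marker/bp/logP, threshold, level and run bounds.
#' @export
call_qtls <- function(scan, thresholds, level = 99, split_level = 95) {
  th_all <- if (inherits(thresholds, "cc_thresholds")) thresholds$thresholds
  else thresholds
  lv <- as.character(level)
  if (!lv %in% names(th_all)) stop("no threshold at percentile ", level)
  thr <- th_all[[lv]]
  split_thr <- th_all[[as.character(split_level)]] %||% thr
  mk <- scan$markers
  calls <- list()
  for (ch in unique(mk$chrom)) {
    idx <- which(mk$chrom == ch)
    above <- scan$logp[idx] >= thr
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- cbind(starts[r$values], ends[r$values])
    # merge proximal runs unless the valley dips below the split threshold
    merged <- list(runs[1, ])
    if (nrow(runs) > 1) {
      for (q in 2:nrow(runs)) {
        prev <- merged[[length(merged)]]
        gap <- idx[(prev[2] + 1L):(runs[q, 1] - 1L)]
        if (min(scan$logp[gap]) >= split_thr) {
          merged[[length(merged)]] <- c(prev[1], runs[q, 2])
        } else {
          merged[[length(merged) + 1L]] <- runs[q, ]
        }
      }
    }
    for (run in merged) {
      ii <- idx[run[1]:run[2]]
      pk <- ii[which.max(scan$logp[ii])]  # which.max: first max = lowest bp
      calls[[length(calls) + 1L]] <- data.frame(
        trait = scan$trait, chrom = ch,
        peak_marker = mk$marker_id[pk], peak_bp = mk$pos_bp[pk],
        peak_logp = scan$logp[pk], threshold = thr, level = level,
        run_start_bp = mk$pos_bp[ii[1]], run_end_bp = mk$pos_bp[ii[length(ii)]])
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(trait = character(), chrom = character(),
               peak_marker = character(), peak_bp = numeric(),
               peak_logp = numeric(), threshold = numeric(),
               level = numeric(), run_start_bp = numeric(),
               run_end_bp = numeric())
  rownames(out) <- NULL
  class(out) <- c("cc_qtl", "data.frame")
  out
}

#' Regional heritability at a marker
#'
#' The RSS-ratio heritability recomputed with the founder dosages at one
#' marker (instead of the line factor) as the genetic term:
#' `H2_r = (RSS(F0) - RSS(F0 + dosages)) / RSS(F00)` on the animal-level
#' data, with the F test of the genetic against the covariate model.
#'
#' @param phenotypes animal-level phenotype data frame.
#' @param trait trait column name.
#' @param tensor a [cc_tensor()].
#' @param marker marker id or index (typically a QTL peak).
#' @param covariates covariates for the F0 model.
#' @param clamp upper bound on reported logP.
#' @return List with `h2_r`, `logp`, `marker` and a `degenerate` flag.
#' @export
regional_h2 <- function(phenotypes, trait, tensor, marker,
                        covariates = intersect(c("sex", "age_weeks"),
                                               names(phenotypes)),
                        clamp = LOGP_CLAMP) {
  fits <- fit_nested_models(phenotypes, trait, covariates)
  dat <- fits$data
  mi <- marker_index(tensor, marker)
  li <- tensor_lines(tensor, as.character(dat$line))
  X <- tensor$P[li, mi, -cc_ref_founder(), drop = TRUE]
  X <- as.matrix(X)
  keep <- apply(X, 2, function(v) diff(range(v)) > 1e-12)
  if (!any(keep)) {
    return(list(h2_r = 0, logp = 0, marker = marker, degenerate = TRUE))
  }
  X <- X[, keep, drop = FALSE]
  Z <- if (length(fits$covariates)) {
    stats::model.matrix(stats::reformulate(fits$covariates), dat)
  } else matrix(1, nrow(dat), 1)
  mg <- lm.fit(cbind(Z, X), dat$.y)
  rssg <- sum(mg$residuals^2)
  df1 <- fits$F0$df_resid - mg$df.residual
  h2_r <- if (fits$F00$rss > 0) (fits$F0$rss - rssg) / fits$F00$rss else 0
  list(h2_r = h2_r,
       logp = f_test_logp(fits$F0$rss, rssg, df1, mg$df.residual, clamp),
       marker = tensor$markers$marker_id[mi], degenerate = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues numeric vector of P values in (0, 1].
#' @return Adjusted values in the original order (monotone, <= 1).
#' @export
fdr_bh <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(pvalues <= 0 | pvalues > 1 | is.na(pvalues))) {
    stop("P values must lie in (0, 1]")
  }
  n <- length(pvalues)
  o <- order(pvalues, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(pvalues[o] * n / seq(n, 1)))[ro]
}

#' Leave-k-lines-out sensitivity sweep of a scan
#'
#' Rescans the genome on random subsets of the lines (never fewer than
#' `min_lines`) and reports each subset's peak.  This exposes how sensitive
#' a locus is to individual lines; the maximising subset is reported, never
#' silently substituted for the full-cohort scan.
#'
#' @inheritParams marker_fit
#' @param min_lines smallest subset size (default 28).
#' @param n_subsets number of random subsets to draw.
#' @param seed optional integer seed.
#' @return Data frame: subset id, dropped lines, peak marker/logP; the
#'   maximising subset is flagged.
#' @export
subset_scan_sweep <- function(line_means, tensor, min_lines = 28,
                              n_subsets = 100, weights = NULL, seed = NULL) {
  lm_ <- resolve_means(line_means, weights)
  n <- length(lm_$y)
  if (min_lines >= n) stop("min_lines must be smaller than the line count")
  with_seed(seed, {
    rows <- lapply(seq_len(n_subsets), function(s) {
      size <- sample(min_lines:(n - 1L), 1)
      keep <- sort(sample.int(n, size))
      sc <- scan_haplotypes(setNames(lm_$y[keep], lm_$lines[keep]), tensor,
                            weights = lm_$w[keep], trait = "subset")
      pk <- which.max(sc$logp)
      data.frame(subset = s, n_lines = size,
                 dropped = paste(lm_$lines[-keep], collapse = ","),
                 peak_marker = sc$markers$marker_id[pk],
                 peak_logp = sc$logp[pk])
    })
    out <- do.call(rbind, rows)
    out$best <- seq_len(nrow(out)) == which.max(out$peak_logp)
    out
  })
}
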