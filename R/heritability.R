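# Broad-sense heritability and covariate effects from nested linear models.
#
# Three least-squares fits of the animal-level trait:
#   F00: intercept only (null),
#   F0:  intercept + covariates (sex, age),
#   F1:  intercept + covariates + line (fixed factor).
# Heritability is the RSS ratio (RSS(F0) - RSS(F1)) / RSS(F00); covariate
# effects are analogous RSS ratios; significance comes from ANOVA F tests
# on the nested pairs.

#' Fit the nested trait models
#'
#' @param phenotypes animal-level phenotype data frame (needs a `line`
#'   column and the trait column; covariate columns as available).
#' @param trait name of the trait column.
#' @param covariates covariate column names to include in F0/F1; defaults
#'   to whichever of `sex` and `age_weeks` are present.
#' @return Object of class `cc_nested`: per-model RSS, residual df and
#'   coefficients, plus the analysis data for downstream refits.
#' @export
fit_nested_models <- function(phenotypes, trait,
                              covariates = intersect(c("sex", "age_weeks"),
                                                     names(phenotypes))) {
  if (!trait %in% names(phenotypes)) stop("no trait column: ", trait)
  dat <- phenotypes[, c("line", covariates, trait)]
  names(dat)[ncol(dat)] <- ".y"
  keep <- !is.na(dat$.y)
  dropped_lines <- setdiff(unique(dat$line), unique(dat$line[keep]))
  if (length(dropped_lines)) {
    warning("lines with all-missing trait dropped: ",
            paste(dropped_lines, collapse = ", "))
  }
  dat <- dat[keep, , drop = FALSE]
  if (nrow(dat) < 3) stop("need at least 3 non-missing trait values")
  if (length(unique(dat$line)) < 2) stop("need at least 2 lines")
  dat$line <- factor(dat$line)

  # drop degenerate covariates (constant, or collinear once factored)
  usable <- character()
  for (cv in covariates) {
    v <- dat[[cv]]
    if (length(unique(v)) < 2) {
      warning("covariate '", cv, "' is constant; dropped")
    } else {
      usable <- c(usable, cv)
    }
  }
  f00 <- lm(.y ~ 1, data = dat)
  f0 <- if (length(usable)) {
    lm(stats::reformulate(usable, ".y"), data = dat)
  } else f00
  f1 <- lm(stats::reformulate(c(usable, "line"), ".y"), data = dat)
  alias0 <- is.na(coef(f0))
  if (any(alias0)) {
    warning("collinear covariate term dropped: ",
            paste(names(coef(f0))[alias0], collapse = ", "))
  }
  rss <- function(m) sum(residuals(m)^2)
  mk <- function(m, id) list(model_id = id, rss = rss(m),
                             df_resid = df.residual(m),
                             coefficients = coef(m))
  structure(list(F00 = mk(f00, "F00"), F0 = mk(f0, "F0"), F1 = mk(f1, "F1"),
                 covariates = usable, trait = trait, data = dat,
                 n = nrow(dat), n_lines = nlevels(dat$line)),
            class = "cc_nested")
}

#' Broad-sense heritability from nested fits
#'
#' `H2 = (RSS(F0) - RSS(F1)) / RSS(F00)`, with significance from the
#' ANOVA F test of F1 against F0.  When the trait is constant
#' (`RSS(F00) = 0`) the heritability is defined as 0 and flagged.
#'
#' @param fits a [fit_nested_models()] result.
#' @param clamp upper bound on reported logP (default 15).
#' @return Object of class `cc_herit` with `h2`, `logp`, the per-covariate
#'   effects (see [covariate_effect()]) and a `degenerate` flag.
#' @export
heritability <- function(fits, clamp = LOGP_CLAMP) {
  stopifnot(inherits(fits, "cc_nested"))
  rss00 <- fits$F00$rss
  # constant trait: RSS(F00) is numerically zero relative to the data scale
  degenerate <- rss00 <= 1e-12 * max(1, sum(fits$data$.y^2))
  h2 <- if (degenerate) 0 else (fits$F0$rss - fits$F1$rss) / rss00
  df1 <- fits$F0$df_resid - fits$F1$df_resid
  logp <- if (degenerate) 0 else
    f_test_logp(fits$F0$rss, fits$F1$rss, df1, fits$F1$df_resid, clamp)
  effs <- lapply(setNames(fits$covariates, fits$covariates), function(cv) {
    covariate_effect(fits, cv, clamp = clamp)
  })
  structure(list(trait = fits$trait, h2 = h2, logp = logp,
                 covariate_effects = effs, n = fits$n,
                 n_lines = fits$n_lines, degenerate = degenerate),
            class = "cc_herit")
}

#' @export
print.cc_herit <- function(x, ...) {
  cat(sprintf("Broad-sense heritability of %s: H2 = %.2f (logP = %.2f)\n",
              x$trait, x$h2, x$logp))
  for (nm in names(x$covariate_effects)) {
    e <- x$covariate_effects[[nm]]
    cat(sprintf("  %s effect: %.2f (logP = %.2f)\n", nm, e$effect, e$logp))
  }
  cat(sprintf("  n = %d animals, %d lines\n", x$n, x$n_lines))
  if (x$degenerate) cat("  [degenerate: trait constant]\n")
  invisible(x)
}

#' Covariate effect as an RSS fraction
#'
#' Default mode (`"single"`) refits the trait on the single covariate alone
#' and reports `(RSS(F00) - RSS(F0_single)) / RSS(F00)` with the F test of
#' that fit against the null.  Mode `"strict"` instead reports
#' `(RSS(F00) - RSS(F1)) / RSS(F00)` verbatim; note that this expression
#' involves the full line model and therefore mixes the covariate with the
#' genetic contribution - it is provided for comparability, not as the
#' default (see the methods vignette).
#'
#' @param fits a [fit_nested_models()] result.
#' @param which covariate name (e.g. `"sex"` or `"age_weeks"`).
#' @param mode `"single"` (default) or `"strict"`.
#' @param clamp upper bound on reported logP.
#' @return List with `effect`, `logp`, `mode` and a `degenerate` flag.
#' @export
covariate_effect <- function(fits, which, mode = c("single", "strict"),
                             clamp = LOGP_CLAMP) {
  stopifnot(inherits(fits, "cc_nested"))
  mode <- match.arg(mode)
  rss00 <- fits$F00$rss
  if (rss00 <= 1e-12 * max(1, sum(fits$data$.y^2))) {
    return(list(effect = 0, logp = 0, mode = mode, degenerate = TRUE))
  }
  if (!which %in% names(fits$data) || length(unique(fits$data[[which]])) < 2) {
    return(list(effect = 0, logp = 0, mode = mode, degenerate = TRUE))
  }
  if (mode == "strict") {
    df1 <- fits$F00$df_resid - fits$F1$df_resid
    return(list(effect = (rss00 - fits$F1$rss) / rss00,
                logp = f_test_logp(rss00, fits$F1$rss, df1,
                                   fits$F1$df_resid, clamp),
                mode = mode, degenerate = FALSE))
  }
  m <- lm(stats::reformulate(which, ".y"), data = fits$data)
  rss1 <- sum(residuals(m)^2)
  df1 <- fits$F00$df_resid - df.residual(m)
  list(effect = (rss00 - rss1) / rss00,
       logp = f_test_logp(rss00, rss1, df1, df.residual(m), clamp),
       mode = mode, degenerate = FALSE)
}

#' Covariate-adjusted line means
#'
#' Residuals of the covariate model F0 plus the grand mean, averaged per
#' line.  The per-line animal counts are recorded for use as scan weights.
#'
#' @param phenotypes animal-level phenotype data frame.
#' @param trait trait column name.
#' @param covariates passed to [fit_nested_models()].
#' @return Data frame of class `cc_line_means` (`line`, `mean`, `n`, `se`),
#'   with attributes `sigma2` (residual mean square of the line model) and
#'   `df` (its residual df) for use in line grouping.
#' @export
adjusted_line_means <- function(phenotypes, trait,
                                covariates = intersect(c("sex", "age_weeks"),
                                                       names(phenotypes))) {
  fits <- fit_nested_models(phenotypes, trait, covariates)
  dat <- fits$data
  m0 <- if (length(fits$covariates)) {
    lm(stats::reformulate(fits$covariates, ".y"), data = dat)
  } else lm(.y ~ 1, data = dat)
  adj <- residuals(m0) + mean(dat$.y)
  mn <- tapply(adj, dat$line, mean)
  n <- as.integer(table(dat$line))
  sigma2 <- fits$F1$rss / max(fits$F1$df_resid, 1)
  out <- data.frame(line = names(mn), mean = as.numeric(mn), n = n,
                    se = sqrt(sigma2 / n))
  rownames(out) <- NULL
  attr(out, "sigma2") <- sigma2
  attr(out, "df") <- fits$F1$df_resid
  attr(out, "trait") <- trait
  class(out) <- c("cc_line_means", "data.frame")
  out
}

#' Pairwise Pearson correlations between traits
#'
#' @param phenotypes animal-level phenotype data frame.
#' @param traits trait column names.
#' @return Symmetric correlation matrix with unit diagonal; zero-variance
#'   traits give `NA` entries with a warning.
#' @export
trait_correlations <- function(phenotypes, traits) {
  X <- as.matrix(phenotypes[, traits, drop = FALSE])
  if (sum(complete.cases(X)) < 3) stop("need at least 3 complete pairs")
  zv <- apply(X, 2, function(v) var(v, na.rm = TRUE) == 0)
  if (any(zv)) {
    warning("zero-variance trait(s): ", paste(traits[zv], collapse = ", "))
  }
  r <- suppressWarnings(cor(X, use = "pairwise.complete.obs"))
  diag(r) <- 1
  r
}

#' Group lines by Tukey's honestly significant difference
#'
#' Lines are sorted by descending adjusted mean and partitioned greedily:
#' a line opens a new group when it differs from the current group's
#' leading line by more than the Tukey HSD at `alpha`.  Each resulting
#' group differs significantly from the next; the procedure is
#' deterministic given the input.
#'
#' @param line_means an [adjusted_line_means()] result (needs the `sigma2`
#'   and `df` attributes).
#' @param alpha familywise significance level (default 0.001).
#' @return The input with an integer `group` column (1 = highest mean).
#' @export
group_lines <- function(line_means, alpha = 0.001) {
  stopifnot(nrow(line_means) >= 2, all(line_means$n >= 1))
  sigma2 <- attr(line_means, "sigma2")
  df <- attr(line_means, "df")
  if (is.null(sigma2) || is.null(df)) {
    stop("line_means must come from adjusted_line_means()")
  }
  k <- nrow(line_means)
  ord <- order(line_means$mean, decreasing = TRUE)
  out <- line_means[ord, , drop = FALSE]
  qcrit <- qtukey(1 - alpha, k, max(df, 1))
  group <- integer(k)
  group[1] <- 1L
  lead <- 1L
  for (j in 2:k) {
    hsd <- qcrit * sqrt(sigma2 / 2 * (1 / out$n[lead] + 1 / out$n[j]))
    if (out$mean[lead] - out$mean[j] > hsd) {
      group[j] <- group[j - 1L] + 1L
      lead <- j
    } else {
      group[j] <- group[j - 1L]
    }
  }
  out$group <- group
  rownames(out) <- NULL
  attr(out, "sigma2") <- sigma2
  attr(out, "df") <- df
  out
}
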