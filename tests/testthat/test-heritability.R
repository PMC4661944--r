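# Nested-model heritability, covariate effects, line means, grouping.

toy_phen <- function(seed = 5, n_lines = 6, n_per = 2, sex_effect = 2,
                     line_sd = 1.5, residual_sd = 0.7) {
  set.seed(seed)
  lines <- sprintf("T%02d", seq_len(n_lines))
  g <- rnorm(n_lines, 0, line_sd)
  do.call(rbind, lapply(seq_len(n_lines), function(i) {
    sex <- rep(c("F", "M"), length.out = n_per)
    age <- runif(n_per, 10, 13)
    data.frame(animal_id = sprintf("%s_%d", lines[i], seq_len(n_per)),
               line = lines[i], sex = sex, age_weeks = age,
               y = 10 + g[i] + sex_effect * (sex == "M") + 0.1 * age +
                 rnorm(n_per, 0, residual_sd))
  }))
}

test_that("nested RSS values match a normal-equations oracle", {
  phen <- toy_phen()
  fits <- fit_nested_models(phen, "y")
  y <- phen$y
  # oracle fits by explicit least squares
  X00 <- matrix(1, length(y))
  X0 <- cbind(1, phen$sex == "M", phen$age_weeks)
  L <- stats::model.matrix(~ factor(phen$line))
  X1 <- cbind(X0, L[, -1])
  orss <- function(X) {
    b <- solve(crossprod(X), crossprod(X, y))
    sum((y - X %*% b)^2)
  }
  expect_equal(fits$F00$rss, orss(X00), tolerance = 1e-10)
  expect_equal(fits$F0$rss, orss(X0), tolerance = 1e-10)
  expect_equal(fits$F1$rss, orss(X1), tolerance = 1e-10)
  expect_true(fits$F00$rss >= fits$F0$rss)
  expect_true(fits$F0$rss >= fits$F1$rss)
})

test_that("heritability handles degenerate and planted cases", {
  phen <- toy_phen()
  phen$y <- 3  # constant trait
  fits <- fit_nested_models(phen, "y")
  h <- heritability(fits)
  expect_equal(h$h2, 0)
  expect_true(h$degenerate)

  # planted line effects: F1 strictly better than F0
  phen2 <- toy_phen(seed = 8, n_lines = 31, n_per = 5, line_sd = 2)
  fits2 <- fit_nested_models(phen2, "y")
  expect_lt(fits2$F1$rss, fits2$F0$rss)
  h2 <- heritability(fits2)
  expect_gt(h2$h2, 0.3)
  expect_true(h2$h2 <= 1 && h2$h2 >= 0)

  # near-zero within-line variance, no covariates: h2 -> RSS(F0)/RSS(F00) ~ 1
  phen3 <- toy_phen(seed = 9, n_lines = 8, n_per = 3, sex_effect = 0,
                    line_sd = 3, residual_sd = 1e-8)
  h3 <- heritability(fit_nested_models(phen3, "y", covariates = character()))
  expect_gt(h3$h2, 0.99)
})

test_that("heritability is invariant to affine trait rescaling", {
  phen <- toy_phen(seed = 12, n_lines = 10, n_per = 4)
  h1 <- heritability(fit_nested_models(phen, "y"))
  phen$y <- -3.7 * phen$y + 11
  h2 <- heritability(fit_nested_models(phen, "y"))
  expect_equal(h1$h2, h2$h2, tolerance = 1e-12)
  expect_equal(h1$logp, h2$logp, tolerance = 1e-9)
})

test_that("null heritability logP is calibrated", {
  set.seed(31)
  exceed <- vapply(1:300, function(i) {
    phen <- data.frame(animal_id = as.character(1:155),
                       line = rep(sprintf("L%02d", 1:31), each = 5),
                       y = rnorm(155))
    heritability(fit_nested_models(phen, "y",
                                   covariates = character()))$logp > 1.301
  }, logical(1))
  # ~5% of null fits should exceed logP 1.301 (P = 0.05)
  expect_lt(abs(mean(exceed) - 0.05), 3 * sqrt(0.05 * 0.95 / 300))
})

test_that("covariate effects recover planted sex shifts", {
  phen <- toy_phen(seed = 14, n_lines = 10, n_per = 4, sex_effect = 0,
                   line_sd = 0)
  fits <- fit_nested_models(phen, "y")
  e0 <- covariate_effect(fits, "sex")
  expect_lt(e0$effect, 0.15)

  # planted shift of 1 within-sex sd, balanced sexes, no line variance:
  # population variance fraction = 0.25 / 1.25 = 0.2
  set.seed(15)
  effs <- vapply(1:200, function(i) {
    n <- 155
    sex <- rep(c("F", "M"), length.out = n)
    y <- rnorm(n) + (sex == "M")
    ph <- data.frame(animal_id = as.character(1:n),
                     line = rep(sprintf("L%02d", 1:31), each = 5),
                     sex = sex, y = y)
    covariate_effect(fit_nested_models(ph, "y", covariates = "sex"),
                     "sex")$effect
  }, numeric(1))
  se <- sd(effs) / sqrt(length(effs))
  expect_lt(abs(mean(effs) - 0.2), 3 * se + 1 / 155)

  # strict mode reproduces (RSS(F00) - RSS(F1)) / RSS(F00) verbatim
  fits2 <- fit_nested_models(toy_phen(seed = 16), "y")
  es <- covariate_effect(fits2, "sex", mode = "strict")
  expect_equal(es$effect, (fits2$F00$rss - fits2$F1$rss) / fits2$F00$rss,
               tolerance = 1e-12)

  # constant covariate: flagged, effect 0
  phc <- toy_phen(seed = 17)
  phc$sex <- "F"
  fitsc <- suppressWarnings(fit_nested_models(phc, "y"))
  ec <- covariate_effect(fitsc, "sex")
  expect_equal(ec$effect, 0)
  expect_true(ec$degenerate)
})

test_that("adjusted line means remove covariates and keep counts", {
  # no covariates: equals raw line means
  phen <- toy_phen(seed = 18, sex_effect = 0)
  m <- adjusted_line_means(phen, "y", covariates = character())
  raw <- tapply(phen$y, phen$line, mean)
  expect_equal(m$mean, as.numeric(raw[m$line]), tolerance = 1e-10)

  # balanced two-line toy with a known sex offset: offset removed exactly
  ph2 <- data.frame(animal_id = as.character(1:8),
                    line = rep(c("A", "B"), each = 4),
                    sex = rep(c("F", "M"), 4),
                    y = c(1, 3, 1, 3, 5, 7, 5, 7))  # M = F + 2 in both lines
  m2 <- adjusted_line_means(ph2, "y", covariates = "sex")
  expect_equal(m2$mean, c(2, 6), tolerance = 1e-10)
  expect_equal(m2$n, c(4L, 4L))

  # default study-scale scenario keeps all 31 lines
  cohort <- sim_cohort(seed = 19)
  m3 <- adjusted_line_means(cohort$phenotypes, "BVTV")
  expect_equal(nrow(m3), 31L)
  expect_equal(sum(m3$n), nrow(cohort$phenotypes))
})

test_that("trait correlations match the textbook formula", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.0)
  y <- c(0.7, 2.9, 1.8, 4.4, 3.1)
  phen <- data.frame(animal_id = as.character(1:5),
                     line = c("A", "A", "B", "B", "C"), t1 = x, t2 = y,
                     t3 = 2 * x - 1)
  r <- trait_correlations(phen, c("t1", "t2", "t3"))
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r["t1", "t2"], r_hand, tolerance = 1e-12)
  expect_equal(r["t1", "t1"], 1)
  expect_equal(r["t1", "t3"], 1, tolerance = 1e-12)  # affine image
  expect_true(isSymmetric(r))
})

test_that("line grouping splits well-separated clusters and nothing else", {
  mk_means <- function(mu, n = 5, sigma2 = 1, df = 100) {
    lm_ <- data.frame(line = sprintf("G%02d", seq_along(mu)), mean = mu,
                      n = n, se = sqrt(sigma2 / n))
    attr(lm_, "sigma2") <- sigma2
    attr(lm_, "df") <- df
    class(lm_) <- c("cc_line_means", "data.frame")
    lm_
  }
  same <- group_lines(mk_means(rep(4, 6)), alpha = 0.001)
  expect_equal(unique(same$group), 1L)

  three <- group_lines(mk_means(c(0, 0.2, 10, 10.3, 20, 20.1)), alpha = 0.001)
  expect_equal(max(three$group), 3L)
  expect_true(!is.unsorted(three$group))           # sorted desc by mean
  expect_equal(three$mean, sort(three$mean, decreasing = TRUE))
  # deterministic
  again <- group_lines(mk_means(c(0, 0.2, 10, 10.3, 20, 20.1)), alpha = 0.001)
  expect_identical(three, again)
})
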