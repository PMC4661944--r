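# Synthetic CC cohort generator: mosaics, probability tensors, catalogues,
# phenotypes.

test_that("mosaic breakpoint process matches its Poisson rate", {
  g <- c(c1 = 100e6)
  # no recombination: one segment per chromosome
  mos0 <- sim_mosaics(10, g, breakpoint_rate_per_mb = 0, seed = 1)
  expect_equal(nrow(mos0$segments), 10L)
  expect_true(all(mos0$segments$start_bp == 0))
  expect_true(all(mos0$segments$end_bp == 100e6))

  # mean segment count = 1 + rate * length, within 3 MC standard errors
  rate <- 0.05
  mos <- sim_mosaics(400, g, breakpoint_rate_per_mb = rate, seed = 2)
  counts <- table(mos$segments$line)
  expected <- 1 + rate * 100
  se <- sqrt(rate * 100 / 400)
  expect_lt(abs(mean(counts) - expected), 3 * se)

  expect_error(sim_mosaics(5, c(c1 = 0)), "zero-length")
})

test_that("residual heterozygosity tracks inbreeding generation", {
  g <- cc_genome(2, 50)
  mos <- sim_mosaics(40, g, inbreeding_generations = sample(11:37, 40, TRUE),
                     seed = 3)
  homozygosity <- 1 - mos$het_fraction
  expect_true(all(homozygosity >= 0.80 & homozygosity <= 0.999))
  # monotone: later generations are more homozygous
  mos11 <- sim_mosaics(5, g, inbreeding_generations = 11, seed = 4)
  mos37 <- sim_mosaics(5, g, inbreeding_generations = 37, seed = 4)
  expect_true(all(mos37$het_fraction < mos11$het_fraction))
})

test_that("probability tensor is one-hot without softening and splits mass at breakpoints", {
  g <- c(c1 = 10e6)
  segs <- data.frame(line = "L1", chrom = "c1",
                     start_bp = c(0, 4e6), end_bp = c(4e6, 10e6),
                     founder = c(2L, 7L))
  mos <- manual_mosaic(segs, g)
  mk <- data.frame(chrom = "c1", pos_bp = c(1e6, 4e6, 8e6),
                   marker_id = c("p1", "p2", "p3"))

  hard <- prob_tensor(mos, mk, soft_halfwidth_bp = 0)
  expect_equal(hard$P[1, 1, ], setNames(c(0, 2, 0, 0, 0, 0, 0, 0),
                                        cc_founders()))
  expect_equal(hard$P[1, 3, 7], 2)

  # marker exactly at the breakpoint: one dose from each flanking founder
  soft <- prob_tensor(mos, mk, soft_halfwidth_bp = 5e5)
  expect_equal(soft$P[1, 2, 2], 1)
  expect_equal(soft$P[1, 2, 7], 1)
  # linear interpolation inside the window
  mk2 <- data.frame(chrom = "c1", pos_bp = 4.25e6, marker_id = "q")
  soft2 <- prob_tensor(mos, mk2, soft_halfwidth_bp = 5e5)
  expect_equal(soft2$P[1, 1, 7], 1.5)
  expect_equal(soft2$P[1, 1, 2], 0.5)

  expect_error(prob_tensor(mos, data.frame(chrom = "c1", pos_bp = 11e6,
                                           marker_id = "z"), 0),
               "outside chromosome bounds")
})

test_that("tensor dosages always sum to 2, with softening and heterozygosity", {
  tens <- fixture_tensor(n_lines = 15, seed = 7)
  sums <- rowSums(tens$P, dims = 2)
  expect_true(max(abs(sums - 2)) < 1e-9)
  expect_true(all(tens$P >= 0))
  # deterministic given the seed when softening is off
  g <- cc_genome(2, 50)
  mk <- marker_grid(g, 1e6)
  t1 <- prob_tensor(sim_mosaics(5, g, seed = 9), mk, 0)
  t2 <- prob_tensor(sim_mosaics(5, g, seed = 9), mk, 0)
  expect_identical(t1$P, t2$P)
})

test_that("catalogue SDPs are never constant and hit the multiallelic fraction", {
  mk <- marker_grid(cc_genome(2, 50), 1e6)
  cat_ <- sim_catalogue(mk, 1000, allele_counts = c(2L, 3L),
                        allele_probs = c(0.8, 0.2), seed = 11)
  sdp <- as.matrix(cat_[, cc_founders()])
  ndist <- apply(sdp, 1, function(r) length(unique(r)))
  expect_true(all(ndist >= 2))
  # observed multiallelic fraction within 3 binomial se of 0.2
  frac <- mean(ndist > 2)
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / 1000))

  expect_error(sim_catalogue(mk, 5, allele_counts = 1L, allele_probs = 1),
               ">= 2")

  # forced SDP via the constructor
  df <- data.frame(chrom = "1", pos_bp = 5e6, variant_id = "v1",
                   alleles = "a,b")
  for (f in cc_founders()) df[[f]] <- if (f == "PWK") "a" else "b"
  forced <- cc_catalogue(df)
  expect_equal(sum(unlist(forced[1, cc_founders()]) == "a"), 1L)
  df2 <- df
  for (f in cc_founders()) df2[[f]] <- "b"
  expect_error(cc_catalogue(df2), "monomorphic")
})

test_that("phenotype simulation composes the generative model", {
  tens <- hard_tensor(n_lines = 12, n_markers = 4)
  # degenerate: all effects and noise zero -> every value equals the mean
  m0 <- cc_trait_model(mean = 7, sex_effect = 0, age_slope = 0,
                       line_sd = 0, residual_sd = 0)
  phen0 <- sim_phenotypes(tens, m0, 3, seed = 1)
  expect_true(all(phen0$BVTV == 7))
  expect_error(sim_phenotypes(tens, m0, 0), "n_per_line")

  # planted founder effects recovered exactly at zero noise
  beta <- c(2, -1, 0.5, 0, 1, -0.5, 3, 0)
  mq <- cc_trait_model(mean = 10, qtl = list(list(marker = "hm02",
                                                  beta = beta)),
                       sex_effect = 0, age_slope = 0,
                       line_sd = 0, residual_sd = 0)
  phen <- sim_phenotypes(tens, mq, 2, seed = 2)
  means <- adjusted_line_means(phen, "BVTV", covariates = character())
  fit <- marker_fit(means, tens, "hm02")
  expect_equal(unname(fit$beta), beta, tolerance = 1e-9)
  expect_error(cc_trait_model(qtl = list(list(marker = 1, beta = rep(1, 8)))),
               "WSB")
})

test_that("default BV/TV-like trait spans roughly the study range", {
  cohort <- sim_cohort(seed = 100)
  y <- cohort$phenotypes$BVTV
  expect_equal(nrow(cohort$phenotypes), 155L)
  expect_equal(length(unique(cohort$phenotypes$line)), 31L)
  expect_gt(diff(range(y)), 15)   # wide spread across lines
  expect_lt(diff(range(y)), 45)
  expect_gt(mean(y), 8); expect_lt(mean(y), 22)
})

test_that("realized heritability matches the configured target", {
  tens <- fixture_tensor(n_lines = 31, n_chrom = 2, seed = 21)
  h2_target <- 0.5
  model <- cc_trait_model(sex_effect = 0, age_slope = 0,
                          line_sd = line_sd_for_h2(h2_target, 1),
                          residual_sd = 1)
  h2 <- vapply(1:200, function(i) {
    phen <- sim_phenotypes(tens, model, 5, seed = 3000 + i)
    heritability(fit_nested_models(phen, "BVTV",
                                   covariates = character()))$h2
  }, numeric(1))
  se <- sd(h2) / sqrt(length(h2))
  expect_lt(abs(mean(h2) - h2_target), 3 * se + 0.01)
})

test_that("Mendelian trait thresholds imputed causal dosage", {
  tens <- hard_tensor(n_lines = 8, n_markers = 3)
  df <- data.frame(chrom = "1", pos_bp = 2e6, variant_id = "alb",
                   alleles = "a,b")
  for (f in cc_founders()) df[[f]] <- if (f == "PWK") "a" else "b"
  cat_ <- cc_catalogue(df)
  phen <- sim_mendelian_trait(tens, cat_, "alb", mode = "recessive")
  aff <- setNames(phen$affected, phen$line)
  expect_equal(unname(aff["HL07"]), 1L)           # PWK line: dosage 2
  expect_true(all(aff[names(aff) != "HL07"] == 0L))
  dom <- sim_mendelian_trait(tens, cat_, "alb", mode = "dominant")
  expect_equal(sum(dom$affected), 1L)

  # monomorphic-in-cohort causal variant is rejected
  tens2 <- hard_tensor(n_lines = 4, n_markers = 3)  # founders 1..4 only
  expect_error(sim_mendelian_trait(tens2, cat_, "alb"), "monomorphic")
})
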