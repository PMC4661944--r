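# Founder-haplotype scan, permutation thresholds, QTL calling, regional
# heritability, BH adjustment.

test_that("marker fit agrees with the weighted normal-equations oracle", {
  set.seed(41)
  for (rep in 1:25) {
    n <- sample(10:20, 1)
    P <- array(NA_real_, c(n, 1, 8))
    P[, 1, ] <- random_dosage_rows(n)
    tens <- cc_tensor(P, sprintf("L%02d", 1:n),
                      data.frame(chrom = "1", pos_bp = 1e6, marker_id = "m"))
    y <- setNames(rnorm(n), tens$lines)
    w <- sample(1:7, n, replace = TRUE)
    fit <- marker_fit(y, tens, "m", weights = w)
    X <- cbind(1, P[, 1, -cc_ref_founder()])
    o <- oracle_wls(as.numeric(y), X, w)
    expect_equal(unname(fit$beta[-cc_ref_founder()]), o$beta[-1],
                 tolerance = 1e-8)
    expect_equal(fit$rss_genetic, o$rss, tolerance = 1e-8)
    expect_equal(fit$logp, oracle_logp(as.numeric(y), X, w), tolerance = 1e-8)
    expect_identical(unname(fit$beta[cc_ref_founder()]), 0)
  }
})

test_that("scan handles degenerate and uninformative markers", {
  # all lines identical dosages: no information, logP 0
  n <- 10
  P <- array(0, c(n, 2, 8))
  P[, , 3] <- 2
  tens <- cc_tensor(P, sprintf("L%02d", 1:n),
                    data.frame(chrom = "1", pos_bp = c(1e6, 2e6),
                               marker_id = c("m1", "m2")))
  y <- setNames(rnorm(n), tens$lines)
  sc <- scan_haplotypes(y, tens)
  expect_equal(sc$logp, c(0, 0))

  # constant trait: all logP 0 everywhere
  tens2 <- fixture_tensor(n_lines = 12, n_chrom = 2, seed = 44)
  sc2 <- scan_haplotypes(setNames(rep(5, 12), tens2$lines), tens2)
  expect_true(all(sc2$logp == 0))
})

test_that("scan satisfies its structural invariants", {
  tens <- fixture_tensor(n_lines = 20, n_chrom = 3, seed = 45)
  phen <- sim_phenotypes(tens, cc_trait_model(), seed = 46)
  m <- adjusted_line_means(phen, "BVTV")
  sc <- scan_haplotypes(m, tens)
  # WSB effects exactly zero; genetic RSS never above null RSS
  expect_true(all(sc$beta[cc_ref_founder(), ] == 0))
  expect_true(all(sc$rss <= sc$rss_null + 1e-8))
  expect_true(all(sc$logp >= 0 & is.finite(sc$logp)))

  # logP invariant under affine rescaling of the trait
  m2 <- m
  m2$mean <- 2.5 * m$mean - 40
  sc2 <- scan_haplotypes(m2, tens)
  expect_equal(sc$logp, sc2$logp, tolerance = 1e-8)
})

test_that("permutation thresholds are ordered quantiles of the max distribution", {
  tens <- fixture_tensor(n_lines = 18, n_chrom = 2, seed = 47)
  phen <- sim_phenotypes(tens, cc_trait_model(), seed = 48)
  m <- adjusted_line_means(phen, "BVTV")
  th <- perm_thresholds(m, tens, n_perm = 60, percentiles = c(90, 95, 99),
                        seed = 49)
  expect_true(th$thresholds[["99"]] >= th$thresholds[["95"]])
  expect_true(th$thresholds[["95"]] >= th$thresholds[["90"]])
  # thresholds equal quantiles of the recorded max vector
  expect_equal(unname(th$thresholds),
               unname(quantile(th$max_logp, c(0.90, 0.95, 0.99), type = 7)),
               tolerance = 1e-12)
  expect_length(th$max_logp, 60)
  # reproducible given the seed
  th2 <- perm_thresholds(m, tens, n_perm = 60, percentiles = c(90, 95, 99),
                         seed = 49)
  expect_identical(th$max_logp, th2$max_logp)
  expect_error(perm_thresholds(m, tens, n_perm = 10), "unstable")
})

test_that("QTL calling merges runs and splits on deep valleys", {
  mk <- data.frame(chrom = rep("2", 9), pos_bp = (1:9) * 1e6,
                   marker_id = sprintf("s%d", 1:9))
  mk_scan <- function(logp) {
    structure(list(markers = mk, logp = logp, trait = "t"),
              class = "cc_scan")
  }
  th <- structure(list(thresholds = c("95" = 3, "99" = 5)),
                  class = "cc_thresholds")

  # no super-threshold markers
  expect_equal(nrow(call_qtls(mk_scan(rep(1, 9)), th)), 0L)

  # two peaks separated by a valley below the 95th threshold: two calls
  two <- call_qtls(mk_scan(c(1, 6, 7, 2, 1, 2, 8, 6, 1)), th)
  expect_equal(nrow(two), 2L)
  expect_equal(two$peak_marker, c("s3", "s7"))

  # valley stays above the 95th threshold: merged into one proximal call
  one <- call_qtls(mk_scan(c(1, 6, 7, 4, 3.5, 4, 8, 6, 1)), th)
  expect_equal(nrow(one), 1L)
  expect_equal(one$peak_marker, "s7")

  # ties broken to the lowest bp
  tie <- call_qtls(mk_scan(c(1, 6, 6, 1, 1, 1, 1, 1, 1)), th)
  expect_equal(tie$peak_marker, "s2")
})

test_that("regional heritability isolates the peak-marker contribution", {
  tens <- fixture_tensor(n_lines = 31, n_chrom = 2, seed = 50)
  # monomorphic marker: h2_r = 0
  P <- array(0, c(5, 1, 8)); P[, 1, 1] <- 2
  tmono <- cc_tensor(P, sprintf("L%d", 1:5),
                     data.frame(chrom = "1", pos_bp = 1e6, marker_id = "m"))
  ph <- data.frame(animal_id = as.character(1:10),
                   line = rep(sprintf("L%d", 1:5), 2), y = rnorm(10))
  rh0 <- regional_h2(ph, "y", tmono, "m", covariates = character())
  expect_equal(rh0$h2_r, 0)
  expect_true(rh0$degenerate)

  # one QTL carries all line variance: regional h2 ~ genome-wide h2
  model <- cc_trait_model(qtl = list(list(marker = "m_1_0050",
                                          beta = c(0, 0, 0, 0, 0, 0, 5, 0))),
                          sex_effect = 0, age_slope = 0,
                          line_sd = 0, residual_sd = 1)
  phen <- sim_phenotypes(tens, model, 5, seed = 51)
  hg <- heritability(fit_nested_models(phen, "BVTV",
                                       covariates = character()))
  rh <- regional_h2(phen, "BVTV", tens, "m_1_0050",
                    covariates = character())
  expect_gt(rh$h2_r, 0.5)
  expect_lt(abs(rh$h2_r - hg$h2), 0.15)
})

test_that("Benjamini-Hochberg adjustment matches the step-up rule", {
  expect_equal(fdr_bh(0.04), 0.04)
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_bh(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(fdr_bh(numeric(0)), numeric(0))
  expect_error(fdr_bh(c(0.1, 0)), "0, 1")
  # independent cross-check against stats::p.adjust
  set.seed(52)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))
    expect_equal(fdr_bh(p), p.adjust(p, "BH"), tolerance = 1e-12)
  }
})

test_that("subset sweep reports per-subset peaks without substitution", {
  tens <- fixture_tensor(n_lines = 31, n_chrom = 2, seed = 53)
  phen <- sim_phenotypes(tens, cc_trait_model(), seed = 54)
  m <- adjusted_line_means(phen, "BVTV")
  sw <- subset_scan_sweep(m, tens, min_lines = 28, n_subsets = 10, seed = 55)
  expect_equal(nrow(sw), 10L)
  expect_true(all(sw$n_lines >= 28 & sw$n_lines <= 30))
  expect_equal(sum(sw$best), 1L)
})
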