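# Shared fixtures, built in code.

# small genome + tensor with soft breakpoints and residual heterozygosity
fixture_tensor <- function(n_lines = 20, n_chrom = 4, length_mb = 100,
                           spacing_bp = 1e6, hw = 2e5, seed = 42) {
  g <- cc_genome(n_chrom, length_mb)
  mos <- sim_mosaics(n_lines, g, seed = seed)
  prob_tensor(mos, marker_grid(g, spacing_bp), hw)
}

# tensor in which line i is fixed for founder ((i-1) %% 8) + 1 everywhere
hard_tensor <- function(n_lines = 8, n_markers = 5) {
  P <- array(0, c(n_lines, n_markers, 8))
  f <- ((seq_len(n_lines) - 1L) %% 8L) + 1L
  for (l in seq_len(n_lines)) P[l, , f[l]] <- 2
  mk <- data.frame(chrom = "1", pos_bp = seq_len(n_markers) * 1e6,
                   marker_id = sprintf("hm%02d", seq_len(n_markers)))
  cc_tensor(P, sprintf("HL%02d", seq_len(n_lines)), mk)
}

# hand-built mosaic object (single line unless more segments given)
manual_mosaic <- function(segments, chrom_lengths,
                          het = NULL) {
  lines <- unique(segments$line)
  structure(list(
    segments = segments,
    het = het %||% data.frame(line = character(), chrom = character(),
                              start_bp = numeric(), end_bp = numeric(),
                              founder2 = integer()),
    lines = lines, chrom_lengths = chrom_lengths,
    het_fraction = setNames(rep(0, length(lines)), lines),
    generations = setNames(rep(37L, length(lines)), lines)),
    class = "cc_mosaic")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent weighted least-squares oracle via explicit normal equations
oracle_wls <- function(y, X, w) {
  XtW <- t(X * w)
  beta <- solve(XtW %*% X, XtW %*% y)
  res <- y - X %*% beta
  rss <- sum(w * res^2)
  list(beta = as.numeric(beta), rss = rss)
}

# oracle logP for the genetic-vs-null F test
oracle_logp <- function(y, X, w, clamp = 15) {
  fit <- oracle_wls(y, X, w)
  ybar <- sum(w * y) / sum(w)
  rss0 <- sum(w * (y - ybar)^2)
  n <- length(y)
  p <- ncol(X)
  fstat <- ((rss0 - fit$rss) / (p - 1)) / (fit$rss / (n - p))
  lp <- -pf(fstat, p - 1, n - p, lower.tail = FALSE, log.p = TRUE) / log(10)
  min(max(lp, 0), clamp)
}

# random dosage rows summing to 2 (for synthetic designs)
random_dosage_rows <- function(n) {
  t(vapply(seq_len(n), function(i) {
    x <- rgamma(8, shape = 0.5)
    2 * x / sum(x)
  }, numeric(8)))
}
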