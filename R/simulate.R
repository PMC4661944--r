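# Synthetic Collaborative Cross cohorts with known ground truth.
#
# A CC line genome is a mosaic of the 8 founder haplotypes.  Mosaics are
# simulated with a homogeneous Poisson breakpoint process per chromosome;
# residual heterozygosity (lines are sampled at inbreeding generations
# 11-37, i.e. 80-99.9% homozygous) is represented as intervals where the
# line carries one dose each of two founder haplotypes.

#' Simulate CC line founder mosaics
#'
#' @param n_lines number of lines to simulate.
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param breakpoint_rate_per_mb expected breakpoints per Mb per line
#'   (default 0.05, roughly the density observed in genotyped CC genomes).
#' @param inbreeding_generations integer vector (recycled) of generations of
#'   inbreeding per line; sampled uniformly from 11..37 when `NULL`.
#' @param seed optional integer seed.
#' @return An object of class `cc_mosaic`: segment table, heterozygosity
#'   overlay, per-line heterozygous genome fraction and generations.
#' @export
sim_mosaics <- function(n_lines, chrom_lengths, breakpoint_rate_per_mb = 0.05,
                        inbreeding_generations = NULL, seed = NULL) {
  stopifnot(n_lines >= 1, breakpoint_rate_per_mb >= 0)
  if (is.null(names(chrom_lengths))) stop("chrom_lengths must be named")
  if (any(chrom_lengths <= 0)) stop("zero-length chromosome")
  with_seed(seed, {
    lines <- sprintf("CC%03d", seq_len(n_lines))
    gens <- inbreeding_generations %||% sample(11:37, n_lines, replace = TRUE)
    gens <- rep_len(gens, n_lines)
    # heterozygous fraction decays geometrically with inbreeding generation,
    # spanning 0.20 at generation 11 down to 0.001 at generation 37
    het_frac <- pmin(pmax(0.2 * 0.816^(gens - 11), 0.001), 0.2)
    segs <- list()
    hets <- list()
    total_len <- sum(chrom_lengths)
    for (li in seq_len(n_lines)) {
      for (ch in names(chrom_lengths)) {
        L <- chrom_lengths[[ch]]
        nbk <- rpois(1, breakpoint_rate_per_mb * L / 1e6)
        bks <- sort(runif(nbk, 0, L))
        starts <- c(0, bks)
        ends <- c(bks, L)
        segs[[length(segs) + 1L]] <- data.frame(
          line = lines[li], chrom = ch,
          start_bp = floor(starts), end_bp = c(floor(bks), L),
          founder = sample.int(8L, length(starts), replace = TRUE))
      }
      # heterozygosity overlay: exponential-length intervals until the
      # target het fraction of the genome is reached
      remaining <- het_frac[li] * total_len
      guard <- 0L
      while (remaining > 0 && guard < 100L) {
        guard <- guard + 1L
        len <- min(remaining, rexp(1, 1 / 5e6))
        ch <- sample(names(chrom_lengths), 1,
                     prob = chrom_lengths / total_len)
        L <- chrom_lengths[[ch]]
        len <- min(len, L)
        start <- floor(runif(1, 0, L - len))
        hets[[length(hets) + 1L]] <- data.frame(
          line = lines[li], chrom = ch,
          start_bp = start, end_bp = floor(start + len),
          founder2 = sample.int(8L, 1))
        remaining <- remaining - len
      }
    }
    structure(list(
      segments = do.call(rbind, segs),
      het = if (length(hets)) do.call(rbind, hets) else
        data.frame(line = character(), chrom = character(),
                   start_bp = numeric(), end_bp = numeric(),
                   founder2 = integer()),
      lines = lines, chrom_lengths = chrom_lengths,
      het_fraction = setNames(het_frac, lines),
      generations = setNames(gens, lines)), class = "cc_mosaic")
  })
}

#' @export
print.cc_mosaic <- function(x, ...) {
  cat(sprintf("CC founder mosaics: %d lines, %d chromosomes, %d segments\n",
              length(x$lines), length(x$chrom_lengths), nrow(x$segments)))
  cat(sprintf("Homozygosity range: %.3f-%.3f\n",
              1 - max(x$het_fraction), 1 - min(x$het_fraction)))
  invisible(x)
}

#' Founder descent probabilities at a marker grid
#'
#' Converts hard mosaics to an additive-dosage probability tensor.  Markers
#' far from any breakpoint get dosage 2 on the segment's founder.  Within
#' `soft_halfwidth_bp` of a breakpoint the dosage is linearly interpolated
#' between the two flanking founders (1/1 exactly at the breakpoint),
#' emulating the short region of descent uncertainty that haplotype
#' reconstruction produces around recombination events.  Heterozygous
#' intervals contribute one dose of the overlay founder.
#'
#' @param mosaics a [sim_mosaics()] result.
#' @param markers marker map data frame (`chrom`, `pos_bp`, `marker_id`).
#' @param soft_halfwidth_bp half-width of the uncertainty window (>= 0).
#' @return A [cc_tensor()].
#' @export
prob_tensor <- function(mosaics, markers, soft_halfwidth_bp = 0) {
  stopifnot(soft_halfwidth_bp >= 0)
  markers$chrom <- as.character(markers$chrom)
  for (ch in unique(markers$chrom)) {
    if (!ch %in% names(mosaics$chrom_lengths)) {
      stop("marker chromosome not in mosaic: ", ch)
    }
    p <- markers$pos_bp[markers$chrom == ch]
    if (any(p < 0) || any(p >= mosaics$chrom_lengths[[ch]])) {
      stop("marker outside chromosome bounds on ", ch)
    }
  }
  lines <- mosaics$lines
  P <- array(0, c(length(lines), nrow(markers), 8L))
  hw <- soft_halfwidth_bp
  for (li in seq_along(lines)) {
    for (ch in unique(markers$chrom)) {
      mk_idx <- which(markers$chrom == ch)
      pos <- markers$pos_bp[mk_idx]
      segs <- mosaics$segments[mosaics$segments$line == lines[li] &
                                 mosaics$segments$chrom == ch, ]
      segs <- segs[order(segs$start_bp), ]
      si <- findInterval(pos, segs$start_bp)
      f <- segs$founder[si]
      row <- matrix(0, length(pos), 8L)
      row[cbind(seq_along(pos), f)] <- 2
      if (hw > 0 && nrow(segs) > 1) {
        for (j in seq_along(pos)) {
          k <- si[j]
          # distance to nearest internal breakpoint and the founder across it
          dl <- if (k > 1) pos[j] - segs$start_bp[k] else Inf
          dr <- if (k < nrow(segs)) segs$end_bp[k] - pos[j] else Inf
          d <- min(dl, dr)
          if (d < hw) {
            g <- if (dl <= dr) segs$founder[k - 1L] else segs$founder[k + 1L]
            row[j, ] <- 0
            row[j, f[j]] <- 1 + d / hw
            row[j, g] <- row[j, g] + 1 - d / hw
          }
        }
      }
      het <- mosaics$het[mosaics$het$line == lines[li] &
                           mosaics$het$chrom == ch, ]
      if (nrow(het)) {
        for (hh in seq_len(nrow(het))) {
          inh <- which(pos >= het$start_bp[hh] & pos < het$end_bp[hh])
          if (length(inh)) {
            g2 <- het$founder2[hh]
            row[inh, ] <- row[inh, , drop = FALSE] / 2
            row[inh, g2] <- row[inh, g2] + 1
          }
        }
      }
      P[li, mk_idx, ] <- row
    }
  }
  cc_tensor(P, lines, markers)
}

#' Simulate a founder variant catalogue
#'
#' Draws variants at uniform positions within the span of the marker grid,
#' each with a strain distribution pattern (SDP): the assignment of one
#' allele to each of the 8 founders.  SDPs are drawn uniformly over
#' non-constant assignments; the number of alleles per variant follows
#' `allele_counts`/`allele_probs` (biallelic by default, a configurable
#' fraction multiallelic).
#'
#' @param markers marker map defining per-chromosome spans.
#' @param n_variants number of variants (>= 1).
#' @param allele_counts,allele_probs distribution of the number of distinct
#'   alleles per variant; counts must all be >= 2.
#' @param seed optional integer seed.
#' @return An object of class `cc_catalogue`: a data frame with `chrom`,
#'   `pos_bp`, `variant_id`, `alleles` (comma-separated) and one column per
#'   founder holding its allele.
#' @export
sim_catalogue <- function(markers, n_variants,
                          allele_counts = c(2L, 3L),
                          allele_probs = c(0.8, 0.2), seed = NULL) {
  stopifnot(n_variants >= 1, length(allele_counts) == length(allele_probs))
  if (any(allele_counts < 2)) {
    stop("allele_counts must all be >= 2 (a variant needs two alleles)")
  }
  if (sum(allele_probs) <= 0) stop("degenerate allele count distribution")
  with_seed(seed, {
    chroms <- unique(markers$chrom)
    span <- lapply(chroms, function(ch) range(markers$pos_bp[markers$chrom == ch]))
    names(span) <- chroms
    ch <- sample(chroms, n_variants, replace = TRUE)
    pos <- vapply(ch, function(c_) round(runif(1, span[[c_]][1], span[[c_]][2])),
                  numeric(1))
    k <- sample(allele_counts, n_variants, replace = TRUE, prob = allele_probs)
    bases <- c("A", "C", "G", "T")
    sdp <- matrix("", n_variants, 8L)
    for (v in seq_len(n_variants)) {
      al <- sample(bases, k[v])
      repeat {
        assign_ <- sample(al, 8L, replace = TRUE)
        if (length(unique(assign_)) == k[v]) break
      }
      sdp[v, ] <- assign_
    }
    df <- data.frame(chrom = ch, pos_bp = pos,
                     variant_id = sprintf("v%05d", seq_len(n_variants)),
                     alleles = vapply(seq_len(n_variants), function(v)
                       paste(sort(unique(sdp[v, ])), collapse = ","),
                       character(1)))
    colnames(sdp) <- cc_founders()
    df <- cbind(df, as.data.frame(sdp))
    df <- df[order(match(df$chrom, chroms), df$pos_bp), ]
    rownames(df) <- NULL
    cc_catalogue(df)
  })
}

#' Validate and class a variant catalogue
#'
#' @param df data frame with columns `chrom`, `pos_bp`, `variant_id`,
#'   `alleles` and one allele column per founder.
#' @return The validated data frame with class `cc_catalogue`.
#' @export
cc_catalogue <- function(df) {
  req <- c("chrom", "pos_bp", "variant_id", "alleles", cc_founders())
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("catalogue missing columns: ",
                         paste(miss, collapse = ", "))
  sdp <- as.matrix(df[, cc_founders()])
  ndist <- apply(sdp, 1, function(r) length(unique(r)))
  if (any(ndist < 2)) {
    stop("constant SDP (monomorphic variant): ",
         paste(df$variant_id[ndist < 2], collapse = ", "))
  }
  for (ch in unique(df$chrom)) {
    if (is.unsorted(df$pos_bp[df$chrom == ch])) {
      stop("catalogue positions unsorted on chromosome ", ch)
    }
  }
  class(df) <- c("cc_catalogue", "data.frame")
  df
}

#' Trait model for phenotype simulation
#'
#' Describes a quantitative trait as grand mean + additive founder-effect
#' QTL + sex and age covariate effects + a line-level polygenic term + an
#' animal-level residual.  Founder effects are expressed relative to WSB
#' (whose effect is 0), matching the scan parameterisation.
#'
#' @param trait trait name.
#' @param mean grand mean, in trait units.
#' @param qtl list of QTL, each `list(marker = <id or index>, beta =
#'   <numeric(8), WSB entry 0>)`.
#' @param sex_effect additive shift for males, trait units.
#' @param age_slope trait units per week of age.
#' @param line_sd standard deviation of the line-level polygenic effect.
#' @param residual_sd standard deviation of the animal-level residual.
#' @return An object of class `cc_trait_model`.
#' @export
cc_trait_model <- function(trait = "BVTV", mean = 12, qtl = list(),
                           sex_effect = 3, age_slope = 0.3,
                           line_sd = 3.5, residual_sd = 2.5) {
  stopifnot(line_sd >= 0, residual_sd >= 0)
  for (q in qtl) {
    if (length(q$beta) != 8) stop("QTL effect vector must have length 8")
    if (abs(q$beta[cc_ref_founder()]) > 0) {
      stop("QTL effects are relative to WSB; the WSB entry must be 0")
    }
  }
  structure(list(trait = trait, mean = mean, qtl = qtl,
                 sex_effect = sex_effect, age_slope = age_slope,
                 line_sd = line_sd, residual_sd = residual_sd),
            class = "cc_trait_model")
}

#' Line-level polygenic SD that targets a broad-sense heritability
#'
#' The RSS-ratio heritability estimator absorbs within-line noise into the
#' between-line sum of squares (the line factor spends k-1 of ~N degrees of
#' freedom), so the population variance fraction that realises a given
#' expected estimate depends on the design.  This helper inverts the
#' balanced one-way ANOVA moments: with k lines and r animals per line,
#' E[SS_between] = (k-1)(sigma_e^2 + r sigma_l^2) and
#' E[SS_within] = (N-k) sigma_e^2, and solves
#' E[SS_between] / E[SS_total] = h2 for sigma_l.
#'
#' @param h2 target heritability estimate (0 < h2 < 1).
#' @param residual_sd animal-level residual SD.
#' @param n_lines,n_per_line design dimensions.
#' @return Line-level SD (0 when `h2` is below the noise floor of the design).
#' @export
line_sd_for_h2 <- function(h2, residual_sd, n_lines = 31, n_per_line = 5) {
  stopifnot(h2 >= 0, h2 < 1)
  k <- n_lines
  N <- n_lines * n_per_line
  v <- residual_sd^2 * (h2 * (N - 1) - (k - 1)) / (n_per_line * (k - 1) * (1 - h2))
  sqrt(max(v, 0))
}

#' Simulate animal-level phenotypes on a CC cohort
#'
#' Each animal's value is
#' `mean + sum_QTL sum_s dosage_s * beta_s + sex_effect * I(male) +
#'  age_slope * age + line polygenic + residual`.
#'
#' @param tensor a [cc_tensor()] giving the founder dosages of each line.
#' @param model a [cc_trait_model()].
#' @param n_per_line animals per line (scalar or per-line vector, >= 1).
#' @param sex_ratio probability an animal is male (default 86/160, the
#'   cohort composition the generator emulates).
#' @param age_range ages drawn uniformly from this range, in weeks.
#' @param seed optional integer seed.
#' @return Phenotype data frame (`animal_id`, `line`, `sex`, `age_weeks`,
#'   trait column) with a `"truth"` attribute recording the per-line
#'   genetic values and simulation components.
#' @export
sim_phenotypes <- function(tensor, model, n_per_line = 5,
                           sex_ratio = 86 / 160, age_range = c(10, 13),
                           seed = NULL) {
  stopifnot(inherits(model, "cc_trait_model"))
  n_per_line <- rep_len(as.integer(n_per_line), length(tensor$lines))
  if (any(n_per_line < 1)) stop("n_per_line must be >= 1")
  with_seed(seed, {
    nl <- length(tensor$lines)
    qtl_value <- numeric(nl)
    for (q in model$qtl) {
      mi <- marker_index(tensor, q$marker)
      qtl_value <- qtl_value + as.vector(tensor$P[, mi, ] %*% q$beta)
    }
    polygenic <- rnorm(nl, 0, model$line_sd)
    g <- qtl_value + polygenic
    rows <- lapply(seq_len(nl), function(li) {
      n <- n_per_line[li]
      sex <- ifelse(runif(n) < sex_ratio, "M", "F")
      age <- runif(n, age_range[1], age_range[2])
      val <- model$mean + g[li] +
        model$sex_effect * (sex == "M") +
        model$age_slope * age +
        rnorm(n, 0, model$residual_sd)
      data.frame(animal_id = sprintf("%s_a%02d", tensor$lines[li], seq_len(n)),
                 line = tensor$lines[li], sex = sex, age_weeks = age,
                 val = val)
    })
    phen <- do.call(rbind, rows)
    names(phen)[names(phen) == "val"] <- model$trait
    rownames(phen) <- NULL
    attr(phen, "truth") <- list(model = model,
                                line_genetic = setNames(g, tensor$lines),
                                qtl_value = setNames(qtl_value, tensor$lines),
                                polygenic = setNames(polygenic, tensor$lines))
    phen
  })
}

#' Simulate a Mendelian (albino-like) line trait
#'
#' Imputes the dosage of a causal allele in every line from the founder
#' probabilities and the variant's SDP, then thresholds it: recessive
#' lines are affected when they carry two doses of the causal allele,
#' dominant lines when they carry at least one.  Serves as a positive
#' control for the scan (the albinism control mapped to its known locus).
#'
#' @param tensor a [cc_tensor()].
#' @param catalogue a [cc_catalogue()].
#' @param variant_id id of the causal variant.
#' @param mode `"recessive"` or `"dominant"`.
#' @param allele causal allele label; defaults to the rarest founder allele.
#' @return Phenotype data frame with one animal per line and a binary
#'   `affected` trait; attribute `"causal"` records variant, allele, mode.
#' @export
sim_mendelian_trait <- function(tensor, catalogue, variant_id,
                                mode = c("recessive", "dominant"),
                                allele = NULL) {
  mode <- match.arg(mode)
  v <- catalogue[catalogue$variant_id == variant_id, ]
  if (nrow(v) != 1) stop("causal variant not in catalogue: ", variant_id)
  sdp <- unlist(v[1, cc_founders()])
  if (length(unique(sdp)) < 2) stop("causal variant is monomorphic")
  if (is.null(allele)) {
    tab <- sort(table(sdp))
    allele <- names(tab)[1]
  }
  dos <- impute_dosages(tensor, v)
  D <- dos$dosage[[v$variant_id]]
  d <- D[, allele]
  if (max(d) - min(d) < 1e-9) {
    stop("causal variant monomorphic across lines (imputed dosage constant)")
  }
  affected <- as.integer(if (mode == "recessive") d > 1.5 else d > 0.5)
  phen <- data.frame(animal_id = paste0(tensor$lines, "_a01"),
                     line = tensor$lines, sex = "F", age_weeks = 12,
                     affected = affected)
  attr(phen, "causal") <- list(variant_id = variant_id, allele = allele,
                               mode = mode, chrom = v$chrom, pos_bp = v$pos_bp,
                               dosage = d)
  phen
}

#' Default synthetic genome for desk-scale cohorts
#'
#' @param n_chrom number of chromosomes.
#' @param length_mb chromosome length in Mb.
#' @return Named vector of chromosome lengths in bp.
#' @export
cc_genome <- function(n_chrom = 10, length_mb = 100) {
  setNames(rep(length_mb * 1e6, n_chrom), as.character(seq_len(n_chrom)))
}

#' Simulate a complete CC cohort
#'
#' One-call generator mirroring the emulated study design: 31 lines, 5 mice
#' per line, sexes ~86M:74F, ages uniform on 10-13 weeks, over a reduced
#' genome (10 x 100 Mb, 1 marker/Mb) for tractable scans.
#'
#' @param n_lines,n_per_line cohort dimensions.
#' @param chrom_lengths genome; defaults to [cc_genome()].
#' @param marker_spacing_bp marker grid spacing.
#' @param model a [cc_trait_model()]; default BV/TV-like trait.
#' @param n_variants catalogue size (0 to skip the catalogue).
#' @param breakpoint_rate_per_mb,soft_halfwidth_bp mosaic parameters.
#' @param seed integer seed; sub-stages use fixed offsets from it.
#' @return List with `mosaics`, `tensor`, `catalogue`, `phenotypes`,
#'   `markers` and `model`.
#' @export
sim_cohort <- function(n_lines = 31, n_per_line = 5,
                       chrom_lengths = cc_genome(),
                       marker_spacing_bp = 1e6,
                       model = cc_trait_model(),
                       n_variants = 200,
                       breakpoint_rate_per_mb = 0.05,
                       soft_halfwidth_bp = 2e5,
                       seed = NULL) {
  mos <- sim_mosaics(n_lines, chrom_lengths, breakpoint_rate_per_mb,
                     seed = if (is.null(seed)) NULL else seed + 1L)
  mk <- marker_grid(chrom_lengths, marker_spacing_bp)
  tens <- prob_tensor(mos, mk, soft_halfwidth_bp)
  cat_ <- if (n_variants > 0) {
    sim_catalogue(mk, n_variants,
                  seed = if (is.null(seed)) NULL else seed + 2L)
  }
  phen <- sim_phenotypes(tens, model, n_per_line,
                         seed = if (is.null(seed)) NULL else seed + 3L)
  list(mosaics = mos, tensor = tens, catalogue = cat_, phenotypes = phen,
       markers = mk, model = model)
}
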