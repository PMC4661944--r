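# Merge analysis: impute variant allele dosages from founder descent
# probabilities and the variant's strain distribution pattern (SDP), then
# test the merged (collapsed-founder) model against the null.  Because the
# merged design is a linear collapse of the 8 founder columns it is a
# sub-model of the haplotype model: its RSS can never be smaller, but with
# fewer degrees of freedom it can reach higher logP, which is what makes a
# variant a credible quantitative trait nucleotide.

#' Impute variant allele dosages in every line
#'
#' For each variant, the dosage of allele `a` in line `L` is the sum of the
#' founder descent dosages of the founders carrying `a`, taken at the
#' nearest marker:
#' `dosage(a) = sum_s X_p(a, s) * dosage_s`,
#' the additive collapse of the founder-pair double sum
#' `G_pi(a, b) = sum_{s,t} X_p(a, s) X_p(b, t) F_Li(s, t)`.
#'
#' @param tensor a [cc_tensor()].
#' @param catalogue a [cc_catalogue()].
#' @param region optional `list(chrom =, start_bp =, end_bp =)` restricting
#'   the variants.
#' @return Object of class `cc_dosage`: a `variants` table (with assigned
#'   marker and its distance) and a named list `dosage` of line x allele
#'   matrices, each row summing to 2.
#' @export
impute_dosages <- function(tensor, catalogue, region = NULL) {
  cat_ <- catalogue
  if (!is.null(region)) {
    cat_ <- cat_[cat_$chrom == region$chrom &
                   cat_$pos_bp >= region$start_bp &
                   cat_$pos_bp <= region$end_bp, , drop = FALSE]
  }
  if (!nrow(cat_)) stop("no variants in region")
  mk <- tensor$markers
  keep <- cat_$chrom %in% unique(mk$chrom)
  if (any(!keep)) {
    warning("variants with no covering marker skipped: ",
            paste(cat_$variant_id[!keep], collapse = ", "))
    cat_ <- cat_[keep, , drop = FALSE]
  }
  vars <- list()
  dosage <- list()
  for (v in seq_len(nrow(cat_))) {
    idx <- which(mk$chrom == cat_$chrom[v])
    j <- idx[which.min(abs(mk$pos_bp[idx] - cat_$pos_bp[v]))]
    sdp <- unlist(cat_[v, cc_founders()])
    alleles <- sort(unique(sdp))
    Pm <- matrix(tensor$P[, j, ], nrow = length(tensor$lines))
    ind <- outer(sdp, alleles, "==") + 0  # 8 x k founder-carries-allele
    D <- Pm %*% ind
    dimnames(D) <- list(tensor$lines, alleles)
    dosage[[cat_$variant_id[v]]] <- D
    vars[[v]] <- data.frame(
      chrom = cat_$chrom[v], pos_bp = cat_$pos_bp[v],
      variant_id = cat_$variant_id[v], marker_id = mk$marker_id[j],
      marker_bp = mk$pos_bp[j],
      distance_bp = abs(mk$pos_bp[j] - cat_$pos_bp[v]),
      alleles = paste(alleles, collapse = ","),
      sdp = paste(sdp, collapse = ""))
  }
  structure(list(variants = do.call(rbind, vars), dosage = dosage,
                 lines = tensor$lines), class = "cc_dosage")
}

#' @export
print.cc_dosage <- function(x, ...) {
  cat(sprintf("Imputed dosages: %d variants x %d lines\n",
              nrow(x$variants), length(x$lines)))
  invisible(x)
}

#' Merge scan: test imputed variants against the trait
#'
#' Per variant, the (weighted) line means are regressed on k-1 allele
#' dosage columns (k = allele count; the most frequent allele is the
#' reference) and tested against the weighted-mean null.  Variants whose
#' total minor-allele dosage mass across lines falls below
#' `min_minor_mass` are flagged monomorphic and given logP 0.
#'
#' @inheritParams marker_fit
#' @param dosages an [impute_dosages()] result.
#' @param scan optional [scan_haplotypes()] result used to attach (and
#'   check against) the haplotype logP and RSS at each covering marker.
#' @param min_minor_mass minimum summed minor-dosage mass (default 0.5).
#' @return Data frame of class `cc_merge`: variant coordinates, SDP string,
#'   allele class (`BA`/`MA`), `merge_logp`, the haplotype `hap_logp` at
#'   the covering marker, and flags.
#' @export
merge_scan <- function(line_means, dosages, scan = NULL, weights = NULL,
                       min_minor_mass = 0.5, clamp = LOGP_CLAMP) {
  lm_ <- resolve_means(line_means, weights)
  li <- match(lm_$lines, dosages$lines)
  if (anyNA(li)) stop("line means and dosages cover different lines")
  w <- lm_$w
  ybar <- weighted.mean(lm_$y, w)
  rss0 <- sum(w * (lm_$y - ybar)^2)
  n <- length(lm_$y)
  vars <- dosages$variants
  out <- vars[, c("chrom", "pos_bp", "variant_id", "marker_id",
                  "distance_bp", "alleles", "sdp")]
  out$k <- lengths(strsplit(vars$alleles, ","))
  out$class <- ifelse(out$k > 2, "MA", "BA")
  out$merge_logp <- 0
  out$merge_rss <- NA_real_
  out$monomorphic <- FALSE
  for (v in seq_len(nrow(vars))) {
    D <- dosages$dosage[[vars$variant_id[v]]][li, , drop = FALSE]
    major <- which.max(colSums(D))
    minor_mass <- sum(2 - D[, major])
    if (minor_mass < min_minor_mass) {
      out$monomorphic[v] <- TRUE
      next
    }
    X <- cbind(1, D[, -major, drop = FALSE])
    fit <- lm.wfit(X, lm_$y, w)
    rss1 <- sum(w * fit$residuals^2)
    df1 <- fit$rank - 1
    df2 <- n - fit$rank
    out$merge_rss[v] <- rss1
    out$merge_logp[v] <- f_test_logp(rss0, rss1, df1, df2, clamp)
  }
  if (!is.null(scan)) {
    mi <- match(vars$marker_id, scan$markers$marker_id)
    out$hap_logp <- scan$logp[mi]
    hap_rss <- scan$rss[mi]
    # sub-model property: the merged design is a collapse of the founder
    # design, so its RSS is never below the haplotype-model RSS
    ok <- is.na(out$merge_rss) |
      out$merge_rss >= hap_rss - 1e-8 * pmax(hap_rss, 1)
    if (!all(ok)) stop("sub-model violation: merge RSS below haplotype RSS")
  }
  class(out) <- c("cc_merge", "data.frame")
  rownames(out) <- NULL
  out
}

#' Filter merge results to candidate variants
#'
#' Keeps variants whose merge logP is at least the haplotype-scan peak
#' logP (testable variants only), sorted by decreasing merge logP.  When a
#' gene annotation table is supplied each candidate is annotated with the
#' nearest gene.
#'
#' @param merge_result a [merge_scan()] result.
#' @param peak_logp haplotype-scan peak logP of the corresponding QTL.
#' @param annotation optional data frame (`chrom`, `start_bp`, `end_bp`,
#'   `gene`).
#' @return Filtered, sorted `cc_merge` data frame (possibly 0 rows).
#' @export
candidate_filter <- function(merge_result, peak_logp, annotation = NULL) {
  out <- merge_result[!merge_result$monomorphic &
                        merge_result$merge_logp >= peak_logp, , drop = FALSE]
  out <- out[order(-out$merge_logp, out$pos_bp), , drop = FALSE]
  if (!is.null(annotation) && nrow(out)) {
    out$gene <- vapply(seq_len(nrow(out)), function(i) {
      g <- annotation[annotation$chrom == out$chrom[i], , drop = FALSE]
      if (!nrow(g)) return(NA_character_)
      mid <- (g$start_bp + g$end_bp) / 2
      g$gene[which.min(abs(mid - out$pos_bp[i]))]
    }, character(1))
  }
  rownames(out) <- NULL
  out
}
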