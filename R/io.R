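# Plain-text readers and writers for the pipeline's objects.
#
# All machine files are TSV/CSV with fixed column orders.  Floating point
# values are written with "%.17g" so that write -> read -> write round
# trips are byte-identical.

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

write_tsv_raw <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2)) {
    if (is.numeric(df2[[j]]) && !is.integer(df2[[j]])) {
      df2[[j]] <- fmt_num(df2[[j]])
    }
  }
  write.table(df2, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write / read an animal-level phenotype table
#'
#' CSV with header `animal_id,line,sex,age_weeks,<traits...>`; sex is
#' `F`/`M`.
#'
#' @param phenotypes phenotype data frame.
#' @param path file path.
#' @return `read_phenotypes` returns the phenotype data frame.
#' @export
write_phenotypes <- function(phenotypes, path) {
  req <- c("animal_id", "line", "sex", "age_weeks")
  stopifnot(all(req %in% names(phenotypes)))
  df <- phenotypes[, c(req, setdiff(names(phenotypes), req)), drop = FALSE]
  df2 <- df
  for (j in seq_along(df2)) {
    if (is.numeric(df2[[j]]) && !is.integer(df2[[j]])) {
      df2[[j]] <- fmt_num(df2[[j]])
    }
  }
  write.csv(df2, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("animal_id", "line", "sex", "age_weeks")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("malformed phenotype header, missing: ", paste(miss, collapse = ", "))
  }
  bad <- which(!df$sex %in% c("F", "M"))
  if (length(bad)) {
    stop("invalid sex value at data line ", bad[1], ": ", df$sex[bad[1]])
  }
  for (j in setdiff(names(df), c("animal_id", "line", "sex"))) {
    df[[j]] <- as.numeric(df[[j]])
  }
  if (anyDuplicated(df$animal_id)) {
    stop("duplicated animal_id: ", df$animal_id[anyDuplicated(df$animal_id)])
  }
  df
}

#' Write / read a founder probability tensor
#'
#' Two files: `<prefix>.markers.tsv` (`chrom`, `pos_bp`, `marker_id`,
#' sorted) and `<prefix>.probs.tsv` (`line`, `marker_id`, one dosage column
#' per founder).
#'
#' @param tensor a [cc_tensor()].
#' @param prefix path prefix for the two files.
#' @return `read_tensor` returns the [cc_tensor()].
#' @export
write_tensor <- function(tensor, prefix) {
  write_tsv_raw(tensor$markers, paste0(prefix, ".markers.tsv"))
  nl <- length(tensor$lines)
  nm <- nrow(tensor$markers)
  probs <- data.frame(line = rep(tensor$lines, each = nm),
                      marker_id = rep(tensor$markers$marker_id, nl))
  for (f in seq_len(8L)) {
    probs[[cc_founders()[f]]] <- as.vector(t(tensor$P[, , f]))
  }
  write_tsv_raw(probs, paste0(prefix, ".probs.tsv"))
  invisible(prefix)
}

#' @rdname write_tensor
#' @export
read_tensor <- function(prefix) {
  mk <- read.delim(paste0(prefix, ".markers.tsv"), stringsAsFactors = FALSE)
  miss <- setdiff(c("chrom", "pos_bp", "marker_id"), names(mk))
  if (length(miss)) {
    stop("malformed marker map header, missing: ",
         paste(miss, collapse = ", "))
  }
  mk$chrom <- as.character(mk$chrom)
  for (ch in unique(mk$chrom)) {
    p <- mk$pos_bp[mk$chrom == ch]
    if (is.unsorted(p)) {
      line_no <- which(mk$chrom == ch)[which(diff(p) < 0)[1] + 1L] + 1L
      stop("unsorted marker positions on chromosome ", ch,
           " at file line ", line_no)
    }
  }
  probs <- read.delim(paste0(prefix, ".probs.tsv"), check.names = FALSE,
                      stringsAsFactors = FALSE)
  founder_cols <- setdiff(names(probs), c("line", "marker_id"))
  unknown <- setdiff(founder_cols, cc_founders())
  if (length(unknown)) {
    stop("unknown founder column: ", paste(unknown, collapse = ", "))
  }
  if (length(founder_cols) != 8L) {
    stop("expected 8 founder columns, found ", length(founder_cols))
  }
  lines <- unique(probs$line)
  nm <- nrow(mk)
  P <- array(NA_real_, c(length(lines), nm, 8L))
  row_l <- match(probs$line, lines)
  row_m <- match(probs$marker_id, mk$marker_id)
  if (anyNA(row_m)) {
    stop("probability row references unknown marker at file line ",
         which(is.na(row_m))[1] + 1L)
  }
  for (f in seq_len(8L)) {
    P[cbind(row_l, row_m, f)] <- as.numeric(probs[[cc_founders()[f]]])
  }
  cc_tensor(P, lines, mk)
}

#' Write / read a founder variant catalogue
#'
#' VCF-like TSV with columns `CHROM`, `POS`, `ID`, `ALLELES` (comma list)
#' and exactly one allele column per founder
#' (`A/J`, `C57BL/6J`, `129S1`, `NOD`, `NZO`, `CAST`, `PWK`, `WSB`).
#'
#' @param catalogue a [cc_catalogue()].
#' @param path file path.
#' @return `read_catalogue` returns the [cc_catalogue()].
#' @export
write_catalogue <- function(catalogue, path) {
  df <- data.frame(CHROM = catalogue$chrom, POS = catalogue$pos_bp,
                   ID = catalogue$variant_id, ALLELES = catalogue$alleles,
                   check.names = FALSE)
  fc <- cc_founder_columns()
  for (f in cc_founders()) df[[fc[[f]]]] <- catalogue[[f]]
  write_tsv_raw(df, path)
  invisible(path)
}

#' @rdname write_catalogue
#' @export
read_catalogue <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("CHROM", "POS", "ID", "ALLELES")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("malformed catalogue header, missing: ", paste(miss, collapse = ", "))
  }
  fc <- cc_founder_columns()
  extra <- setdiff(names(df), c(req, unname(fc)))
  if (length(extra)) {
    stop("unexpected founder column in catalogue: ",
         paste(extra, collapse = ", "))
  }
  miss_f <- setdiff(unname(fc), names(df))
  if (length(miss_f)) {
    stop("catalogue missing founder column: ", paste(miss_f, collapse = ", "))
  }
  out <- data.frame(chrom = as.character(df$CHROM), pos_bp = df$POS,
                    variant_id = df$ID, alleles = df$ALLELES)
  for (f in cc_founders()) out[[f]] <- df[[fc[[f]]]]
  for (ch in unique(out$chrom)) {
    p <- out$pos_bp[out$chrom == ch]
    if (is.unsorted(p)) {
      line_no <- which(out$chrom == ch)[which(diff(p) < 0)[1] + 1L] + 1L
      stop("unsorted catalogue positions on chromosome ", ch,
           " at file line ", line_no)
    }
  }
  cc_catalogue(out)
}

#' Write a scan result to TSV
#'
#' Columns: `chrom`, `bp`, `marker_id`, `logP`, then the eight founder
#' effect columns `beta_AJ` ... `beta_WSB`.
#'
#' @param scan a [scan_haplotypes()] result.
#' @param path file path.
#' @export
write_scan_tsv <- function(scan, path) {
  df <- data.frame(chrom = scan$markers$chrom, bp = scan$markers$pos_bp,
                   marker_id = scan$markers$marker_id, logP = scan$logp)
  B <- t(scan$beta)
  colnames(B) <- paste0("beta_", gsub("/", "", cc_founders()))
  write_tsv_raw(cbind(df, as.data.frame(B)), path)
  invisible(path)
}

#' Write QTL calls to TSV
#' @param calls a [call_qtls()] result (optionally augmented with
#'   regional heritability / CI columns).
#' @param path file path.
#' @export
write_calls_tsv <- function(calls, path) {
  write_tsv_raw(as.data.frame(calls), path)
  invisible(path)
}

#' Write confidence intervals to TSV
#' @param ci a [qtl_ci_sim()] / [qtl_ci_li()] result (rows may be bound
#'   together).
#' @param path file path.
#' @export
write_ci_tsv <- function(ci, path) {
  write_tsv_raw(as.data.frame(ci), path)
  invisible(path)
}

#' Write merge-analysis results to TSV
#' @param merge_result a [merge_scan()] result.
#' @param path file path.
#' @export
write_merge_tsv <- function(merge_result, path) {
  write_tsv_raw(as.data.frame(merge_result), path)
  invisible(path)
}

#' Write a heritability report (one row per trait)
#' @param herit_list list of [heritability()] results.
#' @param path file path.
#' @export
write_herit_tsv <- function(herit_list, path) {
  rows <- lapply(herit_list, function(h) {
    sx <- h$covariate_effects[["sex"]]
    ag <- h$covariate_effects[["age_weeks"]]
    data.frame(trait = h$trait, H2 = h$h2, logP = h$logp,
               sex_effect = if (is.null(sx)) NA_real_ else sx$effect,
               sex_logP = if (is.null(sx)) NA_real_ else sx$logp,
               age_effect = if (is.null(ag)) NA_real_ else ag$effect,
               age_logP = if (is.null(ag)) NA_real_ else ag$logp)
  })
  write_tsv_raw(do.call(rbind, rows), path)
  invisible(path)
}
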