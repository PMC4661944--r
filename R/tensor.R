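# Founder-descent probability tensor: lines x markers x 8 founders, on the
# additive dosage scale (rows sum to 2).  This is the regression design for
# the haplotype scan and the basis of variant imputation.

#' Construct a founder probability tensor
#'
#' Bundles a line-by-marker-by-founder dosage array with its marker map.
#' Dosages are on the additive diploid scale: for every line and marker the
#' eight founder entries are non-negative and sum to 2.
#'
#' @param P numeric array `lines x markers x 8`; `dimnames` may be absent.
#' @param lines character vector of line labels (rows of `P`).
#' @param markers data frame with columns `chrom`, `pos_bp`, `marker_id`,
#'   sorted by position within chromosome.
#' @return An object of class `cc_tensor`.
#' @export
cc_tensor <- function(P, lines, markers) {
  stopifnot(is.array(P), length(dim(P)) == 3)
  if (dim(P)[3] != 8L) stop("tensor must have 8 founder slices")
  if (dim(P)[1] != length(lines)) stop("line labels do not match tensor rows")
  req <- c("chrom", "pos_bp", "marker_id")
  if (!all(req %in% names(markers))) {
    stop("marker map needs columns: ", paste(req, collapse = ", "))
  }
  if (dim(P)[2] != nrow(markers)) stop("marker map does not match tensor")
  markers$chrom <- as.character(markers$chrom)
  markers$marker_id <- as.character(markers$marker_id)
  if (is.unsorted(order(match(markers$chrom, unique(markers$chrom)),
                        markers$pos_bp))) {
    stop("markers must be sorted by position within chromosome")
  }
  for (ch in unique(markers$chrom)) {
    p <- markers$pos_bp[markers$chrom == ch]
    if (is.unsorted(p)) stop("marker positions unsorted on chromosome ", ch)
  }
  dimnames(P) <- list(lines, markers$marker_id, cc_founders())
  obj <- structure(list(P = P, lines = as.character(lines), markers = markers),
                   class = "cc_tensor")
  validate_tensor(obj)
  obj
}

#' Check the sum-to-2 invariant of a probability tensor
#'
#' @param tensor a [cc_tensor()].
#' @param tol numeric tolerance on the dosage sums.
#' @return `tensor`, invisibly; errors if the invariant fails.
#' @export
validate_tensor <- function(tensor, tol = 1e-9) {
  P <- tensor$P
  if (any(P < -tol)) stop("negative founder dosage in tensor")
  s <- rowSums(P, dims = 2)  # lines x markers, summed over founders
  if (any(abs(s - 2) > tol)) {
    bad <- which(abs(s - 2) > tol, arr.ind = TRUE)[1, ]
    stop(sprintf("dosages at line %s, marker %s sum to %.12f (expected 2)",
                 tensor$lines[bad[1]], tensor$markers$marker_id[bad[2]],
                 s[bad[1], bad[2]]))
  }
  invisible(tensor)
}

#' @export
print.cc_tensor <- function(x, ...) {
  cat(sprintf("Founder probability tensor: %d lines x %d markers x 8 founders\n",
              length(x$lines), nrow(x$markers)))
  cat("Chromosomes:", paste(unique(x$markers$chrom), collapse = ", "), "\n")
  invisible(x)
}

#' Evenly spaced marker grid over a genome
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param spacing_bp marker spacing in bp.
#' @param start_bp position of the first marker on each chromosome.
#' @return Marker map data frame (`chrom`, `pos_bp`, `marker_id`).
#' @export
marker_grid <- function(chrom_lengths, spacing_bp, start_bp = spacing_bp / 2) {
  stopifnot(!is.null(names(chrom_lengths)), all(chrom_lengths > 0))
  out <- lapply(names(chrom_lengths), function(ch) {
    pos <- seq(start_bp, chrom_lengths[[ch]] - 1, by = spacing_bp)
    data.frame(chrom = ch, pos_bp = pos,
               marker_id = sprintf("m_%s_%04d", ch, seq_along(pos)))
  })
  do.call(rbind, out)
}

# resolve a marker reference (id or index) to an index into the marker map
marker_index <- function(tensor, marker) {
  if (is.numeric(marker)) {
    i <- as.integer(marker)
    if (i < 1 || i > nrow(tensor$markers)) stop("marker index out of range")
    return(i)
  }
  i <- match(marker, tensor$markers$marker_id)
  if (is.na(i)) stop("unknown marker: ", marker)
  i
}

# reorder/subset tensor rows to a set of line labels
tensor_lines <- function(tensor, lines) {
  idx <- match(lines, tensor$lines)
  if (anyNA(idx)) {
    stop("lines absent from tensor: ",
         paste(lines[is.na(idx)], collapse = ", "))
  }
  idx
}

# lines x founders x markers cube for the compiled scan
tensor_cube <- function(tensor, line_idx = seq_along(tensor$lines),
                        marker_idx = seq_len(nrow(tensor$markers))) {
  aperm(tensor$P[line_idx, marker_idx, , drop = FALSE], c(1, 3, 2))
}

#' Average markers in consecutive windows
#'
#' Collapses each run of `window` consecutive markers (within chromosome)
#' to a single pseudo-marker whose founder dosages are the window means,
#' renormalised to sum to 2.  The representative position is the bp midpoint
#' of the window; a trailing partial window is averaged as-is.  This mirrors
#' the pruning used on dense genotyping arrays to speed up scans and damp
#' genotyping error.
#'
#' @param tensor a [cc_tensor()].
#' @param window integer window size (>= 1); `window = 1` returns the input.
#' @return A pruned [cc_tensor()].
#' @export
prune_markers <- function(tensor, window) {
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  if (window == 1L) return(tensor)
  mk <- tensor$markers
  out_P <- list()
  out_mk <- list()
  for (ch in unique(mk$chrom)) {
    idx <- which(mk$chrom == ch)
    grp <- (seq_along(idx) - 1L) %/% window
    for (g in unique(grp)) {
      w_idx <- idx[grp == g]
      block <- tensor$P[, w_idx, , drop = FALSE]
      avg <- apply(block, c(1, 3), mean)
      avg <- 2 * avg / rowSums(avg)
      pos <- round((min(mk$pos_bp[w_idx]) + max(mk$pos_bp[w_idx])) / 2)
      out_P[[length(out_P) + 1L]] <- avg
      out_mk[[length(out_mk) + 1L]] <-
        data.frame(chrom = ch, pos_bp = pos,
                   marker_id = sprintf("pr_%s_%04d", ch, g + 1L))
    }
  }
  newmk <- do.call(rbind, out_mk)
  newP <- array(NA_real_, c(length(tensor$lines), nrow(newmk), 8L))
  for (j in seq_along(out_P)) newP[, j, ] <- out_P[[j]]
  cc_tensor(newP, tensor$lines, newmk)
}
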