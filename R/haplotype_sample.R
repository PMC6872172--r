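#' Haplotype sample container
#'
#' A sample of phased haplotypes from one region: a binary matrix
#' (rows = haplotypes, columns = SNPs; 0 = ancestral, 1 = derived), SNP
#' positions in bp on `[0, L)`, an integer deme label per haplotype
#' (0 = panmictic / unlabelled, 1 and 2 for the two demes) and, when known
#' from simulation truth, the position of the selected site.
#'
#' Positions must be strictly increasing. Columns are expected to be
#' polymorphic in the pooled sample; the (possibly fixed) selected site is
#' the only allowed exception and validation is therefore not enforced
#' per column.
#'
#' @param matrix Integer/numeric matrix of 0s and 1s, n_hap x n_snp.
#' @param positions Numeric vector of bp coordinates, strictly increasing,
#'   in `[0, region_length)`.
#' @param region_length Region length L in bp.
#' @param deme_labels Integer vector, one per haplotype. Default all 0.
#' @param selected_pos bp position of the selected site, or `NA`.
#'
#' @return An object of class `haplotype_sample`.
#' @export
haplotype_sample <- function(matrix, positions, region_length,
                             deme_labels = NULL, selected_pos = NA_real_) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "integer"
  if (ncol(matrix) != length(positions)) {
    stop("ncol(matrix) must equal length(positions)")
  }
  if (length(positions) > 0) {
    if (any(positions < 0 | positions >= region_length)) {
      stop("positions must lie in [0, region_length)")
    }
    if (any(diff(positions) <= 0)) stop("positions must be strictly increasing")
  }
  if (!all(matrix %in% c(0L, 1L))) stop("matrix entries must be 0 or 1")
  if (is.null(deme_labels)) deme_labels <- rep(0L, nrow(matrix))
  if (length(deme_labels) != nrow(matrix)) {
    stop("deme_labels must have one entry per haplotype")
  }
  structure(
    list(matrix = matrix, positions = as.numeric(positions),
         region_length = as.numeric(region_length),
         deme_labels = as.integer(deme_labels),
         selected_pos = as.numeric(selected_pos)),
    class = "haplotype_sample"
  )
}

#' @export
print.haplotype_sample <- function(x, ...) {
  cat(sprintf(
    "haplotype_sample: %d haplotypes x %d SNPs over [0, %g) bp%s\n",
    nrow(x$matrix), ncol(x$matrix), x$region_length,
    if (!is.na(x$selected_pos)) sprintf(", selected site at %g bp", x$selected_pos) else ""
  ))
  invisible(x)
}

#' Subset a haplotype sample by deme or interval
#'
#' Restricts a sample to the haplotypes of one deme (by label) and/or to a
#' bp interval. Columns monomorphic after subsetting are retained: window
#' statistics skip them by frequency, and dropping them would
#' desynchronise positions between demes for the cross-population
#' statistics.
#'
#' @param sample A [haplotype_sample].
#' @param deme Deme label(s) to keep, or `NULL` for all.
#' @param from,to bp interval bounds (half-open), or `NULL`.
#' @return A [haplotype_sample].
#' @export
subset_sample <- function(sample, deme = NULL, from = NULL, to = NULL) {
  m <- sample$matrix
  pos <- sample$positions
  lab <- sample$deme_labels
  if (!is.null(deme)) {
    keep <- lab %in% deme
    m <- m[keep, , drop = FALSE]
    lab <- lab[keep]
  }
  if (!is.null(from) || !is.null(to)) {
    from <- if (is.null(from)) 0 else from
    to <- if (is.null(to)) sample$region_length else to
    keep <- pos >= from & pos < to
    m <- m[, keep, drop = FALSE]
    pos <- pos[keep]
  }
  haplotype_sample(m, pos, sample$region_length, lab, sample$selected_pos)
}
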