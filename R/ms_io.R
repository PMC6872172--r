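#' Read haplotype samples from Hudson ms-format text
#'
#' Parses the ms dialect (`//` replicate separator, `segsites:`,
#' `positions:` with fractional coordinates in `[0, 1)`, then one 0/1 row
#' per haplotype). Fractional positions are scaled to bp by
#' `region_length` and kept as continuous coordinates (no rounding), in
#' keeping with the infinite-sites assumption. Tied positions after
#' scaling are separated by a minimal jitter with a warning.
#'
#' @param con A file path, connection, or character vector of lines.
#' @param region_length Region length L in bp used to scale positions.
#' @param deme_sizes Optional integer vector: number of haplotypes per deme
#'   in row order (as produced by ms `-I`); used to assign deme labels
#'   1, 2, ... If `NULL`, all labels are 0.
#'
#' @return A list of [haplotype_sample] objects, one per replicate.
#' @seealso [write_ms()]
#' @export
read_ms <- function(con, region_length, deme_sizes = NULL) {
  lines <- if (is.character(con) && length(con) > 1) {
    con
  } else if (is.character(con) && !file.exists(con) && any(grepl("\n", con))) {
    strsplit(con, "\n", fixed = TRUE)[[1]]
  } else {
    readLines(con)
  }
  n_hap_header <- NA_integer_
  if (length(lines) > 0) {
    toks <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
    if (length(toks) >= 3 && !is.na(suppressWarnings(as.integer(toks[2])))) {
      n_hap_header <- as.integer(toks[2])
    }
  }
  rep_starts <- which(trimws(lines) == "//")
  samples <- vector("list", length(rep_starts))
  bounds <- c(rep_starts, length(lines) + 1L)
  for (k in seq_along(rep_starts)) {
    block <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    block <- block[nzchar(trimws(block))]
    seg_line <- grep("^segsites:", block, value = TRUE)
    if (length(seg_line) != 1) {
      stop(sprintf("replicate %d: missing 'segsites:' line", k))
    }
    segsites <- as.integer(sub("^segsites:\\s*", "", seg_line))
    if (segsites == 0L) {
      n_hap <- if (!is.na(n_hap_header)) n_hap_header else 0L
      samples[[k]] <- haplotype_sample(
        matrix(integer(0), nrow = n_hap, ncol = 0),
        numeric(0), region_length,
        deme_labels = ms_deme_labels(n_hap, deme_sizes)
      )
      next
    }
    pos_line <- grep("^positions:", block, value = TRUE)
    if (length(pos_line) != 1) {
      stop(sprintf("replicate %d: missing 'positions:' line", k))
    }
    frac <- as.numeric(strsplit(sub("^positions:\\s*", "", pos_line), "\\s+")[[1]])
    if (length(frac) != segsites) {
      stop(sprintf("replicate %d: %d positions for segsites: %d",
                   k, length(frac), segsites))
    }
    rows <- block[grepl("^[01]+$", block)]
    widths <- nchar(rows)
    if (any(widths != segsites)) {
      stop(sprintf("replicate %d: haplotype row length %d does not match segsites: %d",
                   k, widths[which(widths != segsites)[1]], segsites))
    }
    m <- matrix(
      as.integer(unlist(strsplit(rows, "", fixed = TRUE), use.names = FALSE)),
      nrow = length(rows), ncol = segsites, byrow = TRUE
    )
    pos <- frac * region_length
    if (anyDuplicated(pos)) {
      pos <- dejitter_positions(pos)
      warning(sprintf("replicate %d: tied positions jittered by minimal increment", k))
    }
    samples[[k]] <- haplotype_sample(
      m, pos, region_length,
      deme_labels = ms_deme_labels(nrow(m), deme_sizes)
    )
  }
  samples
}

ms_deme_labels <- function(n_hap, deme_sizes) {
  if (is.null(deme_sizes)) return(rep(0L, n_hap))
  if (sum(deme_sizes) != n_hap) {
    stop("deme_sizes must sum to the number of haplotypes")
  }
  rep(seq_along(deme_sizes), deme_sizes)
}

# Separate exact ties by the smallest representable increment while
# preserving order.
dejitter_positions <- function(pos) {
  for (i in seq_along(pos)[-1]) {
    if (pos[i] <= pos[i - 1]) {
      pos[i] <- pos[i - 1] + max(.Machine$double.eps * abs(pos[i - 1]),
                                 .Machine$double.xmin)
    }
  }
  pos
}

#' Write haplotype samples as ms-format text
#'
#' Emits the ms dialect parseable by [read_ms()] and by third-party ms
#' consumers. Positions are written as fractions of the region length with
#' 10 decimal digits.
#'
#' @param samples A list of [haplotype_sample] objects (or a single one).
#' @param con Optional file path or connection; if `NULL` the lines are
#'   returned as a character vector.
#' @param digits Decimal digits for fractional positions (at least 6).
#'
#' @return Invisibly (or visibly when `con` is `NULL`) the character vector
#'   of output lines.
#' @export
write_ms <- function(samples, con = NULL, digits = 10) {
  if (inherits(samples, "haplotype_sample")) samples <- list(samples)
  stopifnot(digits >= 6)
  n_hap <- if (length(samples)) nrow(samples[[1]]$matrix) else 0L
  out <- c(sprintf("ms %d %d", n_hap, length(samples)), "0 0 0", "")
  for (s in samples) {
    if (length(s$positions) &&
        any(s$positions < 0 | s$positions >= s$region_length)) {
      stop("positions outside [0, region_length)")
    }
    out <- c(out, "//", sprintf("segsites: %d", ncol(s$matrix)))
    if (ncol(s$matrix) > 0) {
      frac <- s$positions / s$region_length
      out <- c(out,
               paste("positions:",
                     paste(formatC(frac, digits = digits, format = "f"),
                           collapse = " ")),
               apply(s$matrix, 1, paste, collapse = ""))
    }
    out <- c(out, "")
  }
  if (is.null(con)) return(out)
  writeLines(out, con)
  invisible(out)
}
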