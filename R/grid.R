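#' Parameter rows of the single-site simulation grid
#'
#' The 11 two-deme and 8 three-deme parameter rows of the single-site
#' experiment: per-deme haploid sizes (10,000 unless varied) and selection
#' coefficients. Rows in which the allele is neutral in one deme are
#' flagged `asterisk`: for those, the lowest migration rate Nm = 0.02 is
#' excluded from execution because the waiting time to fixation in the
#' neutral deme becomes prohibitive.
#'
#' @param demes `"two"`, `"three"`, or `"both"`.
#' @return A data.frame with columns `row_id`, `demes`, `Ne0`, `Ne1`,
#'   `Ne2`, `s0`, `s1`, `s2`, `asterisk`.
#' @export
grid_rows <- function(demes = c("both", "two", "three")) {
  demes <- match.arg(demes)
  two <- data.frame(
    demes = "two", Ne0 = NA_integer_,
    Ne1 = c(rep(10000L, 7), 5000L, 1000L, 10000L, 10000L),
    Ne2 = c(rep(10000L, 9), 5000L, 1000L),
    s0 = NA_real_,
    s1 = c(0.005, 0.02, 0.05, 0.1, 0.02, 0.02, 0.05, 0.02, 0.02, 0.02, 0.02),
    s2 = c(0.005, 0.02, 0.05, 0.1, 0.05, 0,    0.02, 0.02, 0.02, 0.02, 0.02)
  )
  three <- data.frame(
    demes = "three", Ne0 = 10000L, Ne1 = 10000L, Ne2 = 10000L,
    s0 = c(0.005, 0.02, 0.05, 0.1, 0.02, 0.02,  0.02, 0.02),
    s1 = c(0.005, 0.02, 0.05, 0.1, 0,    0.005, 0.05, 0.05),
    s2 = c(0.005, 0.02, 0.05, 0.1, 0.02, 0.02,  0.02, 0.05)
  )
  out <- switch(demes, two = two, three = three, both = rbind(two, three))
  out$asterisk <- (!is.na(out$s0) & out$s0 == 0) | out$s1 == 0 | out$s2 == 0
  out$row_id <- seq_len(nrow(out))
  out[, c("row_id", "demes", "Ne0", "Ne1", "Ne2", "s0", "s1", "s2", "asterisk")]
}

#' Enumerate the single-site parameter grid
#'
#' Crosses parameter rows with migration rates (and, for three-deme rows,
#' migration topologies). The full default grid has 55 two-deme and 120
#' three-deme combinations; combinations pairing Nm = 0.02 with a
#' neutral-in-one-deme row are enumerated but flagged `excluded`.
#'
#' @param rows Output of [grid_rows()] (possibly subset).
#' @param rates Migration rates Nm.
#' @param layouts Three-deme topologies to cross with three-deme rows.
#' @return A data.frame, one row per (row, rate\[, layout\]) combination,
#'   with an `excluded` flag.
#' @export
grid_combinations <- function(rows = grid_rows(),
                              rates = c(0.02, 0.2, 2, 20, 200),
                              layouts = c("connected", "forked", "stepping")) {
  combos <- list()
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    lay <- if (r$demes == "two") "two" else layouts
    combos[[i]] <- data.frame(r, Nm = rep(rates, each = length(lay)),
                              layout = lay, row.names = NULL)
  }
  out <- do.call(rbind, combos)
  out$excluded <- out$asterisk & out$Nm == 0.02
  out
}

#' Run the single-site timing grid
#'
#' Executes every non-excluded combination of [grid_combinations()] with
#' [run_timing_batch()], emitting one row per conditioned replicate with
#' its timing summary and bookkeeping (combination id, Nm, layout,
#' replicate index, derived seed).
#'
#' @param rows Parameter rows, as from [grid_rows()].
#' @param rates Migration rates Nm.
#' @param layouts Three-deme topologies.
#' @param reps Conditioned replicates per combination.
#' @param seed Master seed; per-combination seeds are derived from it.
#' @param max_gen Per-attempt generation cap.
#' @return A data.frame of per-replicate timing rows.
#' @export
run_grid <- function(rows = grid_rows("two"), rates = c(0.02, 0.2, 2, 20, 200),
                     layouts = c("connected", "forked", "stepping"),
                     reps = 100, seed = 1, max_gen = 1e6) {
  stopifnot(reps >= 1)
  combos <- grid_combinations(rows, rates, layouts)
  run <- combos[!combos$excluded, , drop = FALSE]
  seeds <- derive_seeds(seed, nrow(run))
  out <- vector("list", nrow(run))
  for (i in seq_len(nrow(run))) {
    cb <- run[i, ]
    spec <- if (cb$layout == "two") {
      deme_spec(Ne = c(cb$Ne1, cb$Ne2), s = c(cb$s1, cb$s2), Nm = cb$Nm,
                topology = "two")
    } else {
      deme_spec(Ne = c(cb$Ne0, cb$Ne1, cb$Ne2), s = c(cb$s0, cb$s1, cb$s2),
                Nm = cb$Nm, topology = cb$layout)
    }
    tm <- run_timing_batch(spec, reps = reps, seed = seeds[i], max_gen = max_gen)
    # harmonise two- and three-deme columns so rows can be pooled
    for (nm in setdiff(timing_colnames(3), names(tm))) tm[[nm]] <- NA_real_
    tm <- tm[, c("rep", timing_colnames(3), "n_restarts", "truncated")]
    out[[i]] <- data.frame(row_id = cb$row_id, Nm = cb$Nm, layout = cb$layout,
                           seed = seeds[i], tm, row.names = NULL)
  }
  do.call(rbind, out)
}

#' Correlation of migration rate with a timing column
#'
#' Pearson correlation of log10(Nm) with a chosen timing column, pooled
#' over all replicate rows of a timing table (as produced by [run_grid()]
#' or assembled from [run_timing_batch()] outputs).
#'
#' @param table A data.frame containing `Nm` and the column `y`.
#' @param y Name of the timing column (e.g. `"t995_d2"`, `"phase_d2"`).
#' @return A list with `r`, `r2`, `p_value`, `n`, and `degenerate` (TRUE
#'   when `y` has zero variance, in which case r2 is reported as 0).
#' @export
trajectory_stats <- function(table, y) {
  stopifnot(y %in% names(table), "Nm" %in% names(table))
  keep <- stats::complete.cases(table[, c("Nm", y)])
  x <- log10(table$Nm[keep])
  yy <- table[[y]][keep]
  if (length(yy) < 3) stop("need at least 3 complete rows")
  if (stats::sd(yy) == 0 || stats::sd(x) == 0) {
    return(list(r = NA_real_, r2 = 0, p_value = NA_real_, n = length(yy),
                degenerate = TRUE))
  }
  ct <- stats::cor.test(x, yy)
  list(r = unname(ct$estimate), r2 = unname(ct$estimate)^2,
       p_value = ct$p.value, n = length(yy), degenerate = FALSE)
}

#' Closed-form timing under deterministic logistic growth
#'
#' The deterministic haploid selection recursion p' = p(1+s)/(1+ps)
#' corresponds to logistic growth of the odds ratio; the time to move from
#' frequency `p0` to `p1` is `(log(p1/(1-p1)) - log(p0/(1-p0))) / log(1+s)`,
#' approximately `(1/s) * (logit(p1) - logit(p0))` for small s. This gives
#' the classical expectation that the selection phase scales with
#' log(Ne)/s when `p0` is the single-copy frequency 1/Ne.
#'
#' @param s Selection coefficient.
#' @param p0,p1 Start and end allele frequencies in (0, 1).
#' @param exact If `TRUE` use the exact discrete-time rate `log(1+s)`;
#'   otherwise the continuous-time approximation `s`.
#' @return Time in generations.
#' @export
logistic_phase_time <- function(s, p0 = 0.05, p1 = 0.995, exact = FALSE) {
  rate <- if (exact) log(1 + s) else s
  (log(p1 / (1 - p1)) - log(p0 / (1 - p0))) / rate
}

#' Relative change of the selection-phase length with population size
#'
#' Under the log(Ne)/s scaling of the sweep duration, moving from
#' reference size `Ne_ref` to `Ne` changes the expected selection phase by
#' the factor `log(Ne)/log(Ne_ref)`. `phase_scaling_reduction()` returns
#' the fractional reduction `1 - log(Ne)/log(Ne_ref)` (25% for Ne = 1,000
#' vs 10,000; 7.5% for Ne = 5,000 vs 10,000). `phase_scaling_difference()`
#' returns the fractional excess `log(Ne_hi)/log(Ne_lo) - 1` of the larger
#' population's phase relative to the smaller one's, the form relevant in
#' the high-migration limit where the two demes merge into one panmictic
#' population whose size varies between Ne1 + Ne2 extremes (6.4% between
#' 11,000 and 20,000).
#'
#' @param Ne,Ne_ref,Ne_lo,Ne_hi Haploid population sizes.
#' @return A fraction (not a percentage).
#' @export
phase_scaling_reduction <- function(Ne, Ne_ref = 10000) {
  1 - log(Ne) / log(Ne_ref)
}

#' @rdname phase_scaling_reduction
#' @export
phase_scaling_difference <- function(Ne_lo, Ne_hi) {
  log(Ne_hi) / log(Ne_lo) - 1
}
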