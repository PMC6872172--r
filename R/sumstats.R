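# The 13 window/grid statistics of the sweep scan, plus per-site FST.
# SFS estimators are computed from derived-allele counts (ancestral state
# is known simulation truth); haplotype spectra and EHH integrals run in
# C++ kernels.

#' Site-frequency-spectrum estimators for one window
#'
#' Computes theta_pi (mean pairwise differences), Watterson's theta_w
#' (S / a_{n-1}), Fay and Wu's theta_h (sum of 2 i^2 S_i / (n(n-1)) over
#' derived counts i), Tajima's D and the unnormalised Fay and Wu's
#' H = theta_pi - theta_h. Columns monomorphic in the matrix are ignored.
#' With no segregating site the thetas are 0 and D and H are `NA`;
#' D additionally requires at least 3 segregating sites.
#'
#' @param m Binary haplotype matrix (rows = haplotypes) for the window.
#' @return Named numeric vector `theta_pi`, `theta_w`, `theta_h`,
#'   `tajima_d`, `faywu_h`.
#' @export
sfs_stats <- function(m) {
  n <- nrow(m)
  d <- colSums(m)
  d <- d[d > 0 & d < n]
  S <- length(d)
  if (S == 0) {
    return(c(theta_pi = 0, theta_w = 0, theta_h = 0,
             tajima_d = NA_real_, faywu_h = NA_real_))
  }
  a1 <- sum(1 / seq_len(n - 1))
  theta_pi <- sum(d * (n - d)) / choose(n, 2)
  theta_w <- S / a1
  theta_h <- sum(2 * d^2) / (n * (n - 1))
  tajima_d <- if (S >= 3) {
    a2 <- sum(1 / seq_len(n - 1)^2)
    b1 <- (n + 1) / (3 * (n - 1))
    b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1
    c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    e1 <- c1 / a1
    e2 <- c2 / (a1^2 + a2)
    (theta_pi - theta_w) / sqrt(e1 * S + e2 * S * (S - 1))
  } else NA_real_
  c(theta_pi = theta_pi, theta_w = theta_w, theta_h = theta_h,
    tajima_d = tajima_d, faywu_h = theta_pi - theta_h)
}

#' Haplotype-spectrum statistics for one window
#'
#' Distinct row patterns within the window define the haplotype spectrum
#' p1 >= p2 >= ...; returns the number of haplotypes n_H, H1 = sum p_i^2,
#' H12 = (p1 + p2)^2 + sum_{i>=3} p_i^2 and H2/H1 with H2 = H1 - p1^2.
#'
#' @param m Binary haplotype matrix for the window.
#' @return Named numeric vector `n_H`, `H1`, `H12`, `H2H1`.
#' @export
haplotype_stats <- function(m) {
  v <- .hap_spectrum(m, 0L, ncol(m))
  c(n_H = unname(v["n_H"]), H1 = unname(v["H1"]), H12 = unname(v["H12"]),
    H2H1 = unname(v["H2"]) / unname(v["H1"]))
}

#' Unstandardised iHS and nSL scores
#'
#' For every pivot SNP with derived sample frequency inside
#' `band`, extended haplotype homozygosity is computed outward from
#' the pivot separately for derived and ancestral carriers, integrated by
#' the trapezoid rule until EHH drops below `cutoff` or the data edge,
#' and the two sides summed into iHH. The score is
#' log(iHH_ancestral / iHH_derived): negative when derived haplotypes are
#' unusually long. iHS measures distance in bp, nSL in number of
#' segregating sites.
#'
#' @param sample A [haplotype_sample] (or a matrix with `positions`).
#' @param positions Needed when `sample` is a bare matrix.
#' @param band Derived-frequency eligibility range for pivots.
#' @param cutoff EHH truncation level.
#' @return data.frame `col`, `pos`, `derived_count`, `score` (score `NA`
#'   where an EHH integral is degenerate).
#' @export
ihs_scores <- function(sample, positions = NULL, band = c(0.06, 0.94),
                       cutoff = 0.05) {
  ehh_scores_internal(sample, positions, band, cutoff, use_bp = TRUE)
}

#' @rdname ihs_scores
#' @export
nsl_scores <- function(sample, positions = NULL, band = c(0.06, 0.94),
                       cutoff = 0.05) {
  ehh_scores_internal(sample, positions, band, cutoff, use_bp = FALSE)
}

ehh_scores_internal <- function(sample, positions, band, cutoff, use_bp) {
  if (inherits(sample, "haplotype_sample")) {
    m <- sample$matrix
    positions <- sample$positions
  } else m <- sample
  out <- .ehh_scores(m, as.numeric(positions), use_bp, band[1], band[2], cutoff)
  data.frame(col = as.integer(out[, "col"]),
             pos = positions[out[, "col"]],
             derived_count = as.integer(out[, "derived_count"]),
             score = out[, "score"])
}

#' Frequency-stratified normalisation of EHH scores
#'
#' `build_normalisation_table()` pools unstandardised scores from neutral
#' background samples and records mean and standard deviation per derived
#' sample count (i.e. per frequency value on the 1/n lattice inside the
#' eligibility band). `normalise_scores()` standardises scores against
#' the table; scores in bins absent from the table are dropped with a
#' warning.
#'
#' @param score_list List of score data.frames from [ihs_scores()] /
#'   [nsl_scores()] on neutral background samples.
#' @return A data.frame `derived_count`, `mean`, `sd`, `n`.
#' @export
build_normalisation_table <- function(score_list) {
  all <- do.call(rbind, score_list)
  all <- all[!is.na(all$score), , drop = FALSE]
  tab <- do.call(rbind, lapply(split(all$score, all$derived_count), function(x) {
    data.frame(mean = mean(x), sd = stats::sd(x), n = length(x))
  }))
  tab$derived_count <- as.integer(rownames(tab))
  if (any(!is.finite(tab$sd) | tab$sd == 0)) {
    stop("degenerate normalisation bin (zero or undefined SD)")
  }
  rownames(tab) <- NULL
  tab[, c("derived_count", "mean", "sd", "n")]
}

#' @rdname build_normalisation_table
#' @param scores A score data.frame to standardise.
#' @param table Output of `build_normalisation_table()`.
#' @return `scores` with a `z` column, rows without a matching bin removed.
#' @export
normalise_scores <- function(scores, table) {
  i <- match(scores$derived_count, table$derived_count)
  drop <- is.na(i) & !is.na(scores$score)
  if (any(drop)) {
    warning(sprintf("%d score(s) dropped: no normalisation bin", sum(drop)))
  }
  scores$z <- (scores$score - table$mean[i]) / table$sd[i]
  scores[!is.na(i) | is.na(scores$score), , drop = FALSE]
}

#' Per-window proportion of significant EHH scores
#'
#' The window statistic for iHS and nSL: the fraction of scored SNPs in a
#' window whose normalised score exceeds 2 in absolute value. Windows
#' containing no scored SNP are `NA`.
#'
#' @param scores Normalised score data.frame (with `pos` and `z`).
#' @param grid A [make_windows()] grid.
#' @return Numeric vector, one proportion per window.
#' @export
window_significance <- function(scores, grid) {
  scores <- scores[!is.na(scores$z), , drop = FALSE]
  apply(grid$windows, 1, function(w) {
    z <- scores$z[scores$pos >= w[1] & scores$pos < w[2]]
    if (!length(z)) NA_real_ else mean(abs(z) > 2)
  })
}

#' Simplified SweepFinder-style composite likelihood ratio scan
#'
#' A grid-based composite likelihood contrast between the sample's own
#' site frequency spectrum (the background) and a sweep-distorted
#' spectrum. For a putative sweep at grid point g with intensity alpha, a
#' SNP at distance d escapes the sweep with probability
#' 1 - exp(-alpha d); escaped SNPs draw their derived count from the
#' background SFS, swept SNPs from a spectrum with all mass on counts 1
#' and n-1 (equal shares). CLR(g) = 2 (max_alpha log CL - log CL at the
#' alpha -> infinity background limit). This is a deliberately simplified
#' re-implementation: its contract is neutral calibration and directional
#' behaviour, not parity with released SweepFinder2.
#'
#' @param sample A [haplotype_sample] (single population; deme labels are
#'   ignored).
#' @param grid_step Grid spacing in bp.
#' @param alpha Grid of sweep intensities (per bp).
#' @return data.frame `pos`, `clr` (`NA` with fewer than 2 SNPs).
#' @export
sf2_clr <- function(sample, grid_step = 10000,
                    alpha = 10^seq(-7, -2.5, length.out = 19)) {
  m <- sample$matrix
  n <- nrow(m)
  d <- colSums(m)
  keep <- d > 0 & d < n
  d <- d[keep]
  pos <- sample$positions[keep]
  gpos <- seq(0, sample$region_length, by = grid_step)
  if (length(d) < 2) {
    return(data.frame(pos = gpos, clr = NA_real_))
  }
  sfs <- tabulate(d, nbins = n - 1) / length(d)
  bg <- log(sfs[d])                      # background log-density per SNP
  swept <- ifelse(d == 1 | d == n - 1, 0.5, 0)
  clr <- vapply(gpos, function(g) {
    dist <- abs(pos - g)
    ll <- vapply(alpha, function(a) {
      pe <- 1 - exp(-a * dist)
      sum(log(pmax(pe * sfs[d] + (1 - pe) * swept, 1e-300)))
    }, 0)
    2 * (max(ll) - sum(bg))
  }, 0)
  data.frame(pos = gpos, clr = pmax(clr, 0))
}

#' Simplified cross-population composite likelihood scan
#'
#' Contrasts focal-deme allele frequencies against the control deme:
#' under drift the focal frequency is modelled as Gaussian around the
#' control frequency with variance omega * p(1-p) (omega estimated from
#' all shared SNPs); a sweep at grid point g inflates the variance of
#' nearby SNPs by a factor 1 + s exp(-d / decay). The score is
#' 2 (max_s log CL - log CL at s = 0), zero when s = 0 maximises.
#' Simplified re-implementation; calibration and direction are the
#' contract, not parity with released XP-CLR.
#'
#' @param sample A two-deme [haplotype_sample].
#' @param focal Focal deme label (control is the other deme).
#' @param grid_step Grid spacing in bp.
#' @param s_grid Grid of variance-inflation intensities (0 included).
#' @param decay Distance scale of the inflation, bp.
#' @return data.frame `pos`, `xpclr`.
#' @export
xpclr <- function(sample, focal = 1, grid_step = 10000,
                  s_grid = c(0, 10^seq(-1, 2, length.out = 13)),
                  decay = 50000) {
  labs <- sample$deme_labels
  demes <- sort(unique(labs[labs > 0]))
  if (length(demes) != 2) stop("xpclr needs a two-deme sample")
  control <- setdiff(demes, focal)
  m1 <- sample$matrix[labs == focal, , drop = FALSE]
  m2 <- sample$matrix[labs == control, , drop = FALSE]
  p1 <- colMeans(m1)
  p2 <- colMeans(m2)
  keep <- (p1 > 0 | p2 > 0) & (p1 < 1 | p2 < 1)
  gpos <- seq(0, sample$region_length, by = grid_step)
  if (!any(keep)) return(data.frame(pos = gpos, xpclr = NA_real_))
  p1 <- p1[keep]; p2 <- p2[keep]
  pos <- sample$positions[keep]
  n2 <- nrow(m2)
  pb <- pmin(pmax((p1 + p2) / 2, 1 / (2 * n2)), 1 - 1 / (2 * n2))
  base_var <- pb * (1 - pb)
  omega <- max(mean((p1 - p2)^2 / base_var), 1e-4)
  ll0 <- sum(stats::dnorm(p1, p2, sqrt(omega * base_var), log = TRUE))
  score <- vapply(gpos, function(g) {
    infl <- exp(-abs(pos - g) / decay)
    ll <- vapply(s_grid, function(s) {
      v <- omega * base_var * (1 + s * infl)
      sum(stats::dnorm(p1, p2, sqrt(v), log = TRUE))
    }, 0)
    2 * (max(ll) - ll0)
  }, 0)
  data.frame(pos = gpos, xpclr = score)
}

#' Mean per-site Hudson FST between the two demes
#'
#' Plug-in per-site FST = 1 - Hw/Hb with Hw = p1 q1 + p2 q2 and
#' Hb = p1 q2 + p2 q1, averaged over sites polymorphic in the pooled
#' sample within `span` (default the first 200 kb, centred on the
#' selected locus).
#'
#' @param sample A two-deme [haplotype_sample].
#' @param span bp interval `c(from, to)`.
#' @return Mean FST (`NA` when no usable site).
#' @export
fst_stats <- function(sample, span = c(0, 200000)) {
  labs <- sample$deme_labels
  demes <- sort(unique(labs[labs > 0]))
  if (length(demes) != 2) stop("fst_stats needs a two-deme sample")
  inw <- sample$positions >= span[1] & sample$positions < span[2]
  m1 <- sample$matrix[labs == demes[1], inw, drop = FALSE]
  m2 <- sample$matrix[labs == demes[2], inw, drop = FALSE]
  p1 <- colMeans(m1)
  p2 <- colMeans(m2)
  pooled <- (p1 + p2) / 2
  keep <- pooled > 0 & pooled < 1
  if (!any(keep)) return(NA_real_)
  p1 <- p1[keep]; p2 <- p2[keep]
  hw <- p1 * (1 - p1) + p2 * (1 - p2)
  hb <- p1 * (1 - p2) + p2 * (1 - p1)
  ok <- hb > 0
  if (!any(ok)) return(NA_real_)
  mean(1 - hw[ok] / hb[ok])
}

# Vectorised per-window SFS tracks via cumulative sums over the
# position-sorted columns; identical to sfs_stats() per window.
window_sfs_tracks <- function(m, lo, hi, nw) {
  n <- nrow(m)
  d <- colSums(m)
  poly <- d > 0 & d < n
  cs <- function(x) cumsum(c(0, x))
  c_pi <- cs(d * (n - d))
  c_S <- cs(as.numeric(poly))
  c_h <- cs(ifelse(poly, 2 * d^2, 0))
  wsum <- function(cv) cv[hi + 1L] - cv[lo]
  S <- wsum(c_S)
  theta_pi <- wsum(c_pi) / choose(n, 2)
  theta_w <- S / sum(1 / seq_len(n - 1))
  theta_h <- wsum(c_h) / (n * (n - 1))
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  tajima_d <- ifelse(S >= 3, (theta_pi - theta_w) /
                       sqrt(e1 * S + e2 * S * (S - 1)), NA_real_)
  faywu_h <- ifelse(S >= 1, theta_pi - theta_h, NA_real_)
  cbind(theta_pi = theta_pi, theta_w = theta_w, theta_h = theta_h,
        tajima_d = tajima_d, faywu_h = faywu_h)
}

# ---- scan driver -----------------------------------------------------------

#' Direction of each statistic under a sweep
#'
#' Which tail of each statistic indicates a sweep: `"high"` for theta_h,
#' H1, H12, XPCLR, SF2-CLR and the significance proportions of iHS and
#' nSL; `"low"` for the others.
#'
#' @return Named character vector over all 13 statistics.
#' @export
stat_directions <- function() {
  c(theta_pi = "low", theta_w = "low", theta_h = "high", tajima_d = "low",
    faywu_h = "low", n_H = "low", H1 = "high", H12 = "high", H2H1 = "low",
    ihs_prop = "high", nsl_prop = "high", clr = "high", xpclr = "high")
}

#' In-house window statistics used as classifier features
#' @return Character vector of the 11 window statistics.
#' @export
window_stat_names <- function() {
  c("theta_pi", "theta_w", "theta_h", "tajima_d", "faywu_h",
    "n_H", "H1", "H12", "H2H1", "ihs_prop", "nsl_prop")
}

#' Score one sample on all requested statistics
#'
#' Computes the per-window (or per-grid-point) tracks of the scan
#' statistics for one sample. Window statistics use the sliding grid; iHS
#' and nSL scores are standardised against the supplied neutral
#' normalisation tables before the per-window significance proportion is
#' taken; CLR and XPCLR are computed on their bp grid. For labelled
#' two-deme samples, window statistics are computed on the haplotypes of
#' `deme` (pass `deme = NULL` to use all haplotypes, e.g. for mixed
#' samples).
#'
#' @param sample A [haplotype_sample].
#' @param stats Statistics to compute (default: the 11 window statistics).
#' @param grid A [make_windows()] grid (default 100 kb / 10 kb over the
#'   sample's region).
#' @param norm_ihs,norm_nsl Normalisation tables (required for
#'   `ihs_prop` / `nsl_prop`).
#' @param deme Deme label to score (default: all haplotypes).
#' @param focal Focal deme for `xpclr`.
#' @return data.frame `stat`, `window` (1-based index; grid index for
#'   bp-grid statistics), `pos` (window start or grid point), `value`.
#' @export
score_sample <- function(sample, stats = window_stat_names(), grid = NULL,
                         norm_ihs = NULL, norm_nsl = NULL, deme = NULL,
                         focal = 1) {
  if (is.null(grid)) grid <- make_windows(sample$region_length, 100000, 10000)
  sub <- if (!is.null(deme)) subset_sample(sample, deme = deme) else sample
  m <- sub$matrix
  pos <- sub$positions
  out <- list()
  wstats <- intersect(stats, c("theta_pi", "theta_w", "theta_h", "tajima_d",
                               "faywu_h", "n_H", "H1", "H12", "H2H1"))
  if (length(wstats)) {
    nw <- nrow(grid$windows)
    # column index range [lo, hi] per window from the sorted positions
    lo <- findInterval(grid$windows[, 1] - 1e-9, pos) + 1L
    hi <- findInterval(grid$windows[, 2] - 1e-9, pos)
    vals <- window_sfs_tracks(m, lo, hi, nw)
    if (any(wstats %in% c("n_H", "H1", "H12", "H2H1"))) {
      hp <- .hap_spectrum_windows(m, lo - 1L, pmax(hi, lo - 1L))
      vals <- cbind(vals, n_H = hp[, "n_H"], H1 = hp[, "H1"],
                    H12 = hp[, "H12"],
                    H2H1 = hp[, "H2"] / hp[, "H1"])
    }
    for (s in wstats) {
      out[[s]] <- data.frame(stat = s, window = seq_len(nw),
                             pos = grid$windows[, 1], value = vals[, s])
    }
  }
  if ("ihs_prop" %in% stats) {
    if (is.null(norm_ihs)) stop("ihs_prop requires a normalisation table")
    z <- normalise_scores(ihs_scores(sub), norm_ihs)
    out$ihs_prop <- data.frame(stat = "ihs_prop",
                               window = seq_len(nrow(grid$windows)),
                               pos = grid$windows[, 1],
                               value = window_significance(z, grid))
  }
  if ("nsl_prop" %in% stats) {
    if (is.null(norm_nsl)) stop("nsl_prop requires a normalisation table")
    z <- normalise_scores(nsl_scores(sub), norm_nsl)
    out$nsl_prop <- data.frame(stat = "nsl_prop",
                               window = seq_len(nrow(grid$windows)),
                               pos = grid$windows[, 1],
                               value = window_significance(z, grid))
  }
  if ("clr" %in% stats) {
    cl <- sf2_clr(sub)
    out$clr <- data.frame(stat = "clr", window = seq_along(cl$pos),
                          pos = cl$pos, value = cl$clr)
  }
  if ("xpclr" %in% stats) {
    xp <- xpclr(sample, focal = focal)
    out$xpclr <- data.frame(stat = "xpclr", window = seq_along(xp$pos),
                            pos = xp$pos, value = xp$xpclr)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Score a set of samples into per-statistic matrices
#'
#' Applies [score_sample()] to a list of samples and reshapes the result
#' into one samples x windows matrix per statistic, each carrying its
#' window/grid `pos` as an attribute. This is the score-track container
#' consumed by threshold calibration, power tables and the classifier.
#'
#' @inheritParams score_sample
#' @param samples List of [haplotype_sample] objects.
#' @return Named list of matrices with attributes `pos` and `direction`.
#' @export
score_set <- function(samples, stats = window_stat_names(), grid = NULL,
                      norm_ihs = NULL, norm_nsl = NULL, deme = NULL,
                      focal = 1) {
  tracks <- lapply(samples, score_sample, stats = stats, grid = grid,
                   norm_ihs = norm_ihs, norm_nsl = norm_nsl, deme = deme,
                   focal = focal)
  dirs <- stat_directions()
  out <- list()
  for (s in unique(tracks[[1]]$stat)) {
    rows <- lapply(tracks, function(t) t$value[t$stat == s])
    mat <- do.call(rbind, rows)
    attr(mat, "pos") <- tracks[[1]]$pos[tracks[[1]]$stat == s]
    attr(mat, "direction") <- unname(dirs[s])
    out[[s]] <- mat
  }
  out
}
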