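# Brute-force oracles for the scan statistics, kept deliberately naive and
# independent of the package implementation.

brute_theta_pi <- function(m) {
  n <- nrow(m)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(m[i, ] != m[j, ])
  }
  tot / choose(n, 2)
}
brute_theta_w <- function(m) {
  n <- nrow(m)
  d <- colSums(m)
  sum(d > 0 & d < n) / sum(1 / seq_len(n - 1))
}
brute_theta_h <- function(m) {
  n <- nrow(m)
  d <- colSums(m)
  d <- d[d > 0 & d < n]
  sum(2 * d^2) / (n * (n - 1))
}
brute_hap <- function(m) {
  p <- sort(table(apply(m, 1, paste, collapse = "")) / nrow(m),
            decreasing = TRUE)
  p <- as.numeric(p)
  H1 <- sum(p^2)
  list(n_H = length(p), H1 = H1,
       H12 = if (length(p) >= 2) (p[1] + p[2])^2 + sum(p[-(1:2)]^2) else H1,
       H2H1 = (H1 - p[1]^2) / H1)
}
brute_fst <- function(p1, p2) {
  hw <- p1 * (1 - p1) + p2 * (1 - p2)
  hb <- p1 * (1 - p2) + p2 * (1 - p1)
  mean(1 - hw[hb > 0] / hb[hb > 0])
}

test_that("SFS estimators reproduce the worked four-haplotype example", {
  m <- rbind(c(0, 0, 1), c(0, 1, 1), c(1, 0, 0), c(0, 0, 0))
  v <- sfs_stats(m)
  expect_equal(unname(v["theta_pi"]), 10 / 6, tolerance = 1e-12)
  expect_equal(unname(v["theta_w"]), 3 / (1 + 1 / 2 + 1 / 3), tolerance = 1e-12)
  expect_equal(unname(v["theta_h"]), 1.0, tolerance = 1e-12)
  expect_equal(unname(v["faywu_h"]), 10 / 6 - 1, tolerance = 1e-12)
  # monomorphic window: thetas zero, D and H missing, no error
  v0 <- sfs_stats(matrix(0L, 4, 0))
  expect_equal(unname(v0["theta_pi"]), 0)
  expect_true(is.na(v0["tajima_d"]) && is.na(v0["faywu_h"]))
  # n = 2 with one difference: theta_pi = theta_w = 1 (a_1 = 1)
  v2 <- sfs_stats(rbind(1, 0))
  expect_equal(unname(v2["theta_pi"]), 1)
  expect_equal(unname(v2["theta_w"]), 1)
})

test_that("SFS and haplotype statistics match brute force on random matrices", {
  set.seed(7)
  for (k in 1:200) {
    n <- sample(2:8, 1); S <- sample(1:8, 1)
    m <- matrix(rbinom(n * S, 1, runif(1, 0.2, 0.8)), n, S)
    d <- colSums(m)
    if (!any(d > 0 & d < n)) next  # no segregating site: policy case above
    v <- sfs_stats(m)
    expect_equal(unname(v["theta_pi"]), brute_theta_pi(m), tolerance = 1e-10)
    expect_equal(unname(v["theta_w"]), brute_theta_w(m), tolerance = 1e-10)
    expect_equal(unname(v["theta_h"]), brute_theta_h(m), tolerance = 1e-10)
    expect_equal(unname(v["faywu_h"]),
                 brute_theta_pi(m) - brute_theta_h(m), tolerance = 1e-10)
    h <- haplotype_stats(m)
    b <- brute_hap(m)
    expect_equal(unname(h["n_H"]), b$n_H)
    expect_equal(unname(h["H1"]), b$H1, tolerance = 1e-10)
    expect_equal(unname(h["H12"]), b$H12, tolerance = 1e-10)
    expect_equal(unname(h["H2H1"]), b$H2H1, tolerance = 1e-10)
  }
})

test_that("Tajima's D matches a literal transcription of its definition", {
  # independent implementation straight from the 1989 normalisation
  tajima_oracle <- function(m) {
    n <- nrow(m); d <- colSums(m); S <- sum(d > 0 & d < n)
    a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
    b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n * n + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    (brute_theta_pi(m) - S / a1) /
      sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
  }
  set.seed(8)
  for (k in 1:50) {
    n <- sample(4:8, 1); S <- sample(3:8, 1)
    m <- matrix(rbinom(n * S, 1, 0.5), n, S)
    d <- colSums(m)
    if (sum(d > 0 & d < n) < 3) next
    expect_equal(unname(sfs_stats(m)["tajima_d"]), tajima_oracle(m),
                 tolerance = 1e-10)
  }
  # fewer than 3 segregating sites: D missing by policy
  expect_true(is.na(sfs_stats(rbind(c(0, 1), c(1, 0), c(0, 0)))["tajima_d"]))
})

test_that("haplotype spectrum handles degenerate and textbook cases", {
  m <- diag(4)  # 4 distinct haplotypes
  h <- haplotype_stats(m)
  expect_equal(unname(h["n_H"]), 4)
  expect_equal(unname(h["H1"]), 0.25)
  expect_equal(unname(h["H12"]), 0.375)
  expect_equal(unname(h["H2H1"]), 0.75)
  h1 <- haplotype_stats(matrix(1, 5, 3))  # all identical
  expect_equal(unname(h1["n_H"]), 1)
  expect_equal(unname(h1["H1"]), 1)
  expect_equal(unname(h1["H12"]), 1)
  expect_equal(unname(h1["H2H1"]), 0)
  # frequencies (0.5, 0.3, 0.2)
  m3 <- matrix(0L, 10, 2)
  m3[6:8, 1] <- 1L; m3[9:10, 2] <- 1L
  h3 <- haplotype_stats(m3)
  expect_equal(unname(h3["H1"]), 0.38, tolerance = 1e-12)
  expect_equal(unname(h3["H12"]), 0.68, tolerance = 1e-12)
  expect_equal(unname(h3["H2H1"]), (0.38 - 0.25) / 0.38, tolerance = 1e-12)
})

test_that("haplotype-statistic inequalities hold on random windows", {
  set.seed(9)
  for (k in 1:100) {
    n <- sample(2:10, 1); S <- sample(1:10, 1)
    m <- matrix(rbinom(n * S, 1, 0.5), n, S)
    h <- haplotype_stats(m)
    expect_true(h["H1"] <= h["H12"])
    expect_true(h["H2H1"] >= 0 && h["H2H1"] <= 1)
    expect_true(h["H1"] >= 1 / n && h["H1"] <= 1)
    expect_true(h["n_H"] <= min(n, 2^S))
  }
})

test_that("statistics are invariant to row and column order", {
  set.seed(10)
  m <- matrix(rbinom(80, 1, 0.4), 8, 10)
  pos <- sort(runif(10, 0, 1000))
  sfs1 <- sfs_stats(m)
  hap1 <- haplotype_stats(m)
  ro <- sample(8); co <- sample(10)
  expect_equal(sfs_stats(m[ro, ]), sfs1)
  expect_equal(haplotype_stats(m[ro, ]), hap1)
  expect_equal(sfs_stats(m[, co]), sfs1)
  # iHS per-SNP scores are row-order invariant
  s1 <- ihs_scores(m, positions = pos)
  s2 <- ihs_scores(m[ro, ], positions = pos)
  expect_equal(s1$score, s2$score)
})

test_that("EHH scores behave per construction on hand-built haplotypes", {
  # identical decay on both alleles: score 0
  m <- rbind(c(1, 0, 0), c(1, 0, 1), c(0, 1, 0), c(0, 1, 1))
  pos <- c(0, 500, 1000)
  s <- ihs_scores(m, positions = pos, band = c(0.3, 0.7))
  pivot2 <- s[s$col == 2, ]
  expect_equal(pivot2$score, 0)

  # derived carriers identical across the region, ancestral pair split at
  # the adjacent SNP: negative score with hand-enumerated areas
  m2 <- rbind(c(1, 0, 0, 0),
              c(1, 0, 0, 0),
              c(0, 1, 0, 1),
              c(0, 0, 1, 1))
  pos2 <- c(0, 400, 800, 1200)
  sc <- ihs_scores(m2, positions = pos2, band = c(0.4, 0.6))
  v <- sc$score[sc$col == 1]
  # derived pair stays identical: EHH = 1 over 1200 bp -> iHH_D = 1200
  # ancestral pair splits at the first step (EHH 1 -> 0): iHH_A = 200
  expect_equal(v, log(200 / 1200), tolerance = 1e-10)

  # frequency band excludes rare pivots
  m3 <- rbind(c(1, 0), c(0, 1), c(0, 0), c(0, 0))
  expect_equal(nrow(ihs_scores(m3, positions = c(0, 10), band = c(0.3, 0.7))), 0)
})

test_that("nSL ranks pivots like iHS when SNPs are equally spaced", {
  set.seed(12)
  m <- matrix(rbinom(20 * 40, 1, 0.5), 20, 40)
  pos <- seq(0, 39) * 100
  ih <- ihs_scores(m, positions = pos)
  ns <- nsl_scores(m, positions = pos)
  ok <- !is.na(ih$score) & !is.na(ns$score)
  expect_gt(sum(ok), 10)
  expect_equal(rank(ih$score[ok]), rank(ns$score[ok]))
})

test_that("normalisation gives per-bin mean 0 and SD 1 on its own data", {
  set.seed(13)
  fake <- lapply(1:30, function(i) {
    k <- sample(5:15, 1)
    data.frame(col = seq_len(k), pos = seq_len(k) * 100,
               derived_count = sample(3:10, k, replace = TRUE),
               score = rnorm(k))
  })
  tab <- build_normalisation_table(fake)
  z <- do.call(rbind, lapply(fake, normalise_scores, table = tab))
  for (dc in unique(z$derived_count)) {
    zz <- z$z[z$derived_count == dc]
    if (length(zz) < 2) next
    expect_equal(mean(zz), 0, tolerance = 1e-10)
    expect_equal(sd(zz), 1, tolerance = 1e-10)
  }
  # constant scores in a bin are refused at table build
  bad <- list(data.frame(col = 1:3, pos = 1:3, derived_count = c(5, 5, 5),
                         score = c(1, 1, 1)))
  expect_error(build_normalisation_table(bad), "degenerate")
})

test_that("window significance counts |z| > 2 fractions per window", {
  grid <- make_windows(400, 100, 100)
  sc <- data.frame(pos = c(10, 50, 90, 150, 250),
                   z = c(2.5, -1.0, 0.3, -2.2, 1.0))
  ws <- window_significance(sc, grid)
  expect_equal(ws[1], 1 / 3)
  expect_equal(ws[2], 1)
  expect_equal(ws[3], 0)
  expect_true(is.na(ws[4]))
  sc$z <- c(0.5, -1, 0.3, -1.5, 1)
  expect_equal(window_significance(sc, grid)[1:3], c(0, 0, 0))
})

test_that("simplified CLR is zero in the all-escape limit and peaks at sweeps", {
  set.seed(14)
  m <- matrix(rbinom(20 * 60, 1, 0.3), 20, 60)
  smp <- haplotype_sample(m, sort(runif(60, 0, 6e5)), 6e5)
  # alpha -> infinity only: everything escapes, model collapses to background
  out_inf <- sf2_clr(smp, alpha = 1e6)
  expect_true(all(abs(out_inf$clr) < 1e-8))
  # near-centre high-frequency-derived sites: CLR larger at centre than edge
  n <- 20
  d <- c(rep(n - 1, 15), sample(1:5, 45, replace = TRUE))
  m2 <- matrix(0L, n, 60)
  for (j in 1:60) m2[sample(n, d[j]), j] <- 1L
  pos2 <- c(sort(runif(15, 2.9e5, 3.1e5)), sort(runif(45, 0, 6e5)))
  o <- order(pos2)
  smp2 <- haplotype_sample(m2[, o], pos2[o], 6e5)
  out <- sf2_clr(smp2)
  centre <- out$clr[which.min(abs(out$pos - 3e5))]
  expect_gt(centre, out$clr[1])
  expect_gt(centre, out$clr[nrow(out)])
  # fewer than 2 SNPs: missing
  tiny <- haplotype_sample(matrix(c(1, 0), 2, 1), 100, 6e5)
  expect_true(all(is.na(sf2_clr(tiny)$clr)))
})

test_that("simplified XP-CLR is exactly zero under forced null and near zero for identical demes", {
  set.seed(15)
  m <- matrix(rbinom(40 * 30, 1, 0.4), 40, 30)
  smp <- haplotype_sample(rbind(m[1:20, ], m[1:20, ]), sort(runif(30, 0, 6e5)),
                          6e5, deme_labels = rep(1:2, each = 20))
  out0 <- xpclr(smp, s_grid = 0)  # s = 0 forced
  expect_true(all(out0$xpclr == 0))
  out_id <- xpclr(smp)  # identical frequencies: null attains the maximum
  expect_true(all(out_id$xpclr < 1e-6))
})

test_that("Hudson FST matches direct evaluation and its fixed points", {
  n <- 10
  mk <- function(p1, p2) {
    m <- rbind(matrix(as.integer(seq_len(n) <= round(p1 * n)), n, 1),
               matrix(as.integer(seq_len(n) <= round(p2 * n)), n, 1))
    haplotype_sample(m, 100, 6e5, deme_labels = rep(1:2, each = n))
  }
  expect_equal(fst_stats(mk(1, 0)), 1)
  expect_equal(fst_stats(mk(0.5, 0.5)), 0)
  expect_equal(fst_stats(mk(0.8, 0.2)), 1 - 0.32 / 0.68, tolerance = 1e-10)
  set.seed(16)
  for (k in 1:50) {
    p1 <- runif(8); p2 <- runif(8)
    m1 <- sapply(p1, function(p) rbinom(12, 1, p))
    m2 <- sapply(p2, function(p) rbinom(12, 1, p))
    smp <- haplotype_sample(rbind(m1, m2), sort(runif(8, 0, 2e5)), 6e5,
                            deme_labels = rep(1:2, each = 12))
    f1 <- colMeans(m1); f2 <- colMeans(m2)
    keep <- (f1 + f2) / 2 > 0 & (f1 + f2) / 2 < 1
    if (!any(keep)) next
    expect_equal(fst_stats(smp), brute_fst(f1[keep], f2[keep]),
                 tolerance = 1e-10)
  }
})
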