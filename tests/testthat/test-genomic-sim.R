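# Engine-level oracles for the forward infinite-sites simulator. Small
# populations keep these fast; the statistical checks compare against
# closed-form Wright-Fisher moments and the coalescent backend.

tiny_config <- function(Ne = 200, mu = 0.05, cc = 0.05, s = 0.3,
                        n_demes = 1, Nm = NA, kind = "global") {
  cfg <- scenario_table("m0G")
  cfg$Ne <- rep(as.integer(Ne), n_demes)
  cfg$n_demes <- as.integer(n_demes)
  cfg$mu <- mu; cfg$cc <- cc
  cfg$s <- rep(s, n_demes)
  if (kind == "local" && n_demes == 2) cfg$s <- c(s, 0)
  cfg$Nm <- Nm
  cfg$m <- if (n_demes == 2) Nm / Ne else 0
  cfg
}

test_that("zero mutation rate burn-in yields zero segregating sites", {
  cfg <- tiny_config(Ne = 50, mu = 0, cc = 0.05)
  st <- init_neutral_population(cfg, backend = "burnin", seed = 1,
                                burnin_gens = 50)
  expect_equal(length(st$positions), 0)
  expect_equal(length(st$chroms), 50)
})

test_that("coalescent backend matches the Watterson prediction for S", {
  skip_if(Sys.which("python") == "", "no python for the coalescent backend")
  nb <- neutral_background("m0NB", n_regions = 40, sample_size = 50, seed = 21)
  S <- vapply(nb, function(s) ncol(s$matrix), 0)
  expect_equal(mean(S), 240 * sum(1 / (1:49)), tolerance = 0.12)
})

test_that("burn-in and coalescent backends agree on mean pairwise diversity", {
  skip_if(Sys.which("python") == "", "no python for the coalescent backend")
  cfg <- tiny_config(Ne = 100, mu = 0.5, cc = 0.5, s = 0)
  pis_b <- vapply(1:80, function(i) {
    st <- init_neutral_population(cfg, backend = "burnin", seed = 3000 + i,
                                  burnin_gens = 1000)
    smp <- draw_samples(st, n_samples = 1, per_deme = 40, seed = i)[[1]]
    unname(sfs_stats(smp$matrix)["theta_pi"])
  }, 0)
  pis_c <- vapply(1:80, function(i) {
    st <- init_neutral_population(cfg, backend = "coalescent", seed = 4000 + i)
    smp <- draw_samples(st, n_samples = 1, per_deme = 40, seed = i)[[1]]
    unname(sfs_stats(smp$matrix)["theta_pi"])
  }, 0)
  expect_equal(mean(pis_b), mean(pis_c), tolerance = 0.05)
})

test_that("one neutral generation has binomial Wright-Fisher drift moments", {
  # a single segregating site at p = 0.3, no mutation/recombination/selection
  N <- 100
  carriers <- lapply(seq_len(N), function(i) if (i <= 30) 0L else integer(0))
  dp <- vapply(1:2000, function(i) {
    set.seed(5000 + i)
    snap <- subsweep:::.fw_step_once(carriers, 50000, N, s = 0, m = 0,
                                     mu = 0, cc = 0, L = 6e5, sel_site = 0L)
    sum(lengths(snap$chroms)) / N - 0.3
  }, 0)
  expect_lt(abs(mean(dp)), 4 * sqrt(0.3 * 0.7 / N / 2000))
  expect_equal(var(dp), 0.3 * 0.7 / N, tolerance = 0.1)
})

test_that("one selected generation matches the co-dominant deterministic update", {
  N <- 200; s <- 0.3; p <- 0.3
  carriers <- lapply(seq_len(N), function(i) if (i <= N * p) 0L else integer(0))
  dp <- vapply(1:2000, function(i) {
    set.seed(6000 + i)
    snap <- subsweep:::.fw_step_once(carriers, 100000, N, s = s, m = 0,
                                     mu = 0, cc = 0, L = 6e5, sel_site = 1L)
    sum(lengths(snap$chroms)) / N
  }, 0)
  p_det <- p * (1 + s) / (1 + p * s)
  expect_equal(mean(dp), p_det, tolerance = 4 * sqrt(p_det * (1 - p_det) / N / 2000) / p_det)
})

test_that("balanced migration moves Nm chromosomes per direction on average", {
  # a site fixed in d1 and absent in d2; expected derived count arriving in
  # d2 after one generation = N * m
  N <- 100; m <- 0.5
  carriers <- c(lapply(1:N, function(i) 0L),
                lapply(1:N, function(i) integer(0)))
  moved <- vapply(1:500, function(i) {
    set.seed(7000 + i)
    snap <- subsweep:::.fw_step_once(carriers, 50000, c(N, N), s = c(0, 0),
                                     m = m, mu = 0, cc = 0, L = 6e5,
                                     sel_site = 0L)
    sum(lengths(snap$chroms[snap$deme == 2]))
  }, 0)
  expect_equal(mean(moved), N * m, tolerance = 0.1)
})

test_that("panmictic runs take 11 in-run snapshots and record stages in order", {
  cfg <- tiny_config(Ne = 200, s = 0.3)
  sr <- run_scenario(cfg, seed = 11, sweep = "hard", backend = "burnin")
  expect_length(sr$snapshots, 11)
  stages <- vapply(sr$snapshots, function(s) s$stage, "")
  expect_equal(stages, c("f20s", "f40s", "f60s", "f80s", "f99.5s", "f100s",
                         paste0("t", 1:5, "Kr")))
  expect_equal(sr$initial$stage, "neutral")
  # global fixation snapshot: selected column at frequency 1 in samples
  smp <- draw_samples(find_snapshot(sr, "f100s"), n_samples = 3,
                      per_deme = 50, seed = 2)
  for (s in smp) {
    sel_col <- which(s$positions == s$selected_pos)
    expect_length(sel_col, 1)
    expect_equal(sum(s$matrix[, sel_col]), 50)
  }
})

test_that("two-deme runs take 21 in-run snapshots (22 time points with neutral)", {
  cfg <- tiny_config(Ne = 150, s = 0.3, n_demes = 2, Nm = 20)
  sr <- run_scenario(cfg, seed = 13, sweep = "hard", backend = "burnin")
  expect_length(sr$snapshots, 21)
  stages <- vapply(sr$snapshots, function(s) s$stage, "")
  expect_equal(sum(stages == "f100s"), 1)
  expect_equal(sum(stages == "f80s"), 2)  # one per deme
  # per-deme analysis set: neutral + 11 deme-relevant snapshots
  deme1 <- sum(vapply(sr$snapshots,
                      function(s) s$trigger_deme %in% c(0, 1), NA))
  expect_equal(deme1 + 1, 12)
})

test_that("interval schedules emit fixed-interval snapshots and stop at the cap", {
  cfg <- tiny_config(Ne = 150, s = 0.3, n_demes = 2, Nm = 0.2, kind = "local")
  sched <- list(mode = "interval", interval = 10L, n_snapshots = 8L,
                max_gen = 300L)
  sr <- run_scenario(cfg, seed = 17, sweep = "hard", backend = "burnin",
                     schedule = sched)
  expect_length(sr$snapshots, 8)
  expect_equal(vapply(sr$snapshots, function(s) s$generation, 0),
               seq(10, 80, by = 10))
  expect_false(sr$truncated)
})

test_that("the f80s trigger fires just past 80% frequency", {
  cfg <- tiny_config(Ne = 200, s = 0.3)
  f <- vapply(1:10, function(i) {
    sr <- run_scenario(cfg, seed = 100 + i, sweep = "hard", backend = "burnin")
    find_snapshot(sr, "f80s")$sel_freq[1]
  }, 0)
  expect_gte(mean(f), 0.75)
  expect_lte(mean(f), 0.88)
})

test_that("sample drawing is seeded, stratified and size-checked", {
  cfg <- tiny_config(Ne = 100, s = 0.3, n_demes = 2, Nm = 2)
  sr <- run_scenario(cfg, seed = 19, sweep = "hard", backend = "burnin")
  snap <- find_snapshot(sr, "f100s")
  a <- draw_samples(snap, n_samples = 2, per_deme = 30, seed = 5)
  b <- draw_samples(snap, n_samples = 2, per_deme = 30, seed = 5)
  expect_identical(a[[1]]$matrix, b[[1]]$matrix)
  expect_equal(a[[1]]$deme_labels, rep(1:2, each = 30))
  mx <- draw_samples(snap, n_samples = 1, per_deme = 30, mixed = TRUE,
                     seed = 6)[[1]]
  expect_equal(mx$deme_labels, rep(0L, 60))
  expect_error(draw_samples(snap, n_samples = 1, per_deme = 1000),
               "exceeds deme size")
  # pooled-monomorphic columns are dropped (selected site exempt)
  pooled <- colSums(a[[1]]$matrix)
  sel <- which(a[[1]]$positions == a[[1]]$selected_pos)
  expect_true(all(pooled[-sel] > 0 & pooled[-sel] < nrow(a[[1]]$matrix)))
})

test_that("soft sweeps start from a standing variant near 10% frequency", {
  cfg <- tiny_config(Ne = 400, mu = 0.5, cc = 0.5, s = 0.3)
  sr <- run_scenario(cfg, seed = 23, sweep = "soft", backend = "burnin")
  init_freq <- mean(vapply(sr$initial$state$chroms,
                           function(ch) (sr$initial$state$sel_site - 1L) %in% ch,
                           NA))
  expect_gte(init_freq, 0.08)
  expect_lte(init_freq, 0.12)
  expect_equal(sr$sweep, "soft")
})

test_that("rescaling leaves neutral diversity invariant (scaling-law check)", {
  cfg1 <- tiny_config(Ne = 200, mu = 0.25, cc = 0.25, s = 0)
  cfg2 <- cfg1
  cfg2$Ne <- 100L; cfg2$mu <- 0.5; cfg2$cc <- 0.5
  pi_of <- function(cfg, seed, gens) {
    st <- init_neutral_population(cfg, backend = "burnin", seed = seed,
                                  burnin_gens = gens)
    smp <- draw_samples(st, n_samples = 1, per_deme = 40, seed = seed)[[1]]
    unname(sfs_stats(smp$matrix)["theta_pi"])
  }
  p1 <- vapply(1:40, function(i) pi_of(cfg1, 8000 + i, 2000), 0)
  p2 <- vapply(1:40, function(i) pi_of(cfg2, 8800 + i, 1000), 0)
  expect_equal(mean(p2), mean(p1), tolerance = 0.10)
})

test_that("step_generation advances a population in place", {
  cfg <- tiny_config(Ne = 60, mu = 0.2, cc = 0.2, s = 0)
  st <- init_neutral_population(cfg, backend = "burnin", seed = 2,
                                burnin_gens = 200)
  st2 <- step_generation(st, cfg)
  expect_s3_class(st2, "population_state")
  expect_length(st2$chroms, 60)
  expect_false(identical(st$chroms, st2$chroms))
})

test_that("unreachable schedule triggers set the truncation flag", {
  cfg <- tiny_config(Ne = 100, s = 0.3)
  sched <- list(mode = "frequency", triggers = c(0.2, 0.4, 0.6, 0.8, 0.995),
                post_offsets = c(100, 200, 300, 400, 500), max_gen = 10L)
  sr <- run_scenario(cfg, seed = 31, sweep = "hard", backend = "burnin",
                     schedule = sched)
  expect_true(sr$truncated)
})
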