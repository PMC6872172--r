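# Shared simulation fixtures, built once per test run and cached.
# Desk-scale study conditions: lambda = 10 rescaling, 20 replicates x 10
# samples for the panmictic power surface, 5 replicates for the two-deme
# scenarios, 200 training / 100 test samples per class per stage.
# Builders score samples as they go and drop the population states, so
# only score matrices, features and summary values are kept in memory.

.fx_env <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, envir = .fx_env)) {
    assign(name, builder(), envir = .fx_env)
  }
  get(name, envir = .fx_env)
}

FX_LAMBDA <- 10
FX_SAMPLES_PER_STAGE <- 10
FX_M0G_RUNS <- 20
FX_TWO_DEME_RUNS <- 5
FX_NB_CAL <- 600
FX_NB_HOLD <- 200
FX_NB_TWO <- 250
FX_TEST_RUNS <- 10
FX_STAGES <- c("f60s", "f80s", "f99.5s", "f100s", "t1Kr")

fx_grid <- function() make_windows(600000, 100000, 10000)

# append the rows of score-set b under score-set a, keeping attributes
rbind_scores <- function(a, b) {
  if (is.null(a)) return(b)
  for (s in names(b)) {
    pos <- attr(a[[s]], "pos"); dir <- attr(a[[s]], "direction")
    a[[s]] <- rbind(a[[s]], b[[s]])
    attr(a[[s]], "pos") <- pos
    attr(a[[s]], "direction") <- dir
  }
  a
}

# ---- neutral backgrounds ---------------------------------------------------

fx_nb_m0_all <- function() fx("nb_m0_all", function() {
  samples <- neutral_background("m0NB", n_regions = FX_NB_CAL, seed = 101)
  norm <- list(ihs = build_normalisation_table(lapply(samples, ihs_scores)),
               nsl = build_normalisation_table(lapply(samples, nsl_scores)))
  scores <- score_set(samples, stats = window_stat_names(), grid = fx_grid(),
                      norm_ihs = norm$ihs, norm_nsl = norm$nsl)
  list(norm = norm, scores = scores)
})

fx_norm_m0 <- function() fx_nb_m0_all()$norm

fx_score_m0 <- function(samples, deme = NULL) {
  nm <- fx_norm_m0()
  score_set(samples, stats = window_stat_names(), grid = fx_grid(),
            norm_ihs = nm$ihs, norm_nsl = nm$nsl, deme = deme)
}

fx_nb_m0_scores <- function() fx_nb_m0_all()$scores

fx_nb_m0_holdout_scores <- function() fx("nb_m0_holdout_scores", function() {
  fx_score_m0(neutral_background("m0NB", n_regions = FX_NB_HOLD, seed = 909))
})

fx_thresholds_m0 <- function() fx("thresholds_m0", function() {
  calibrate_thresholds(fx_nb_m0_scores())
})

fx_impute <- function() fx("impute", function() {
  nb_impute_table(fx_nb_m0_scores())
})

# two-deme neutral backgrounds, reduced to what the tests consume:
# per-region FST, and block thresholds for separate-deme and mixed
# sampling on the SFS statistics
fx_nb_two_bundle <- function(code, seed) fx(paste0("nb2_", code), function() {
  nb <- neutral_background(code, n_regions = FX_NB_TWO, seed = seed)
  fst <- vapply(nb, fst_stats, 0)
  sep <- split_demes(nb)
  sep_scores <- score_set(sep, stats = c("theta_pi", "tajima_d"),
                          grid = fx_grid())
  th_sep <- calibrate_thresholds(sep_scores)
  set.seed(7171)
  mixed <- lapply(nb, function(s) {
    k <- rbinom(1, 50, 0.5)
    take <- c(sample(which(s$deme_labels == 1), k),
              sample(which(s$deme_labels == 2), 50 - k))
    m <- s$matrix[take, , drop = FALSE]
    poly <- colSums(m) > 0 & colSums(m) < nrow(m)
    haplotype_sample(m[, poly, drop = FALSE], s$positions[poly],
                     s$region_length)
  })
  th_mix <- calibrate_thresholds(
    score_set(mixed, stats = c("theta_pi", "tajima_d"), grid = fx_grid()))
  list(fst = fst, th_sep = th_sep, th_mix = th_mix,
       sep_scores = sep_scores)
})

# ---- panmictic sweep bundles ----------------------------------------------

fx_m0G_stages <- function() c("neutral", "f20s", "f40s", "f60s", "f80s",
                              "f99.5s", "f100s", "t1Kr", "t2Kr", "t3Kr",
                              "t4Kr", "t5Kr")

# run panmictic replicates one at a time, drawing and scoring samples per
# stage, then discarding the population state
fx_sweep_bundle <- function(sweep, run_seed, draw_seed, n_runs, stages) {
  cfg <- scenario_table("m0G", lambda = FX_LAMBDA)
  run_seeds <- derive_seeds(run_seed, n_runs)
  draw_seeds <- derive_seeds(draw_seed, n_runs)
  scores <- setNames(vector("list", length(stages)), stages)
  f80 <- numeric(0)
  n_snapshots <- integer(0)
  for (i in seq_len(n_runs)) {
    run <- run_scenario(cfg, seed = run_seeds[i], sweep = sweep)
    n_snapshots <- c(n_snapshots, length(run$snapshots))
    f80 <- c(f80, find_snapshot(run, "f80s")$sel_freq[1])
    for (stage in stages) {
      snap <- find_snapshot(run, stage)
      if (is.null(snap)) next
      smp <- draw_samples(snap, n_samples = FX_SAMPLES_PER_STAGE,
                          per_deme = 50, seed = draw_seeds[i])
      scores[[stage]] <- rbind_scores(scores[[stage]], fx_score_m0(smp))
    }
    rm(run)
  }
  list(scores = scores, f80 = f80, n_snapshots = n_snapshots)
}

fx_hard_bundle <- function() fx("hard_bundle", function() {
  fx_sweep_bundle("hard", 2201, 3301, FX_M0G_RUNS, fx_m0G_stages())
})

fx_soft_bundle <- function() fx("soft_bundle", function() {
  fx_sweep_bundle("soft", 2301, 3401, FX_M0G_RUNS, FX_STAGES)
})

fx_m0G_power <- function() fx("m0G_power", function() {
  th <- fx_thresholds_m0()
  lapply(fx_hard_bundle()$scores, power_table, thresholds = th)
})

# ---- classifier fixtures ---------------------------------------------------

fx_predictors <- function() fx("predictors", function() {
  imp <- fx_impute()
  Xneu <- featurize(fx_nb_m0_scores(), "200kb", imp)
  Xind <- featurize(fx_nb_m0_holdout_scores(), "200kb", imp)
  hard <- fx_hard_bundle()$scores
  soft <- fx_soft_bundle()$scores
  pairs <- list()
  seeds <- derive_seeds(515, length(FX_STAGES) + 1, stream = 21)
  feats <- list()
  for (stage in FX_STAGES) {
    feats[[stage]] <- list(hard = featurize(hard[[stage]], "200kb", imp),
                           soft = featurize(soft[[stage]], "200kb", imp))
  }
  for (i in seq_along(FX_STAGES)) {
    stage <- FX_STAGES[i]
    pname <- unname(subsweep:::stage_to_predictor(stage))
    pairs[[pname]] <- train_pair(Xneu, feats[[stage]]$hard,
                                 feats[[stage]]$soft, Xind, stage = pname,
                                 seed = seeds[i])
  }
  # pooled pmix pair: a fifth of each stage per class
  fifth <- function(cls) {
    do.call(rbind, lapply(feats, function(f) {
      f[[cls]][seq_len(nrow(f[[cls]]) / 5), , drop = FALSE]
    }))
  }
  pairs[["pmix"]] <- train_pair(Xneu, fifth("hard"), fifth("soft"), Xind,
                                stage = "pmix", seed = seeds[length(seeds)])
  list(pairs = pairs, impute = imp, mode = "200kb")
})

fx_test_bundles <- function() fx("test_bundles", function() {
  list(hard = fx_sweep_bundle("hard", 5601, 5801, FX_TEST_RUNS, FX_STAGES)$scores,
       soft = fx_sweep_bundle("soft", 5701, 5901, FX_TEST_RUNS, FX_STAGES)$scores)
})

fx_test_features <- function() fx("test_features", function() {
  imp <- fx_predictors()$impute
  hard <- fx_test_bundles()$hard
  soft <- fx_test_bundles()$soft
  out <- list()
  for (stage in FX_STAGES) {
    out[[stage]] <- list(hard = featurize(hard[[stage]], "200kb", imp),
                         soft = featurize(soft[[stage]], "200kb", imp))
  }
  out
})

fx_cross_test <- function() fx("cross_test_tab", function() {
  cross_test(fx_predictors()$pairs, fx_test_features(), fpr = 0.01)
})

# ---- two-deme scenario bundles ---------------------------------------------

# per replicate: mean-FST trajectory over neutral + 21 snapshots, the
# stage labels, scored d2 samples at global fixation, and (for the
# mixed-sample analyses) separate-deme and mixed scores post fixation
fx_two_deme_bundle <- function(code, seed) fx(paste0("bundle_", code), function() {
  cfg <- scenario_table(code, lambda = FX_LAMBDA)
  seeds <- derive_seeds(seed, FX_TWO_DEME_RUNS)
  fst <- list()
  stages <- list()
  n_snapshots <- integer(0)
  d2_scores <- NULL
  sep_scores <- list(t1Kr = NULL, t2Kr = NULL)
  mix_scores <- list(t1Kr = NULL, t2Kr = NULL)
  for (i in seq_len(FX_TWO_DEME_RUNS)) {
    run <- run_scenario(cfg, seed = seeds[i], sweep = "hard")
    n_snapshots <- c(n_snapshots, length(run$snapshots))
    snaps <- c(list(run$initial), run$snapshots)
    stages[[i]] <- vapply(snaps, function(s) s$stage, "")
    fst[[i]] <- vapply(snaps, function(sn) {
      smp <- draw_samples(sn, n_samples = FX_SAMPLES_PER_STAGE,
                          per_deme = 50, seed = 881 + i)
      mean(vapply(smp, fst_stats, 0), na.rm = TRUE)
    }, 0)
    snap100 <- find_snapshot(run, "f100s")
    smp <- draw_samples(snap100, n_samples = FX_SAMPLES_PER_STAGE,
                        per_deme = 50, seed = 991 + i)
    d2_scores <- rbind_scores(
      d2_scores, fx_score_m0(lapply(smp, subset_sample, deme = 2)))
    for (stage in c("t1Kr", "t2Kr")) {
      snap <- find_snapshot(run, stage, deme = 2)
      if (is.null(snap)) next
      sep <- draw_samples(snap, n_samples = FX_SAMPLES_PER_STAGE,
                          per_deme = 50, seed = 555 + i)
      mix <- draw_samples(snap, n_samples = FX_SAMPLES_PER_STAGE,
                          per_deme = 25, mixed = TRUE, seed = 655 + i)
      sep_scores[[stage]] <- rbind_scores(
        sep_scores[[stage]],
        score_set(lapply(sep, subset_sample, deme = 2),
                  stats = c("theta_pi", "tajima_d"), grid = fx_grid()))
      mix_scores[[stage]] <- rbind_scores(
        mix_scores[[stage]],
        score_set(mix, stats = c("theta_pi", "tajima_d"), grid = fx_grid()))
    }
    rm(run)
  }
  list(fst = fst, stages = stages, n_snapshots = n_snapshots,
       d2_scores = d2_scores, sep_scores = sep_scores,
       mix_scores = mix_scores)
})

fx_m20G_bundle <- function() fx_two_deme_bundle("m20G", 6601)
fx_m20L_bundle <- function() fx_two_deme_bundle("m20L", 6701)
fx_m02G_bundle <- function() fx_two_deme_bundle("m0.2G", 6801)
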