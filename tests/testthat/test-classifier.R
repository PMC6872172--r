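# Protocol-level tests of the two-stage classifier on small synthetic
# feature sets; the temporal/spatial misclassification phenomena on
# simulated sweeps live in the acceptance suite.

fake_score_list <- function(n, fill = 0, nw = 51) {
  out <- lapply(window_stat_names(), function(s) {
    m <- matrix(fill, n, nw)
    attr(m, "pos") <- seq(0, by = 10000, length.out = nw)
    attr(m, "direction") <- "high"
    m
  })
  names(out) <- window_stat_names()
  out
}

synthetic_features <- function(n, shift, seed, p = 22) {
  set.seed(seed)
  X <- matrix(rnorm(n * p, mean = shift), n, p)
  colnames(X) <- paste0("f", seq_len(p))
  X
}

test_that("featurize builds fixed-length imputed vectors", {
  sc <- fake_score_list(4, fill = 1)
  sc$H1[2, 3] <- NA           # a single missing entry
  sc$tajima_d[3, ] <- NA      # an all-missing statistic for one sample
  imp <- nb_impute_table(fake_score_list(10, fill = 7))
  X <- featurize(sc, mode = "200kb", impute = imp)
  expect_equal(ncol(X), 11 * 11)
  expect_equal(nrow(X), 4)
  expect_equal(attr(X, "n_imputed"), 12)
  expect_equal(unname(X[2, "H1_w3"]), 7)      # imputed to the NB mean
  expect_equal(unname(X[3, "tajima_d_w5"]), 7)
  expect_true(all(is.finite(X)))
  # identical samples give identical vectors
  expect_equal(X[1, ], X[4, ])
  # 600-kb mode uses all 51 windows
  expect_equal(ncol(featurize(fake_score_list(2, 1), "600kb", imp)), 11 * 51)
})

test_that("featurize excludes samples with mostly-missing features", {
  sc <- fake_score_list(3, fill = 1)
  for (s in window_stat_names()[1:7]) sc[[s]][2, ] <- NA
  imp <- nb_impute_table(fake_score_list(5, fill = 0))
  X <- featurize(sc, "200kb", imp)
  expect_equal(nrow(X), 2)
  expect_equal(attr(X, "excluded"), 2L)
})

test_that("a trained pair separates its own training data and is deterministic", {
  neutral <- synthetic_features(120, 0, 1)
  hard <- synthetic_features(120, 2.5, 2)
  soft <- synthetic_features(120, 1.4, 3)
  nb_ind <- synthetic_features(200, 0, 4)
  pair <- train_pair(neutral, hard, soft, nb_ind, stage = "p100", seed = 9)
  # self-consistency: almost all sweep training data above the 5% cutoff
  s1 <- subsweep:::predict_booster(pair$booster1, rbind(hard, soft))
  expect_gte(mean(s1 >= pair$thresholds["0.05"]), 0.95)
  # predictor 2 recognises its own hard training data
  s2 <- subsweep:::predict_booster(pair$booster2, hard)
  expect_gte(mean(s2 > 0.5), 0.90)
  # thresholds are decreasing in FPR (higher cutoff for stricter FPR)
  expect_true(all(diff(pair$thresholds) >= 0))
  # retraining with the same seed reproduces the pair exactly
  pair2 <- train_pair(neutral, hard, soft, nb_ind, stage = "p100", seed = 9)
  expect_equal(subsweep:::predict_booster(pair2$booster1, nb_ind),
               subsweep:::predict_booster(pair$booster1, nb_ind))
  expect_equal(pair2$thresholds, pair$thresholds)
})

test_that("the three-way rule is threshold-first, then 0.5 on predictor 2", {
  neutral <- synthetic_features(150, 0, 11)
  hard <- synthetic_features(150, 3, 12)
  soft <- synthetic_features(150, 3, 13)
  # make predictor 2 informative: hard has higher first feature
  hard[, 1] <- hard[, 1] + 4
  nb_ind <- synthetic_features(300, 0, 14)
  pair <- train_pair(neutral, hard, soft, nb_ind, stage = "pmix", seed = 21)
  res_n <- classify(synthetic_features(200, 0, 15), pair, fpr = 0.01)
  # neutral-like data: about 1% called non-neutral
  expect_lte(1 - res_n$proportions["neutral"], 0.06)
  res_h <- classify(synthetic_features(100, 3, 16) +
                      cbind(matrix(4, 100, 1), matrix(0, 100, 21)),
                    pair, fpr = 0.01)
  expect_gte(res_h$proportions["hard"], 0.8)
  res_s <- classify(synthetic_features(100, 3, 17), pair, fpr = 0.01)
  expect_gte(res_s$proportions["soft"], 0.8)
  # proportions sum to one
  expect_equal(sum(res_h$proportions), 1)
  expect_error(classify(neutral, pair, fpr = 0.2), "no threshold")
})

test_that("cross_test assembles the full predictor-by-stage matrix", {
  neutral <- synthetic_features(80, 0, 31)
  hard <- synthetic_features(80, 2.5, 32)
  soft <- synthetic_features(80, 1.2, 33)
  nb_ind <- synthetic_features(150, 0, 34)
  pairs <- list(p60 = train_pair(neutral, hard, soft, nb_ind, "p60", seed = 1),
                p100 = train_pair(neutral, hard, soft, nb_ind, "p100", seed = 2))
  tf <- list(f60s = list(hard = hard, soft = soft),
             f100s = list(hard = hard, soft = soft))
  ct <- cross_test(pairs, tf, fpr = 0.05)
  expect_equal(nrow(ct), 2 * 2 * 2)
  expect_true(all(abs(ct$neutral + ct$soft + ct$hard - 1) < 1e-12))
  expect_setequal(unique(ct$predictor), c("p60", "p100"))
})

test_that("false positive rates agree across the three neutral 200-kb segments", {
  # only the first segment's windows enter training; similar detection
  # rates on the other two segments indicate no over-fitting
  pr <- fx_predictors()
  sc <- fx_nb_m0_holdout_scores()
  seg_features <- function(cols) {
    sliced <- lapply(sc, function(m) {
      x <- m[, cols, drop = FALSE]
      attr(x, "pos") <- attr(m, "pos")[cols]
      attr(x, "direction") <- attr(m, "direction")
      x
    })
    featurize(sliced, "200kb", pr$impute)
  }
  segs <- list(seg_features(1:11), seg_features(21:31), seg_features(41:51))
  hits <- vapply(segs, function(X) {
    sum(classify(X, pr$pairs$p100, 0.05)$labels != "neutral")
  }, 0)
  n <- vapply(segs, nrow, 0)
  pt <- suppressWarnings(prop.test(hits, n))
  expect_gt(pt$p.value, 0.01)
})

test_that("the region next to a hard sweep is read as a soft sweep", {
  # soft shoulder: features taken from the second 200-kb segment (0.1 to
  # 0.3 cM from the selected site) of hard-sweep samples are detected
  # mostly as soft
  pr <- fx_predictors()
  sc <- fx_test_bundles()$hard$f99.5s
  shoulder <- lapply(sc, function(m) {
    x <- m[, 21:31, drop = FALSE]
    attr(x, "pos") <- attr(m, "pos")[21:31]
    attr(x, "direction") <- attr(m, "direction")
    x
  })
  X <- featurize(shoulder, "200kb", pr$impute)
  soft <- hard <- 0
  for (p in c("p80", "p99.5", "p100")) {
    pr_p <- classify(X, pr$pairs[[p]], 0.01)$proportions
    soft <- soft + pr_p["soft"]; hard <- hard + pr_p["hard"]
  }
  expect_gt(soft, hard)
})

test_that("a fresh neutral set is called non-neutral at about the nominal rate", {
  pr <- fx_predictors()
  nb <- neutral_background("m0NB", n_regions = 100, seed = 1313)
  X <- featurize(fx_score_m0(nb), "200kb", pr$impute)
  rate <- mean(classify(X, pr$pairs$pmix, 0.01)$labels != "neutral")
  expect_lte(rate, 0.06)
})

test_that("the end-to-end training pipeline runs at toy scale", {
  skip_if(Sys.which("python") == "", "no python for the coalescent backend")
  cfg <- scenario_table("m0G", lambda = FX_LAMBDA)
  ts <- make_training_sets(cfg, stages = c("f80s", "f100s"), n_per_class = 4,
                           n_neutral = 8, samples_per_rep = 2, seed = 31)
  expect_length(ts$stages$f80s$hard, 4)
  expect_length(ts$stages$f100s$soft, 4)
  expect_length(ts$neutral, 8)
  expect_length(ts$mix$hard, 4)
  nm <- fx_norm_m0()
  tp <- train_all_pairs(ts, utils::head(neutral_background("m0NB", 30, seed = 77)),
                        mode = "200kb", norm_ihs = nm$ihs, norm_nsl = nm$nsl,
                        seed = 5, nrounds = 8)
  expect_setequal(names(tp$pairs), c("p80", "p100", "pmix"))
  expect_s3_class(tp$pairs$p80, "predictor_pair")
})
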