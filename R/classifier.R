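# Two-stage sweep classification: a sweep-vs-neutral predictor with
# neutral-FPR-calibrated thresholds, then a hard-vs-soft predictor at the
# fixed 0.5 cutoff. Backend: gradient-boosted trees (xgboost) over
# per-window values of the in-house statistics.

#' Turn score tracks into classifier feature vectors
#'
#' The feature vector of a sample is the concatenation of its per-window
#' values of the 11 in-house window statistics over the first 11 windows
#' (200-kb mode) or all 51 (600-kb mode). Missing entries are imputed by
#' the neutral-background mean of the same statistic and window; samples
#' with more than half of their entries missing are excluded (attribute
#' `excluded`).
#'
#' @param scores Score-track list from [score_set()].
#' @param mode `"200kb"` or `"600kb"`.
#' @param impute Imputation table from [nb_impute_table()].
#' @return Numeric matrix samples x features, with attributes `excluded`
#'   (row indices removed) and `n_imputed`.
#' @export
featurize <- function(scores, mode = c("200kb", "600kb"), impute) {
  mode <- match.arg(mode)
  stats <- intersect(window_stat_names(), names(scores))
  nw <- if (mode == "200kb") 11L else 51L
  mats <- lapply(stats, function(s) scores[[s]][, seq_len(nw), drop = FALSE])
  X <- do.call(cbind, mats)
  colnames(X) <- unlist(lapply(stats, function(s) paste0(s, "_w", seq_len(nw))))
  miss_frac <- rowMeans(is.na(X))
  excluded <- which(miss_frac > 0.5)
  if (length(excluded)) X <- X[-excluded, , drop = FALSE]
  n_imputed <- sum(is.na(X))
  if (n_imputed > 0) {
    fill <- rep(unlist(lapply(stats, function(s) impute[[s]][seq_len(nw)])),
                each = 1)
    for (j in seq_len(ncol(X))) {
      X[is.na(X[, j]), j] <- fill[j]
    }
  }
  attr(X, "excluded") <- excluded
  attr(X, "n_imputed") <- n_imputed
  X
}

#' Neutral-background imputation table
#'
#' Per-statistic, per-window mean over neutral background samples, used
#' to impute missing feature entries.
#'
#' @param nb_scores Score-track list from [score_set()] on neutral
#'   samples.
#' @return Named list of per-window mean vectors.
#' @export
nb_impute_table <- function(nb_scores) {
  lapply(nb_scores, function(m) {
    v <- colMeans(m, na.rm = TRUE)
    v[is.nan(v)] <- 0
    v
  })
}

xgb_params <- function() {
  list(objective = "binary:logistic", max_depth = 3, eta = 0.3,
       subsample = 1, nthread = 1)
}

fit_booster <- function(X, y, seed, nrounds = 60) {
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  xgboost::xgb.train(params = xgb_params(), data = dtrain,
                     nrounds = nrounds, verbose = 0)
}

predict_booster <- function(booster, X) {
  stats::predict(booster, xgboost::xgb.DMatrix(X, nthread = 1))
}

#' Train one stage-labelled predictor pair
#'
#' Predictor 1 separates neutral (y = 0) from sweep (y = 1, hard and soft
#' pooled); its detection thresholds are set so that an independent
#' neutral background set is detected at the nominal false positive
#' rates. Predictor 2 separates soft (y = 0) from hard (y = 1) and is
#' always used at the fixed threshold 0.5, avoiding an a priori bias
#' toward either sweep type.
#'
#' @param neutral,hard,soft Feature matrices from [featurize()].
#' @param nb_independent Feature matrix of neutral samples independent of
#'   the training neutrals, used for thresholding.
#' @param stage Stage label (`"p60"`, ..., `"pmix"`).
#' @param fprs Nominal false positive rates for predictor 1.
#' @param seed Integer seed.
#' @param nrounds Boosting rounds.
#' @return A `predictor_pair`: boosters, thresholds, stage, mode
#'   metadata.
#' @export
train_pair <- function(neutral, hard, soft, nb_independent, stage,
                       fprs = c(0.05, 0.01, 0.001), seed = 1, nrounds = 60) {
  X1 <- rbind(neutral, hard, soft)
  y1 <- c(rep(0, nrow(neutral)), rep(1, nrow(hard) + nrow(soft)))
  X2 <- rbind(soft, hard)
  y2 <- c(rep(0, nrow(soft)), rep(1, nrow(hard)))
  seeds <- derive_seeds(seed, 2, stream = 5)
  b1 <- fit_booster(X1, y1, seeds[1], nrounds)
  b2 <- fit_booster(X2, y2, seeds[2], nrounds)
  sc1 <- predict_booster(b1, X1)
  if (stats::sd(sc1) == 0) stop("degenerate predictor: no separation in training scores")
  nb_sc <- predict_booster(b1, nb_independent)
  srt <- sort(nb_sc, decreasing = TRUE)
  thresholds <- vapply(fprs, function(f) {
    srt[max(1L, round(f * length(srt)))]
  }, 0)
  names(thresholds) <- as.character(fprs)
  structure(list(stage = stage, booster1 = b1, booster2 = b2,
                 thresholds = thresholds, fprs = fprs,
                 n_features = ncol(neutral), seed = seed),
            class = "predictor_pair")
}

#' @export
print.predictor_pair <- function(x, ...) {
  cat(sprintf("predictor_pair %s: %d features, thresholds [%s]\n", x$stage,
              x$n_features,
              paste(sprintf("%s=%.3f", names(x$thresholds), x$thresholds),
                    collapse = ", ")))
  invisible(x)
}

#' Three-way classification of samples
#'
#' A sample below the stage's neutral threshold (at the chosen FPR) on
#' predictor 1 is "neutral" regardless of predictor 2; otherwise it is
#' "soft" when predictor 2 scores below 0.5 and "hard" when at or above.
#'
#' @param features Feature matrix from [featurize()].
#' @param pair A `predictor_pair`.
#' @param fpr Which calibrated threshold to use.
#' @return A list: `labels` (factor neutral/soft/hard), `proportions`
#'   (named numeric summing to 1), `scores1`, `scores2`.
#' @export
classify <- function(features, pair, fpr = 0.01) {
  thr <- pair$thresholds[as.character(fpr)]
  if (is.na(thr)) stop("no threshold calibrated at fpr = ", fpr)
  s1 <- predict_booster(pair$booster1, features)
  s2 <- predict_booster(pair$booster2, features)
  lab <- ifelse(s1 < thr, "neutral", ifelse(s2 < 0.5, "soft", "hard"))
  lab <- factor(lab, levels = c("neutral", "soft", "hard"))
  list(labels = lab, proportions = prop.table(table(lab)),
       scores1 = s1, scores2 = s2)
}

#' Cross-test predictor pairs against stage-labelled test sets
#'
#' Applies every predictor pair to every stage test set of both sweep
#' classes and records the proportions classified neutral, soft and
#' hard -- the matrix behind temporal softening and hardening.
#'
#' @param pairs Named list of `predictor_pair` objects.
#' @param test_features Nested list: `test_features[[stage]][[class]]` is
#'   a feature matrix (`class` in `"hard"`, `"soft"`; other names
#'   allowed, e.g. `"neutral"`).
#' @param fpr FPR level for predictor 1 thresholds.
#' @return data.frame `predictor`, `test_stage`, `test_class`, `neutral`,
#'   `soft`, `hard`, `n`.
#' @export
cross_test <- function(pairs, test_features, fpr = 0.01) {
  out <- list()
  for (pn in names(pairs)) {
    for (stage in names(test_features)) {
      for (cls in names(test_features[[stage]])) {
        X <- test_features[[stage]][[cls]]
        if (is.null(X) || nrow(X) == 0) next
        pr <- classify(X, pairs[[pn]], fpr)$proportions
        out[[length(out) + 1L]] <- data.frame(
          predictor = pn, test_stage = stage, test_class = cls,
          neutral = unname(pr["neutral"]), soft = unname(pr["soft"]),
          hard = unname(pr["hard"]), n = nrow(X))
      }
    }
  }
  do.call(rbind, out)
}

# stage label of the predictor trained on a given snapshot stage
stage_to_predictor <- function(stage) {
  c(f60s = "p60", f80s = "p80", "f99.5s" = "p99.5", f100s = "p100",
    t1Kr = "p100+", mix = "pmix")[stage]
}

#' Train the full set of stage predictor pairs from training sets
#'
#' Scores all training samples, featurises them in the requested mode and
#' trains one predictor pair per stage plus the pooled `pmix` pair.
#'
#' @param tsets A `training_sets` object from [make_training_sets()].
#' @param nb_independent List of neutral samples (independent of the
#'   training neutrals) for thresholding.
#' @param mode `"200kb"` or `"600kb"`.
#' @param norm_ihs,norm_nsl EHH normalisation tables.
#' @param seed Integer seed.
#' @param nrounds Boosting rounds per predictor.
#' @return List with `pairs` (named by p60...pmix), `impute`, `mode`.
#' @export
train_all_pairs <- function(tsets, nb_independent, mode = "200kb",
                            norm_ihs, norm_nsl, seed = 1, nrounds = 60) {
  sc_args <- list(stats = window_stat_names(), norm_ihs = norm_ihs,
                  norm_nsl = norm_nsl)
  nb_scores <- do.call(score_set, c(list(tsets$neutral), sc_args))
  impute <- nb_impute_table(nb_scores)
  Xneu <- featurize(nb_scores, mode, impute)
  Xind <- featurize(do.call(score_set, c(list(nb_independent), sc_args)),
                    mode, impute)
  pairs <- list()
  stages <- c(names(tsets$stages), "mix")
  seeds <- derive_seeds(seed, length(stages), stream = 21)
  for (i in seq_along(stages)) {
    stage <- stages[i]
    set <- if (stage == "mix") tsets$mix else tsets$stages[[stage]]
    Xh <- featurize(do.call(score_set, c(list(set$hard), sc_args)), mode, impute)
    Xs <- featurize(do.call(score_set, c(list(set$soft), sc_args)), mode, impute)
    pname <- unname(stage_to_predictor(stage))
    pairs[[pname]] <- train_pair(Xneu, Xh, Xs, Xind, stage = pname,
                                 seed = seeds[i], nrounds = nrounds)
  }
  list(pairs = pairs, impute = impute, mode = mode)
}
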