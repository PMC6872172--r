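#' @useDynLib subsweep, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- population state ------------------------------------------------------

# A population_state is a list: chroms (list of integer vectors of 0-based
# site indices, position-sorted), positions (bp per site), deme (1-based
# deme per chromosome), deme_sizes, L, sel_site (1-based site index, 0 =
# none), config. Chromosome site vectors use 0-based indices because they
# pass through the C++ engine unchanged.

population_state <- function(chroms, positions, deme_sizes, L, sel_site = 0L,
                             config = NULL) {
  structure(
    list(chroms = chroms, positions = as.numeric(positions),
         deme = rep(seq_along(deme_sizes), deme_sizes),
         deme_sizes = as.integer(deme_sizes), L = as.numeric(L),
         sel_site = as.integer(sel_site), config = config),
    class = "population_state"
  )
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("population_state: %d chromosomes in %d deme(s), %d segregating sites over [0, %g)\n",
              length(x$chroms), length(x$deme_sizes), length(x$positions), x$L))
  invisible(x)
}

samples_to_state <- function(sample, deme_sizes, config = NULL) {
  m <- sample$matrix
  chroms <- lapply(seq_len(nrow(m)), function(i) which(m[i, ] == 1L) - 1L)
  population_state(chroms, sample$positions, deme_sizes,
                   sample$region_length, config = config)
}

#' Generate an equilibrium neutral population
#'
#' Builds the neutral starting population for the forward genomic
#' simulator: all chromosomes of the (possibly subdivided) population with
#' their segregating sites at mutation-drift(-migration) equilibrium.
#'
#' Backends: `"coalescent"` runs the bundled msprime script (standard
#' structured coalescent with recombination, infinite sites) and parses
#' its ms output; `"ms_file"` reads any ms-format text with matching
#' sample counts; `"burnin"` starts from zero variation and runs the
#' forward engine neutrally for `burnin_gens` generations (default
#' 20 Ne).
#'
#' @param config A `scenario_config` (possibly rescaled).
#' @param backend `"coalescent"`, `"ms_file"` or `"burnin"`.
#' @param seed Integer seed.
#' @param ms_file Path or text lines for the `"ms_file"` backend.
#' @param burnin_gens Generations for the `"burnin"` backend.
#' @return A `population_state`.
#' @export
init_neutral_population <- function(config,
                                    backend = c("coalescent", "ms_file", "burnin"),
                                    seed = 1, ms_file = NULL,
                                    burnin_gens = NULL) {
  backend <- match.arg(backend)
  n_tot <- sum(config$Ne)
  if (backend == "ms_file") {
    if (is.null(ms_file)) stop("ms_file backend requires ms-format input")
    samp <- read_ms(ms_file, region_length = config$region_length)[[1]]
    if (nrow(samp$matrix) != n_tot) {
      stop(sprintf("ms input has %d chromosomes; scenario needs %d",
                   nrow(samp$matrix), n_tot))
    }
    return(samples_to_state(samp, config$Ne, config))
  }
  if (backend == "coalescent") {
    lines <- run_msprime(
      n1 = if (config$n_demes == 2) config$Ne[1] else n_tot,
      n2 = if (config$n_demes == 2) config$Ne[2] else 0,
      ne = config$Ne[1], nm = if (config$n_demes == 2) config$Nm else 0,
      mu_region = config$mu, rho_region = config$cc,
      length = config$region_length, reps = 1, seed = seed
    )
    samp <- read_ms(lines, region_length = config$region_length)[[1]]
    return(samples_to_state(samp, config$Ne, config))
  }
  # burn-in: forward-neutral from a monomorphic population
  if (is.null(burnin_gens)) burnin_gens <- 20 * config$Ne[1]
  st <- population_state(rep(list(integer(0)), n_tot), numeric(0),
                         config$Ne, config$region_length, config = config)
  set.seed(seed)
  res <- .fw_simulate(st$chroms, st$positions, st$deme_sizes,
                      s = rep(0, config$n_demes), m = config$m,
                      mu = config$mu, cc = config$cc, L = st$L,
                      sel_site = 0L, sel_pos = 0,
                      schedule_mode = "none",
                      freq_triggers = numeric(0), post_offsets = numeric(0),
                      snapshot_interval = 0L, n_interval_snapshots = 0L,
                      max_gen = as.integer(burnin_gens))
  snap <- res$snapshots[[1]]
  population_state(snap$chroms, snap$positions, config$Ne,
                   config$region_length, config = config)
}

# Locate python with msprime and run the bundled coalescent script.
run_msprime <- function(n1, n2, ne, nm, mu_region, rho_region, length, reps,
                        seed) {
  script <- system.file("python", "neutral_ms.py", package = "subsweep")
  if (script == "") script <- file.path("inst", "python", "neutral_ms.py")
  py <- Sys.which("python")
  if (py == "") py <- Sys.which("python3")
  if (py == "") stop("no python interpreter found for the coalescent backend; ",
                     "use backend = 'ms_file' or 'burnin'")
  args <- c(script, "--n1", n1, "--n2", n2, "--ne", ne, "--nm", nm,
            "--mu-region", mu_region, "--rho-region", rho_region,
            "--length", length, "--reps", reps, "--seed", seed)
  out <- suppressWarnings(system2(py, as.character(args), stdout = TRUE,
                                  stderr = FALSE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("msprime coalescent backend failed; use backend = 'ms_file' or 'burnin'")
  }
  out
}

#' Neutral background samples
#'
#' Simulates the neutral calibration samples with the coalescent backend:
#' 50-chromosome samples from a panmictic population (`m0NB`) or paired
#' 50+50 samples from the two-deme island model (`m20NB`, `m2NB`,
#' `m0.2NB`), each deme of a pair usable as an independent sample via
#' [split_demes()]. Scenario parameters are taken at face value from the
#' unrescaled configuration: the equilibrium neutral distribution is what
#' the forward model converges to, and is invariant under the rescaling
#' used for the selection runs.
#'
#' @param code Neutral scenario code (`m0NB`, `m20NB`, `m2NB`, `m0.2NB`).
#' @param n_regions Number of simulated regions (replicates).
#' @param sample_size Chromosomes per deme per sample.
#' @param seed Integer seed.
#' @return List of [haplotype_sample] objects (deme-labelled for two-deme
#'   codes).
#' @export
neutral_background <- function(code, n_regions, sample_size = 50, seed = 1) {
  cfg <- scenario_table(code)
  if (cfg$kind != "neutral") stop("not a neutral background code: ", code)
  two <- cfg$n_demes == 2
  lines <- run_msprime(
    n1 = sample_size, n2 = if (two) sample_size else 0,
    ne = cfg$Ne[1], nm = if (two) cfg$Nm else 0,
    mu_region = cfg$mu, rho_region = cfg$cc,
    length = cfg$region_length, reps = n_regions, seed = seed
  )
  read_ms(lines, region_length = cfg$region_length,
          deme_sizes = if (two) c(sample_size, sample_size) else NULL)
}

#' Split two-deme samples into independent one-deme samples
#'
#' Each deme of a two-deme neutral region is used as an independent
#' neutral sample (2,500 two-deme regions effectively give 5,000
#' samples). Columns monomorphic within a deme are dropped.
#'
#' @param samples List of deme-labelled [haplotype_sample] objects.
#' @return List of one-deme samples, demes interleaved.
#' @export
split_demes <- function(samples) {
  out <- list()
  for (s in samples) {
    for (d in sort(unique(s$deme_labels))) {
      sub <- subset_sample(s, deme = d)
      poly <- colSums(sub$matrix) > 0 & colSums(sub$matrix) < nrow(sub$matrix)
      sub$matrix <- sub$matrix[, poly, drop = FALSE]
      sub$positions <- sub$positions[poly]
      out[[length(out) + 1L]] <- sub
    }
  }
  out
}

# ---- forward simulation ----------------------------------------------------

#' Advance a population by one generation
#'
#' One generation of the forward engine: random diploid pairing, fitness-
#' weighted reproduction with one-breakpoint recombination (probability
#' `cc`), Poisson(`mu`) new mutations per transmitted chromosome, balanced
#' individual migration, pruning of fixed and lost sites.
#'
#' @param state A `population_state`.
#' @param config A `scenario_config` supplying s, m, mu, cc.
#' @return The updated `population_state`.
#' @export
step_generation <- function(state, config) {
  snap <- .fw_step_once(state$chroms, state$positions, state$deme_sizes,
                        s = config$s, m = config$m, mu = config$mu,
                        cc = config$cc, L = state$L,
                        sel_site = state$sel_site)
  out <- population_state(snap$chroms, snap$positions, state$deme_sizes,
                          state$L, sel_site = snap$sel_site,
                          config = state$config)
  out
}

default_schedule <- function(config) {
  lam <- config$lambda
  if (config$schedule == "interval") {
    list(mode = "interval", interval = max(1L, as.integer(round(100 / lam))),
         n_snapshots = 200L,
         max_gen = as.integer(round(20000 / lam)))
  } else {
    list(mode = "frequency", triggers = c(0.2, 0.4, 0.6, 0.8, 0.995),
         post_offsets = as.integer(round(c(1000, 2000, 3000, 4000, 5000) / lam)),
         max_gen = as.integer(round(2e6 / lam)))
  }
}

#' Run one replicate of a genomic sweep scenario
#'
#' Initialises an equilibrium neutral population, introduces the adaptive
#' allele (a brand-new mutation at 100 kb for a hard sweep, or an
#' existing standing variant with pooled frequency closest to 10% --
#' within 10 +/- 2% -- near 100 kb for a soft sweep) and runs the forward
#' engine under the scenario's migration/selection regime, recording
#' population snapshots per schedule: at 20/40/60/80/99.5% within-deme
#' frequency, 1--5 x 1000/lambda generations after a deme reaches 99.5%,
#' and at global fixation (21 snapshots for two demes, 11 panmictic); or
#' at fixed intervals for `m0.2L`-type configurations. If the allele is
#' lost everywhere the population resets to the initial state and the run
#' starts over. For soft sweeps with no eligible standing variant the
#' neutral population is re-drawn (up to `max_redraws` times).
#'
#' @param config A `scenario_config` (use [rescale_config()] for
#'   desk-scale runs).
#' @param seed Integer seed.
#' @param sweep `"hard"` or `"soft"`.
#' @param schedule Optional schedule override from `default_schedule`.
#' @param init Optional pre-built initial `population_state`.
#' @param backend Backend for [init_neutral_population()].
#' @param max_redraws Re-draw attempts for soft-sweep eligibility.
#' @return A `scenario_run`: list with `config`, `snapshots` (each with
#'   `stage`, `trigger_deme`, `generation`, `sel_freq` and the population),
#'   `initial` (the pre-selection neutral state as a snapshot), `n_resets`,
#'   `truncated`, `seed`.
#' @export
run_scenario <- function(config, seed, sweep = c("hard", "soft"),
                         schedule = NULL, init = NULL,
                         backend = "coalescent", max_redraws = 20) {
  sweep <- match.arg(sweep)
  if (is.null(schedule)) schedule <- default_schedule(config)
  seeds <- derive_seeds(seed, max_redraws + 1, stream = 3)
  for (attempt in seq_len(max_redraws + 1)) {
    st <- if (!is.null(init) && attempt == 1) init else
      init_neutral_population(config, backend = backend, seed = seeds[attempt])
    sel_site <- 0L
    if (sweep == "soft") {
      freq <- site_frequencies(st)
      cand <- which(freq >= 0.08 & freq <= 0.12)
      if (!length(cand)) next  # no standing variant near 10%: re-draw
      sel_site <- cand[which.min(abs(st$positions[cand] - config$sel_pos))]
    }
    set.seed(seeds[attempt] %% 2147483647)
    res <- .fw_simulate(
      st$chroms, st$positions, st$deme_sizes,
      s = config$s, m = config$m, mu = config$mu, cc = config$cc, L = st$L,
      sel_site = as.integer(sel_site), sel_pos = config$sel_pos,
      schedule_mode = schedule$mode,
      freq_triggers = if (schedule$mode == "frequency") schedule$triggers else numeric(0),
      post_offsets = if (schedule$mode == "frequency") schedule$post_offsets else numeric(0),
      snapshot_interval = if (schedule$mode == "interval") schedule$interval else 0L,
      n_interval_snapshots = if (schedule$mode == "interval") schedule$n_snapshots else 0L,
      max_gen = schedule$max_gen
    )
    snaps <- lapply(res$snapshots, wrap_snapshot, config = config)
    initial <- wrap_snapshot(
      list(generation = 0L, stage = "neutral", trigger_deme = 0L,
           sel_freq = rep(0, config$n_demes), chroms = st$chroms,
           positions = st$positions, deme = st$deme,
           sel_site = as.integer(sel_site)),
      config = config)
    return(structure(
      list(config = config, sweep = sweep, snapshots = snaps,
           initial = initial, n_resets = res$n_resets,
           truncated = res$truncated, generations = res$generations,
           seed = seed),
      class = "scenario_run"))
  }
  stop("no standing variant within 10% +/- 2% after ", max_redraws, " re-draws")
}

wrap_snapshot <- function(snap, config) {
  snap$state <- population_state(snap$chroms, snap$positions, config$Ne,
                                 config$region_length,
                                 sel_site = snap$sel_site, config = config)
  snap$chroms <- snap$positions <- snap$deme <- NULL
  snap
}

#' @export
print.scenario_run <- function(x, ...) {
  cat(sprintf("scenario_run %s (%s sweep): %d snapshots, %d reset(s)%s\n",
              x$config$code, x$sweep, length(x$snapshots), x$n_resets,
              if (x$truncated) ", truncated" else ""))
  invisible(x)
}

site_frequencies <- function(state) {
  S <- length(state$positions)
  cnt <- tabulate(unlist(state$chroms) + 1L, nbins = S)
  cnt / length(state$chroms)
}

#' Draw haplotype samples from a population snapshot
#'
#' Each sample draws `per_deme` chromosomes without replacement from every
#' deme (deme-stratified, the standard design), or `per_deme *
#' n_demes` chromosomes from the pooled population when `mixed = TRUE`
#' (cryptic-substructure sampling). Columns monomorphic within the sample
#' are dropped, except the selected site, which is retained even when
#' fixed.
#'
#' @param snapshot A snapshot from [run_scenario()] (or a
#'   `population_state`).
#' @param n_samples Number of samples to draw.
#' @param per_deme Chromosomes per deme per sample.
#' @param mixed Pool demes before drawing.
#' @param seed Integer seed.
#' @return List of [haplotype_sample] objects.
#' @export
draw_samples <- function(snapshot, n_samples = 50, per_deme = 50,
                         mixed = FALSE, seed = 1) {
  state <- if (inherits(snapshot, "population_state")) snapshot else snapshot$state
  D <- length(state$deme_sizes)
  if (any(per_deme > state$deme_sizes)) {
    stop("requested sample size exceeds deme size")
  }
  set.seed(seed)
  n_draw <- per_deme * D
  lapply(seq_len(n_samples), function(k) {
    take <- if (mixed || D == 1) {
      sample(length(state$chroms), n_draw)
    } else {
      unlist(lapply(seq_len(D), function(d) {
        sample(which(state$deme == d), per_deme)
      }))
    }
    res <- .fw_sample_matrix(state$chroms, state$positions,
                             as.integer(take), state$sel_site)
    pos <- res$positions
    if (anyDuplicated(pos)) pos <- dejitter_positions(pos)
    haplotype_sample(
      res$matrix, pos, state$L,
      deme_labels = if (mixed || D == 1) rep(0L, n_draw) else
        rep(seq_len(D), each = per_deme),
      selected_pos = if (is.na(res$sel_col)) NA_real_ else pos[res$sel_col]
    )
  })
}

# ---- training sets ---------------------------------------------------------

#' Build stage-labelled training sets for the sweep classifier
#'
#' Simulates panmictic hard and soft sweeps with the forward engine and
#' draws single-deme samples at the requested stages (ongoing sweep at
#' 60/80/99.5% completion, fixation, and 1,000 generations after), plus a
#' shared neutral set from the coalescent backend. Soft sweeps start from
#' a standing variant at 10% frequency. A pooled `mix` stage takes a
#' fifth of each stage per class.
#'
#' @param config Panmictic `scenario_config` (rescale for desk-scale
#'   work).
#' @param stages Stage labels to collect.
#' @param n_per_class Samples per class (hard/soft) per stage.
#' @param n_neutral Shared neutral samples.
#' @param samples_per_rep Samples drawn per replicate run (replicates =
#'   `n_per_class / samples_per_rep`).
#' @param sample_size Chromosomes per sample.
#' @param seed Integer seed.
#' @return A `training_sets` list: `stages` (per stage: `hard`, `soft`
#'   sample lists), `mix`, `neutral`, and the generation parameters.
#' @export
make_training_sets <- function(config,
                               stages = c("f60s", "f80s", "f99.5s", "f100s", "t1Kr"),
                               n_per_class = 1000, n_neutral = 2000,
                               samples_per_rep = 10, sample_size = 50,
                               seed = 1) {
  stopifnot(config$n_demes == 1)
  n_reps <- ceiling(n_per_class / samples_per_rep)
  seeds <- derive_seeds(seed, 2 * n_reps, stream = 11)
  sets <- list()
  for (stage in stages) sets[[stage]] <- list(hard = list(), soft = list())
  for (class_i in 1:2) {
    sweep <- c("hard", "soft")[class_i]
    for (r in seq_len(n_reps)) {
      sr <- run_scenario(config, seed = seeds[(class_i - 1) * n_reps + r],
                         sweep = sweep)
      for (stage in stages) {
        snap <- find_snapshot(sr, stage)
        if (is.null(snap)) next
        smp <- draw_samples(snap, n_samples = samples_per_rep,
                            per_deme = sample_size,
                            seed = seeds[(class_i - 1) * n_reps + r])
        sets[[stage]][[sweep]] <- c(sets[[stage]][[sweep]], smp)
      }
    }
    for (stage in stages) {
      sets[[stage]][[sweep]] <- utils::head(sets[[stage]][[sweep]], n_per_class)
    }
  }
  # pooled mix: one fifth of each stage per class
  per_stage <- floor(n_per_class / length(stages))
  mix <- list(hard = list(), soft = list())
  for (stage in stages) {
    mix$hard <- c(mix$hard, utils::head(sets[[stage]]$hard, per_stage))
    mix$soft <- c(mix$soft, utils::head(sets[[stage]]$soft, per_stage))
  }
  neutral <- neutral_background(
    if (is.na(config$Nm)) "m0NB" else stop("neutral set needs panmictic config"),
    n_regions = n_neutral, sample_size = sample_size,
    seed = derive_seeds(seed, 1, stream = 12)
  )
  structure(list(stages = sets, mix = mix, neutral = neutral,
                 n_per_class = n_per_class, sample_size = sample_size,
                 config = config, seed = seed),
            class = "training_sets")
}

#' Locate a snapshot of a run by stage (and trigger deme)
#'
#' @param run A `scenario_run`.
#' @param stage Stage label (`"f80s"`, `"t1Kr"`, `"f100s"`, `"neutral"`...).
#' @param deme Trigger deme (ignored for global/panmictic stages).
#' @return The snapshot, or `NULL` when absent.
#' @export
find_snapshot <- function(run, stage, deme = NULL) {
  if (stage == "neutral") return(run$initial)
  for (snap in run$snapshots) {
    if (snap$stage != stage) next
    if (!is.null(deme) && snap$trigger_deme != 0 &&
        snap$trigger_deme != deme) next
    return(snap)
  }
  NULL
}
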