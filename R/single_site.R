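#' Deme specification for single-site trajectory simulations
#'
#' Describes a subdivided haploid Wright-Fisher population for the
#' single-locus simulator: 1-3 demes, per-deme sizes and selection
#' coefficients, and a migration topology. `Nm` is the expected number of
#' migrant chromosomes per generation per direction along each edge of the
#' topology; the per-individual migration rate into deme i is `Nm / Ne_i`.
#'
#' Topologies: `"one"` (a single panmictic deme, no migration), `"two"`
#' (d1 -- d2; the allele arises in d1), `"connected"` (all pairs of d0,
#' d1, d2), `"forked"` (d0 -- d1 and d0 -- d2) and `"stepping"`
#' (d0 -- d1 -- d2). In three-deme topologies the allele arises in d0.
#'
#' @param Ne Haploid deme sizes; length 1, 2 or 3 (d0 first for three demes).
#' @param s Per-deme selection coefficients, same length as `Ne`.
#' @param Nm Migrants per generation per direction per edge (0 isolates).
#' @param topology One of `"one"`, `"two"`, `"connected"`, `"forked"`,
#'   `"stepping"`.
#' @return An object of class `deme_spec`.
#' @export
deme_spec <- function(Ne = c(10000, 10000), s = c(0.02, 0.02), Nm = 2,
                      topology = c("two", "one", "connected", "forked",
                                   "stepping")) {
  topology <- match.arg(topology)
  n <- switch(topology, one = 1L, two = 2L, 3L)
  Ne <- as.integer(rep_len(Ne, n))
  s <- rep_len(s, n)
  if (any(Ne < 2)) stop("Ne must be >= 2 in every deme")
  if (any(s < 0)) stop("selection coefficients must be >= 0")
  if (Nm < 0) stop("Nm must be non-negative (0 isolates the demes)")
  edges <- switch(topology,
    one       = matrix(integer(0), 0, 2),
    two       = rbind(c(1L, 2L)),
    connected = rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L)),
    forked    = rbind(c(1L, 2L), c(1L, 3L)),
    stepping  = rbind(c(1L, 2L), c(2L, 3L))
  )
  structure(
    list(Ne = Ne, s = s, Nm = Nm, topology = topology, edges = edges,
         origin = 1L),
    class = "deme_spec"
  )
}

# Row-stochastic migration mixing matrix:
# p'_i = p_i + sum_edges (Nm/Ne_i) (p_j - p_i).
migration_matrix <- function(spec) {
  n <- length(spec$Ne)
  W <- diag(n)
  for (k in seq_len(nrow(spec$edges))) {
    i <- spec$edges[k, 1]; j <- spec$edges[k, 2]
    W[i, j] <- W[i, j] + spec$Nm / spec$Ne[i]
    W[j, i] <- W[j, i] + spec$Nm / spec$Ne[j]
    W[i, i] <- W[i, i] - spec$Nm / spec$Ne[i]
    W[j, j] <- W[j, j] - spec$Nm / spec$Ne[j]
  }
  if (any(diag(W) < 0)) stop("migration rate exceeds 1 per generation; reduce Nm")
  W
}

# One Wright-Fisher generation for a batch of runs. `counts` is an
# R x D integer matrix of adaptive-allele counts; returns the updated
# matrix. Event order: deterministic migration mixing of frequencies,
# deterministic haploid selection p(1+s)/(1+ps), one binomial draw per deme.
wf_step <- function(counts, spec, W = migration_matrix(spec)) {
  R <- nrow(counts); D <- ncol(counts)
  p <- counts %*% diag(1 / spec$Ne, D)
  p <- p %*% t(W)
  s <- matrix(spec$s, R, D, byrow = TRUE)
  p <- p * (1 + s) / (1 + p * s)
  matrix(
    stats::rbinom(R * D, size = rep(spec$Ne, each = R),
                  prob = pmin(pmax(p, 0), 1)),
    R, D
  )
}

#' Simulate the frequency trajectory of one adaptive allele
#'
#' Forward-in-time haploid Wright-Fisher simulation of a single adaptive
#' mutation in a subdivided population, with per-generation deterministic
#' migration and selection and binomial drift. The allele arises as a
#' single copy in the origin deme (d1 for one/two demes, d0 for three).
#' A run in which the allele is lost everywhere is discarded, so every
#' completed trajectory is conditioned on global fixation; the simulation
#' terminates at global fixation or at `max_gen`.
#'
#' Two clock conventions are supported. The default, `clock = "origin"`,
#' keeps the generation counter running across discarded attempts: after a
#' loss the mutation recurs as a single copy and time accumulates, so
#' reported times are totals from the beginning of the simulation and
#' include the waiting period before the successful lineage arises (the
#' loss generations appear as zero-frequency rows in the trajectory).
#' `clock = "lineage"` restarts the clock with each attempt, so times are
#' measured from the origin of the successful lineage only.
#'
#' @param spec A [deme_spec()].
#' @param seed Integer seed.
#' @param max_gen Generation cap; runs hitting it are flagged truncated.
#' @param clock `"origin"` (default) or `"lineage"`; see Details.
#' @return A list of class `trajectory`: `freq` (generations x demes
#'   frequency matrix, generation 0 in row 1), `origin`, `fixed`,
#'   `truncated`, `n_restarts`, `clock`, `seed`.
#' @export
simulate_single_site <- function(spec, seed, max_gen = 1e6,
                                 clock = c("origin", "lineage")) {
  stopifnot(inherits(spec, "deme_spec"))
  clock <- match.arg(clock)
  W <- migration_matrix(spec)
  D <- length(spec$Ne)
  set.seed(seed)
  counts <- matrix(0L, 1, D)
  counts[1, spec$origin] <- 1L
  freq <- matrix(counts / spec$Ne, 1, D)
  gen <- 0L
  n_restarts <- 0L
  repeat {
    if (all(counts == matrix(spec$Ne, 1))) {
      fixed <- TRUE; truncated <- FALSE; break
    }
    if (gen >= max_gen) {
      fixed <- FALSE; truncated <- TRUE; break
    }
    counts <- wf_step(counts, spec, W)
    gen <- gen + 1L
    if (all(counts == 0L)) {
      n_restarts <- n_restarts + 1L
      if (clock == "lineage") {
        gen <- 0L
        freq <- matrix(0, 0, D)
      } else {
        freq <- rbind(freq, counts / spec$Ne)  # record the empty generation
      }
      counts[1, spec$origin] <- 1L
      if (clock == "lineage") freq <- rbind(freq, counts / spec$Ne)
      next
    }
    freq <- rbind(freq, counts / spec$Ne)
  }
  structure(list(freq = freq, origin = spec$origin, fixed = fixed,
                 truncated = truncated, n_restarts = n_restarts,
                 clock = clock, seed = seed),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d generations, %d deme(s), %s (%d restart%s, %s clock)\n",
              nrow(x$freq) - 1L, ncol(x$freq),
              if (x$fixed) "fixed" else "truncated",
              x$n_restarts, if (x$n_restarts == 1) "" else "s", x$clock))
  invisible(x)
}

#' Timing summary of a trajectory
#'
#' First-passage generations at 5% and 99.5% allele frequency per deme,
#' the selection-phase length (their difference), and the waiting period:
#' the last generation in which the watched demes (d1 and d2; all demes
#' but d0 in three-deme runs) carry no copy of the adaptive allele.
#' Thresholds never reached (possible only in truncated runs) yield `NA`
#' without error.
#'
#' @param traj A `trajectory` from [simulate_single_site()].
#' @return A one-row data.frame with columns `t5_d*`, `t995_d*`,
#'   `phase_d*` per deme plus `waiting_period`.
#' @export
summarize_timing <- function(traj) {
  freq <- traj$freq
  gens <- seq_len(nrow(freq)) - 1L
  D <- ncol(freq)
  first_passage <- function(col, thr) {
    i <- which(col >= thr)[1]
    if (is.na(i)) NA_real_ else gens[i]
  }
  t5 <- vapply(seq_len(D), function(d) first_passage(freq[, d], 0.05), 0)
  t995 <- vapply(seq_len(D), function(d) first_passage(freq[, d], 0.995), 0)
  watched <- if (D == 3) 2:3 else seq_len(D)
  empty <- rowSums(freq[, watched, drop = FALSE]) == 0
  waiting <- if (any(empty)) max(gens[empty]) else 0
  out <- data.frame(t(c(t5, t995, t995 - t5)), waiting_period = waiting)
  names(out) <- timing_colnames(D)
  out
}

timing_colnames <- function(D) {
  deme_names <- switch(as.character(D), "1" = "d1", "2" = c("d1", "d2"),
                       "3" = c("d0", "d1", "d2"))
  c(paste0("t5_", deme_names), paste0("t995_", deme_names),
    paste0("phase_", deme_names), "waiting_period")
}

#' Batch of conditioned single-site runs, timing only
#'
#' Runs `reps` replicates of [simulate_single_site()] dynamics vectorised
#' across replicates, recording first-passage times instead of full
#' trajectories (identical per-generation updates via the shared
#' [wf_step()] kernel). Lost runs recur in place, so each finished
#' replicate is conditioned on global fixation; the clock conventions are
#' as in [simulate_single_site()].
#'
#' @param spec A [deme_spec()].
#' @param reps Number of conditioned replicates.
#' @param seed Integer seed.
#' @param max_gen Per-replicate generation cap; capped runs are reported
#'   truncated with `NA` timings where thresholds were not reached.
#' @param clock `"origin"` (default) or `"lineage"`.
#' @return A data.frame with one row per replicate: timing columns as in
#'   [summarize_timing()], plus `rep`, `n_restarts`, `truncated`.
#' @export
run_timing_batch <- function(spec, reps, seed, max_gen = 1e6,
                             clock = c("origin", "lineage")) {
  stopifnot(inherits(spec, "deme_spec"), reps >= 1)
  clock <- match.arg(clock)
  W <- migration_matrix(spec)
  D <- length(spec$Ne)
  set.seed(seed)
  counts <- matrix(0L, reps, D)
  counts[, spec$origin] <- 1L
  gen <- integer(reps)
  t5 <- matrix(NA_real_, reps, D)
  t995 <- matrix(NA_real_, reps, D)
  last_empty <- numeric(reps)
  n_restarts <- integer(reps)
  active <- rep(TRUE, reps)
  truncated <- rep(FALSE, reps)
  watched <- if (D == 3) 2:3 else seq_len(D)
  while (any(active)) {
    idx <- which(active)
    counts[idx, ] <- wf_step(counts[idx, , drop = FALSE], spec, W)
    gen[idx] <- gen[idx] + 1L
    lost <- idx[rowSums(counts[idx, , drop = FALSE]) == 0]
    if (length(lost)) {
      n_restarts[lost] <- n_restarts[lost] + 1L
      if (clock == "lineage") {
        gen[lost] <- 0L
        t5[lost, ] <- NA_real_
        t995[lost, ] <- NA_real_
        last_empty[lost] <- 0
      } else {
        last_empty[lost] <- gen[lost]
      }
      counts[lost, spec$origin] <- 1L
    }
    idx2 <- setdiff(idx, lost)
    if (length(idx2)) {
      p <- counts[idx2, , drop = FALSE] %*% diag(1 / spec$Ne, D)
      for (d in seq_len(D)) {
        hit <- is.na(t5[idx2, d]) & p[, d] >= 0.05
        t5[idx2[hit], d] <- gen[idx2[hit]]
        hit <- is.na(t995[idx2, d]) & p[, d] >= 0.995
        t995[idx2[hit], d] <- gen[idx2[hit]]
      }
      if (D == 3) {
        empty_watch <- rowSums(counts[idx2, watched, drop = FALSE]) == 0
        some <- idx2[empty_watch]
        last_empty[some] <- gen[some]
      }
      fixed <- idx2[rowSums(counts[idx2, , drop = FALSE] ==
                              matrix(spec$Ne, length(idx2), D, byrow = TRUE)) == D]
      active[fixed] <- FALSE
    }
    capped <- idx[gen[idx] >= max_gen & active[idx]]
    if (length(capped)) {
      truncated[capped] <- TRUE
      active[capped] <- FALSE
    }
  }
  out <- data.frame(rep = seq_len(reps), t5, t995, t995 - t5,
                    waiting_period = last_empty,
                    n_restarts = n_restarts, truncated = truncated)
  names(out)[2:(2 + 3 * D)] <- timing_colnames(D)
  out
}
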