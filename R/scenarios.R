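#' Simulation scenarios of the two-deme genomic study
#'
#' The genomic experiment comprises seven selection scenarios and four
#' neutral backgrounds. Codes follow the pattern `m<Nm><G|L|NB>`: the
#' number is the expected migrants per generation per direction, `G` is
#' global adaptation (s = 0.02 in both demes), `L` is local adaptation
#' (s = 0.02 in d1, neutral in d2) and `NB` a neutral background.
#' `m0G`/`m0NB` are panmictic with Ne = 20,000 haploid chromosomes;
#' all subdivided scenarios have two demes of Ne = 10,000 each.
#'
#' Selection scenarios use 100 replicates with 50 resampled samples per
#' snapshot; two-deme scenarios have 22 time points (the initial neutral
#' state plus 21 in-run snapshots), the panmictic one 12 per-deme time
#' points, and `m0.2L` 200 fixed-interval snapshots (every 100 generations
#' for 20,000 generations). Neutral backgrounds use 2,500 two-deme
#' replicates -- each deme used as an independent sample, effectively
#' 5,000 -- or 5,000 panmictic replicates.
#'
#' @param code Optional scenario code; if given, the single matching
#'   configuration is returned (error for unknown codes).
#' @param lambda Rescaling factor (>= 1) applied via [rescale_config()].
#' @param master_seed Master seed recorded in the configuration.
#'
#' @return A data-frame-like list of `scenario_config` objects, or a single
#'   one when `code` is supplied.
#' @export
scenario_table <- function(code = NULL, lambda = 1, master_seed = 1L) {
  base <- list(
    mu = 0.006, cc = 0.006, region_length = 600000, sel_pos = 100000,
    sample_size = 50L, lambda = 1, master_seed = as.integer(master_seed)
  )
  mk <- function(code, Nm, s1, s2, n_demes, Ne, replicates, resamples,
                 time_points, kind, schedule = "frequency") {
    cfg <- c(base, list(
      code = code, Nm = Nm, s = c(s1, s2)[seq_len(max(1, n_demes))],
      n_demes = n_demes, Ne = rep(Ne, max(1, n_demes)),
      m = if (n_demes >= 2) Nm / Ne else 0,
      replicates = replicates, resamples = resamples,
      time_points = time_points, kind = kind, schedule = schedule
    ))
    structure(cfg, class = "scenario_config")
  }
  tab <- list(
    m20G  = mk("m20G",  20,  0.02, 0.02, 2, 10000, 100, 50, 22, "global"),
    m2G   = mk("m2G",    2,  0.02, 0.02, 2, 10000, 100, 50, 22, "global"),
    m0.2G = mk("m0.2G", 0.2, 0.02, 0.02, 2, 10000, 100, 50, 22, "global"),
    m0G   = mk("m0G",    NA, 0.02, 0.02, 1, 20000, 100, 50, 12, "global"),
    m20L  = mk("m20L",  20,  0.02, 0,    2, 10000, 100, 50, 22, "local"),
    m2L   = mk("m2L",    2,  0.02, 0,    2, 10000, 100, 50, 22, "local"),
    m0.2L = mk("m0.2L", 0.2, 0.02, 0,    2, 10000, 100, 50, 200, "local",
               schedule = "interval"),
    m20NB  = mk("m20NB",  20,  0, 0, 2, 10000, 2500, 1, 1, "neutral"),
    m2NB   = mk("m2NB",    2,  0, 0, 2, 10000, 2500, 1, 1, "neutral"),
    m0.2NB = mk("m0.2NB", 0.2, 0, 0, 2, 10000, 2500, 1, 1, "neutral"),
    m0NB   = mk("m0NB",    NA, 0, 0, 1, 20000, 5000, 1, 1, "neutral")
  )
  if (lambda != 1) tab <- lapply(tab, rescale_config, lambda = lambda)
  if (is.null(code)) return(tab)
  if (!code %in% names(tab)) stop(sprintf("unknown scenario code '%s'", code))
  tab[[code]]
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "scenario %s: %d deme(s) of Ne=%s, Nm=%s, s=(%s), %d replicates x %d resamples, %d time points%s\n",
    x$code, x$n_demes, paste(x$Ne, collapse = "/"),
    ifelse(is.na(x$Nm), "panmictic", format(x$Nm)),
    paste(format(x$s), collapse = ", "),
    x$replicates, x$resamples, x$time_points,
    if (x$lambda != 1) sprintf(" [rescaled, lambda=%g]", x$lambda) else ""
  ))
  invisible(x)
}

#' Rescale a scenario configuration for faster simulation
#'
#' Classical population-genetic rescaling by a factor `lambda`: deme sizes
#' are divided by `lambda` while s, m, mu and c are multiplied by it, so
#' that the compound parameters Ne*s, Ne*m (= Nm), Ne*mu and Ne*c are
#' preserved. Time is compressed by `lambda`; generation counts reported
#' from a rescaled run are comparable to the full-scale model after
#' multiplying by `lambda`. Rescaling is refused when `s * lambda >= 0.5`,
#' where the weak-selection equivalence underlying the scaling breaks down.
#'
#' @param config A `scenario_config` from [scenario_table()].
#' @param lambda Rescaling factor, >= 1.
#' @return The rescaled configuration (with `lambda` recorded).
#' @export
rescale_config <- function(config, lambda) {
  stopifnot(inherits(config, "scenario_config"), lambda >= 1)
  if (lambda == 1) return(config)
  if (any(config$s * lambda >= 0.5)) {
    stop("s * lambda >= 0.5: rescaling would leave the weak-selection regime")
  }
  config$Ne <- as.integer(round(config$Ne / lambda))
  config$s <- config$s * lambda
  config$m <- min(config$m * lambda, 1)
  config$mu <- config$mu * lambda
  config$cc <- config$cc * lambda
  config$lambda <- config$lambda * lambda
  config
}

#' Derive per-replicate seeds from a master seed
#'
#' Deterministic counter-based derivation (an LCG over the Mersenne prime
#' 2^31 - 1) that does not touch R's global RNG state. Seeds are reported
#' alongside results so any replicate can be re-run in isolation.
#'
#' @param master_seed Integer master seed.
#' @param n Number of seeds to derive.
#' @param stream Offset separating independent consumers of the same
#'   master seed.
#' @return An integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(master_seed, n, stream = 0) {
  mod <- 2147483647
  counter <- stream * 1e6 + seq_len(n)
  x <- (as.double(master_seed) %% mod) + 1
  seeds <- (x * 48271 + counter * 16807) %% mod
  as.integer(seeds %% (mod - 1) + 1)
}

#' Read a scenario configuration from a key-value file
#'
#' A plain text file with one `key = value` (or `key: value`) pair per
#' line defining `code` (required), `lambda` and `seed`; blank lines and
#' `#` comments are ignored. Returns the matching (rescaled, seeded)
#' configuration from [scenario_table()].
#'
#' @param path File path or character vector of lines.
#' @return A `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  lines <- if (length(path) == 1 && !grepl("\n", path) && file.exists(path)) {
    readLines(path)
  } else unlist(strsplit(path, "\n"))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*[=:]\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  if (!"code" %in% names(vals)) stop("config must define 'code'")
  scenario_table(vals[["code"]],
                 lambda = if ("lambda" %in% names(vals))
                   as.numeric(vals[["lambda"]]) else 1,
                 master_seed = if ("seed" %in% names(vals))
                   as.integer(vals[["seed"]]) else 1L)
}
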