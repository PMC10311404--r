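#' Describe one coalescent simulation scenario
#'
#' A `sim_config` bundles every parameter of the built-in coalescent
#' simulator: sample size, region length, population-scaled mutation and
#' recombination rates, stepwise demographic size changes, a continent-island
#' migration model with a ghost continent, recombination hotspots, and an
#' optional hard complete selective sweep.
#'
#' Time is expressed backward from the present in units of `4*N0` generations,
#' where `N0 = pop_size` is the present-day (island) diploid effective size.
#' `theta = 4*N0*mu` and `rho = 4*N0*r` refer to the whole region.
#'
#' @param n_samples number of haplotypes sampled (2..64).
#' @param region_len region length in bp.
#' @param theta population mutation rate for the region (> 0).
#' @param rho population recombination rate for the region (>= 0).
#' @param epochs optional data frame with columns `time` (4N0 generations,
#'   strictly increasing) and `size` (relative to `N0`): stepwise size
#'   changes applied backward in time, as with the ms `-eN` option.
#' @param migration optional list describing a continent-island model with a
#'   ghost (unsampled) continent: `M` (`4*Nc*m`, the scaled rate at which the
#'   island receives continental migrants), `size_ratio` (continent size as a
#'   multiple of the island size), `join_time` (backward time at which the
#'   island merges into the continent) and `join_units` (`"4Nc"` or `"4N0"`,
#'   default `"4Nc"`).
#' @param hotspots optional data frame with columns `start`, `end` (bp, within
#'   the region, non-overlapping) and `intensity` (>= 1): local multipliers of
#'   the background recombination rate, msHOT-style.
#' @param sweep optional list with `s` (selection coefficient per generation,
#'   > 0), `start_time` (backward time, 4N0 generations, at which the sweep
#'   completed) and `position` (bp of the selected site).
#' @param pop_size present-day diploid effective population size used to
#'   convert between coalescent units and generations (default 50000).
#' @param label optional free-text scenario name.
#'
#' @return an object of class `sim_config`.
#' @seealso [simulate_ms()], [sweep_trajectory()], [preset_config()]
#' @export
sim_config <- function(n_samples = 20, region_len = 1e5, theta = 2000,
                       rho = 0, epochs = NULL, migration = NULL,
                       hotspots = NULL, sweep = NULL, pop_size = 50000,
                       label = NULL) {
  stopifnot(n_samples >= 2, n_samples <= 64, region_len >= 1, pop_size >= 2)
  if (!is.numeric(theta) || theta <= 0) stop("theta must be > 0")
  if (!is.numeric(rho) || rho < 0) stop("rho must be >= 0")
  if (!is.null(epochs)) {
    epochs <- as.data.frame(epochs)
    stopifnot(all(c("time", "size") %in% names(epochs)))
    if (any(epochs$time <= 0) || is.unsorted(epochs$time, strictly = TRUE))
      stop("epoch times must be positive and strictly increasing")
    if (any(epochs$size <= 0)) stop("epoch sizes must be > 0")
  }
  if (!is.null(migration)) {
    migration <- modifyList(list(M = 3, size_ratio = 20, join_time = NULL,
                                 join_units = "4Nc"), migration)
    if (is.null(migration$join_time)) stop("migration needs a join_time")
    stopifnot(migration$M >= 0, migration$size_ratio > 0,
              migration$join_time > 0,
              migration$join_units %in% c("4Nc", "4N0"))
  }
  if (!is.null(hotspots)) {
    hotspots <- as.data.frame(hotspots)
    stopifnot(all(c("start", "end", "intensity") %in% names(hotspots)))
    hotspots <- hotspots[order(hotspots$start), , drop = FALSE]
    if (any(hotspots$start < 0) || any(hotspots$end > region_len) ||
        any(hotspots$end <= hotspots$start))
      stop("hotspot intervals must lie within [0, region_len]")
    if (nrow(hotspots) > 1 &&
        any(hotspots$start[-1] < hotspots$end[-nrow(hotspots)]))
      stop("hotspot intervals must not overlap")
    if (any(hotspots$intensity < 1)) stop("hotspot intensity must be >= 1")
  }
  if (!is.null(sweep)) {
    sweep <- modifyList(list(s = 0.02, start_time = 0.005,
                             position = region_len / 2), sweep)
    if (sweep$s <= 0) stop("selection coefficient s must be > 0")
    stopifnot(sweep$start_time > 0)
    if (sweep$position < 0 || sweep$position > region_len)
      stop("sweep position must be within the region")
  }
  structure(list(n_samples = as.integer(n_samples), region_len = region_len,
                 theta = theta, rho = rho, epochs = epochs,
                 migration = migration, hotspots = hotspots, sweep = sweep,
                 pop_size = pop_size, label = label),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Coalescent scenario", if (!is.null(x$label)) paste0("'", x$label, "'"),
      "\n")
  cat(sprintf("  n = %d haplotypes, region %g bp, theta = %g, rho = %g\n",
              x$n_samples, x$region_len, x$theta, x$rho))
  if (!is.null(x$epochs))
    cat("  size changes at t =", paste(x$epochs$time, collapse = ", "),
        "to", paste(x$epochs$size, collapse = ", "), "\n")
  if (!is.null(x$migration))
    cat(sprintf("  ghost continent: M = %g, %gx island size, join at %g (%s)\n",
                x$migration$M, x$migration$size_ratio, x$migration$join_time,
                x$migration$join_units))
  if (!is.null(x$hotspots))
    cat(sprintf("  %d recombination hotspot(s), intensity %s\n",
                nrow(x$hotspots), paste(x$hotspots$intensity, collapse = "/")))
  if (!is.null(x$sweep))
    cat(sprintf("  hard sweep: s = %g at %g bp, completed %g x 4N0 gen ago\n",
                x$sweep$s, x$sweep$position, x$sweep$start_time))
  invisible(x)
}

#' Deterministic logistic frequency trajectory of a hard complete sweep
#'
#' The beneficial allele follows the deterministic logistic path of genic
#' selection, `dx/dt = s x (1 - x)` with `t` in generations, from an initial
#' frequency of `1/(2N)` to fixation. The trajectory is anchored so that
#' fixation occurs `start_time` generations before the present; the sojourn
#' time between `1/(2N)` and `1 - 1/(2N)` is `(2/s) * log(2N - 1)`
#' generations (about 1151 generations for `s = 0.02`, `N = 50000`).
#'
#' @param s selection coefficient per generation (> 0).
#' @param pop_size diploid population size `N` (>= 2).
#' @param start_time time before present, in generations, at which the sweep
#'   completed (frequency reached 1).
#' @param n_grid number of points of the uniform time grid.
#' @return a data frame of class `sweep_trajectory` with columns `time_ago`
#'   (generations before present, decreasing) and `freq` (non-decreasing
#'   forward in time; last value exactly 1).
#' @export
sweep_trajectory <- function(s, pop_size, start_time, n_grid = 1000) {
  if (!is.numeric(s) || length(s) != 1 || s <= 0)
    stop("invalid selection coefficient: s must be > 0")
  stopifnot(pop_size >= 2, start_time >= 0, n_grid >= 2)
  x0 <- 1 / (2 * pop_size)
  dur <- sweep_duration(s, pop_size)
  tau <- seq(0, dur, length.out = n_grid)       # forward time since origin
  freq <- logistic_freq(tau, s, x0)
  freq[n_grid] <- 1
  out <- data.frame(time_ago = start_time + dur - tau, freq = freq)
  class(out) <- c("sweep_trajectory", "data.frame")
  attr(out, "s") <- s
  attr(out, "pop_size") <- pop_size
  attr(out, "duration") <- dur
  out
}

# sojourn time of the logistic path between 1/(2N) and 1 - 1/(2N), generations
sweep_duration <- function(s, pop_size) {
  (2 / s) * log(2 * pop_size - 1)
}

logistic_freq <- function(tau, s, x0) {
  1 / (1 + ((1 - x0) / x0) * exp(-s * tau))
}

# backward piecewise-constant frequency grid handed to the C++ simulator:
# value j covers the j-th backward sub-interval after fixation
traj_backward_grid <- function(s, pop_size, n_grid = 1000) {
  x0 <- 1 / (2 * pop_size)
  dur <- sweep_duration(s, pop_size)
  tau <- dur * (1 - (seq_len(n_grid) - 0.5) / n_grid)
  pmin(pmax(logistic_freq(tau, s, x0), x0), 1 - x0)
}

#' Simulate replicates under a coalescent scenario
#'
#' Draws independent replicates of the ancestral recombination graph under the
#' demography, migration, recombination map and (optionally) the hard-sweep
#' conditioning described by `config`, places mutations under the
#' infinite-sites model, and returns Hudson-ms-style replicates with relative
#' positions in `[0, 1]` and 0/1 haplotype rows.
#'
#' Sweeps are simulated with a structured coalescent conditioned on the
#' deterministic logistic trajectory of [sweep_trajectory()]: within the sweep
#' phase, lineages carry the allelic class at the selected site, coalesce only
#' within their class at a rate inversely proportional to the class frequency,
#' and recombination between a lineage's ancestral material and the selected
#' site moves the lineage onto a random background. Hotspots multiply the
#' local recombination rate inside their interval.
#'
#' @param config a [sim_config()].
#' @param n_reps number of replicates (>= 1).
#' @param seed optional integer seed (sets R's RNG; identical config + seed
#'   gives identical output).
#' @return a list of `ms_rep` objects (`positions`, `haplotypes`,
#'   `region_len`), with the generating command line in attribute `command`.
#' @examples
#' reps <- simulate_ms(sim_config(n_samples = 4, theta = 5), 2, seed = 1)
#' length(reps)
#' @export
simulate_ms <- function(config, n_reps, seed = NULL) {
  stopifnot(inherits(config, "sim_config"), n_reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  L <- config$region_len

  # recombination intensity map over [0, 1]
  if (is.null(config$hotspots)) {
    breaks <- c(0, 1); lam <- 1
  } else {
    h <- config$hotspots
    breaks <- sort(unique(c(0, h$start / L, h$end / L, 1)))
    lam <- rep(1, length(breaks) - 1)
    mid <- (breaks[-length(breaks)] + breaks[-1]) / 2
    for (i in seq_len(nrow(h)))
      lam[mid > h$start[i] / L & mid < h$end[i] / L] <- h$intensity[i]
  }

  epochs <- if (is.null(config$epochs)) {
    matrix(numeric(0), ncol = 2)
  } else {
    cbind(config$epochs$time, config$epochs$size)
  }

  mig_rate <- -1; cont_size <- 1; join_time <- -1
  if (!is.null(config$migration)) {
    m <- config$migration
    # M = 4*Nc*m converts to a per-lineage backward rate of M / size_ratio
    # in 4*N0 (island) time units
    mig_rate <- m$M / m$size_ratio
    cont_size <- m$size_ratio
    join_time <- if (m$join_units == "4Nc") m$join_time * m$size_ratio
                 else m$join_time
  }

  has_sweep <- !is.null(config$sweep)
  sweep_pos <- 0.5; sweep_end <- 0; sweep_dur <- 0; traj <- numeric(0)
  if (has_sweep) {
    sw <- config$sweep
    sweep_pos <- sw$position / L
    sweep_end <- sw$start_time
    sweep_dur <- sweep_duration(sw$s, config$pop_size) / (4 * config$pop_size)
    traj <- traj_backward_grid(sw$s, config$pop_size)
  }

  raw <- .sim_coalescent_cpp(config$n_samples, config$theta, config$rho,
                             breaks, lam, epochs, mig_rate, cont_size,
                             join_time, has_sweep, sweep_pos, sweep_end,
                             sweep_dur, traj, as.integer(n_reps))
  reps <- lapply(raw, function(r) {
    structure(list(positions = r$positions,
                   haplotypes = r$haplotypes,
                   region_len = L),
              class = "ms_rep")
  })
  attr(reps, "command") <- sim_command(config, n_reps)
  attr(reps, "config") <- config
  reps
}

# ms-like command line recorded in written files
sim_command <- function(config, n_reps) {
  parts <- c("sweepcnn-sim", config$n_samples, n_reps,
             "-t", config$theta, "-r", config$rho, config$region_len)
  if (!is.null(config$epochs))
    for (i in seq_len(nrow(config$epochs)))
      parts <- c(parts, "-eN", config$epochs$time[i], config$epochs$size[i])
  if (!is.null(config$migration))
    parts <- c(parts, "-I", config$migration$M, config$migration$size_ratio,
               "-ej", config$migration$join_time, config$migration$join_units)
  if (!is.null(config$hotspots))
    for (i in seq_len(nrow(config$hotspots)))
      parts <- c(parts, "-v", config$hotspots$start[i],
                 config$hotspots$end[i], config$hotspots$intensity[i])
  if (!is.null(config$sweep))
    parts <- c(parts, "-s", config$sweep$s, "-sp", config$sweep$position,
               "-st", config$sweep$start_time)
  paste(parts, collapse = " ")
}

#' @export
print.ms_rep <- function(x, ...) {
  cat(sprintf("ms replicate: %d haplotypes x %d segregating sites (%g bp)\n",
              nrow(x$haplotypes), length(x$positions), x$region_len))
  invisible(x)
}
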