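# The 101 named evolutionary models shipped with the package, grouped into
# four families. Published values: the fixed parameters (selection
# coefficient 0.02; sweep completion times; theta = rho = 2000 over a 100-kb
# region for the migration/hotspot families; sample size 20) and the
# parameter ranges per family. Where only a range is printed, the per-model
# grids below are this package's choice (documented in the methods
# vignette): log-spaced join times 0.003..3 for the migration family, and
# intensity grids {2,3,5,10,20,50,100} (neutral hotspots) and
# {2,5,10,15,20} (sweep + hotspot).

mig_join_times <- function() signif(exp(seq(log(0.003), log(3),
                                            length.out = 10)), 3)

hot_intensities <- c(2, 3, 5, 10, 20, 50, 100)
sweep_hot_intensities <- c(2, 5, 10, 15, 20)

#' Catalog of the named evolutionary models
#'
#' @return a data frame with one row per named model (`dataset-1` ..
#'   `dataset-101`): family, confounder parameters, and whether the model
#'   contains a selective sweep.
#' @export
dataset_presets <- function() {
  rows <- list()
  # 1-60: bottleneck (+ sweep); severity/onset/duration vary over the
  # published ranges and must be supplied per model
  for (i in 1:60)
    rows[[i]] <- data.frame(name = paste0("dataset-", i),
                            family = "bottleneck", sweep = TRUE,
                            parameter = NA_real_)
  # 61-70: continent-island migration (+ sweep), join time varies
  tm <- mig_join_times()
  for (k in 1:10)
    rows[[60 + k]] <- data.frame(name = paste0("dataset-", 60 + k),
                                 family = "migration", sweep = TRUE,
                                 parameter = tm[k])
  # 71-91: neutral recombination hotspots; three size layouts x 7 intensities
  layouts <- c("5kb", "10kb", "3x5kb")
  idx <- 71
  for (l in layouts) for (v in hot_intensities) {
    rows[[idx]] <- data.frame(name = paste0("dataset-", idx),
                              family = paste0("hotspot-", l), sweep = FALSE,
                              parameter = v)
    idx <- idx + 1
  }
  # 92-101: sweep + 5-kb hotspot; sweep inside (50 kb) then outside (30 kb)
  for (loc in c(50000, 30000)) for (v in sweep_hot_intensities) {
    rows[[idx]] <- data.frame(name = paste0("dataset-", idx),
                              family = sprintf("sweep%s-hotspot",
                                               if (loc == 50000) "-in"
                                               else "-out"),
                              sweep = TRUE, parameter = v)
    idx <- idx + 1
  }
  do.call(rbind, rows)
}

#' Build the simulation configs of a named model
#'
#' Returns the neutral and (when the model has one) selection scenario of a
#' named model. The bottleneck family prints only parameter ranges, so
#' `severity`, `begin` and `duration` must be supplied for `dataset-1` ..
#' `dataset-60`.
#'
#' @param name model name, `"dataset-1"` .. `"dataset-101"`.
#' @param theta,rho population-scaled rates for the region (the published
#'   experiments use 2000; smaller values give faster desk-scale runs).
#' @param n_samples sample size (haplotypes).
#' @param region_len region length in bp.
#' @param severity,begin,duration bottleneck parameters (relative size;
#'   onset and duration in 4N0 generations), required for the bottleneck
#'   family. Published ranges: severity 0.005-0.5, begin 0.004-0.1,
#'   duration 0.0004-0.002.
#' @param pop_size present-day diploid size for trajectory anchoring.
#' @return a list with elements `neutral` and `selection` (the latter NULL
#'   for sweep-free models), each a [sim_config()].
#' @export
preset_config <- function(name, theta = 2000, rho = 2000, n_samples = 20,
                          region_len = 1e5, severity = NULL, begin = NULL,
                          duration = NULL, pop_size = 50000) {
  cat_tab <- dataset_presets()
  row <- cat_tab[cat_tab$name == name, ]
  if (!nrow(row)) stop("unknown model: ", name)
  fam <- row$family
  base <- list(n_samples = n_samples, region_len = region_len,
               theta = theta, rho = rho, pop_size = pop_size)
  sweep_center <- list(s = 0.02, start_time = 0.005,
                       position = region_len / 2)
  if (fam == "bottleneck") {
    if (is.null(severity) || is.null(begin) || is.null(duration))
      stop("bottleneck models need severity, begin and duration ",
           "(only ranges are published per model)")
    epochs <- data.frame(time = c(begin, begin + duration),
                         size = c(severity, 1))
    sw <- modifyList(sweep_center, list(start_time = 0.016))
    neutral <- do.call(sim_config, c(base, list(epochs = epochs,
                                                label = name)))
    selection <- do.call(sim_config, c(base, list(epochs = epochs,
                                                  sweep = sw, label = name)))
  } else if (fam == "migration") {
    mig <- list(M = 3, size_ratio = 20, join_time = row$parameter,
                join_units = "4Nc")
    neutral <- do.call(sim_config, c(base, list(migration = mig,
                                                label = name)))
    selection <- do.call(sim_config, c(base, list(migration = mig,
                                                  sweep = sweep_center,
                                                  label = name)))
  } else if (startsWith(fam, "hotspot")) {
    hs <- switch(sub("hotspot-", "", fam),
      "5kb" = data.frame(start = region_len / 2 - 2500,
                         end = region_len / 2 + 2500,
                         intensity = row$parameter),
      "10kb" = data.frame(start = region_len / 2 - 5000,
                          end = region_len / 2 + 5000,
                          intensity = row$parameter),
      "3x5kb" = data.frame(start = c(0.25, 0.5, 0.75) * region_len - 2500,
                           end = c(0.25, 0.5, 0.75) * region_len + 2500,
                           intensity = row$parameter))
    neutral <- do.call(sim_config, c(base, list(hotspots = hs,
                                                label = name)))
    selection <- NULL
  } else {  # sweep +- 5-kb central hotspot
    hs <- data.frame(start = region_len / 2 - 2500,
                     end = region_len / 2 + 2500,
                     intensity = row$parameter)
    pos <- if (fam == "sweep-in-hotspot") region_len / 2
           else 0.3 * region_len
    neutral <- do.call(sim_config, c(base, list(hotspots = hs,
                                                label = name)))
    selection <- do.call(sim_config, c(base, list(
      hotspots = hs, sweep = modifyList(sweep_center, list(position = pos)),
      label = name)))
  }
  list(neutral = neutral, selection = selection)
}
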