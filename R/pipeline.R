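# End-to-end pipeline: simulate -> train -> scan -> evaluate, with a
# reproducibility manifest. Configs can come from R lists or YAML files.

#' Run the full detection pipeline
#'
#' Simulates training and test data under a neutral and a selection
#' scenario, trains the window classifier, scans every test replicate into a
#' selection profile, and writes the evaluation report. The artifact layout
#' under `out_dir` is `manifest.json`, `simulations/`, `model/`,
#' `profiles/`, `eval/`; the manifest (config, seed, package version) is
#' written before any computation.
#'
#' Training images are non-overlapping width-`W` windows drawn evenly from
#' each training replicate (both classes), mirroring how scan-grade models
#' are trained; `train_windows` controls how many per replicate.
#'
#' @param config a list (or YAML file path) with entries `model`
#'   (a preset name, see [preset_config()]) or `neutral`/`selection`
#'   [sim_config()] objects, and optional `n_train`, `n_test`, `epochs`,
#'   `width`, `scan_step`, `profile_k`, `train_windows`, `theta`, `rho`,
#'   `fpr`, `arch` parameters.
#' @param out_dir output directory.
#' @param seed integer seed governing the whole run.
#' @param force overwrite a partially existing output directory.
#' @param dry_run write the manifest only.
#' @return the evaluation report (invisibly for dry runs).
#' @export
run_pipeline <- function(config, out_dir, seed = 1, force = FALSE,
                         dry_run = FALSE) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  defaults <- list(n_train = 100, n_test = 50, epochs = 6, width = 50,
                   scan_step = 5, profile_k = 5, train_windows = 10,
                   theta = 100, rho = 100, fpr = 0.05)
  config <- modifyList(defaults, config)
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force)
    stop("output directory ", out_dir,
         " already contains files (use force = TRUE)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(config = config[!vapply(config, is.function, TRUE)],
                   seed = seed,
                   package = as.character(utils::packageVersion("sweepcnn")),
                   created = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  manifest$config <- rapply(manifest$config, function(x)
    if (inherits(x, "sim_config")) unclass(x) else x, how = "replace")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  if (dry_run) return(invisible(NULL))

  if (!is.null(config$model)) {
    pc <- preset_config(config$model, theta = config$theta,
                        rho = config$rho)
    neutral <- pc$neutral; selection <- pc$selection
  } else {
    neutral <- config$neutral; selection <- config$selection
  }
  if (is.null(neutral) || is.null(selection))
    stop("config must provide a neutral and a selection scenario")

  for (d in c("simulations", "model", "profiles", "eval"))
    dir.create(file.path(out_dir, d), showWarnings = FALSE)

  set.seed(seed)
  seeds <- sample.int(2^31 - 1, 6)
  message("simulating training data (", config$n_train, " + ",
          config$n_train, " replicates)")
  train_n <- simulate_ms(neutral, config$n_train, seed = seeds[1])
  train_s <- simulate_ms(selection, config$n_train, seed = seeds[2])
  write_ms(train_n, file.path(out_dir, "simulations", "train_neutral.ms"))
  write_ms(train_s, file.path(out_dir, "simulations", "train_selection.ms"))

  tr <- training_images(list(neutral = train_n, selection = train_s),
                        width = config$width,
                        per_rep = config$train_windows)
  message("training CNN (", dim(tr$images)[3], " images, ",
          config$epochs, " epochs)")
  arch <- if (is.null(config$arch)) cnn_arch() else config$arch
  model <- fit_sweep_cnn(tr$images, tr$labels, arch = arch,
                         epochs = config$epochs, seed = seeds[3])
  save_sweep_cnn(model, file.path(out_dir, "model"))

  message("scanning test replicates (", config$n_test, " + ",
          config$n_test, ")")
  test_n <- simulate_ms(neutral, config$n_test, seed = seeds[4])
  test_s <- simulate_ms(selection, config$n_test, seed = seeds[5])
  scan_set <- function(reps, tag) {
    scores <- numeric(length(reps)); locs <- rep(NA_real_, length(reps))
    for (i in seq_along(reps)) {
      R <- suppressWarnings(classify_windows(model, as_snp_matrix(reps[[i]]),
                                             step = config$scan_step))
      # a replicate too short to scan carries no selection evidence
      if (is.null(R)) { scores[i] <- 0; next }
      # short replicates get whatever smoothing they can support
      prof <- make_profile(R, k = min(config$profile_k, ncol(R)))
      cl <- call_sweep(prof)
      scores[i] <- cl$peak_prob; locs[i] <- cl$location_bp
      if (i <= 5)
        write_profile(prof, file.path(out_dir, "profiles",
                                      sprintf("%s_%03d.tsv", tag, i)))
    }
    list(scores = scores, locs = locs)
  }
  sn <- scan_set(test_n, "neutral")
  ss <- scan_set(test_s, "selection")

  report <- evaluate_scan(sn$scores, ss$scores, ss$locs,
                          true_target = selection$sweep$position,
                          region_len = selection$region_len,
                          fpr = config$fpr)
  jsonlite::write_json(unclass(report), file.path(out_dir, "eval",
                                                  "report.json"),
                       auto_unbox = TRUE, digits = NA)
  report
}

# assemble labeled training images: per replicate, up to per_rep
# non-overlapping width-W windows chosen evenly across the replicate.
# Sweep replicates carry fewer SNPs (hitchhiking removes variation), so the
# classes are rebalanced by downsampling the larger one.
training_images <- function(rep_sets, width = 50, per_rep = 10,
                            balance = TRUE) {
  imgs <- list(); labs <- character(0)
  for (lab in names(rep_sets)) {
    for (r in rep_sets[[lab]]) {
      m <- if (inherits(r, "ms_rep")) as_snp_matrix(r) else r
      w <- suppressWarnings(make_windows(m, width = width, step = width))
      if (!nrow(w)) next
      take <- unique(round(seq(1, nrow(w),
                               length.out = min(per_rep, nrow(w)))))
      imgs[[length(imgs) + 1]] <-
        encode_windows(m, w[take, , drop = FALSE])
      labs <- c(labs, rep(lab, length(take)))
    }
  }
  if (!length(imgs)) stop("no training windows could be generated")
  images <- bind_images(imgs)
  if (balance && length(unique(labs)) > 1) {
    n_min <- min(table(labs))
    keep <- sort(unlist(lapply(unique(labs), function(cl) {
      i <- which(labs == cl)
      if (length(i) > n_min) sample(i, n_min) else i
    })))
    images <- structure(images[, , keep, drop = FALSE],
                        class = "window_images")
    labs <- labs[keep]
  }
  list(images = images, labels = labs)
}
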