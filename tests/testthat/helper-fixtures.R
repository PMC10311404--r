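# Shared fixtures. Heavier objects (trained models, calibration scores) are
# built once per test run and cached, so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# linearly separable toy classes: all-black (neutral) vs all-gray (selection)
toy_images <- function(n = 200, H = 20, W = 50) {
  imgs <- array(0L, c(H, W, n))
  lab <- rep(c("neutral", "selection"), length.out = n)
  imgs[, , lab == "selection"] <- 127L
  list(images = structure(imgs, class = "window_images"), labels = lab)
}

get_toy_model <- function() cached("toy_model", {
  tv <- toy_images(200)
  fit_sweep_cnn(tv$images, tv$labels, epochs = 6, seed = 42)
})

# equilibrium scenarios at desk scale (theta = rho = 100 over 100 kb)
eq_neutral <- function() sim_config(n_samples = 20, theta = 100, rho = 100)
eq_sweep <- function()
  sim_config(n_samples = 20, theta = 100, rho = 100,
             sweep = list(s = 0.02, start_time = 0.005, position = 5e4))

# scan-grade model: neutral vs central hard sweep, no hotspots
get_sweep_model <- function() cached("sweep_model", {
  tn <- simulate_ms(eq_neutral(), 150, seed = 201)
  ts <- simulate_ms(eq_sweep(), 150, seed = 202)
  tr <- sweepcnn:::training_images(list(neutral = tn, selection = ts),
                                   width = 50, per_rep = 10)
  fit_sweep_cnn(tr$images, tr$labels, epochs = 6, seed = 203)
})

# hotspot-experiment scale: theta = rho = 200 so a 50-SNP window (~7 kb)
# resolves a 5-kb hotspot
eq_neutral200 <- function() sim_config(n_samples = 20, theta = 200,
                                       rho = 200)
eq_sweep200 <- function()
  sim_config(n_samples = 20, theta = 200, rho = 200,
             sweep = list(s = 0.02, start_time = 0.005, position = 5e4))

get_sweep_model200 <- function() cached("sweep_model200", {
  tn <- simulate_ms(eq_neutral200(), 150, seed = 211)
  ts <- simulate_ms(eq_sweep200(), 150, seed = 212)
  tr <- sweepcnn:::training_images(list(neutral = tn, selection = ts),
                                   width = 50, per_rep = 10)
  fit_sweep_cnn(tr$images, tr$labels, epochs = 6, seed = 213)
})

get_neutral_calibration200 <- function() cached("neutral_calib200", {
  reps <- simulate_ms(eq_neutral200(), 150, seed = 311)
  scan_scores(get_sweep_model200(), reps)$scores
})

# per-replicate scan scores (profile maxima) and peak locations; replicates
# too short to scan score 0 (no selection evidence) with no location
scan_scores <- function(model, reps, step = 10, k = 5) {
  out <- vapply(reps, function(r) {
    R <- suppressWarnings(classify_windows(model, as_snp_matrix(r),
                                           step = step))
    if (is.null(R)) return(c(0, NA_real_))
    prof <- make_profile(R, k = min(k, ncol(R)))
    cl <- call_sweep(prof)
    c(cl$peak_prob, cl$location_bp)
  }, numeric(2))
  list(scores = out[1, ], locs = out[2, ])
}

# neutral calibration scores for the equilibrium sweep model
get_neutral_calibration <- function() cached("neutral_calib", {
  reps <- simulate_ms(eq_neutral(), 100, seed = 301)
  scan_scores(get_sweep_model(), reps)$scores
})

# nucleotide diversity (pi) restricted to a relative position span
pi_in_span <- function(rep, lo, hi) {
  j <- which(rep$positions >= lo & rep$positions <= hi)
  if (!length(j)) return(0)
  h <- rep$haplotypes[, j, drop = FALSE]
  n <- nrow(h)
  p <- colMeans(h)
  sum(2 * p * (1 - p) * n / (n - 1))
}

# mean r^2 over site pairs drawn from two column index sets
mean_r2 <- function(hap, idx_a, idx_b, max_pairs = 200) {
  if (length(idx_a) < 1 || length(idx_b) < 1) return(NA_real_)
  pairs <- expand.grid(a = idx_a, b = idx_b)
  pairs <- pairs[pairs$a < pairs$b, , drop = FALSE]
  if (!nrow(pairs)) return(NA_real_)
  if (nrow(pairs) > max_pairs)
    pairs <- pairs[seq(1, nrow(pairs), length.out = max_pairs), ]
  r2 <- mapply(function(a, b) {
    x <- hap[, a]; y <- hap[, b]
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y)^2
  }, pairs$a, pairs$b)
  mean(r2, na.rm = TRUE)
}

# Tajima's D for a 0/1 haplotype matrix
tajima_d <- function(hap) {
  n <- nrow(hap); S <- ncol(hap)
  if (S == 0) return(NA_real_)
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  p <- colMeans(hap)
  pi <- sum(2 * p * (1 - p) * n / (n - 1))
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}
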