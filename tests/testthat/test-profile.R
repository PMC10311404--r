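# Profile averaging modes and sweep localization.

fake_windows <- function(centers, halfwidth = 500, region_len = 1e5) {
  w <- data.frame(window_index = seq_along(centers),
                  start_col = seq_along(centers),
                  end_col = seq_along(centers),
                  first_snp_bp = centers - halfwidth,
                  last_snp_bp = centers + halfwidth,
                  center_bp = centers)
  attr(w, "region_len") <- region_len
  w
}

fake_R <- function(p, windows) {
  R <- rbind(neutral = 1 - p, selection = p)
  attr(R, "windows") <- windows
  R
}

test_that("snp-mode averaging reproduces moving means and the identity
          case", {
  w <- fake_windows(c(10, 20, 30) * 1e3)
  p <- c(0.2, 0.4, 0.6)
  prof1 <- make_profile(fake_R(p, w), k = 1)
  expect_equal(prof1$prob, p)
  expect_equal(prof1$position_bp, w$center_bp)
  prof3 <- make_profile(fake_R(p, w), k = 3)
  expect_equal(nrow(prof3), 1)
  expect_equal(prof3$prob, 0.4)
  # midpoint of the covered span: first window start to last window end
  expect_equal(prof3$position_bp, (w$first_snp_bp[1] + w$last_snp_bp[3]) / 2)
  expect_error(make_profile(fake_R(p, w), k = 4), "outside")
})

test_that("position-mode averages windows within the bp span", {
  w <- fake_windows(c(10, 11, 30) * 1e3)
  p <- c(0.2, 0.6, 1.0)
  prof <- make_profile(fake_R(p, w), mode = "pos", span = 4000)
  expect_equal(prof$prob, c(0.4, 0.4, 1.0))
  expect_equal(prof$n_windows, c(2, 2, 1))
})

test_that("grid mode covers the contig and flags empty cells with NA", {
  w <- fake_windows(c(10, 20, 30) * 1e3)
  p <- c(0.2, 0.4, 0.9)
  # one point spanning the whole contig averages everything
  prof <- make_profile(fake_R(p, w), mode = "grid", grid = 1, span = 2e5)
  expect_equal(prof$prob, mean(p))
  # a fine grid leaves far-away cells empty (NA, not 0)
  prof2 <- make_profile(fake_R(p, w), mode = "grid", grid = 11, span = 2000)
  expect_true(any(is.na(prof2$prob)))
  expect_false(any(prof2$prob == 0, na.rm = TRUE))
  expect_error(make_profile(fake_R(p, w), mode = "grid", grid = 0), "grid")
})

test_that("profile averaging stays within the input probability range", {
  set.seed(8)
  for (i in 1:20) {
    L <- sample(5:40, 1)
    p <- runif(L)
    w <- fake_windows(sort(runif(L, 1, 1e5)))
    k <- sample(seq_len(L), 1)
    prof <- make_profile(fake_R(p, w), k = k)
    expect_gte(min(prof$prob), min(p))
    expect_lte(max(prof$prob), max(p))
    m2 <- make_profile(fake_R(p, w), mode = "pos", span = 5000)
    expect_gte(min(m2$prob), min(p))
    expect_lte(max(m2$prob), max(p))
  }
})

test_that("call_sweep takes the argmax, breaks ties leftward, and bounds the
          extent by the threshold", {
  w <- fake_windows(c(10, 20, 30, 40) * 1e3)
  cl <- call_sweep(make_profile(fake_R(c(0.1, 0.9, 0.8, 0.2), w), k = 1))
  expect_equal(cl$location_bp, 20000)
  expect_equal(unname(cl$extent), c(20000, 30000))
  expect_false(cl$tie)
  # flat profile: leftmost with the tie flag
  flat <- call_sweep(make_profile(fake_R(rep(0.7, 4), w), k = 1))
  expect_equal(flat$location_bp, 10000)
  expect_true(flat$tie)
  expect_error(call_sweep(data.frame(position_bp = 1, prob = NA)),
               "no data")
})

test_that("smoothing improves localization on strong sweeps", {
  model <- get_sweep_model()
  reps <- simulate_ms(eq_sweep(), 100, seed = 601)
  err <- sapply(c(1, 10), function(k) {
    locs <- vapply(reps, function(r) {
      R <- suppressWarnings(classify_windows(model, as_snp_matrix(r),
                                             step = 2))
      if (is.null(R) || ncol(R) < k) return(NA_real_)
      call_sweep(make_profile(R, k = k))$location_bp
    }, numeric(1))
    median(abs(locs - 5e4), na.rm = TRUE)
  })
  expect_lte(err[2], err[1])
})
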