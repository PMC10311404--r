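# The coalescent simulator against closed forms, an independent coalescent
# implementation, and the classic hitchhiking signatures.

test_that("sweep trajectory is a complete logistic path with the closed-form
          sojourn time", {
  tr <- sweep_trajectory(0.02, 50000, start_time = 3200)
  expect_equal(tail(tr$freq, 1), 1)
  expect_lte(tr$freq[1], 1 / (2 * 50000) + 1e-6)
  expect_true(all(diff(tr$freq) >= 0))        # forward-time monotone
  dur <- attr(tr, "duration")
  # independent closed form: (2/s) * log(2N) ~ 1151 generations
  expect_lt(abs(dur - (2 / 0.02) * log(2 * 50000)) /
            ((2 / 0.02) * log(2 * 50000)), 0.1)
  expect_equal(min(tr$time_ago), 3200)
  expect_error(sweep_trajectory(-0.1, 1000, 100), "s must be > 0")
})

test_that("neutral simulator matches Watterson's E[S] and equilibrium
          Tajima's D", {
  reps <- simulate_ms(sim_config(n_samples = 2, theta = 1, rho = 0),
                      20000, seed = 11)
  S <- vapply(reps, function(r) length(r$positions), numeric(1))
  # E[S] = theta * a_1 = 1, Var[S] = theta * a1 + theta^2 * b1 = 2
  expect_lt(abs(mean(S) - 1), 3 * sqrt(2 / 20000))

  reps10 <- simulate_ms(sim_config(n_samples = 10, theta = 5, rho = 0),
                        2000, seed = 12)
  S10 <- vapply(reps10, function(r) length(r$positions), numeric(1))
  a9 <- sum(1 / 1:9)
  expect_lt(abs(mean(S10) - 5 * a9), 3 * sd(S10) / sqrt(2000))
  # Tajima's D is centred near zero; the exact statistic has a small
  # negative finite-sample expectation (about -0.1 at this n and theta,
  # matched by msprime in the oracle test below), so the band is absolute
  D <- vapply(reps10, function(r) tajima_d(r$haplotypes), numeric(1))
  D <- D[is.finite(D)]
  expect_lt(abs(mean(D)), 0.2)
})

test_that("identity bottleneck is indistinguishable from equilibrium", {
  eq <- simulate_ms(sim_config(n_samples = 10, theta = 10, rho = 0),
                    1000, seed = 21)
  bn <- simulate_ms(sim_config(n_samples = 10, theta = 10, rho = 0,
                               epochs = data.frame(time = c(0.01, 0.02, 0.1),
                                                   size = c(1, 1, 1))),
                    1000, seed = 22)
  S1 <- vapply(eq, function(r) length(r$positions), numeric(1))
  S2 <- vapply(bn, function(r) length(r$positions), numeric(1))
  expect_gt(suppressWarnings(ks.test(S1, S2))$p.value, 0.01)
})

test_that("segregating sites and Tajima's D agree with an independent
          coalescent implementation (msprime)", {
  script <- paste(
    "import msprime, numpy as np",
    "svals = []; dvals = []; i = 0",
    "for ts in msprime.sim_ancestry(samples=5, ploidy=2,",
    "        population_size=0.5, num_replicates=1000, random_seed=7):",
    "    i += 1",
    "    mts = msprime.sim_mutations(ts, rate=2.5, random_seed=1000+i,",
    "        model=msprime.BinaryMutationModel(), discrete_genome=False)",
    "    G = mts.genotype_matrix()",
    "    S = G.shape[0]; n = G.shape[1]",
    "    svals.append(S)",
    "    if S == 0:",
    "        dvals.append(float('nan')); continue",
    "    a1 = sum(1.0/k for k in range(1, n))",
    "    a2 = sum(1.0/k**2 for k in range(1, n))",
    "    b1 = (n+1)/(3*(n-1)); b2 = 2*(n*n+n+3)/(9*n*(n-1))",
    "    c1 = b1 - 1/a1; c2 = b2 - (n+2)/(a1*n) + a2/a1**2",
    "    e1 = c1/a1; e2 = c2/(a1**2+a2)",
    "    p = G.mean(axis=1)",
    "    pi = float((2*p*(1-p)*n/(n-1)).sum())",
    "    dvals.append((pi - S/a1)/np.sqrt(e1*S + e2*S*(S-1)))",
    "print(' '.join(str(v) for v in svals))",
    "print(' '.join(str(v) for v in dvals))",
    sep = "\n")
  out <- suppressWarnings(system2("python", "-", input = script,
                                  stdout = TRUE, stderr = FALSE))
  expect_gte(length(out), 2)  # the oracle must actually have run
  S_ref <- as.numeric(strsplit(out[1], " ")[[1]])
  D_ref <- suppressWarnings(as.numeric(strsplit(out[2], " ")[[1]]))
  D_ref <- D_ref[is.finite(D_ref)]
  # matching parameterization: n=10 haplotypes, theta = 4*N*mu = 5
  reps <- simulate_ms(sim_config(n_samples = 10, theta = 5, rho = 0),
                      1000, seed = 31)
  S <- vapply(reps, function(r) length(r$positions), numeric(1))
  expect_gt(suppressWarnings(ks.test(S, S_ref))$p.value, 0.01)
  D <- vapply(reps, function(r) tajima_d(r$haplotypes), numeric(1))
  D <- D[is.finite(D)]
  se <- sqrt(var(D) / length(D) + var(D_ref) / length(D_ref))
  expect_lt(abs(mean(D) - mean(D_ref)), 3 * se)
})

test_that("sweep replicates show the classic hitchhiking signatures", {
  sw <- simulate_ms(sim_config(n_samples = 20, theta = 100, rho = 50,
                               sweep = list(s = 0.02, start_time = 0.005,
                                            position = 5e4)),
                    200, seed = 41)
  # 1. diversity trough at the selected site
  ctr <- vapply(sw, pi_in_span, numeric(1), 0.45, 0.55)
  flk <- vapply(sw, function(r)
    (pi_in_span(r, 0, 0.1) + pi_in_span(r, 0.9, 1)) / 2, numeric(1))
  expect_lt(mean(ctr), mean(flk))

  # 2. excess of high-frequency derived variants relative to neutrality
  # (for a completed sweep the excess blankets the hitchhiking region;
  # the regenerating trough itself carries young, low-frequency variants)
  nt <- simulate_ms(sim_config(n_samples = 20, theta = 100, rho = 50),
                    200, seed = 42)
  hf <- function(r) {
    if (!length(r$positions)) return(c(0, 0))
    p <- colMeans(r$haplotypes)
    c(sum(p >= 0.75), length(p))
  }
  sw_hf <- rowSums(vapply(sw, hf, numeric(2)))
  nt_hf <- rowSums(vapply(nt, hf, numeric(2)))
  expect_gt(sw_hf[1] / sw_hf[2], nt_hf[1] / nt_hf[2])

  # 3. high LD within each flank, low LD across the selected site
  lds <- vapply(sw, function(r) {
    left <- which(r$positions < 0.4)
    right <- which(r$positions > 0.6)
    within <- mean(c(mean_r2(r$haplotypes, left, left, 100),
                     mean_r2(r$haplotypes, right, right, 100)), na.rm = TRUE)
    across <- mean_r2(r$haplotypes, left, right, 100)
    c(within, across)
  }, numeric(2))
  expect_gt(mean(lds[1, ], na.rm = TRUE), mean(lds[2, ], na.rm = TRUE))
})

test_that("hotspots concentrate recombination without changing diversity", {
  hot <- simulate_ms(sim_config(n_samples = 12, theta = 60, rho = 40,
                                hotspots = data.frame(start = 45000,
                                                      end = 55000,
                                                      intensity = 50)),
                     150, seed = 51)
  eq <- simulate_ms(sim_config(n_samples = 12, theta = 60, rho = 40),
                    150, seed = 52)
  S_hot <- vapply(hot, function(r) length(r$positions), numeric(1))
  S_eq <- vapply(eq, function(r) length(r$positions), numeric(1))
  # mutation process untouched by the recombination map
  expect_gt(suppressWarnings(t.test(S_hot, S_eq))$p.value, 1e-4)
  # LD decays faster across the hotspot than across a cold interval
  decay <- vapply(hot, function(r) {
    a <- which(r$positions > 0.40 & r$positions < 0.45)
    b <- which(r$positions > 0.55 & r$positions < 0.60)
    cold_a <- which(r$positions > 0.05 & r$positions < 0.10)
    cold_b <- which(r$positions > 0.20 & r$positions < 0.25)
    c(mean_r2(r$haplotypes, a, b, 50),
      mean_r2(r$haplotypes, cold_a, cold_b, 50))
  }, numeric(2))
  expect_lt(mean(decay[1, ], na.rm = TRUE), mean(decay[2, ], na.rm = TRUE))
})

test_that("identical config and seed give byte-identical ms output", {
  cfg <- sim_config(n_samples = 8, theta = 20, rho = 10,
                    sweep = list(s = 0.02, start_time = 0.01,
                                 position = 5e4))
  a <- write_ms(simulate_ms(cfg, 5, seed = 99))
  b <- write_ms(simulate_ms(cfg, 5, seed = 99))
  expect_identical(a, b)
  c <- write_ms(simulate_ms(cfg, 5, seed = 100))
  expect_false(identical(a, c))
})

test_that("invalid scenario parameters are rejected", {
  expect_error(sim_config(theta = 0), "theta")
  expect_error(sim_config(rho = -1), "rho")
  expect_error(sim_config(epochs = data.frame(time = c(2, 1),
                                              size = c(1, 1))),
               "strictly increasing")
  expect_error(sim_config(epochs = data.frame(time = 1, size = 0)),
               "size")
  expect_error(sim_config(hotspots = data.frame(start = 0, end = 2e5,
                                                intensity = 2)),
               "within")
  expect_error(sim_config(hotspots = data.frame(start = c(0, 500),
                                                end = c(1000, 1500),
                                                intensity = c(2, 2))),
               "overlap")
  expect_error(sim_config(sweep = list(s = -1)), "s must be > 0")
  expect_error(sim_config(sweep = list(position = 2e5)), "within the region")
})
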