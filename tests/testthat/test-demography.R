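test_that("Tajima's D matches an independent constant-by-constant transcription", {
  aln <- aln_from_strings(c("AAAAAAAAAA", "AAAAAAAAAT",
                            "AAAAAAAAGT", "AAAAAAAAAA"))
  got <- tajimas_d(aln, n_sim = 0)
  expect_equal(got$S, 2L)
  # oracle: fresh transcription of the constants for n = 4, S = 2
  n <- 4; S <- 2
  a1 <- 1 + 1/2 + 1/3
  a2 <- 1 + 1/4 + 1/9
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  d <- pairwise_differences(aln)
  pi_hat <- mean(d[upper.tri(d)])
  oracle <- (pi_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  expect_equal(got$D, oracle, tolerance = 1e-12)
  # no variation: flagged undefined
  flat <- tajimas_d(aln_from_strings(rep("AAAA", 5)), n_sim = 0)
  expect_true(is.na(flat$D))
  expect_match(flat$flags, "no segregating sites")
  expect_error(tajimas_d(aln[1:3, ]), "at least 4")
})

test_that("Tajima's D is centred near zero under neutral constant size", {
  cfg <- sim_config(n_pops = 1, samples_per_pop = 20, group_of_pop = "a",
                    deme_sizes = c(a = 10000), split_times_years = numeric(0),
                    indel_rate_rel = 0, seed = 1)
  D <- rep(NA_real_, 300)
  for (r in seq_along(D)) {
    ds <- simulate_sequences(cfg, seed = 5000 + r)
    res <- tajimas_d(ds$alignment, n_sim = 0)
    D[r] <- res$D
  }
  D <- D[!is.na(D)]
  # the exact null mean of D is slightly below 0; a generous band around 0
  expect_lt(abs(mean(D)), 0.15)
  # the simulation p-value is seed-stable
  ds <- simulate_sequences(cfg, seed = 123)
  p1 <- tajimas_d(ds$alignment, n_sim = 300, seed = 7)$p_value
  p2 <- tajimas_d(ds$alignment, n_sim = 300, seed = 7)$p_value
  expect_identical(p1, p2)
})

test_that("Fu's Fs equals exhaustive Ewens enumeration for n <= 8", {
  # oracle: tabulate unsigned Stirling numbers by the textbook recurrence
  # in plain arithmetic, then enumerate the Ewens distribution directly
  stirling_table <- function(n) {
    s <- matrix(0, n, n)
    s[1, 1] <- 1
    if (n > 1) for (m in 2:n) {
      for (k in 1:m) {
        s[m, k] <- (if (k > 1) s[m - 1, k - 1] else 0) + (m - 1) * s[m - 1, k]
      }
    }
    s[n, ]
  }
  for (n in c(4, 6, 8)) {
    for (theta in c(0.5, 1, 3)) {
      st <- stirling_table(n)
      pk <- st * theta^(seq_len(n)) / prod(theta + 0:(n - 1))
      expect_equal(sum(pk), 1, tolerance = 1e-12)
      for (k_obs in 2:n) {
        sp <- sum(pk[k_obs:n])
        oracle_fs <- log(sp / (1 - sp))
        got <- fus_fs(n, k_obs, theta)
        expect_equal(got$Fs, oracle_fs, tolerance = 1e-9,
                     info = sprintf("n=%d k=%d theta=%g", n, k_obs, theta))
      }
    }
  }
  # logit identity: S' = 0.5 -> Fs = 0 (verified through the inverse)
  got <- fus_fs(5, 2, 1)
  expect_equal(got$Fs, log(got$S_prime / (1 - got$S_prime)), tolerance = 1e-12)
  # k = 1 makes S' = 1 and Fs unbounded, flagged
  inf_case <- fus_fs(5, 1, 1)
  expect_true(is.infinite(inf_case$Fs))
  expect_true(length(inf_case$flags) > 0)
})

test_that("Fu's Fs is strongly negative under simulated expansion", {
  set.seed(20)
  hits <- 0L
  for (r in 1:50) {
    # 100-fold expansion: theta0 = 0.2 -> theta1 = 20, recent in
    # mutational time
    br <- phylorefugia:::.sim_coal_branches(30, theta1 = 20, theta0 = 0.2,
                                            tau = 6)
    dd <- phylorefugia:::.pair_diffs_from_branches(
      br, phylorefugia:::.branch_mutations(br))
    theta_pi <- mean(dd[upper.tri(dd)])
    # distinct haplotypes = distinct difference profiles under infinite sites
    k <- length(unique(apply(dd, 1, paste, collapse = ",")))
    if (theta_pi <= 0) next
    res <- fus_fs(30, k, theta_pi, n_sim = 200)
    if (is.finite(res$Fs) && res$Fs < 0 && res$p_value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 40L)
})

test_that("expected mismatch distribution integrates to one and nests equilibria", {
  for (par in list(c(0, 2, 2), c(3, 0.5, 8), c(8, 0.1, 40), c(1.5, 1, 1))) {
    s <- sum(mismatch_expected(0:600, par[1], par[2], par[3]))
    expect_equal(s, 1, tolerance = 1e-8,
                 info = paste(par, collapse = "/"))
  }
  # tau = 0 collapses to the old equilibrium, tau -> Inf to the new one
  eq <- function(i, th) th^i / (th + 1)^(i + 1)
  expect_equal(mismatch_expected(0:10, 0, 2, 9), eq(0:10, 2))
  expect_equal(mismatch_expected(0:10, 500, 2, 9), eq(0:10, 9),
               tolerance = 1e-10)
})

test_that("raggedness and degenerate mismatch cases follow the definitions", {
  expect_equal(raggedness(c(0.4, 0.3, 0.2, 0.1)), 0.03)
  same <- aln_from_strings(rep("ACGT", 5))
  res <- mismatch_fit(same, n_bootstrap = 0)
  expect_equal(res$SSD, 0)
  expect_equal(res$tau, 0)
  expect_equal(unname(res$observed), 1)
  expect_equal(res$p_SSD, 1)
})

test_that("the SSD test does not reject true sudden expansions", {
  set.seed(21)
  ok <- 0L
  n_rep <- 50L
  for (r in seq_len(n_rep)) {
    br <- phylorefugia:::.sim_coal_branches(25, theta1 = 30, theta0 = 0.3,
                                            tau = 5)
    dd <- phylorefugia:::.pair_diffs_from_branches(
      br, phylorefugia:::.branch_mutations(br))
    # rebuild a pseudo-alignment-free path: feed the difference histogram
    # through the public fitter via a synthetic alignment is unnecessary;
    # use the internal fit + bootstrap machinery the public function uses
    ds <- dd[upper.tri(dd)]
    f <- tabulate(ds + 1L, nbins = max(ds) + 1L) / length(ds)
    if (length(f) < 2) next
    fit <- phylorefugia:::.fit_mismatch(f)
    ssd_sim <- numeric(60)
    for (b in 1:60) {
      brb <- phylorefugia:::.sim_coal_branches(25, theta1 = fit$theta1,
                                               theta0 = fit$theta0,
                                               tau = fit$tau)
      db <- phylorefugia:::.pair_diffs_from_branches(
        brb, phylorefugia:::.branch_mutations(brb))
      dsb <- db[upper.tri(db)]
      fb <- tabulate(dsb + 1L, nbins = max(dsb) + 1L) / length(dsb)
      if (length(fb) < 2) fb <- c(fb, 0)
      ssd_sim[b] <- phylorefugia:::.fit_mismatch(fb)$ssd
    }
    p <- (sum(ssd_sim >= fit$ssd) + 1) / 61
    if (p > 0.05) ok <- ok + 1L
  }
  expect_gte(ok, 40L)
})

test_that("mismatch_fit end-to-end on a simulated expansion alignment", {
  cfg <- sim_config(n_pops = 1, samples_per_pop = 25, group_of_pop = "a",
                    deme_sizes = c(a = 50000), split_times_years = numeric(0),
                    indel_rate_rel = 0, seed = 77)
  ds <- simulate_sequences(cfg)
  res <- mismatch_fit(ds$alignment, n_bootstrap = 100, seed = 3)
  expect_s3_class(res, "mismatch_result")
  expect_gte(res$tau, 0)
  expect_lte(res$theta0, res$theta1)
  expect_equal(sum(res$observed), 1, tolerance = 1e-12)
  expect_true(res$p_SSD >= 0 && res$p_SSD <= 1)
})
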