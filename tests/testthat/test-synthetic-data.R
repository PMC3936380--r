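test_that("sequence simulation is seed-deterministic down to the FASTA bytes", {
  cfg <- sim_config(n_pops = 6, samples_per_pop = rep(4, 6),
                    group_of_pop = rep(c("n", "s"), each = 3),
                    deme_sizes = c(n = 5000, s = 5000),
                    split_times_years = 5e5, seed = 21)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(simulate_sequences(cfg)$alignment, f1)
  write_alignment(simulate_sequences(cfg)$alignment, f2)
  expect_identical(readLines(f1), readLines(f2))
  # and a different seed gives a different dataset
  ds3 <- simulate_sequences(cfg, seed = 22)
  expect_false(identical(readLines(f1), {
    write_alignment(ds3$alignment, f2); readLines(f2)
  }))
})

test_that("simulated datasets are internally consistent", {
  cfg <- sim_config(seed = 2)
  ds <- simulate_sequences(cfg)
  expect_s3_class(ds, "synthetic_dataset")
  # every alignment record appears exactly once in the popmap, and the
  # genealogy tips are exactly the samples
  expect_setequal(rownames(ds$alignment), ds$pop_map$sample)
  expect_equal(anyDuplicated(ds$pop_map$sample), 0L)
  expect_setequal(ds$genealogy$tip.label, ds$pop_map$sample)
  expect_equal(nrow(ds$alignment), sum(cfg$samples_per_pop))
  expect_equal(ncol(ds$alignment), cfg$locus_length)
  # groups on the transect are separated by the barrier gap
  lon_by_group <- split(ds$pop_map$longitude, ds$pop_map$group)
  expect_gt(min(lon_by_group$south) - max(lon_by_group$north), 1)
})

test_that("deme sizes must match group labels", {
  expect_error(sim_config(n_pops = 4, samples_per_pop = rep(3, 4),
                          group_of_pop = rep(c("a", "b"), 2),
                          deme_sizes = c(x = 100, y = 100),
                          split_times_years = 1000),
               "group labels")
})

test_that("deep isolation makes every haplotype private to one group", {
  # two demes, no migration, split 10 Myr ago, tiny Ne: reciprocal
  # monophyly is near-certain, so no haplotype is shared across groups
  for (sd in 1:20) {
    cfg <- sim_config(n_pops = 4, samples_per_pop = rep(4, 4),
                      group_of_pop = c("a", "a", "b", "b"),
                      deme_sizes = c(a = 1000, b = 1000),
                      split_times_years = 1e7, seed = 100 + sd)
    ds <- simulate_sequences(cfg)
    ht <- collapse_haplotypes(ds$alignment, "fifth_state", ds$pop_map)
    grp <- unique(ds$pop_map[, c("population", "group")])
    by_group <- t(apply(ht$counts, 1, function(r)
      tapply(r, grp$group[match(colnames(ht$counts), grp$population)], sum)))
    shared <- sum(rowSums(by_group > 0) > 1)
    expect_equal(shared, 0L, info = paste("seed", 100 + sd))
  }
})

test_that("segregating sites scale with mu * L * tree length", {
  cfg <- sim_config(n_pops = 2, samples_per_pop = c(5, 5),
                    group_of_pop = c("g", "g"), deme_sizes = c(g = 20000),
                    split_times_years = numeric(0), indel_rate_rel = 0,
                    seed = 1)
  mu_gen <- cfg$mu_site_year * cfg$gen_time_years
  set.seed(5)
  S <- expected <- numeric(100)
  for (r in 1:100) {
    ds <- simulate_sequences(cfg, seed = 1000 + r)
    S[r] <- phylorefugia:::.segregating_sites(ds$alignment)
    expected[r] <- mu_gen * cfg$locus_length * sum(ds$genealogy$edge.length)
  }
  ratio <- mean(S) / mean(expected)
  # multiple hits can only lose sites; Poisson noise bounds the rest
  expect_gt(ratio, 0.9)
  expect_lt(ratio, 1.05)
})

test_that("niche simulation validates config and respects structure", {
  expect_error(niche_sim_config(n_occurrences = 2), ">= 3")
  bad_cov <- diag(3); bad_cov[1, 2] <- 0.5   # asymmetric
  expect_error(niche_sim_config(env_dim = 3,
                                lineage_cov = list(bad_cov, diag(3))),
               "symmetric")
  cfg <- niche_sim_config(n_occurrences = 50, n_background = 100,
                          env_dim = 4, seed = 9)
  nd <- simulate_niche_data(cfg)
  expect_equal(nrow(nd$occurrence), 100L)
  expect_equal(nrow(nd$background), 200L)
  expect_named(nd$occurrence,
               c("lineage", "lon", "lat", paste0("BIO", 1:4)))
  # determinism
  nd2 <- simulate_niche_data(cfg)
  expect_identical(nd, nd2)
  # the constructed mean shift appears on BIO1
  m <- tapply(nd$occurrence$BIO1, nd$occurrence$lineage, mean)
  expect_gt(m[["north"]], m[["south"]])
})

test_that("a constructed 10-SD separation on one variable is called divergence", {
  mns <- matrix(0, 2, 6); mns[1, 1] <- 5; mns[2, 1] <- -5
  cfg <- niche_sim_config(n_occurrences = 200, n_background = 500,
                          env_dim = 6, lineage_means = mns,
                          background_means = matrix(0, 2, 6),
                          background_cov = list(diag(6), diag(6)),
                          seed = 31)
  nd <- simulate_niche_data(cfg)
  env <- function(df, who) as.matrix(df[df$lineage == who, -(1:3)])
  res <- niche_divergence_test(env(nd$occurrence, "north"),
                               env(nd$occurrence, "south"),
                               env(nd$background, "north"),
                               env(nd$background, "south"),
                               n_axes = 3, seed = 5)
  # the axis loading BIO1 most strongly carries the divergence call
  ax <- attr(res, "axes")
  bio1_axis <- which.max(abs(ax$loadings["BIO1", 1:3]))
  expect_equal(res$call[bio1_axis], "divergence")
})
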