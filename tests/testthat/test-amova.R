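test_that("distance models agree with closed-form oracles", {
  aln <- aln_from_strings(c("ACGTACGTAC", "ACGTACGTAT"))
  expect_equal(pairwise_distance_matrix(aln)["s1", "s2"], 1)
  # degenerate base composition: TN93 undefined, falls back to raw
  expect_warning(
    d0 <- pairwise_distance_matrix(aln_from_strings(c("AAAA", "AAAA")),
                                   "tamura_nei"),
    "falling back")
  expect_equal(d0["s1", "s2"], 0)

  # TN93 closed form coded independently: distance from transition
  # proportions P1 (A<->G), P2 (C<->T) and transversions Q with the
  # stationary frequencies of the pooled pair
  s1 <- strsplit("ACGTACGTACGTACGTACGAACGTACGTGCGT", "")[[1]]
  s2 <- strsplit("ACGTACGCACGTATGTACGTACGCACGTACGT", "")[[1]]
  aln2 <- aln_from_strings(c(paste(s1, collapse = ""), paste(s2, collapse = "")))
  n <- length(s1)
  f <- table(factor(c(s1, s2), levels = c("A", "C", "G", "T"))) / (2 * n)
  gA <- f[["A"]]; gC <- f[["C"]]; gG <- f[["G"]]; gT <- f[["T"]]
  gR <- gA + gG; gY <- gC + gT
  P1 <- mean(s1 != s2 & ((s1 == "A" & s2 == "G") | (s1 == "G" & s2 == "A")))
  P2 <- mean(s1 != s2 & ((s1 == "C" & s2 == "T") | (s1 == "T" & s2 == "C")))
  Q <- mean(s1 != s2) - P1 - P2
  k1 <- 2 * gA * gG / gR; k2 <- 2 * gC * gT / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gC * gT * gR / gY)
  oracle <- -k1 * log(1 - P1 / k1 - Q / (2 * gR)) -
    k2 * log(1 - P2 / k2 - Q / (2 * gY)) -
    k3 * log(1 - Q / (2 * gR * gY))
  got <- pairwise_distance_matrix(aln2, "tamura_nei")["s1", "s2"] / n
  expect_equal(got, unname(oracle), tolerance = 1e-10)
})

test_that("AMOVA components equal the brute-force sums-of-squares oracle", {
  set.seed(10)
  for (rep in 1:5) {
    toy <- random_toy_distances(n_pops = 3, n_per_pop = 4)
    grouping <- stats::setNames(c("A", "A", "B"), unique(toy$pop))
    got <- phylorefugia:::.amova_components(toy$d, toy$pop, grouping)
    want <- oracle_amova(toy$d, toy$pop, grouping)
    expect_equal(unname(got$sigma[c("a", "b", "c")]), unname(want$sigma),
                 tolerance = 1e-12)
    expect_equal(got$indices[["F_CT"]], want$F_CT, tolerance = 1e-12)
    expect_equal(got$indices[["F_SC"]], want$F_SC, tolerance = 1e-12)
    expect_equal(got$indices[["F_ST"]], want$F_ST, tolerance = 1e-12)
    # two-level route
    got2 <- phylorefugia:::.amova_components(toy$d, toy$pop, NULL)
    want2 <- oracle_amova(toy$d, toy$pop, NULL)
    expect_equal(got2$indices[["F_ST"]], want2$F_ST, tolerance = 1e-12)
  }
})

test_that("AMOVA table bookkeeping and degenerate cases are correct", {
  aln <- aln_from_strings(c("AAAA", "AAAA", "AAAA", "TTTT", "TTTT", "TTTT"))
  pm <- toy_popmap(rownames(aln), rep(c("P1", "P2"), each = 3),
                   groups = rep(c("g1", "g2"), each = 3))
  d <- pairwise_distance_matrix(aln)
  # two single-population groups fixed for distinct haplotypes
  res <- amova(d, pm, grouping = TRUE)
  expect_equal(res$indices[["F_ST"]], 1)
  expect_equal(res$table$percent[res$table$source == "Among groups"], 100)
  expect_equal(sum(res$table$df[-nrow(res$table)]), nrow(d) - 1L)
  # identical sequences: no variance, indices flagged NA
  same <- aln_from_strings(rep("AAAA", 6))
  rs <- amova(pairwise_distance_matrix(same), pm)
  expect_true(is.na(rs$indices[["F_ST"]]))
  # percentages sum to 100
  toy <- random_toy_distances(4, 3)
  pm2 <- toy_popmap(rownames(toy$d), toy$pop)
  r2 <- amova(toy$d, pm2)
  expect_equal(sum(r2$table$percent[-nrow(r2$table)]), 100, tolerance = 0.01)
})

test_that("every-population-its-own-group reduces F_CT to the two-level F_ST", {
  set.seed(11)
  toy <- random_toy_distances(4, 3)
  grouping <- stats::setNames(paste0("G", 1:4), unique(toy$pop))
  three <- phylorefugia:::.amova_components(toy$d, toy$pop, grouping)
  two <- phylorefugia:::.amova_components(toy$d, toy$pop, NULL)
  expect_equal(three$indices[["F_CT"]], two$indices[["F_ST"]],
               tolerance = 1e-12)
})

test_that("permutation tests detect extreme structure and are seed-stable", {
  aln <- aln_from_strings(c(rep("AAAA", 6), rep("TTTT", 6)))
  pm <- toy_popmap(paste0("s", 1:12),
                   rep(c("P1", "P2", "P3", "P4"), each = 3),
                   groups = rep(c("g1", "g2"), each = 6))
  rownames(aln) <- pm$sample
  d <- pairwise_distance_matrix(aln)
  res <- amova(d, pm, grouping = TRUE, n_perm = 1000, seed = 3)
  expect_lte(res$p_values[["F_ST"]], 0.05)
  res2 <- amova(d, pm, grouping = TRUE, n_perm = 1000, seed = 3)
  expect_identical(res$p_values, res2$p_values)
})

test_that("p-values are calibrated under panmixia", {
  # populations drawn from one pool: P(F_ST) should be uniform, so
  # rejections at 0.05 stay near nominal over 50 replicates
  set.seed(12)
  rej <- 0L
  for (r in 1:50) {
    toy <- random_toy_distances(4, 4)
    pm <- toy_popmap(rownames(toy$d), toy$pop)
    p <- amova(toy$d, pm, n_perm = 99)$p_values[["F_ST"]]
    if (p <= 0.05) rej <- rej + 1L
  }
  expect_lte(rej, 8L)
})

test_that("Delaunay adjacency handles general and collinear layouts", {
  # unit square plus centre: the centre is adjacent to all corners
  pts <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(0.5, 0.5))
  rownames(pts) <- paste0("P", 1:5)
  adj <- delaunay_adjacency(pts)
  expect_true(all(adj["P5", c("P1", "P2", "P3", "P4")]))
  # opposite corners are not Delaunay neighbours (centre blocks them)
  expect_false(adj["P1", "P4"])
  # collinear: chain along the line
  line <- cbind(c(3, 1, 2, 5, 4), 0)
  rownames(line) <- paste0("P", 1:5)
  adjl <- delaunay_adjacency(line)
  expect_equal(sum(adjl) / 2, 4)
  # x-order is P2(1) P3(2) P1(3) P5(4) P4(5)
  expect_true(adjl["P2", "P3"] && adjl["P3", "P1"] &&
                adjl["P1", "P5"] && adjl["P5", "P4"])
})

test_that("SAMOVA finds the exhaustive-search optimum and respects contiguity", {
  cfg <- sim_config(n_pops = 8, samples_per_pop = rep(5, 8),
                    group_of_pop = rep(c("n", "s"), each = 4),
                    deme_sizes = c(n = 2000, s = 2000),
                    split_times_years = 2e6, seed = 14)
  ds <- simulate_sequences(cfg)
  d <- pairwise_distance_matrix(ds$alignment)
  res <- samova(d, ds$pop_map, K = 2, n_runs = 20, n_steps = 300, seed = 6)
  # oracle: exhaustive contiguous bipartitions scored by full amova()
  oracle <- oracle_best_bipartition(d, ds$pop_map, res$adjacency)
  expect_equal(res$phi_ct, oracle$phi_ct, tolerance = 1e-10)
  # the recovered split is the simulated one
  truth <- unique(ds$pop_map[, c("population", "group")])
  split_labels <- split(truth$group, res$assignment[truth$population])
  expect_true(all(lengths(lapply(split_labels, unique)) == 1))
  # groups are contiguous under the adjacency graph
  for (g in unique(res$assignment)) {
    S <- which(res$assignment == g)
    expect_true(phylorefugia:::.is_connected_subset(S, res$adjacency))
  }
  # phi_ct equals a fresh AMOVA on the returned assignment
  grouping <- stats::setNames(paste0("G", res$assignment),
                              names(res$assignment))
  expect_equal(res$phi_ct, amova(d, ds$pop_map, grouping)$indices[["F_CT"]],
               tolerance = 1e-10)
})

test_that("SAMOVA beats random contiguous partitions and degrades past true K", {
  cfg <- sim_config(n_pops = 9, samples_per_pop = rep(4, 9),
                    group_of_pop = rep(c("n", "s", "t"), each = 3),
                    deme_sizes = c(n = 2000, s = 2000, t = 2000),
                    split_times_years = c(3e6, 1.5e6), seed = 15)
  ds <- simulate_sequences(cfg)
  d <- pairwise_distance_matrix(ds$alignment)
  res3 <- samova(d, ds$pop_map, K = 3, n_runs = 15, n_steps = 300, seed = 7)
  # never worse than the best of 100 random contiguous partitions
  set.seed(8)
  pops <- unique(ds$pop_map$population)
  n_p <- table(factor(ds$pop_map$population, levels = pops))
  rand_best <- max(vapply(1:100, function(i) {
    a <- phylorefugia:::.random_contiguous_partition(res3$adjacency, 3L)
    grouping <- stats::setNames(paste0("G", a), pops)
    amova(d, ds$pop_map, grouping)$indices[["F_CT"]]
  }, numeric(1)))
  expect_gte(res3$phi_ct + 1e-10, rand_best)
  # past the true K the optimum cannot improve
  res4 <- samova(d, ds$pop_map, K = 4, n_runs = 15, n_steps = 300, seed = 9)
  expect_lte(res4$phi_ct, res3$phi_ct + 0.02)
  expect_error(samova(d, ds$pop_map, K = 9), "K must")
})
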