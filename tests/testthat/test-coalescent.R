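test_that("population models are validated", {
  expect_error(population_model(c(a = 0), c(a = 2)))
  expect_error(population_model(c(a = 10, b = 10), c(a = 2, b = 2)),
               "join events")
  expect_error(population_model(c(a = 10, b = 10), c(a = 2, b = 2),
                                joins = data.frame(time = -1, from = "a",
                                                   to = "b", size = 10)),
               "positive")
  m <- population_model(c(a = 10, b = 10), c(a = 2, b = 2),
                        joins = data.frame(time = 5, from = "a", to = "b",
                                           size = 20))
  expect_s3_class(m, "population_model")
})

test_that("pair TMRCA matches the single-deme coalescent expectation", {
  N <- 800
  m <- population_model(c(a = N), c(a = 2))
  set.seed(3)
  tm <- replicate(1000, max(ape::node.depth.edgelength(simulate_genealogy(m))))
  se <- sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - N), 3 * se)
})

test_that("a join at time zero is indistinguishable from one pooled deme", {
  m_join <- population_model(c(a = 500, b = 500), c(a = 4, b = 4),
                             joins = data.frame(time = 1e-9, from = "a",
                                                to = "b", size = 500))
  m_pool <- population_model(c(b = 500), c(b = 8))
  set.seed(4)
  t1 <- replicate(800, max(ape::node.depth.edgelength(simulate_genealogy(m_join))))
  t2 <- replicate(800, max(ape::node.depth.edgelength(simulate_genealogy(m_pool))))
  expect_gt(suppressWarnings(stats::ks.test(t1, t2)$p.value), 0.01)
})

test_that("deep splits yield reciprocal monophyly (s = 1)", {
  m <- population_model(c(a = 100, b = 100), c(a = 6, b = 6),
                        joins = data.frame(time = 2000, from = "a", to = "b",
                                           size = 100))
  set.seed(5)
  sv <- replicate(1000, phylorefugia:::.coalesce_core(m, "s"))
  expect_gte(mean(sv == 1), 0.95)
})

test_that("the s statistic handles the analytic cases", {
  m <- population_model(c(a = 100, b = 100), c(a = 4, b = 4),
                        joins = data.frame(time = 50, from = "a", to = "b",
                                           size = 100))
  tr <- simulate_genealogy(m, seed = 6)
  # all tips one label -> 0
  one <- stats::setNames(rep("x", 8), tr$tip.label)
  expect_equal(s_statistic(tr, one), 0)
  # reciprocally monophyletic two-label tree -> 1
  bal <- ape::read.tree(text = "(((a1,a2),(a3,a4)),((b1,b2),(b3,b4)));")
  labs <- stats::setNames(rep(c("A", "B"), each = 4), bal$tip.label)
  expect_equal(s_statistic(bal, labs), 1)
  # 8-tip caterpillar with alternating labels: exhaustive oracle
  cat8 <- ape::read.tree(text = "(t1,(t2,(t3,(t4,(t5,(t6,(t7,t8)))))));")
  labs8 <- stats::setNames(rep(c("A", "B"), 4), paste0("t", 1:8))
  expect_equal(s_statistic(cat8, labs8), oracle_fitch(cat8, labs8))
  expect_equal(s_statistic(cat8, labs8), 4)
  # unlabeled tip errors
  expect_error(s_statistic(bal, labs[1:6]), "unlabeled")
  # invariant to branch lengths
  tr2 <- tr
  tr2$edge.length <- tr2$edge.length * 1000 + 1
  expect_equal(s_statistic(tr2), s_statistic(tr))
})

test_that("the fast simulation path agrees with Fitch on the full genealogy", {
  m <- population_model(c(a = 300, b = 300), c(a = 7, b = 5),
                        joins = data.frame(time = 150, from = "a", to = "b",
                                           size = 600))
  for (sd in 1:25) {
    set.seed(sd)
    s_fast <- phylorefugia:::.coalesce_core(m, "s")
    set.seed(sd)
    tr <- simulate_genealogy(m)
    expect_equal(s_fast, s_statistic(tr), info = paste("seed", sd))
  }
})

test_that("simulated s decreases stochastically with deeper splits", {
  mk <- function(tgen) population_model(
    c(a = 1000, b = 1000), c(a = 8, b = 8),
    joins = data.frame(time = tgen, from = "a", to = "b", size = 1000))
  set.seed(7)
  means <- vapply(c(100, 1000, 10000), function(tg)
    mean(replicate(400, phylorefugia:::.coalesce_core(mk(tg), "s"))),
    numeric(1))
  expect_gt(means[1], means[2])
  expect_gt(means[2], means[3])
})

test_that("refugia_test applies the falls-outside decision rule", {
  sc <- scenario_fragmentation(1000, 34000, 34, c(a = 6, b = 6))
  # an observed value far above any simulated s must reject (the printed
  # observed statistic can be supplied directly)
  res_hi <- refugia_test(212, sc, n_sims = 300, seed = 8)
  expect_equal(res_hi$decision, "reject")
  # an observed genealogy simulated under the scenario itself is usually
  # compatible with it
  obs <- simulate_genealogy(sc, seed = 9)
  res <- refugia_test(obs, sc, n_sims = 300, seed = 10)
  expect_true(res$s_observed >= res$q2.5 - 1e-9 ||
                res$decision %in% c("reject", "fail_to_reject"))
  expect_s3_class(res, "refugia_test")
  expect_identical(
    refugia_test(obs, sc, n_sims = 200, seed = 11)$q97.5,
    refugia_test(obs, sc, n_sims = 200, seed = 11)$q97.5)
  # scenario with a deme absent from the observed labels errors
  sc_bad <- scenario_fragmentation(1000, 34000, 34, c(a = 6, zz = 6))
  expect_error(refugia_test(obs, sc_bad, n_sims = 10, seed = 1), "zz")
})

test_that("scenario presets encode the intended histories", {
  tw <- scenario_two_refugia(1e4, 120000, 34, c(n = 5, s = 5))
  expect_equal(unname(tw$deme_sizes), c(1e4, 1e4))
  expect_equal(tw$joins$size, 1e4)
  expect_equal(tw$joins$time, 120000 / 34)
  fr <- scenario_fragmentation(1e4, 120000, 34, c(n = 5, s = 5))
  expect_equal(unname(fr$deme_sizes), c(5e3, 5e3))
  expect_equal(fr$joins$size, 1e4)
})
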