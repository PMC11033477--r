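test_that("simulate_ct is deterministic and leaves the caller's RNG alone", {
  spec <- paper_like_design("tissues", seed = 42)
  set.seed(1); before <- rnorm(1)
  set.seed(1)
  s1 <- simulate_ct(spec)
  after <- rnorm(1)
  s2 <- simulate_ct(spec)
  expect_identical(s1$ct$ct, s2$ct$ct)
  expect_identical(s1$truth$disturbance, s2$truth$disturbance)
  expect_equal(before, after)   # RNG state restored
})

test_that("the noiseless limit returns baselines and zero stability", {
  spec <- simulation_spec(
    genes = data.frame(gene = c("A", "B", "C"), mu = c(20, 22, 24),
                       sigma = 0, delta = 0),
    groups = data.frame(label = c("g1", "g2"), n_biological = 3L,
                        n_technical = 1L),
    loading_sd = 0, seed = 9)
  sim <- simulate_ct(spec)
  expect_equal(unname(sim$ct$ct), matrix(rep(c(20, 22, 24), 6), 3))
  t <- sim$ct
  expect_equal(unname(delta_ct_stability(t)$values), rep(0, 3))
  expect_equal(unname(genorm(to_relative_quantities(t))$values), rep(0, 3))
  expect_equal(unname(bestkeeper(t)$values), rep(0, 3))
  expect_equal(unname(normfinder(t)$values), rep(0, 3))
  expect_equal(unname(sim$truth$disturbance), rep(0, 3))
})

test_that("paper_like_design shapes match the four study conditions", {
  shapes <- c(ages = 3L, tissues = 6L, temperature = 5L, sex = 2L)
  for (cond in names(shapes)) {
    spec <- paper_like_design(cond, seed = 5)
    expect_equal(nrow(spec$groups), shapes[[cond]])
    expect_true(all(spec$groups$n_biological == 3L))
    sim <- simulate_ct(spec)
    expect_equal(dim(sim$ct), c(10L, shapes[[cond]] * 3L))
    expect_identical(simulate_ct(paper_like_design(cond, seed = 5))$ct$ct,
                     sim$ct$ct)
  }
  expect_error(paper_like_design("hosts"), "arg")
  # designed separation: >= 3x between the 2 most and 2 least stable
  g <- paper_like_design("tissues")$genes
  nominal <- sqrt(g$sigma ^ 2 + g$delta ^ 2 * 5 / 6)  # E[v], 6 groups
  ord <- order(nominal)
  expect_gt(min(nominal[rev(ord)][1:2]) / max(nominal[ord][1:2]), 3)
})

test_that("spec validation names the offending field", {
  genes <- data.frame(gene = c("A", "B"), mu = c(20, 22), sigma = 0.1,
                      delta = 0.1)
  groups <- data.frame(label = "g", n_biological = 3L, n_technical = 1L)
  expect_error(simulation_spec(genes[1, ], groups), "genes")
  expect_error(simulation_spec(transform(genes, mu = c(3, 22)), groups),
               "mu")
  expect_error(simulation_spec(transform(genes, sigma = -1), groups),
               "sigma")
  expect_error(simulation_spec(genes, groups, loading_sd = -0.1),
               "loading_sd")
  expect_error(simulation_spec(genes, groups,
                               target_spec = list(gene = "T", mu = 24,
                                                  sigma = 0.1)),
               "target_spec")
})

test_that("technical replicates share a unit and aggregate cleanly", {
  spec <- paper_like_design("sex", seed = 3, n_technical = 3L)
  sim <- simulate_ct(spec)
  expect_equal(dim(sim$ct), c(10L, 18L))
  expect_equal(length(unique(sim$ct$replicate_of)), 6L)
  agg <- aggregate_replicates(sim$ct)
  expect_equal(dim(agg), c(10L, 6L))
})

test_that("loading shifts move BestKeeper but not the loading-invariant
           methods beyond noise", {
  base <- paper_like_design("tissues", seed = 77)
  quiet <- simulation_spec(base$genes, base$groups, loading_sd = 0,
                           seed = 77)
  loud <- simulation_spec(base$genes, base$groups, loading_sd = 2,
                          seed = 77)
  s0 <- simulate_ct(quiet); s2 <- simulate_ct(loud)
  # identical seed: same loading-free draws, so invariant methods agree
  expect_equal(delta_ct_stability(s2$ct)$values,
               delta_ct_stability(s0$ct)$values, tolerance = 1e-9)
  expect_equal(normfinder(s2$ct)$values, normfinder(s0$ct)$values,
               tolerance = 1e-9)
  expect_gt(mean(bestkeeper(s2$ct)$values), mean(bestkeeper(s0$ct)$values))
})

test_that("a simulated target's fold change is recovered by 2^-ddCt", {
  folds <- c(g1 = 1, g2 = 4)
  est <- vapply(1:200, function(s) {
    spec <- simulation_spec(
      genes = data.frame(gene = c("R1", "R2"), mu = c(18, 20),
                         sigma = 0.1, delta = 0),
      groups = data.frame(label = c("g1", "g2"), n_biological = 3L,
                          n_technical = 1L),
      loading_sd = 0.5, seed = s,
      target_spec = list(gene = "T", mu = 24, sigma = 0.15, fold = folds))
    sim <- simulate_ct(spec)
    re <- relative_expression(sim$ct, "T", c("R1", "R2"), calibrator = "g1")
    re$per_group$mean_rq[re$per_group$group == "g2"]
  }, numeric(1))
  expect_equal(mean(est), 4, tolerance = 0.15)
})
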