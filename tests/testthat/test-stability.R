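# hand-frozen values for the A/B/C table (see helper-fixtures.R):
# sd(B-A) = 0, sd(C-A) = sd(C-B) = sd(5, 5.4, 4.6, 5) = 0.3265986

test_that("delta-Ct stability reproduces the hand-worked table", {
  r <- delta_ct_stability(abc_table())
  expect_equal(unname(r$values), c(0.1632993, 0.1632993, 0.3265986),
               tolerance = 1e-6)
  expect_equal(unname(r$ranks), c(1L, 1L, 2L))
  expect_equal(r$details$pairwise_sd["A", "B"], 0)
  # identical rows score 0
  m <- rbind(A = c(20, 21, 22), B = c(20, 21, 22))
  colnames(m) <- paste0("s", 1:3)
  expect_equal(unname(delta_ct_stability(
    ct_table(m, groups = rep("g", 3)))$values), c(0, 0))
})

test_that("per-sample loading shifts cancel in delta-Ct and geNorm", {
  set.seed(11)
  for (i in 1:5) {
    t <- random_table()
    shift <- rnorm(ncol(t$ct), 0, 3)
    t2 <- t
    t2$ct <- sweep(t$ct, 2, -shift)
    expect_equal(delta_ct_stability(t2)$values, delta_ct_stability(t)$values)
    expect_equal(genorm(to_relative_quantities(t2))$values,
                 genorm(to_relative_quantities(t))$values)
    nf1 <- normfinder(t, use_groups = FALSE)
    nf2 <- normfinder(t2, use_groups = FALSE)
    expect_equal(nf1$values, nf2$values)
    # BestKeeper works on raw Ct, so its dispersion must change
    expect_false(isTRUE(all.equal(bestkeeper(t)$values,
                                  bestkeeper(t2)$values)))
  }
})

test_that("geNorm reproduces the hand-worked elimination and V series", {
  g <- genorm(to_relative_quantities(abc_table()))
  expect_equal(unname(g$details$initial_m["A"]), 0.1632993, tolerance = 1e-6)
  expect_equal(unname(g$details$initial_m["C"]), 0.3265986, tolerance = 1e-6)
  expect_equal(g$details$elimination_order, "C")
  expect_equal(g$details$final_pair, c("A", "B"))
  expect_equal(unname(g$ranks[c("A", "B")]), c(1L, 1L))
  expect_equal(unname(g$values["C"]), 0.3265986, tolerance = 1e-6)
  # independent V2/3: NF2 = sqrt(qA qB), NF3 = (qA qB qC)^(1/3)
  q <- to_relative_quantities(abc_table())$q
  nf2 <- sqrt(q["A", ] * q["B", ])
  nf3 <- (q["A", ] * q["B", ] * q["C", ]) ^ (1 / 3)
  expect_equal(unname(g$details$v_series["V2/3"]),
               sd(log2(nf2 / nf3)), tolerance = 1e-12)
  expect_equal(g$details$n_recommended, 2L)
})

test_that("duplicate genes form the geNorm final pair with M = 0", {
  m <- rbind(A = c(20, 21, 22, 23), B = c(20, 21, 22, 23),
             C = c(20, 25, 21, 24))
  colnames(m) <- paste0("s", 1:4)
  g <- genorm(to_relative_quantities(ct_table(m, groups = rep("g", 4))))
  expect_equal(g$details$final_pair, c("A", "B"))
  expect_equal(unname(g$values[c("A", "B")]), c(0, 0))
})

test_that("delta-Ct stability equals initial geNorm M at base 2", {
  set.seed(23)
  for (i in 1:20) {
    t <- random_table(n_genes = 5, n_samples = 8)
    expect_equal(delta_ct_stability(t)$values,
                 genorm(to_relative_quantities(t))$details$initial_m,
                 tolerance = 1e-9)
  }
})

test_that("NormFinder ungrouped reproduces the hand-worked centering", {
  nf <- suppressWarnings(normfinder(abc_table(), use_groups = TRUE))
  # z_A = (2.3333, 2.4667, 2.2, 2.3333); sd = 0.10887
  expect_equal(unname(nf$values["A"]), 0.1088662, tolerance = 1e-6)
  expect_false(nf$details$grouped)   # single group falls back, with warning
  expect_warning(normfinder(abc_table(), use_groups = TRUE), "one group")
  # a gene tracking the sample mean exactly scores 0
  m <- rbind(A = c(20, 21, 22), B = c(22, 23, 24), C = c(24, 25, 26))
  colnames(m) <- paste0("s", 1:3)
  nf0 <- normfinder(ct_table(m, groups = rep("g", 3)), use_groups = FALSE)
  expect_equal(unname(nf0$values), c(0, 0, 0))
  expect_equal(unname(nf0$ranks), c(1L, 1L, 1L))
})

test_that("grouped NormFinder: weighted deviations sum to zero, shrinkage
           vanishes without group effects", {
  set.seed(5)
  grp <- rep(c("g1", "g2", "g3"), each = 200)
  n <- length(grp)
  sig <- c(0.2, 0.3, 0.4, 0.25)
  m <- do.call(rbind, lapply(sig, function(s) 22 + rnorm(n, 0, s)))
  dimnames(m) <- list(paste0("G", 1:4), paste0("s", 1:n))
  t <- ct_table(m, groups = grp)
  nf <- normfinder(t)
  expect_true(nf$details$grouped)
  wsum <- nf$details$d_raw %*% nf$details$group_sizes
  expect_equal(max(abs(wsum)), 0, tolerance = 1e-9)
  # no true group effects at n_g = 200: tau2 ~ 0, so S ~ mean_g sqrt(s2/n)
  expect_equal(unname(nf$values),
               unname(rowMeans(sqrt(sweep(nf$details$group_vars, 2,
                                          nf$details$group_sizes, "/")))),
               tolerance = 0.05)
  expect_error(
    normfinder(ct_table(m[, 1:201], groups = c(grp[1:200], "lone"))),
    "lone")
})

test_that("BestKeeper reproduces hand-worked descriptives and index", {
  bk <- bestkeeper(abc_table())
  expect_equal(unname(bk$values["A"]), 0.08164966, tolerance = 1e-6)
  expect_equal(unname(bk$details$index["s1"]), (20 * 22 * 25) ^ (1 / 3),
               tolerance = 1e-9)
  d <- bk$details$descriptives
  expect_true(all(d$min_ct <= d$geo_mean_ct & d$geo_mean_ct <= d$mean_ct &
                    d$mean_ct <= d$max_ct))
  expect_true(all(abs(bk$details$correlations$r) <= 1, na.rm = TRUE))
  bk2 <- bestkeeper(abc_table(), dispersion = "mean_abs_dev")
  expect_equal(unname(bk2$values["A"]), 0.05, tolerance = 1e-12)
  # constant gene row: dispersion 0, rank 1, correlation undefined (no error)
  m <- rbind(K = c(20, 20, 20), L = c(22, 23, 24))
  colnames(m) <- paste0("s", 1:3)
  bk3 <- bestkeeper(ct_table(m, groups = rep("g", 3)))
  expect_equal(unname(bk3$values["K"]), 0)
  expect_equal(unname(bk3$ranks["K"]), 1L)
  expect_true(is.na(bk3$details$correlations$r[1]))
})

test_that("values and ranks are equivariant under gene permutation", {
  set.seed(99)
  t <- random_table(n_genes = 6)
  perm <- sample(nrow(t$ct))
  t2 <- ct_table(t$ct[perm, ], groups = t$groups)
  for (f in list(delta_ct_stability, bestkeeper,
                 function(x) normfinder(x, use_groups = FALSE),
                 function(x) genorm(to_relative_quantities(x)))) {
    r1 <- f(t); r2 <- f(t2)
    expect_equal(r2$values[names(r1$values)], r1$values)
    expect_equal(r2$ranks[names(r1$ranks)], r1$ranks)
  }
})

test_that("iid noise: M and delta-Ct -> sqrt(2) sigma, NormFinder ->
           sigma sqrt((K-1)/K)", {
  set.seed(314)
  K <- 6; sigma <- 0.3; n <- 800
  m <- matrix(25 + rnorm(K * n, 0, sigma), K, n,
              dimnames = list(paste0("G", 1:K), paste0("s", 1:n)))
  t <- ct_table(m, groups = rep("g", n))
  expect_equal(mean(delta_ct_stability(t)$values), sqrt(2) * sigma,
               tolerance = 0.05)
  expect_equal(mean(normfinder(t, use_groups = FALSE)$values),
               sigma * sqrt((K - 1) / K), tolerance = 0.05)
})

test_that("missing cells are handled pairwise-complete", {
  m <- rbind(A = c(20, 20.1, 19.9, 20, NA), B = c(22, 22.1, 21.9, 22, 22),
             C = c(25, 25.5, 24.5, 25, 25.2))
  colnames(m) <- paste0("s", 1:5)
  t <- ct_table(m, groups = rep("g", 5))
  r <- delta_ct_stability(t)
  expect_equal(unname(r$values["A"]), 0.1632993, tolerance = 1e-6)
  expect_warning(bestkeeper(t), "missing")
})
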