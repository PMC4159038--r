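test_that("wilson_interval matches the closed form and prop.test's score interval", {
  expect_equal(wilson_interval(0, 10)[["low"]], 0.0)
  expect_equal(wilson_interval(10, 10)[["high"]], 1.0)
  expect_equal(unname(wilson_interval(5, 10)),
               wilson_transcription(5, 10), tolerance = 1e-10)
  expect_error(wilson_interval(3, 0), "n must be")

  set.seed(3)
  for (i in 1:50) {
    n <- sample(1:500, 1)
    k <- sample(0:n, 1)
    conf <- sample(c(0.9, 0.95, 0.99), 1)
    expect_equal(unname(wilson_interval(k, n, conf)),
                 wilson_transcription(k, n, conf), tolerance = 1e-10)
    # independent oracle: prop.test's Wilson interval (no continuity corr.)
    pt <- suppressWarnings(prop.test(k, n, conf.level = conf,
                                     correct = FALSE))
    expect_equal(unname(wilson_interval(k, n, conf)),
                 as.numeric(pt$conf.int), tolerance = 1e-10)
  }
})

test_that("newcombe_diff_interval combines the two Wilson intervals as specified", {
  expect_equal(unname(newcombe_diff_interval(56, 70, 48, 80)),
               newcombe_transcription(56, 70, 48, 80), tolerance = 1e-10)
  # equal counts: symmetric about zero and containing it
  ci <- newcombe_diff_interval(7, 20, 7, 20)
  expect_equal(ci[["low"]], -ci[["high"]], tolerance = 1e-12)
  expect_true(ci[["low"]] <= 0 && ci[["high"]] >= 0)
  # extreme case clips at 1
  ci2 <- newcombe_diff_interval(15, 15, 0, 12)
  expect_equal(ci2[["high"]], 1.0)
  set.seed(4)
  for (i in 1:50) {
    n1 <- sample(1:300, 1); n2 <- sample(1:300, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    expect_equal(unname(newcombe_diff_interval(k1, n1, k2, n2)),
                 newcombe_transcription(k1, n1, k2, n2), tolerance = 1e-10)
  }
})

test_that("the exact two-proportion p agrees with enumeration and fisher.test", {
  expect_equal(fisher_exact_two_proportions(5, 10, 5, 10)$p_value, 1.0)
  deg <- fisher_exact_two_proportions(0, 10, 0, 15)
  expect_equal(deg$p_value, 1.0)
  expect_equal(deg$diff, 0.0)

  set.seed(5)
  for (i in 1:60) {
    n1 <- sample(1:60, 1); n2 <- sample(1:60, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    p <- fisher_exact_two_proportions(k1, n1, k2, n2)$p_value
    expect_equal(p, fisher_p_enumeration(k1, n1, k2, n2), tolerance = 1e-10)
    # independent library oracle on the same 2x2 table
    ft <- fisher.test(matrix(c(k1, n1 - k1, k2, n2 - k2), 2))
    expect_equal(p, ft$p.value, tolerance = 1e-7)
  }
})

test_that("the exact p is invariant under sample swap and success/failure relabeling", {
  set.seed(6)
  for (i in 1:40) {
    n1 <- sample(1:40, 1); n2 <- sample(1:40, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    p <- fisher_exact_two_proportions(k1, n1, k2, n2)$p_value
    expect_equal(fisher_exact_two_proportions(k2, n2, k1, n1)$p_value, p,
                 tolerance = 1e-12)
    expect_equal(fisher_exact_two_proportions(n1 - k1, n1, n2 - k2, n2)$p_value,
                 p, tolerance = 1e-12)
  }
})

test_that("the Monte-Carlo permutation mode approximates the exact p", {
  p_exact <- fisher_exact_two_proportions(30, 100, 15, 100)$p_value
  p_perm <- permutation_two_proportions(30, 100, 15, 100,
                                        n_perm = 20000, seed = 9)
  expect_lt(abs(p_perm - p_exact), 0.02)
})

test_that("the hybrid difference interval holds near-nominal coverage for rare proportions", {
  # two binomials n = 200, p = 0.05 each; true difference 0
  set.seed(12)
  k1 <- rbinom(10000, 200, 0.05)
  k2 <- rbinom(10000, 200, 0.05)
  covered <- vapply(seq_along(k1), function(i) {
    ci <- newcombe_diff_interval(k1[i], 200, k2[i], 200)
    ci[["low"]] <= 0 && 0 <= ci[["high"]]
  }, TRUE)
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.98)
})

test_that("comparison results respect their structural invariants", {
  set.seed(7)
  for (i in 1:30) {
    n1 <- sample(1:200, 1); n2 <- sample(1:200, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    r <- fisher_exact_two_proportions(k1, n1, k2, n2)
    expect_true(r$ci_low <= r$diff + 1e-12 && r$diff <= r$ci_high + 1e-12)
    expect_true(r$p_value >= 0 && r$p_value <= 1)
    expect_true(r$ci_low >= -1 && r$ci_high <= 1)
  }
})

test_that("per-genus screen flags exactly the differing genus and sorts by difference", {
  genera <- c("Alcanivorax", "Marinobacter", "Cycloclasticus", "OtherX")
  counts <- data.frame(P = c(1000, 50, 50, 23900),
                       C = c(0, 50, 50, 24900))
  tab <- genus_matrix_table(counts, genera)
  guild <- toy_guild(genera[1:3])
  res <- per_genus_screen(tab, guild, "P", "C")
  expect_equal(nrow(res), 3L)
  expect_equal(res$label[res$significant], "Alcanivorax")
  expect_equal(res$label[1], "Alcanivorax")  # largest diff first
  expect_true(all(diff(res$diff) <= 0))

  same <- genus_matrix_table(data.frame(A = c(100, 50, 24850),
                                        B = c(100, 50, 24850)),
                             genera[c(1, 2, 4)])
  res0 <- per_genus_screen(same, toy_guild(genera[1:2]), "A", "B")
  expect_false(any(res0$significant))

  expect_error(per_genus_screen(tab, guild, "P", "nope"), "nope")
})

test_that("Benjamini-Hochberg flags are a subset of uncorrected flags", {
  set.seed(8)
  genera <- paste0("Gen", 1:30)
  counts <- data.frame(A = rpois(30, 40) + 1L, B = rpois(30, 40) + 1L)
  counts$A[1:3] <- counts$A[1:3] + c(150, 60, 30)
  tab <- genus_matrix_table(counts, genera)
  guild <- toy_guild(genera)
  none <- per_genus_screen(tab, guild, "A", "B", correction = "none")
  bh <- per_genus_screen(tab, guild, "A", "B", correction = "bh")
  expect_true(all(bh$label[bh$significant] %in% none$label[none$significant]))
  expect_true(all(bh$p_adjusted >= none$p_adjusted - 1e-12))
})

test_that("the guild-level proportions equal the EIHE values over 100", {
  genera <- c("Alcanivorax", "Marinobacter", "OtherX")
  counts <- data.frame(P = c(1000, 300, 23700), C = c(150, 100, 24750))
  tab <- genus_matrix_table(counts, genera)
  guild <- toy_guild()
  gl <- guild_level_test(tab, guild, "P", "C")
  v <- eihe_values(compute_eihe(tab, guild))
  expect_equal(100 * gl$p1, v[["P"]], tolerance = 1e-9)
  expect_equal(100 * gl$p2, v[["C"]], tolerance = 1e-9)
  expect_equal(gl$k1, 1300)
  expect_equal(gl$n1, 25000)

  # the 5.2-vs-1.0 shape: guild reads 1300/25000 vs 250/25000
  shape <- genus_matrix_table(data.frame(P = c(1300, 23700),
                                         C = c(250, 24750)),
                              c("Alcanivorax", "OtherX"))
  g2 <- guild_level_test(shape, toy_guild("Alcanivorax"), "P", "C")
  expect_equal(g2$p1, 0.052)
  expect_equal(g2$p2, 0.010)
  expect_equal(g2$diff, 0.042)
  expect_lt(g2$p_value, 1e-15)

  # guild absent from both samples
  none <- guild_level_test(tab, toy_guild("Cycloclasticus"), "P", "C")
  expect_equal(none$diff, 0)
  expect_equal(none$p_value, 1.0)
})

test_that("welch_t reproduces the Welch statistic and df from first principles", {
  a <- c(5.2, 4.8, 5.9, 4.4, 5.1)
  b <- c(1.0, 1.4, 0.8, 1.2, 1.6)
  w <- welch_t(a, b)
  # independent transcription of the Welch formulas
  s1 <- var(a) / length(a); s2 <- var(b) / length(b)
  t_ref <- (mean(a) - mean(b)) / sqrt(s1 + s2)
  df_ref <- (s1 + s2)^2 / (s1^2 / (length(a) - 1) + s2^2 / (length(b) - 1))
  p_ref <- 2 * pt(-abs(t_ref), df_ref)
  expect_equal(w$statistic, t_ref, tolerance = 1e-10)
  expect_equal(w$df, df_ref, tolerance = 1e-10)
  expect_equal(w$p_value, p_ref, tolerance = 1e-10)

  same <- welch_t(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1.0)

  expect_error(welch_t(1, c(1, 2)), "at least 2")
  # documented zero-variance policy: equal means p = 1, different means p = 0
  expect_equal(welch_t(c(0, 0, 0), c(0, 0, 0))$p_value, 1.0)
  expect_equal(welch_t(c(0, 0, 0, 0), c(1, 1, 1, 1))$p_value, 0.0)
})

test_that("kruskal_wallis reproduces a hand-ranked H and is exchangeable", {
  groups <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  kw <- kruskal_wallis(groups)
  # hand computation: no ties, mean ranks 2, 5, 8, N = 9
  # H = 12/(N(N+1)) * sum n_i (Rbar_i - (N+1)/2)^2 = 7.2
  expect_equal(kw$statistic, 7.2, tolerance = 1e-12)
  expect_equal(kw$p_value, pchisq(7.2, df = 2, lower.tail = FALSE),
               tolerance = 1e-12)

  perm <- kruskal_wallis(groups[c(3, 1, 2)])
  expect_equal(perm$statistic, kw$statistic)
  expect_equal(perm$p_value, kw$p_value)

  flat <- kruskal_wallis(list(c(2, 2), c(2, 2), c(2, 2)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1.0)
  expect_error(kruskal_wallis(list(1:3)), "at least 2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "empty group")
})

test_that("Dunn post-hoc comparisons separate the distant groups after Bonferroni", {
  set.seed(10)
  groups <- list(a = rnorm(8, 0), b = rnorm(8, 0.2), c = rnorm(8, 6))
  kw <- kruskal_wallis(groups, posthoc = TRUE)
  pw <- kw$pairwise
  expect_equal(nrow(pw), 3L)
  ac <- pw$p_adjusted[pw$group_a == "a" & pw$group_b == "c"]
  ab <- pw$p_adjusted[pw$group_a == "a" & pw$group_b == "b"]
  expect_lt(ac, 0.05)
  expect_gt(ab, 0.05)
  expect_true(all(pw$p_adjusted >= 0 & pw$p_adjusted <= 1))
})
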