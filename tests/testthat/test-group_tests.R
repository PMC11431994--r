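test_that("midranks handle ties, order and constants", {
  expect_equal(midranks(c(10, 20, 20, 30)), c(1, 2.5, 2.5, 4))
  expect_equal(midranks(c(3, 7, 9, 11)), 1:4, ignore_attr = TRUE)
  expect_equal(midranks(rep(5, 6)), rep(3.5, 6))
  expect_equal(sum(midranks(rnorm(17))), 17 * 18 / 2)
})

test_that("Mann-Whitney exact p matches hand enumeration on separated groups", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$u_x, 0)
  expect_equal(res$u, 0)
  expect_equal(res$p_value, 2 / 20)   # 2 extreme labelings of C(6,3)=20
  expect_equal(res$method, "exact")
})

test_that("identical samples give the central U and p = 1", {
  x <- c(1, 2, 2, 5)
  res <- mann_whitney_u(x, x)
  expect_equal(res$u_x, length(x)^2 / 2)
  expect_equal(res$p_value, 1)
  expect_error(mann_whitney_u(numeric(0), 1:3), "nonempty")
})

test_that("exact mode equals full enumeration for all n+m <= 10", {
  set.seed(51)
  for (n in 1:5) {
    for (m in n:(10 - n)) {
      x <- sample(1:6, n, replace = TRUE)   # ties likely
      y <- sample(1:6, m, replace = TRUE)
      expect_equal(mann_whitney_u(x, y, mode = "exact")$p_value,
                   mw_enumeration_oracle(x, y),
                   info = sprintf("n=%d m=%d", n, m))
      xc <- rnorm(n); yc <- rnorm(m)       # continuous: compare wilcox.test
      expect_equal(mann_whitney_u(xc, yc, mode = "exact")$p_value,
                   wilcox.test(xc, yc, exact = TRUE)$p.value,
                   tolerance = 1e-12)
    }
  }
})

test_that("normal approximation tracks the permutation distribution", {
  set.seed(52)
  x <- rnorm(30); y <- rnorm(30)
  res <- mann_whitney_u(x, y, mode = "normal")
  pool <- c(x, y)
  r <- rank(pool)
  u_perm <- replicate(2e4, {
    ix <- sample(60, 30)
    sum(r[ix]) - 30 * 31 / 2
  })
  p_perm <- mean(abs(u_perm - 450) >= abs(res$u_x - 450) - 1e-9)
  expect_lt(abs(res$p_value - p_perm), 0.02)
  # and the tie-corrected variance matches wilcox.test's normal p
  xt <- sample(1:4, 40, replace = TRUE); yt <- sample(1:4, 35, replace = TRUE)
  expect_equal(mann_whitney_u(xt, yt, mode = "normal")$p_value,
               wilcox.test(xt, yt, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-10)
})

test_that("SRH decomposition matches aov on ranks for balanced data", {
  set.seed(53)
  a <- rep(c("a1", "a2", "a3"), each = 12)
  b <- rep(rep(c("b1", "b2"), each = 6), 3)
  y <- rnorm(36) + 2 * (a == "a2")
  res <- scheirer_ray_hare(y, a, b)
  r <- rank(y)
  fit <- anova(aov(r ~ factor(a) * factor(b)))
  expect_equal(res$effects$sum_sq, fit$`Sum Sq`[1:3], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(res$residual_ss, fit$`Sum Sq`[4], tolerance = 1e-8)
  # balanced decomposition is exact
  expect_equal(sum(res$effects$sum_sq) + res$residual_ss, res$ss_total,
               tolerance = 1e-6)
  expect_equal(res$effects$df, c(2L, 1L, 2L))
  expect_equal(res$residual_df, 30L)
})

test_that("SRH is invariant under strictly monotone transforms", {
  set.seed(54)
  a <- rep(c("x", "y"), each = 20)
  b <- rep(rep(c("u", "v"), each = 10), 2)
  y <- rnorm(40)
  r1 <- scheirer_ray_hare(y, a, b)
  r2 <- scheirer_ray_hare(exp(y), a, b)
  expect_identical(r1$effects$H, r2$effects$H)
  expect_identical(r1$tie_correction, r2$tie_correction)
})

test_that("SRH type-I error is near nominal under the null", {
  set.seed(55)
  n_sims <- 400L
  a <- rep(c("a1", "a2"), each = 10)
  b <- rep(rep(c("b1", "b2"), each = 5), 2)
  rej <- 0L
  for (i in seq_len(n_sims)) {
    res <- scheirer_ray_hare(rnorm(20), a, b)
    if (res$effects$p_raw[1] < 0.05) rej <- rej + 1L
  }
  expect_lt(abs(rej / n_sims - 0.05), 0.03)
})

test_that("SRH detects a large main effect and reports the design shape", {
  set.seed(56)
  a <- rep(c("a1", "a2", "a3"), each = 154)   # 462 observations, 3x3
  b <- rep(rep(c("b1", "b2", "b3"), 52)[1:154], 3)
  y <- rnorm(462) + 3 * (a == "a1")
  res <- scheirer_ray_hare(y, a, b, bonferroni_m = 12L)
  expect_lt(res$effects$p_raw[1], 0.001)
  expect_equal(res$residual_df, 453L)
  expect_true(all(res$effects$H >= 0))
})

test_that("SRH rejects degenerate layouts", {
  expect_error(scheirer_ray_hare(rnorm(10), rep("a", 10),
                                 rep(c("u", "v"), 5)), "2 levels")
  a <- c("a1", "a1", "a2", "a2")
  b <- c("b1", "b1", "b1", "b2")
  expect_error(scheirer_ray_hare(rnorm(4), a, b), "empty cell: a1 x b2")
})

test_that("Bonferroni-corrected chi-square p-values reproduce reference cells", {
  cells <- reference_srh_cells()
  for (i in seq_len(nrow(cells))) {
    p <- srh_corrected_p(cells$H[i], cells$df[i], 12L)
    expect_equal(round(p, cells$digits[i]), cells$p_corrected[i])
  }
  expect_equal(srh_corrected_p(0, 2, 12), 1.0)
})

test_that("tie correction divides H when values are heavily tied", {
  set.seed(57)
  a <- rep(c("a1", "a2"), each = 12)
  b <- rep(rep(c("b1", "b2"), each = 6), 2)
  y <- sample(1:3, 24, replace = TRUE)
  res <- scheirer_ray_hare(y, a, b)
  expect_lt(res$tie_correction, 1)
  expect_gt(res$tie_correction, 0)
  # the correction equals the standard Kruskal-Wallis tie factor
  g <- rep(c("g1", "g2", "g3"), each = 8)
  v <- sample(1:4, 24, replace = TRUE)
  ours <- scheirer_ray_hare(v, g, rep(c("u", "v"), 12))
  ties <- table(rank(v))
  D <- 1 - sum(ties^3 - ties) / (24^3 - 24)
  expect_equal(ours$tie_correction, D)
})

test_that("component-wise SRH table covers every PC and effect per caste", {
  cfg <- synth_config(n_sites = 9L)
  sites <- generate_sites(cfg, seed = 58)
  traits <- generate_workers(sites, cfg, seed = 59)
  m <- build_morphospace(traits, "major")
  tab <- srh_by_component(m, sites)
  expect_equal(nrow(tab), 12L)  # 4 PCs x 3 effects
  expect_setequal(unique(tab$component), paste0("PC", 1:4))
  expect_true(all(tab$p_corrected >= tab$p_raw - 1e-12))
  expect_true(all(tab$residual_df == nrow(m$scores) - 9L))
})

test_that("distribution diagnostics are descriptive only", {
  set.seed(60)
  d <- rank_test_diagnostics(rnorm(60), rep(c("a", "b"), 30),
                             rep(c("u", "v"), each = 30))
  expect_length(d$skewness_range, 2L)
  expect_gte(d$sd_ratio, 1)
})
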