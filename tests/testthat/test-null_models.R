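test_that("stratified subsamples satisfy the colony composition contract", {
  set.seed(61)
  labels <- rep(c("C1", "C2", "C3"), each = 7)
  ix <- stratified_subsample(labels, n = 10, min_per_colony = 3)
  expect_length(ix, 10L)
  expect_length(unique(ix), 10L)
  counts <- sort(as.integer(table(labels[ix])))
  expect_equal(counts, c(3L, 3L, 4L))
  expect_error(stratified_subsample(rep(c("C1", "C2", "C3"), c(2, 7, 7))),
               "infeasible stratum")
  expect_error(stratified_subsample(rep(c("C1", "C2"), each = 3),
                                    n = 5, min_per_colony = 3),
               "exceeds subsample size")
})

test_that("the extra draw is assigned to colonies uniformly", {
  set.seed(62)
  labels <- rep(c("C1", "C2", "C3"), each = 7)
  extra <- table(replicate(3000, {
    ix <- stratified_subsample(labels, 10, 3)
    names(which.max(table(labels[ix])))
  }))
  expect_true(all(abs(extra / 3000 - 1 / 3) < 0.03))
})

test_that("hull and null distributions have the configured lengths and reproduce", {
  toy <- toy_scores(seed = 63)
  members <- which(toy$site_id == "S01")
  set.seed(1)
  obs <- observed_hull_distribution(toy$scores, toy$site_id, toy$colony_id,
                                    members, reps = 100)
  expect_length(obs, 100L)
  expect_true(all(obs >= 0))
  set.seed(9)
  n1 <- null_hull_distribution(toy$scores, reps = 50)
  set.seed(9)
  n2 <- null_hull_distribution(toy$scores, reps = 50)
  expect_identical(n1, n2)
  expect_length(n1, 50L)
})

test_that("an infeasible unit is reported", {
  toy <- toy_scores(per_colony = 2, seed = 64)
  expect_error(
    observed_hull_distribution(toy$scores, toy$site_id, toy$colony_id,
                               which(toy$site_id == "S01")),
    "no feasible site")
})

test_that("centroid displacement follows the Euclidean geometry", {
  toy <- toy_scores(seed = 65)
  centroid <- colMeans(toy$scores)
  expect_equal(centroid_distance(toy$scores, centroid), 0)
  v <- c(1, -2, 0.5, 3)
  shifted <- sweep(toy$scores, 2, v, "+")
  expect_equal(centroid_distance(shifted, centroid), sqrt(sum(v^2)),
               tolerance = 1e-12)
  expect_equal(centroid_distance(rbind(c(0, 0, 0, 0), c(2, 0, 0, 0)),
                                 c(0, 0, 0, 0)), 1.0)
})

test_that("a degenerate unit inside a varied pool is flagged as clustered", {
  toy <- toy_scores(n_sites = 4, seed = 66)
  members <- which(toy$site_id == "S01")
  toy$scores[members, ] <- matrix(rep(c(1, 1, 1, 1), each = length(members)),
                                  length(members), 4)
  set.seed(2)
  res <- hull_test(toy$scores, toy$site_id, toy$colony_id, members,
                   "S01", n = 10, hull_reps = 50, null_reps = 200)
  expect_true(all(res$observed == 0))
  expect_true(res$significant)
  expect_equal(res$direction, "smaller")
})

test_that("alpha = 1 makes any non-degenerate comparison significant", {
  toy <- toy_scores(seed = 67)
  set.seed(3)
  res <- hull_test(toy$scores, toy$site_id, toy$colony_id,
                   which(toy$site_id == "S02"), "S02",
                   hull_reps = 20, null_reps = 50, alpha = 1)
  expect_true(res$significant)
  expect_lt(res$p_value, 1)
})

test_that("planted variance shrink lowers the observed hull volumes", {
  # scaled-down planted-effect recovery; the acceptance suite runs the
  # full-replication version
  cfg <- synth_config()
  plan <- effect_plan(variance_shrink = c(MTZ.F = 0.5))
  wins <- 0L
  for (s in 1:10) {
    sites <- generate_sites(cfg, seed = 700 + s)
    traits <- generate_workers(sites, cfg, plan, seed = 800 + s)
    m <- build_morphospace(traits, "major")
    combo <- sites$combo[match(m$site_id, sites$site_id)]
    set.seed(900 + s)
    obs_shrunk <- observed_hull_distribution(
      m$scores, m$site_id, m$colony_id, which(combo == "MTZ.F"), reps = 30)
    obs_ref <- observed_hull_distribution(
      m$scores, m$site_id, m$colony_id, which(combo == "STZ.UP"), reps = 30)
    if (median(obs_shrunk) < median(obs_ref)) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("the pooled null envelops combo hulls when every combo is shrunk", {
  cfg <- synth_config()
  shrink <- setNames(rep(0.8, 9), combo_levels())
  shrink["MTZ.F"] <- 0.5
  sites <- generate_sites(cfg, seed = 70)
  traits <- generate_workers(sites, cfg,
                             effect_plan(variance_shrink = shrink),
                             seed = 71)
  m <- build_morphospace(traits, "minor")
  cfga <- analysis_config(hull_reps = 40L, null_reps = 200L)
  nm <- run_null_models(m, sites, cfga, seed = 72)
  tab <- nm$table[nm$table$statistic == "hull_volume", ]
  # the most strongly shrunk combo occupies by far the least volume and is
  # flagged as clustered against the pooled null
  expect_equal(tab$combo[which.min(tab$observed_median)], "MTZ.F")
  mtzf <- tab[tab$combo == "MTZ.F", ]
  expect_lt(mtzf$observed_median / mtzf$null_median, 0.5)
  expect_true(mtzf$significant)
  expect_equal(mtzf$direction, "smaller")
})

test_that("a planted centroid shift is detected, and only where planted", {
  # colony intercepts off so the pooled null is the true null of the
  # untouched combos
  cfg <- synth_config(colony_sd_frac = 0)
  plan <- effect_plan(centroid_shift = list(WTZ.SW = c(head_width = 2,
                                                       head_length = 2)))
  sites <- generate_sites(cfg, seed = 73)
  traits <- generate_workers(sites, cfg, plan, seed = 74)
  m <- build_morphospace(traits, "minor")
  combo <- sites$combo[match(m$site_id, sites$site_id)]
  set.seed(75)
  hit <- centroid_test(m$scores, m$site_id, m$colony_id,
                       which(combo == "WTZ.SW"), "WTZ.SW", reps = 500)
  expect_true(hit$significant)
  expect_equal(hit$direction, "larger")
})

test_that("with exchangeable workers observed and null distributions coincide", {
  # the resampling design is anti-conservative at the significance level
  # (replicates of overlapping subsamples are not independent draws), so the
  # calibrated statement is about effect size, not flag counts: under
  # exchangeability the observed and null medians agree closely, far inside
  # the shifts produced by planted effects
  cfg <- synth_config(colony_sd_frac = 0)
  ratios <- numeric(0)
  for (s in 1:6) {
    sites <- generate_sites(cfg, seed = 1100 + s)
    traits <- generate_workers(sites, cfg, seed = 1200 + s)
    m <- build_morphospace(traits, "major")
    cfga <- analysis_config(hull_reps = 30L, null_reps = 150L)
    nm <- run_null_models(m, sites, cfga, seed = 1300 + s)
    tab <- nm$table[nm$table$statistic == "hull_volume", ]
    ratios <- c(ratios, tab$observed_median / tab$null_median)
  }
  expect_lt(abs(median(ratios) - 1), 0.15)
  # hull volume raises dispersion noise to the 4th power, so individual
  # site-conditional medians scatter widely; only gross asymmetry would
  # indicate a biased implementation
  expect_true(all(ratios > 0.25 & ratios < 4))
})

test_that("null-model runs are reproducible bit-for-bit under a fixed seed", {
  cfg <- synth_config(n_sites = 9L)
  sites <- generate_sites(cfg, seed = 76)
  traits <- generate_workers(sites, cfg, seed = 77)
  m <- build_morphospace(traits, "major")
  cfga <- analysis_config(hull_reps = 10L, null_reps = 30L)
  r1 <- run_null_models(m, sites, cfga, seed = 78)
  r2 <- run_null_models(m, sites, cfga, seed = 78)
  expect_identical(r1$table, r2$table)
  expect_identical(r1$results[["MTZ.F.hull"]]$observed,
                   r2$results[["MTZ.F.hull"]]$observed)
})
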