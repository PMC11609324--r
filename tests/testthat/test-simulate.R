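test_that("the generator is fully deterministic under a seed", {
  cfg <- sim_config(n_families = 200, seed = 41)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1, c2)
  f1 <- simulate_connectivity(c1, cfg)
  f2 <- simulate_connectivity(c2, cfg)
  expect_identical(f1[, feature_keys()], f2[, feature_keys()])
  t1 <- simulate_label_volume(seed = 41)
  t2 <- simulate_label_volume(seed = 41)
  expect_identical(t1$vol$grid, t2$vol$grid)
  expect_identical(t1$nets, t2$nets)
})

test_that("family sizes follow the configured sibling mix", {
  cfg <- sim_config(seed = 42)   # defaults: 3952 families, observed mix
  co <- simulate_cohort(cfg)
  sizes <- table(table(co$family_id))
  nf <- cfg$n_families
  probs <- cfg$sibling_probs
  for (k in 1:3) {
    obs <- if (as.character(k) %in% names(sizes)) sizes[[as.character(k)]]
           else 0
    # multinomial 99% band per category
    band <- qbinom(c(0.005, 0.995), nf, probs[k])
    expect_gte(obs, band[1])
    expect_lte(obs, band[2])
  }
})

test_that("parent-youth score correlations hit the configured target", {
  cfg <- sim_config(seed = 43)
  co <- simulate_cohort(cfg)
  rs <- c(cor(co$int_p, co$int_y), cor(co$ext_p, co$ext_y),
          cor(co$tot_p, co$tot_y))
  # each scale's r within a 99% sampling band around the 0.15 target
  half <- qnorm(0.995) / sqrt(nrow(co) - 3)
  for (r in rs) {
    expect_gt(atanh(r), atanh(0.15) - 1.5 * half)
    expect_lt(atanh(r), atanh(0.15) + 1.5 * half)
  }
  # scores are non-negative integers with right skew
  for (cc in c("int_p", "ext_p", "tot_p", "int_y")) {
    expect_true(all(co[[cc]] >= 0))
    expect_true(all(co[[cc]] == round(co[[cc]])))
    expect_gt(mean(co[[cc]]), median(co[[cc]]))  # right-skewed
  }
})

test_that("parental scores are family-constant and youth scores are not", {
  co <- simulate_cohort(sim_config(n_families = 300, seed = 44,
                                   sibling_probs = c(0.4, 0.5, 0.1)))
  rng <- tapply(co$int_p, co$family_id, function(v) diff(range(v)))
  expect_true(all(rng == 0))
  sib <- names(which(table(co$family_id) >= 2))
  rng_y <- tapply(co$int_y[co$family_id %in% sib],
                  co$family_id[co$family_id %in% sib],
                  function(v) diff(range(v)))
  expect_gt(mean(rng_y > 0), 0.8)
})

test_that("zero-noise, zero-effect features equal the configured means", {
  cfg <- sim_config(n_families = 50, seed = 45, planted_effects = NULL,
                    family_sd = 0, noise_sd = 0, site_sd = 0,
                    site_scale_range = c(1, 1))
  co <- simulate_connectivity(simulate_cohort(cfg), cfg)
  for (key in network_keys()) {
    expect_equal(unique(co[[key]]), cfg$within_mean)
  }
  for (key in setdiff(feature_keys(), network_keys())) {
    expect_equal(unique(co[[key]]), cfg$between_mean)
  }
})

test_that("site batch effects inflate between-site variance as configured", {
  co_batch <- quick_cohort(n_families = 500, seed = 46, site_sd = 0.1)
  co_clean <- quick_cohort(n_families = 500, seed = 46, site_sd = 0)
  v_batch <- sd(sapply(split(co_batch$ERN1, co_batch$site_id), mean))
  v_clean <- sd(sapply(split(co_clean$ERN1, co_clean$site_id), mean))
  expect_gt(v_batch, 2 * v_clean)
})

test_that("matrix mode reproduces feature-mode values through extraction", {
  toy <- simulate_label_volume(dims = c(16, 16, 16), n_parcels = 8,
                               voxel_mm = 2, seed = 47)
  map <- map_networks_to_parcels(toy$nets, toy$vol, radius_mm = 4,
                                 rule = "fixed", fixed_min = 0)
  cfg <- sim_config(n_families = 40, seed = 47, pair_sd = 0.02)
  co <- simulate_cohort(cfg)
  sim <- simulate_connectivity(co, cfg, mode = "matrices", map = map)
  feats_direct <- simulate_connectivity(co, cfg, mode = "features")
  tab <- extract_features_table(sim$matrices, map)
  # pair noise shrinks by averaging: extracted features track the planted
  # subject-level values closely
  m <- merge(tab, feats_direct[, c("subject_id", feature_keys())],
             by = "subject_id", suffixes = c("_mat", "_dir"))
  for (key in feature_keys()) {
    expect_equal(m[[paste0(key, "_mat")]], m[[paste0(key, "_dir")]],
                 tolerance = 0.15)
  }
})

test_that("toy volumes plant a recoverable parcel-network assignment", {
  toy <- simulate_label_volume(dims = c(20, 20, 20), n_parcels = 8,
                               voxel_mm = 2, seed = 48)
  # radius-0 peaks: one row per parcel, one voxel each
  ov0 <- compute_overlap(toy$nets, toy$vol, radius_mm = 0)
  expect_equal(nrow(ov0), 8L)
  expect_true(all(ov0$voxel_count == 1L))
  map <- assign_parcels(ov0)
  got <- merge(map, toy$truth, by = "parcel_id")
  expect_true(all(got$network_id.x == got$network_id.y))
})

test_that("Cronbach's alpha matches its formula and edge behaviour", {
  set.seed(49)
  base <- rnorm(50)
  # identical items are perfectly consistent
  ident <- cbind(base, base, base)
  expect_equal(cronbach_alpha(ident), 1)
  # independent items at large n are near zero
  indep <- matrix(rnorm(5000 * 4), 5000, 4)
  expect_lt(abs(cronbach_alpha(indep)), 0.06)
  # k = 2 toy table against a hand evaluation of the formula
  items <- cbind(c(1, 2, 3, 4), c(2, 2, 4, 5))
  hand <- 2 / 1 * (1 - (var(items[, 1]) + var(items[, 2])) /
                     var(rowSums(items)))
  expect_equal(cronbach_alpha(items), hand)
  expect_error(cronbach_alpha(cbind(1:5)), ">= 2")
  expect_error(cronbach_alpha(cbind(rep(1, 4), rep(2, 4))), "variance")
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_families = 0), "at least 1")
  expect_error(sim_config(sibling_probs = c(0.5, 0.4, 0.2)), "sum to 1")
  expect_error(sim_config(noise_sd = -1), "non-negative")
  expect_error(sim_config(planted_effects = data.frame(
    scale = "int_p", measure = "ERN1", beta = 1.2)), "beta")
  expect_error(simulate_label_volume(dims = c(2, 2, 2), n_parcels = 99),
               "more parcels")
})
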