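test_that("configuration invariants are enforced", {
  expect_error(sim_config(genotype_freqs = c(AA = 0.5, AB = 0.6, AC = 0,
                                             BB = 0, BC = 0, CC = 0)),
               "sum to 1")
  expect_error(sim_config(age_class_freqs = c(`1` = 0.5, `2` = 0.5,
                                              `3` = 0.5)), "sum to 1")
  expect_error(sim_config(fix_interval = 7), "divide 86400")
  expect_error(sim_config(days = 3), "at least 7")
  expect_error(sim_config(terrain = list(n = 8, cellsize = 16, relief = 100,
                                         smoothness = 5)), "16x16")
})

test_that("DEM generation is reproducible and honours the zero-relief case", {
  cfg <- sim_config(seed = 5, terrain = list(n = 32, cellsize = 16,
                                             relief = 0, smoothness = 5))
  flat <- generate_dem(cfg)
  expect_true(all(flat$elevation == 0))
  expect_true(all(flat$slope_deg == 0))
  expect_true(all(is.na(flat$aspect_deg)))

  cfg2 <- sim_config(seed = 7)
  d1 <- generate_dem(cfg2)
  d2 <- generate_dem(cfg2)
  expect_identical(d1$elevation, d2$elevation)
  d3 <- generate_dem(sim_config(seed = 8))
  expect_false(identical(d1$elevation, d3$elevation))
})

test_that("strong relief produces rugged terrain (herd median slope > 8 deg)", {
  cfg <- sim_config(seed = 42, terrain = list(n = 128, cellsize = 16,
                                              relief = 300, smoothness = 6))
  dem <- generate_dem(cfg)
  ext <- grazemix:::dem_extent(dem)
  set.seed(1)
  pts <- tibble::tibble(x = runif(2000, ext["xmin"], ext["xmax"]),
                        y = runif(2000, ext["ymin"], ext["ymax"]))
  ann <- annotate_fixes(pts, dem)
  expect_gt(median(ann$slope_deg), 8)
})

test_that("expected-counts genotype mode reproduces the published totals", {
  freqs <- c(AA = 3, AB = 18, AC = 31, BB = 38, BC = 109, CC = 107) / 306
  cfg <- sim_config(seed = 1, n_mobs = 17, cows_per_mob = 18,  # 306 cows
                    genotype_freqs = freqs)
  md <- simulate_herd(cfg, genotype_mode = "expected")
  expect_equal(nrow(md), 306)
  counts <- table(md$genotype)
  expect_equal(as.integer(counts[c("AA", "AB", "AC", "BB", "BC", "CC")]),
               c(3, 18, 31, 38, 109, 107))
})

test_that("degenerate and multinomial genotype draws behave", {
  cfg <- sim_config(seed = 2, n_mobs = 2, cows_per_mob = 10,
                    genotype_freqs = c(AA = 0, AB = 0, AC = 0, BB = 0,
                                       BC = 1, CC = 0))
  md <- simulate_herd(cfg)
  expect_true(all(md$genotype == "BC"))

  freqs <- c(AA = 3, AB = 18, AC = 31, BB = 38, BC = 109, CC = 107) / 306
  cfg2 <- sim_config(seed = 3, n_mobs = 20, cows_per_mob = 500,
                     genotype_freqs = freqs)
  md2 <- simulate_herd(cfg2, genotype_mode = "multinomial")
  props <- table(md2$genotype)[names(freqs)] / nrow(md2)
  expect_true(all(abs(props - freqs) <= 0.02))
})

test_that("herd structure gives every mob at least two sires", {
  md <- tiny_sim(seed = 4, n_mobs = 3, cows_per_mob = 8)$metadata
  sires_per_mob <- tapply(md$sire, md$mob, function(s) length(unique(s)))
  expect_true(all(sires_per_mob >= 2))
})

test_that("trajectory simulation is deterministic and per-cow streams are stable", {
  s1 <- tiny_sim(seed = 21, n_mobs = 1, cows_per_mob = 4, days = 7)
  s2 <- tiny_sim(seed = 21, n_mobs = 1, cows_per_mob = 4, days = 7)
  expect_identical(s1$fixes$x, s2$fixes$x)
  expect_identical(s1$fixes$timestamp, s2$fixes$timestamp)

  # adding a cow must not perturb the existing cows' tracks
  cfg <- s1$config
  md_small <- s1$metadata[1:3, ]
  md_large <- rbind(s1$metadata,
                    transform(s1$metadata[4, ], cow_id = "cow9999"))
  f_small <- simulate_trajectories(md_small, s1$dem, cfg)
  f_large <- simulate_trajectories(md_large, s1$dem, cfg)
  for (id in md_small$cow_id) {
    expect_identical(f_small$x[f_small$cow_id == id],
                     f_large$x[f_large$cow_id == id])
  }
})

test_that("zero dropout yields exactly 86400/300 = 288 fixes per day", {
  s <- tiny_sim(seed = 6, n_mobs = 1, cows_per_mob = 2, days = 7,
                dropout_rate = 0)
  counts <- table(s$fixes$cow_id, as.Date(s$fixes$timestamp, tz = "UTC"))
  expect_true(all(counts == 288))
})

test_that("home-range attraction acts as an effect-size dial", {
  # the hard-attraction limit pins the cow to its home point
  base <- default_movement_params()
  strong <- transform(base, attraction = 1e6)
  cfg_s <- sim_config(seed = 9, n_mobs = 1, cows_per_mob = 2, days = 7,
                      dropout_rate = 0, movement = strong)
  dem <- generate_dem(cfg_s)
  md <- simulate_herd(cfg_s)
  fx_strong <- simulate_trajectories(md, dem, cfg_s)
  cfg_d <- sim_config(seed = 9, n_mobs = 1, cows_per_mob = 2, days = 7,
                      dropout_rate = 0)
  fx_default <- simulate_trajectories(md, dem, cfg_d)
  day1 <- function(f) f[as.Date(f$timestamp, tz = "UTC") ==
                          as.Date("2020-04-01"), ]
  hr_strong <- with(day1(fx_strong[fx_strong$cow_id == md$cow_id[1], ]),
                    mcp_area(x, y))
  hr_default <- with(day1(fx_default[fx_default$cow_id == md$cow_id[1], ]),
                     mcp_area(x, y))
  expect_lt(hr_strong, 0.05 * hr_default)

  # expected log home range decreases monotonically in attraction strength
  hrs <- vapply(c(0.5, 1, 2, 4), function(a) {
    mv <- transform(base, attraction = a)
    cfg <- sim_config(seed = 13, n_mobs = 1, cows_per_mob = 3, days = 7,
                      dropout_rate = 0, movement = mv)
    fx <- simulate_trajectories(simulate_herd(cfg), dem, cfg)
    fx$date <- as.Date(fx$timestamp, tz = "UTC")
    mean(log(vapply(split(fx, list(fx$cow_id, fx$date)),
                    function(d) mcp_area(d$x, d$y), numeric(1))))
  }, numeric(1))
  expect_true(all(diff(hrs) < 0))
})

test_that("ground truth records the latent parameters actually used", {
  s <- tiny_sim(seed = 10, n_mobs = 1, cows_per_mob = 3)
  gt <- sim_ground_truth(s$fixes)
  expect_setequal(gt$cow_id, s$metadata$cow_id)
  mv <- s$config$movement
  for (i in seq_len(nrow(gt))) {
    row <- mv[mv$genotype == gt$genotype[i] &
                mv$age_class == gt$age_class[i], ]
    expect_equal(gt$attraction[i], row$attraction)
  }
})

test_that("phenotype-level generator carries the requested structure", {
  md <- simulate_herd(sim_config(seed = 30, n_mobs = 4, cows_per_mob = 20))
  ph <- simulate_phenotypes(md, days_per_cow = 5,
                            variant_effects = c(A = 1.5, B = 0, C = 0),
                            sigma2_resid = 0.01, sigma2_cow = 0.01,
                            sigma2_mob = 0.01, seed = 2)
  expect_equal(nrow(ph), nrow(md) * 5)
  has_a <- grepl("A", ph$genotype)
  expect_gt(mean(ph$y[has_a]) - mean(ph$y[!has_a]), 1.0)
})
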