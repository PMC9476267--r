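# small fixture builders shared across test files

tiny_sim <- function(seed = 11, n_mobs = 2, cows_per_mob = 6, days = 7, ...) {
  cfg <- sim_config(seed = seed, n_mobs = n_mobs,
                    cows_per_mob = cows_per_mob, days = days, ...)
  dem <- generate_dem(cfg)
  md <- simulate_herd(cfg)
  fixes <- simulate_trajectories(md, dem, cfg)
  list(config = cfg, dem = dem, metadata = md, fixes = fixes)
}

# regular fixes along given coordinates at a fixed cadence
make_fixes <- function(x, y, cow_id = "cowA", interval = 300,
                       start = as.POSIXct("2020-04-01 00:00:00", tz = "UTC")) {
  tibble::tibble(cow_id = cow_id,
                 timestamp = start + (seq_along(x) - 1) * interval,
                 x = x, y = y)
}

# a DEM whose cell centres sit at x = 0, 16, 32, ... (plane z = slope_x * x)
plane_dem <- function(n = 21, cellsize = 16, slope_x = 0.1) {
  centres <- (seq_len(n) - 1) * cellsize
  z <- matrix(rep(slope_x * centres, each = n), nrow = n)
  dem_grid(z, cellsize = cellsize, xll = -cellsize / 2, yll = -cellsize / 2)
}

expect_tibble_equal <- function(a, b, tol = 1e-9) {
  testthat::expect_equal(as.data.frame(a), as.data.frame(b),
                         tolerance = tol)
}
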