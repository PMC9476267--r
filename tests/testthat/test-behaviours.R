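test_that("daily distance metrics match their defining sums", {
  d <- daily_distances(x = c(0, 100, 200, 300), y = c(0, 0, 0, 0),
                       elevation = c(100, 110, 105, 120))
  expect_equal(d$ho_dist, 300)
  expect_equal(d$ve_dist, 30)
  expect_equal(d$ele_gain, 25)
  expect_equal(d$ele_range, 20)

  # single 3-4-5 step
  p <- daily_distances(x = c(0, 30), y = c(0, 0), elevation = c(0, 40))
  expect_equal(p$three_d_dist, 50)

  set.seed(8)
  x <- cumsum(rnorm(400)); y <- cumsum(rnorm(400)); e <- cumsum(rnorm(400))
  d2 <- daily_distances(x, y, e)
  step <- sqrt(diff(x)^2 + diff(y)^2)
  expect_equal(d2$three_d_dist, sum(sqrt(step^2 + diff(e)^2)),
               tolerance = 1e-9)
})

test_that("MCP area matches brute-force hull and shoelace computation", {
  expect_equal(mcp_area(c(0, 0, 100, 100), c(0, 100, 100, 0)), 1.0)
  # interior points do not change the hull
  expect_equal(mcp_area(c(0, 0, 100, 100, 50), c(0, 100, 100, 0, 50)), 1.0)
  # degenerate cases
  expect_equal(mcp_area(c(0, 1), c(0, 1)), 0)
  expect_equal(mcp_area(c(0, 50, 100), c(0, 50, 100)), 0)  # collinear

  set.seed(12)
  x <- rnorm(500, sd = 200); y <- rnorm(500, sd = 150)
  expect_equal(mcp_area(x, y), brute_mcp_ha(x, y), tolerance = 1e-9)
})

test_that("adding a fix never shrinks the hull (monotonicity)", {
  set.seed(13)
  for (rep in 1:20) {
    x <- runif(30, 0, 500); y <- runif(30, 0, 500)
    a <- mcp_area(x, y)
    b <- mcp_area(c(x, runif(1, -100, 600)), c(y, runif(1, -100, 600)))
    expect_gte(b + 1e-12, a)
  }
})

test_that("tortuosity follows its ratio definition and scaling law", {
  expect_equal(tortuosity(3700, 10), 370)
  expect_true(is.na(tortuosity(1000, 0)))
  # doubling coordinates doubles distance and quadruples area
  set.seed(14)
  x <- runif(50, 0, 100); y <- runif(50, 0, 100)
  ho <- sum(sqrt(diff(x)^2 + diff(y)^2))
  t1 <- tortuosity(ho, mcp_area(x, y))
  t2 <- tortuosity(2 * ho, mcp_area(2 * x, 2 * y))
  expect_equal(t2, t1 / 2, tolerance = 1e-12)
})

test_that("slope 85th percentile uses the linear-interpolation rule", {
  expect_equal(slope_q85(rep(10, 40)), 10)
  expect_equal(slope_q85(1:100), 85.15)
  expect_equal(slope_q85(rep(0, 10)), 0)
  expect_true(is.na(slope_q85(numeric(0))))
})

test_that("herd-relative metrics scale by the mob's daily elevation band", {
  # cow a: mean 150 within herd band [100, 300] -> 0.25
  day <- tibble::tibble(
    cow_id = c(rep("a", 3), rep("b", 2)),
    elevation = c(140, 150, 160, 100, 300))
  rel <- herd_relative(day)
  expect_equal(rel$rel_ele[rel$cow_id == "a"], 0.25)
  expect_equal(rel$rel_ele_range[rel$cow_id == "b"], 1.0)  # spans the band

  # oracle for the 85th-quantile variant on a 10-cow herd
  set.seed(15)
  herd <- tibble::tibble(cow_id = rep(sprintf("c%02d", 1:10), each = 40),
                         elevation = rnorm(400, 200, 30))
  rel2 <- herd_relative(herd)
  hmin <- min(herd$elevation); hrange <- diff(range(herd$elevation))
  for (id in unique(herd$cow_id)) {
    q <- quantile(herd$elevation[herd$cow_id == id], 0.85, names = FALSE)
    expect_equal(rel2$rel_ele85[rel2$cow_id == id], (q - hmin) / hrange,
                 tolerance = 1e-12)
  }
  expect_true(all(rel2$rel_ele >= 0 & rel2$rel_ele <= 1))

  # zero herd range leaves the metrics undefined
  flat <- tibble::tibble(cow_id = c("a", "b"), elevation = c(5, 5))
  expect_true(all(is.na(herd_relative(flat)$rel_ele)))
})

test_that("the 75% recording-rate filter keeps days at or above 216 fixes", {
  daily <- tibble::tibble(cow_id = "a", mob = "m", date = as.Date("2020-04-01"),
                          fix_count = c(215, 216, 288))
  out <- filter_days(daily)
  expect_equal(attr(out, "day_filter")$threshold, 216)
  expect_equal(out$valid, c(FALSE, TRUE, TRUE))
})

test_that("a zero-dropout simulation has only valid days", {
  s <- tiny_sim(seed = 16, n_mobs = 1, cows_per_mob = 2, days = 7,
                dropout_rate = 0)
  tr <- build_trajectory(s$fixes)
  ann <- annotate_fixes(tr, s$dem)
  daily <- filter_days(daily_behaviours(ann, s$metadata))
  expect_true(all(daily$valid))
})

test_that("the terrain window caps at 28 days, gates flat mobs and drops short cows", {
  mk <- function(mob, dates, slope, cow = "c1", valid = TRUE)
    tibble::tibble(cow_id = cow, mob = mob, date = dates, fix_count = 288,
                   ho_dist = 1000, ve_dist = 100, three_d_dist = 1010,
                   ele_range = 10, ele_gain = 50, rel_ele = 0.5,
                   rel_ele85 = 0.6, rel_ele_range = 0.5, slope85_pct = 20,
                   slope85_deg = 11, hr_mcp = 5, sp_tortuosity = 200,
                   herd_median_slope_deg = slope, valid = valid)
  dates <- as.Date("2020-04-01") + 0:29
  steep <- mk("m1", dates, 12)
  flat <- mk("m2", dates, 3, cow = "c2")
  short <- mk("m1", dates[1:6], 12, cow = "c3")
  daily <- rbind(steep, flat, short)
  expect_warning(expect_warning(out <- select_window(daily), "slope gate"),
                 "fewer than 7")
  expect_equal(sum(out$cow_id == "c1"), 28)      # first 28 of 30 qualifying
  expect_equal(max(out$date), dates[28])
  expect_false(any(out$cow_id == "c2"))          # flat mob gated out
  expect_false(any(out$cow_id == "c3"))          # 6 valid days -> excluded
})

test_that("profiles are arithmetic means with pairwise-missing handling", {
  md <- tibble::tibble(cow_id = c("c1", "c2"), genotype = c("BC", "CC"),
                       age_class = c(1, 2), farm = 1, mob = "m1",
                       sire = "s1", year = 2020)
  base <- tibble::tibble(
    cow_id = "c1", mob = "m1", date = as.Date("2020-04-01") + 0:2,
    fix_count = 288, ho_dist = c(1000, 2000, 3000), ve_dist = 100,
    three_d_dist = 1010, ele_range = 10, ele_gain = 50, rel_ele = 0.5,
    rel_ele85 = 0.6, rel_ele_range = 0.5, slope85_pct = 20,
    slope85_deg = 11, hr_mcp = c(2, 4, 0), sp_tortuosity = c(500, 500, NA),
    herd_median_slope_deg = 12, valid = TRUE)
  prof <- suppressWarnings(aggregate_profiles(base, md))
  expect_equal(prof$ho_dist, 2000)
  expect_equal(prof$hr_mcp, 3)        # zero-area day treated as missing
  expect_equal(prof$n_valid_days, 3)
  expect_equal(prof$genotype, "BC")

  # a single-day profile equals that day
  one <- suppressWarnings(aggregate_profiles(base[1, ], md))
  expect_equal(one$ho_dist, 1000)
  expect_equal(one$hr_mcp, 2)
})

test_that("profile means equal brute-force group-by means on simulated herds", {
  s <- tiny_sim(seed = 18, n_mobs = 2, cows_per_mob = 4, days = 7,
                dropout_rate = 0)
  ann <- annotate_fixes(build_trajectory(s$fixes), s$dem)
  daily <- filter_days(daily_behaviours(ann, s$metadata))
  ret <- select_window(daily)
  prof <- aggregate_profiles(ret, s$metadata)
  brute <- tapply(ret$ho_dist, ret$cow_id, mean)
  expect_equal(prof$ho_dist, as.numeric(brute[prof$cow_id]),
               tolerance = 1e-12)
})
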