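#' Simulation configuration for a synthetic herd
#'
#' Bundles every knob of the synthetic-data generator: herd structure
#' (farms, mobs, cows), GPS sampling (cadence, dropout), terrain (grid size,
#' relief, smoothness) and the genotype x age-class movement-style
#' parameters that create known ground-truth effects.
#'
#' The default genotype frequencies are those observed in a New Zealand
#' beef-cow GRM5 survey (306 cows over four farms); age-class frequencies
#' default to 0.3/0.4/0.3, a plausible mix for a breeding herd aged 3-10
#' years. Movement defaults give roughly 3-4 km of horizontal travel and
#' 5-10 ha of minimum-convex-polygon home range per day, with home-range
#' attraction strongest for BB cows and weakest for A-carrying heterozygotes
#' so that the simulated herd carries a recoverable genotype effect and the
#' home-range/tortuosity trade-off.
#'
#' @param seed integer; master seed. Per-cow streams are derived by stable
#'   hashing so adding a cow never perturbs the others.
#' @param n_farms,n_mobs,cows_per_mob herd structure; mobs are spread over
#'   farms and two sampling years.
#' @param days tracking days per cow (7-28).
#' @param fix_interval GPS cadence in seconds; must divide 86400.
#' @param dropout_rate i.i.d. probability that a fix is not recorded.
#' @param bursty_dropout if `TRUE`, dropout occurs in runs (two-state Markov
#'   chain with the same marginal rate) instead of independently.
#' @param outlier_rate rate of injected teleport fixes (default 0 = off);
#'   injected displacements exceed the default speed threshold at least
#'   2-fold so filter recall is measurable.
#' @param genotype_freqs named fractions over AA/AB/AC/BB/BC/CC, summing
#'   to 1.
#' @param age_class_freqs named fractions over classes 1/2/3, summing to 1.
#' @param terrain list: `n` (grid cells per side), `cellsize` (m), `relief`
#'   (max - min elevation, m), `smoothness` (correlation length, cells).
#' @param movement data frame of per-genotype x age-class movement
#'   parameters (`step_scale` m per fix, `kappa` turning-angle
#'   concentration, `attraction` home-range attraction strength, `elev_pref`
#'   preferred elevation quantile in \[0,1\]); defaults from
#'   [default_movement_params()].
#' @param start date-time (UTC) of the first fix.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_farms = 4L,
                       n_mobs = 14L,
                       cows_per_mob = 22L,
                       days = 14L,
                       fix_interval = 300L,
                       dropout_rate = 0.05,
                       bursty_dropout = FALSE,
                       outlier_rate = 0,
                       genotype_freqs = c(AA = 3, AB = 18, AC = 31,
                                          BB = 38, BC = 109, CC = 107) / 306,
                       age_class_freqs = c(`1` = 0.3, `2` = 0.4, `3` = 0.3),
                       terrain = list(n = 96L, cellsize = 16, relief = 180,
                                      smoothness = 8),
                       movement = default_movement_params(),
                       start = as.POSIXct("2020-04-01 00:00:00", tz = "UTC")) {
  cfg <- structure(
    list(seed = as.integer(seed), n_farms = as.integer(n_farms),
         n_mobs = as.integer(n_mobs), cows_per_mob = as.integer(cows_per_mob),
         days = as.integer(days), fix_interval = as.integer(fix_interval),
         dropout_rate = dropout_rate, bursty_dropout = bursty_dropout,
         outlier_rate = outlier_rate, genotype_freqs = genotype_freqs,
         age_class_freqs = age_class_freqs, terrain = terrain,
         movement = movement, start = start),
    class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  geno <- c("AA", "AB", "AC", "BB", "BC", "CC")
  if (!setequal(names(cfg$genotype_freqs), geno))
    stop("genotype_freqs must be named over ", paste(geno, collapse = "/"),
         call. = FALSE)
  if (abs(sum(cfg$genotype_freqs) - 1) > 1e-9)
    stop("genotype_freqs must sum to 1", call. = FALSE)
  if (abs(sum(cfg$age_class_freqs) - 1) > 1e-9)
    stop("age_class_freqs must sum to 1", call. = FALSE)
  if (86400L %% cfg$fix_interval != 0L)
    stop("fix_interval must divide 86400", call. = FALSE)
  if (cfg$days < 7L) stop("days must be at least 7", call. = FALSE)
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)", call. = FALSE)
  if (cfg$terrain$n < 16 || cfg$terrain$cellsize <= 0)
    stop("terrain grid must be at least 16x16 with positive cellsize",
         call. = FALSE)
  invisible(cfg)
}

#' Default genotype x age-class movement parameters
#'
#' One row per genotype x age class. `attraction` multiplies the strength of
#' the pull toward the cow's home point: higher attraction confines the walk,
#' shrinking the daily home range and (because daily distance changes little)
#' raising tortuosity. BB cows get the strongest attraction and A-carrying
#' heterozygotes the weakest, and attraction grows with age class, mirroring
#' the qualitative pattern the association stage should recover.
#'
#' @return A tibble with columns `genotype`, `age_class`, `step_scale`,
#'   `kappa`, `attraction`, `elev_pref`.
#' @export
default_movement_params <- function() {
  geno_mult <- c(AA = 0.70, AB = 0.70, AC = 0.75,
                 BB = 1.40, BC = 1.10, CC = 1.10)
  age_mult <- c(`1` = 0.85, `2` = 1.00, `3` = 1.15)
  grid <- tidyr::expand_grid(genotype = names(geno_mult),
                             age_class = as.integer(names(age_mult)))
  dplyr::mutate(grid,
    step_scale = 12,
    kappa = 1.5,
    attraction = geno_mult[.data$genotype] *
      age_mult[as.character(.data$age_class)],
    elev_pref = 0.5)
}

#' Generate a synthetic DEM
#'
#' Builds a smooth pseudo-random elevation field by Gaussian spectral
#' filtering of white noise (FFT low-pass with correlation length
#' `smoothness` cells), rescaled so that `max - min = relief`. With
#' `relief = 0` the grid is exactly flat. Deterministic given
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return A [dem_grid()] with slope/aspect grids already derived.
#' @export
generate_dem <- function(config) {
  t <- config$terrain
  n <- as.integer(t$n)
  if (n < 16) stop("terrain grid must be at least 16x16", call. = FALSE)
  set.seed(sub_seed(config$seed, "dem"))
  if (t$relief == 0) {
    z <- matrix(0, n, n)
  } else {
    noise <- matrix(rnorm(n * n), n, n)
    k <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n   # cycles per cell
    k2 <- outer(k^2, k^2, `+`)
    filt <- exp(-2 * (pi * t$smoothness)^2 * k2)
    z <- Re(stats::fft(stats::fft(noise) * filt, inverse = TRUE)) / (n * n)
    rng <- max(z) - min(z)
    z <- (z - min(z)) / rng * t$relief + 100   # 100 m base elevation
  }
  compute_slope_aspect(
    dem_grid(z, cellsize = t$cellsize, xll = 0, yll = 0))
}

#' Simulate herd structure and genotypes
#'
#' Draws cow metadata: farm, sampling year, mob, sire, genotype and age
#' class. Mobs are assigned round-robin to farm x year combinations; each
#' mob has at least two sires drawn from a shared pool.
#'
#' @param config a [sim_config()].
#' @param genotype_mode `"multinomial"` (sampled from `genotype_freqs`) or
#'   `"expected"` (deterministic largest-remainder counts, useful to
#'   reproduce published frequency tables exactly).
#' @return A tibble with columns `cow_id`, `farm`, `year`, `mob`, `sire`,
#'   `genotype`, `age_class`.
#' @export
simulate_herd <- function(config, genotype_mode = c("multinomial", "expected")) {
  genotype_mode <- match.arg(genotype_mode)
  validate_sim_config(config)
  set.seed(sub_seed(config$seed, "herd"))
  n_cows <- config$n_mobs * config$cows_per_mob
  years <- c(2019L, 2020L)
  farm_year <- tidyr::expand_grid(year = years,
                                  farm = seq_len(config$n_farms))
  fy <- farm_year[((seq_len(config$n_mobs) - 1) %% nrow(farm_year)) + 1, ]
  mobs <- tibble::tibble(mob = sprintf("mob%02d", seq_len(config$n_mobs)),
                         farm = fy$farm, year = fy$year)

  md <- tibble::tibble(
    cow_id = sprintf("cow%04d", seq_len(n_cows)),
    mob = rep(mobs$mob, each = config$cows_per_mob))
  md <- dplyr::left_join(md, mobs, by = "mob")

  # sires: shared pool, >= 2 per mob
  n_sires <- max(4L, round(n_cows / 4))
  pool <- sprintf("sire%03d", seq_len(n_sires))
  md$sire <- NA_character_
  for (m in mobs$mob) {
    rows <- which(md$mob == m)
    k <- max(2L, min(length(rows), ceiling(length(rows) / 5)))
    sires_m <- sample(pool, k)
    s <- sample(rep_len(sires_m, length(rows)))
    # guarantee at least two distinct sires actually used
    if (length(unique(s)) < 2 && length(rows) >= 2) s[1:2] <- sires_m[1:2]
    md$sire[rows] <- s
  }

  geno_names <- c("AA", "AB", "AC", "BB", "BC", "CC")
  freqs <- config$genotype_freqs[geno_names]
  if (genotype_mode == "expected") {
    counts <- largest_remainder(n_cows, freqs)
    md$genotype <- sample(rep(geno_names, counts))
  } else {
    md$genotype <- sample(geno_names, n_cows, replace = TRUE, prob = freqs)
  }
  ages <- names(config$age_class_freqs)
  md$age_class <- as.integer(
    sample(ages, n_cows, replace = TRUE, prob = config$age_class_freqs))
  md[, c("cow_id", "farm", "year", "mob", "sire", "genotype", "age_class")]
}

#' Simulate GPS trajectories for a herd
#'
#' A biased correlated random walk per cow: the heading is a
#' wrapped-normal perturbation (concentration `kappa`) of a compromise
#' between the previous heading and the bearing to the cow's home point.
#' The bias weight grows with distance from home as
#' `d / (d + R0 / attraction)` (R0 = 280 m), so cows roam freely near home
#' and are pulled back when far: stronger attraction means a smaller daily
#' home range. Step lengths are gamma(shape 2) with mean `step_scale`.
#' Cows of the same mob share a home neighbourhood. Fixes are dropped at
#' `dropout_rate`; if `outlier_rate > 0`, isolated teleport fixes
#' (displacement 2000 m, at least twice the default 2.5 m/s speed gate over
#' a 5-min step) are injected and labelled.
#'
#' @param metadata cow metadata from [simulate_herd()].
#' @param dem a [dem_grid()] covering the paddock.
#' @param config a [sim_config()].
#' @return A tibble of fixes (`cow_id`, `timestamp`, `x`, `y`,
#'   `injected_outlier`) with a `ground_truth` attribute: one row per cow of
#'   the latent parameters actually used (see [sim_ground_truth()]).
#' @export
simulate_trajectories <- function(metadata, dem, config) {
  validate_sim_config(config)
  ext <- dem_extent(dem)
  margin <- 0.08 * min(ext["xmax"] - ext["xmin"], ext["ymax"] - ext["ymin"])
  n_per_day <- 86400L %/% config$fix_interval
  n_steps <- n_per_day * config$days
  move <- config$movement

  # mob home neighbourhoods, chosen from the cow's preferred elevation band
  set.seed(sub_seed(config$seed, "homes"))
  ctr <- dem_centres(dem)
  cells <- tidyr::expand_grid(yi = seq_along(ctr$y), xi = seq_along(ctr$x))
  cells$x <- ctr$x[cells$xi]; cells$y <- ctr$y[cells$yi]
  cells$z <- dem$elevation[cbind(cells$yi, cells$xi)]
  interior <- cells$x > ext["xmin"] + margin & cells$x < ext["xmax"] - margin &
    cells$y > ext["ymin"] + margin & cells$y < ext["ymax"] - margin
  cells <- cells[interior, ]
  mob_centres <- lapply(unique(metadata$mob), function(m) {
    i <- sample.int(nrow(cells), 1)
    c(x = cells$x[i], y = cells$y[i])
  })
  names(mob_centres) <- unique(metadata$mob)

  out <- vector("list", nrow(metadata))
  gt <- vector("list", nrow(metadata))
  times <- config$start + (seq_len(n_steps) - 1) * config$fix_interval

  for (ci in seq_len(nrow(metadata))) {
    cow <- metadata[ci, ]
    pars <- move[move$genotype == cow$genotype &
                   move$age_class == cow$age_class, ]
    if (nrow(pars) != 1)
      stop("no movement parameters for genotype ", cow$genotype,
           " age class ", cow$age_class, call. = FALSE)
    set.seed(sub_seed(config$seed, cow$cow_id))
    mc <- mob_centres[[cow$mob]]
    # home point: near the mob centre, nudged toward the cow's preferred
    # elevation band within a 400 m neighbourhood
    near <- cells[abs(cells$x - mc["x"]) < 400 & abs(cells$y - mc["y"]) < 400, ]
    zq <- stats::quantile(near$z, pars$elev_pref, names = FALSE)
    hi <- which.min(abs(near$z - zq) + 0.001 * runif(nrow(near)))
    home <- c(near$x[hi], near$y[hi])
    if (home[1] < ext["xmin"] || home[1] > ext["xmax"] ||
        home[2] < ext["ymin"] || home[2] > ext["ymax"])
      stop("cow ", cow$cow_id, " home point outside DEM bounds",
           call. = FALSE)

    xy <- walk_cow(home, n_steps, pars$step_scale, pars$kappa,
                   pars$attraction, ext, margin = 2 * config$fix_interval)

    keep <- dropout_keep(n_steps, config$dropout_rate, config$bursty_dropout)
    fixes <- tibble::tibble(cow_id = cow$cow_id, timestamp = times,
                            x = xy[, 1], y = xy[, 2],
                            injected_outlier = FALSE)[keep, ]
    if (config$outlier_rate > 0 && nrow(fixes) > 4) {
      n_out <- stats::rbinom(1, nrow(fixes) - 2, config$outlier_rate)
      if (n_out > 0) {
        idx <- sort(sample(2:(nrow(fixes) - 1), n_out))
        idx <- idx[c(TRUE, diff(idx) > 1)]   # keep spikes isolated
        ang <- runif(length(idx), 0, 2 * pi)
        fixes$x[idx] <- fixes$x[idx] + 2000 * cos(ang)
        fixes$y[idx] <- fixes$y[idx] + 2000 * sin(ang)
        fixes$injected_outlier[idx] <- TRUE
      }
    }
    out[[ci]] <- fixes
    gt[[ci]] <- tibble::tibble(
      cow_id = cow$cow_id, genotype = cow$genotype,
      age_class = cow$age_class, mob = cow$mob,
      home_x = home[1], home_y = home[2], home_elevation = near$z[hi],
      step_scale = pars$step_scale, kappa = pars$kappa,
      attraction = pars$attraction, elev_pref = pars$elev_pref)
  }
  fixes <- dplyr::bind_rows(out)
  attr(fixes, "ground_truth") <- dplyr::bind_rows(gt)
  fixes
}

#' Extract the ground truth of a simulated fix table
#'
#' @param fixes the result of [simulate_trajectories()].
#' @return The per-cow latent-parameter tibble stored by the simulator.
#' @export
sim_ground_truth <- function(fixes) {
  gt <- attr(fixes, "ground_truth")
  if (is.null(gt)) stop("fixes carry no ground-truth attribute", call. = FALSE)
  gt
}

# biased correlated random walk; reflecting at the extent minus margin
walk_cow <- function(home, n, step_scale, kappa, attraction, ext, margin) {
  r0 <- 280 / attraction
  turn_sd <- 1 / sqrt(kappa)
  noise <- rnorm(n, 0, turn_sd)
  steps <- rgamma(n, shape = 2, rate = 2 / step_scale)
  xs <- numeric(n); ys <- numeric(n)
  x <- home[1]; y <- home[2]
  h <- runif(1, -pi, pi)
  xmin <- ext["xmin"] + margin * 0; xmax <- ext["xmax"]
  lo_x <- ext["xmin"] + 1; hi_x <- ext["xmax"] - 1
  lo_y <- ext["ymin"] + 1; hi_y <- ext["ymax"] - 1
  for (t in seq_len(n)) {
    dx <- home[1] - x; dy <- home[2] - y
    d <- sqrt(dx * dx + dy * dy)
    if (d > 0) {
      b <- d / (d + r0)
      mx <- (1 - b) * cos(h) + b * dx / d
      my <- (1 - b) * sin(h) + b * dy / d
      mu <- if (mx == 0 && my == 0) h else atan2(my, mx)
    } else {
      b <- 0
      mu <- h
    }
    h <- wrap_angle(mu + noise[t])
    len <- steps[t]
    if (b > 0.999) len <- min(len, d)   # hard-attraction limit: land on home
    x <- x + len * cos(h)
    y <- y + len * sin(h)
    # reflect into the paddock
    if (x < lo_x) x <- 2 * lo_x - x else if (x > hi_x) x <- 2 * hi_x - x
    if (y < lo_y) y <- 2 * lo_y - y else if (y > hi_y) y <- 2 * hi_y - y
    xs[t] <- x; ys[t] <- y
  }
  cbind(xs, ys)
}

dropout_keep <- function(n, rate, bursty) {
  if (rate <= 0) return(rep(TRUE, n))
  if (!bursty) return(runif(n) >= rate)
  # two-state Markov chain with mean burst length 6 fixes and marginal
  # dropout probability `rate`
  mean_burst <- 6
  p_rec <- 1 / mean_burst                 # leave the dropped state
  p_drop <- rate * p_rec / (1 - rate)     # enter the dropped state
  state <- runif(1) < rate                # TRUE = dropped
  keep <- logical(n)
  for (i in seq_len(n)) {
    keep[i] <- !state
    state <- if (state) runif(1) >= p_rec else runif(1) < p_drop
  }
  keep
}

#' Simulate phenotype records directly at the behaviour level
#'
#' Bypasses the GPS layer and draws daily log-scale behaviour values from
#' the mixed model the association stage assumes:
#' `y = intercept + variant/genotype effect + age effect + mob + cow + error`
#' with independent Gaussian random intercepts. Used for calibration studies
#' of the modelling layer (confidence-interval coverage, type-I error,
#' power) where simulating full trajectories would add nothing.
#'
#' @param metadata cow metadata (needs `cow_id`, `mob`, `genotype`,
#'   `age_class`; [simulate_herd()] output works).
#' @param days_per_cow number of daily records per cow.
#' @param intercept grand mean on the (log) model scale.
#' @param variant_effects named effects of carrying each variant
#'   (`c(A=, B=, C=)`), added for each variant present in the genotype.
#' @param age_effects length-3 effects of age classes 1..3.
#' @param sigma2_mob,sigma2_cow,sigma2_resid variance components.
#' @param seed integer seed.
#' @param response name of the response column (default `y`).
#' @return A tibble of daily records with metadata columns, `day` and the
#'   response.
#' @export
simulate_phenotypes <- function(metadata, days_per_cow = 7,
                                intercept = 2,
                                variant_effects = c(A = 0, B = 0, C = 0),
                                age_effects = c(0, 0, 0),
                                sigma2_mob = 0.25, sigma2_cow = 0.3,
                                sigma2_resid = 0.5,
                                seed = 1L, response = "y") {
  assert_columns(metadata, c("cow_id", "mob", "genotype", "age_class"),
                 "metadata")
  set.seed(seed)
  mobs <- unique(metadata$mob)
  b_mob <- stats::setNames(rnorm(length(mobs), 0, sqrt(sigma2_mob)), mobs)
  b_cow <- stats::setNames(rnorm(nrow(metadata), 0, sqrt(sigma2_cow)),
                           metadata$cow_id)
  gvec <- strsplit(metadata$genotype, "")
  gen_eff <- vapply(gvec, function(al)
    sum(variant_effects[unique(al)]), numeric(1))
  mu <- intercept + gen_eff + age_effects[metadata$age_class] +
    b_mob[metadata$mob] + b_cow[metadata$cow_id]
  long <- metadata[rep(seq_len(nrow(metadata)), each = days_per_cow), ]
  long$day <- rep(seq_len(days_per_cow), times = nrow(metadata))
  long[[response]] <- rep(mu, each = days_per_cow) +
    rnorm(nrow(long), 0, sqrt(sigma2_resid))
  tibble::as_tibble(long)
}
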