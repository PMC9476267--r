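#' The eleven grazing-personality behaviours
#'
#' Returns the behaviour catalogue: column name, unit and the transformation
#' used by the association stage (`log` for the seven strictly positive
#' metrics, `proportion` for the three herd-relative metrics and the slope
#' quantile modelled on a 0-1 scale).
#'
#' @return A tibble with columns `behaviour`, `unit`, `transform`.
#' @export
behaviour_catalogue <- function() {
  tibble::tribble(
    ~behaviour,       ~unit,   ~transform,
    "ho_dist",        "m/d",   "log",
    "ve_dist",        "m/d",   "log",
    "three_d_dist",   "m/d",   "log",
    "ele_range",      "m",     "log",
    "ele_gain",       "m/d",   "log",
    "rel_ele",        "0-1",   "proportion",
    "rel_ele85",      "0-1",   "proportion",
    "rel_ele_range",  "0-1",   "proportion",
    "slope85",        "0-1",   "proportion",
    "hr_mcp",         "ha/d",  "log",
    "sp_tortuosity",  "m/ha",  "log")
}

#' Daily distance and elevation metrics for one cow-day
#'
#' Definitional sums over consecutive fixes of a day: horizontal distance
#' (planar step lengths), vertical distance (sum |delta elevation|),
#' three-dimensional distance (sum of 3-D hypotenuses), elevation gain
#' (positive increments only) and elevation range (daily max - min).
#'
#' @param x,y planar coordinates (m), time-ordered.
#' @param elevation DEM-annotated elevations (m), same order.
#' @return A one-row tibble: `ho_dist`, `ve_dist`, `three_d_dist`,
#'   `ele_gain`, `ele_range`.
#' @export
daily_distances <- function(x, y, elevation) {
  n <- length(x)
  if (n < 2) {
    return(tibble::tibble(ho_dist = 0, ve_dist = 0, three_d_dist = 0,
                          ele_gain = 0,
                          ele_range = if (n == 1) 0 else NA_real_))
  }
  step <- sqrt(diff(x)^2 + diff(y)^2)
  dz <- diff(elevation)
  tibble::tibble(
    ho_dist = sum(step),
    ve_dist = sum(abs(dz)),
    three_d_dist = sum(sqrt(step^2 + dz^2)),
    ele_gain = sum(pmax(dz, 0)),
    ele_range = max(elevation) - min(elevation))
}

#' Minimum convex polygon area of a set of fixes
#'
#' Area of the convex hull over all points (a 100% MCP, no percentile
#' trimming), via the shoelace formula on the hull vertices, returned in
#' hectares. Fewer than three distinct non-collinear points give area 0.
#'
#' @param x,y coordinates in metres.
#' @return Area in hectares.
#' @export
mcp_area <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) return(0)
  h <- grDevices::chull(x, y)
  if (length(h) < 3) return(0)
  hx <- x[h]; hy <- y[h]
  area_m2 <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  area_m2 / 1e4
}

#' Movement tortuosity (spatial search pattern)
#'
#' Daily horizontal distance divided by daily home range, m/ha. Undefined
#' (NA) when the home range is zero; such days contribute missing values
#' rather than infinities.
#'
#' @param ho_dist horizontal distance, m/d.
#' @param hr_mcp home-range area, ha/d.
#' @return Tortuosity in m/ha, `NA` where `hr_mcp` is 0 or missing.
#' @export
tortuosity <- function(ho_dist, hr_mcp) {
  out <- ho_dist / hr_mcp
  out[!is.na(hr_mcp) & hr_mcp <= 0] <- NA_real_
  out
}

#' 85th percentile of per-fix slope
#'
#' Linear-interpolation quantile (R type 7) of the slope values visited
#' during a day.
#'
#' @param slope per-fix slope values (percent or degrees; returned in the
#'   same unit).
#' @return The 85th percentile, or `NA` if no finite slopes.
#' @export
slope_q85 <- function(slope) {
  slope <- slope[is.finite(slope)]
  if (length(slope) == 0) return(NA_real_)
  stats::quantile(slope, 0.85, names = FALSE, type = 7)
}

#' Herd-relative elevation metrics for one mob-day
#'
#' Scales each cow's elevation use by the elevation band its mob occupied
#' that day: `rel_ele` positions the cow's mean elevation within the herd
#' range, `rel_ele85` does the same for the cow's 85th elevation
#' percentile, and `rel_ele_range` is the cow's elevation range as a
#' fraction of the herd's. Herd statistics pool all fixes of all cows of
#' the mob on that day. A zero herd range leaves the metrics undefined.
#'
#' @param day_fixes annotated fixes of one mob-day (`cow_id`, `elevation`).
#' @return A tibble with one row per cow: `cow_id`, `rel_ele`, `rel_ele85`,
#'   `rel_ele_range`.
#' @export
herd_relative <- function(day_fixes) {
  assert_columns(day_fixes, c("cow_id", "elevation"), "day_fixes")
  el <- day_fixes$elevation
  herd_min <- min(el, na.rm = TRUE)
  herd_max <- max(el, na.rm = TRUE)
  herd_range <- herd_max - herd_min
  out <- dplyr::summarise(
    dplyr::group_by(day_fixes, .data$cow_id),
    .mean = mean(.data$elevation, na.rm = TRUE),
    .q85 = stats::quantile(.data$elevation, 0.85, names = FALSE, na.rm = TRUE,
                           type = 7),
    .range = max(.data$elevation, na.rm = TRUE) -
      min(.data$elevation, na.rm = TRUE),
    .groups = "drop")
  if (herd_range <= 0) {
    return(tibble::tibble(cow_id = out$cow_id, rel_ele = NA_real_,
                          rel_ele85 = NA_real_, rel_ele_range = NA_real_))
  }
  tibble::tibble(
    cow_id = out$cow_id,
    rel_ele = (out$.mean - herd_min) / herd_range,
    rel_ele85 = (out$.q85 - herd_min) / herd_range,
    rel_ele_range = out$.range / herd_range)
}

#' Compute daily behaviour records for every cow-day
#'
#' Splits annotated fixes into calendar days (civil midnight of `tz`) and
#' computes the eleven behaviours per cow-day, plus the mob-day herd
#' statistics (median per-fix slope, elevation band) needed by the
#' day-window gate and the relative metrics. Steps never cross a day
#' boundary.
#'
#' @param annotated annotated trajectory (from [annotate_fixes()]):
#'   `cow_id`, `timestamp`, `x`, `y`, `elevation`, `slope_deg`,
#'   `slope_pct`.
#' @param metadata cow metadata with at least `cow_id` and `mob`.
#' @param tz timezone defining the day boundary (default `"UTC"`).
#' @return A tibble with one row per cow-day: the eleven behaviours
#'   (slope85 in both percent and degrees), `fix_count`, `mob`,
#'   `herd_median_slope_deg`.
#' @export
daily_behaviours <- function(annotated, metadata, tz = "UTC") {
  assert_columns(annotated, c("cow_id", "timestamp", "x", "y", "elevation",
                              "slope_deg", "slope_pct"), "annotated fixes")
  assert_columns(metadata, c("cow_id", "mob"), "metadata")
  df <- dplyr::inner_join(
    tibble::as_tibble(annotated),
    dplyr::select(metadata, "cow_id", "mob"), by = "cow_id")
  dropped <- setdiff(unique(annotated$cow_id), unique(df$cow_id))
  if (length(dropped) > 0)
    warning(sprintf("%d cow(s) without metadata dropped", length(dropped)),
            call. = FALSE)
  df$date <- as.Date(df$timestamp, tz = tz)
  df <- dplyr::arrange(df, .data$cow_id, .data$timestamp)

  per_day <- df |>
    dplyr::group_by(.data$cow_id, .data$mob, .data$date) |>
    dplyr::group_modify(function(d, key) {
      dist <- daily_distances(d$x, d$y, d$elevation)
      hr <- mcp_area(d$x, d$y)
      dplyr::mutate(dist,
        fix_count = nrow(d),
        hr_mcp = hr,
        sp_tortuosity = tortuosity(dist$ho_dist, hr),
        slope85_pct = slope_q85(d$slope_pct),
        slope85_deg = slope_q85(d$slope_deg))
    }) |>
    dplyr::ungroup()

  herd_day <- df |>
    dplyr::group_by(.data$mob, .data$date) |>
    dplyr::summarise(
      herd_median_slope_deg = stats::median(.data$slope_deg, na.rm = TRUE),
      n_cows_day = dplyr::n_distinct(.data$cow_id),
      .groups = "drop")

  rel <- df |>
    dplyr::group_by(.data$mob, .data$date) |>
    dplyr::group_modify(~herd_relative(.x)) |>
    dplyr::ungroup()

  out <- per_day |>
    dplyr::left_join(rel, by = c("mob", "date", "cow_id")) |>
    dplyr::left_join(herd_day, by = c("mob", "date"))
  # a cow alone in its mob that day spans the whole herd band by construction;
  # relative metrics are only meaningful with >= 2 cows
  out$rel_ele[out$n_cows_day < 2] <- NA_real_
  out$rel_ele85[out$n_cows_day < 2] <- NA_real_
  out$rel_ele_range[out$n_cows_day < 2] <- NA_real_
  dplyr::select(out, "cow_id", "mob", "date", "fix_count",
                "ho_dist", "ve_dist", "three_d_dist", "ele_range",
                "ele_gain", "rel_ele", "rel_ele85", "rel_ele_range",
                "slope85_pct", "slope85_deg", "hr_mcp", "sp_tortuosity",
                "herd_median_slope_deg", "n_cows_day")
}

#' Flag days with sufficient GPS coverage
#'
#' A day is valid when at least 75% of the expected fixes were recorded:
#' 216 of 288 for the 5-minute cadence.
#'
#' @param daily daily records from [daily_behaviours()].
#' @param fix_interval cadence in seconds (default 300).
#' @param min_rate required recording rate (default 0.75).
#' @return `daily` with logical column `valid` appended; the threshold is
#'   stored in the `day_filter` attribute.
#' @export
filter_days <- function(daily, fix_interval = 300, min_rate = 0.75) {
  expected <- 86400 / fix_interval
  threshold <- min_rate * expected
  out <- dplyr::mutate(daily, valid = .data$fix_count >= threshold)
  attr(out, "day_filter") <- list(expected_fixes = expected,
                                  min_rate = min_rate,
                                  threshold = threshold)
  out
}

#' Select the terrain-gated day window and qualifying cows
#'
#' Per mob, keeps the first up-to-`max_days` calendar days on which the
#' herd-level median per-fix slope exceeded `slope_gate_deg` (rolling or
#' steeper terrain). Within the window only valid days (see
#' [filter_days()]) are retained, and cows with fewer than `min_days`
#' retained valid days are excluded entirely.
#'
#' @param daily daily records with `valid` and `herd_median_slope_deg`.
#' @param min_days minimum valid days per cow (default 7).
#' @param max_days window cap per mob (default 28).
#' @param slope_gate_deg herd median-slope gate in degrees (default 8,
#'   strict inequality).
#' @return The retained valid cow-day records; excluded cows and gated
#'   mobs are reported via warnings and the `selection` attribute.
#' @export
select_window <- function(daily, min_days = 7, max_days = 28,
                          slope_gate_deg = 8) {
  assert_columns(daily, c("cow_id", "mob", "date", "valid",
                          "herd_median_slope_deg"), "daily records")
  gate <- daily |>
    dplyr::distinct(.data$mob, .data$date, .data$herd_median_slope_deg) |>
    dplyr::filter(.data$herd_median_slope_deg > slope_gate_deg) |>
    dplyr::arrange(.data$mob, .data$date) |>
    dplyr::group_by(.data$mob) |>
    dplyr::slice_head(n = max_days) |>
    dplyr::ungroup()
  dead_mobs <- setdiff(unique(daily$mob), unique(gate$mob))
  if (length(dead_mobs) > 0)
    warning(sprintf("mob(s) never passing the %g-degree slope gate excluded: %s",
                    slope_gate_deg, paste(dead_mobs, collapse = ", ")),
            call. = FALSE)
  kept <- daily |>
    dplyr::semi_join(gate, by = c("mob", "date")) |>
    dplyr::filter(.data$valid)
  cow_days <- dplyr::count(kept, .data$cow_id)
  short <- cow_days$cow_id[cow_days$n < min_days]
  all_short <- union(short, setdiff(unique(daily$cow_id), cow_days$cow_id))
  if (length(all_short) > 0)
    warning(sprintf("%d cow(s) with fewer than %d valid days excluded",
                    length(all_short), min_days), call. = FALSE)
  out <- dplyr::filter(kept, !(.data$cow_id %in% short))
  attr(out, "selection") <- list(
    slope_gate_deg = slope_gate_deg, min_days = min_days,
    max_days = max_days, excluded_cows = sort(all_short),
    gated_mobs = dead_mobs)
  out
}

#' Aggregate daily records into per-cow behaviour profiles
#'
#' Arithmetic means of each behaviour across a cow's retained valid days,
#' on the raw measurement scale, with pairwise deletion of missing days
#' (a zero-area day contributes to the other ten behaviours but not to
#' home range or tortuosity). Metadata are joined; cows without metadata
#' are dropped with a warning.
#'
#' @param retained retained valid daily records (see [select_window()]).
#' @param metadata cow metadata (`cow_id`, `genotype`, `age_class`, `farm`,
#'   `mob`, `sire`, `year`).
#' @return A tibble with one row per cow: `n_valid_days`, the eleven
#'   behaviour means and the metadata columns.
#' @export
aggregate_profiles <- function(retained, metadata) {
  vars <- c("ho_dist", "ve_dist", "three_d_dist", "ele_range", "ele_gain",
            "rel_ele", "rel_ele85", "rel_ele_range", "slope85_pct",
            "slope85_deg", "hr_mcp", "sp_tortuosity")
  # zero-area days leave both home range and tortuosity undefined at the
  # profile stage, so a cow can qualify on the other behaviours
  retained <- dplyr::mutate(retained,
    hr_mcp = ifelse(!is.na(.data$hr_mcp) & .data$hr_mcp <= 0,
                    NA_real_, .data$hr_mcp))
  prof <- retained |>
    dplyr::group_by(.data$cow_id) |>
    dplyr::summarise(
      n_valid_days = dplyr::n(),
      dplyr::across(dplyr::all_of(vars), ~mean(.x, na.rm = TRUE)),
      .groups = "drop") |>
    dplyr::mutate(dplyr::across(dplyr::all_of(vars),
                                ~ifelse(is.nan(.x), NA_real_, .x)))
  out <- dplyr::inner_join(prof, metadata, by = "cow_id")
  n_drop <- nrow(prof) - nrow(out)
  if (n_drop > 0)
    warning(sprintf("%d cow(s) without metadata dropped from profiles",
                    n_drop), call. = FALSE)
  out
}
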