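#' Encode genotypes as variant-presence indicators
#'
#' Splits each two-allele genotype string over the variants A/B/C into
#' presence indicators (`has_A`, `has_B`, `has_C`) for the dominance
#' models, computes overall genotype frequencies, and flags genotypes whose
#' overall frequency falls below `rare_threshold` for exclusion from model
#' fitting.
#'
#' @param metadata data frame with a `genotype` column over
#'   AA/AB/AC/BB/BC/CC.
#' @param rare_threshold exclusion threshold on overall genotype frequency
#'   (default 0.05).
#' @return The input with `has_A`, `has_B`, `has_C` and `genotype_excluded`
#'   columns appended; the overall and per-farm frequency table is attached
#'   as the `frequencies` attribute.
#' @export
encode_genotypes <- function(metadata, rare_threshold = 0.05) {
  assert_columns(metadata, "genotype", "metadata")
  bad <- setdiff(unique(metadata$genotype),
                 c("AA", "AB", "AC", "BB", "BC", "CC"))
  if (length(bad) > 0)
    stop("unknown genotype(s): ", paste(bad, collapse = ", "), call. = FALSE)
  out <- dplyr::mutate(tibble::as_tibble(metadata),
    has_A = grepl("A", .data$genotype, fixed = TRUE),
    has_B = grepl("B", .data$genotype, fixed = TRUE),
    has_C = grepl("C", .data$genotype, fixed = TRUE))
  freqs <- genotype_frequencies(out)
  overall <- freqs[freqs$farm == "total", ]
  rare <- overall$genotype[overall$n / sum(overall$n) < rare_threshold]
  out$genotype_excluded <- out$genotype %in% rare
  attr(out, "frequencies") <- freqs
  attr(out, "rare_genotypes") <- rare
  out
}

#' Genotype counts and rounded percentage frequencies
#'
#' Tabulates genotype counts per farm and overall, with percentages rounded
#' to whole numbers within each farm (and within the total column), the
#' form used for published frequency tables.
#'
#' @param metadata data frame with `genotype` and (optionally) `farm`.
#' @return A tibble: `farm` (as character, plus `"total"`), `genotype`,
#'   `n`, `pct`.
#' @export
genotype_frequencies <- function(metadata) {
  assert_columns(metadata, "genotype", "metadata")
  md <- tibble::as_tibble(metadata)
  if (!"farm" %in% names(md)) md$farm <- "all"
  md$farm <- as.character(md$farm)
  per_farm <- dplyr::count(md, .data$farm, .data$genotype)
  total <- dplyr::count(md, .data$genotype)
  total$farm <- "total"
  out <- dplyr::bind_rows(per_farm, total[, c("farm", "genotype", "n")])
  out <- out |>
    dplyr::group_by(.data$farm) |>
    dplyr::mutate(pct = round(100 * .data$n / sum(.data$n))) |>
    dplyr::ungroup()
  dplyr::arrange(out, .data$farm != "total", .data$farm, .data$genotype)
}

#' Bundled example genotype survey counts
#'
#' Per-farm GRM5 exon-5 genotype counts for 306 beef cows over four New
#' Zealand farms, the worked frequency-accounting example used throughout
#' the documentation and tests.
#'
#' @return A tibble with columns `farm`, `genotype`, `n`.
#' @export
example_genotype_counts <- function() {
  counts <- matrix(c(
    0, 1, 1, 1,     # AA
    4, 3, 4, 7,     # AB
    11, 6, 5, 9,    # AC
    5, 3, 20, 10,   # BB
    36, 23, 25, 25, # BC
    27, 25, 29, 26  # CC
  ), nrow = 6, byrow = TRUE,
  dimnames = list(c("AA", "AB", "AC", "BB", "BC", "CC"), 1:4))
  tibble::as_tibble(as.table(counts), .name_repair = "minimal") |>
    stats::setNames(c("genotype", "farm", "n")) |>
    dplyr::mutate(n = as.integer(.data$n)) |>
    dplyr::arrange(.data$farm, .data$genotype)
}

#' Transform behaviour responses for modelling
#'
#' Applies the catalogue transformations ([behaviour_catalogue()]): natural
#' log for the seven strictly positive behaviours (non-positive rows are
#' dropped per behaviour with a count), and the 0-1 proportion scale for
#' the herd-relative metrics and the slope 85th percentile
#' (`slope85 = slope85_pct / 100`, capped just below 1 so a logit link is
#' always defined).
#'
#' @param records daily records or profiles containing behaviour columns.
#' @return The input with `log_*` columns and a `slope85` proportion column
#'   appended; the response-to-column map is attached as the
#'   `response_map` attribute.
#' @export
transform_responses <- function(records) {
  cat <- behaviour_catalogue()
  out <- tibble::as_tibble(records)
  map <- list()
  dropped <- integer()
  for (i in seq_len(nrow(cat))) {
    b <- cat$behaviour[i]
    col <- if (b == "slope85") "slope85_pct" else b
    if (!col %in% names(out)) next
    if (cat$transform[i] == "log") {
      newcol <- paste0("log_", b)
      vals <- out[[col]]
      npos <- sum(!is.na(vals) & vals <= 0)
      if (npos > 0) dropped[b] <- npos
      lv <- rep(NA_real_, length(vals))
      pos <- !is.na(vals) & vals > 0
      lv[pos] <- log(vals[pos])
      out[[newcol]] <- lv
      map[[b]] <- list(column = newcol, transform = "log")
    } else {
      if (b == "slope85") {
        out$slope85 <- pmin(out$slope85_pct / 100, 1 - 1e-6)
        map[[b]] <- list(column = "slope85", transform = "proportion")
      } else {
        map[[b]] <- list(column = b, transform = "proportion")
      }
    }
  }
  if (length(dropped) > 0)
    message("non-positive values set missing before log transform: ",
            paste(sprintf("%s (%d)", names(dropped), dropped),
                  collapse = ", "))
  attr(out, "response_map") <- map
  out
}

#' Pearson correlation matrix of behaviour profiles
#'
#' Pairwise-complete Pearson correlations between the eleven per-cow
#' behaviour means, with two-sided p-values from the t distribution and
#' the conventional star annotation (0.05 / 0.01 / 0.001).
#'
#' @param profiles per-cow profiles from [aggregate_profiles()].
#' @param behaviours behaviour columns to correlate; defaults to the
#'   catalogue (slope85 taken in percent).
#' @return A tibble of class `gp_correlation`: `behaviour1`, `behaviour2`,
#'   `r`, `p`, `n`, `stars` for every unordered pair.
#' @export
correlation_matrix <- function(profiles, behaviours = NULL) {
  if (is.null(behaviours)) {
    behaviours <- behaviour_catalogue()$behaviour
    behaviours[behaviours == "slope85"] <- "slope85_pct"
  }
  behaviours <- intersect(behaviours, names(profiles))
  if (nrow(profiles) < 3)
    stop("need at least 3 cows for correlations", call. = FALSE)
  pairs <- utils::combn(behaviours, 2, simplify = FALSE)
  rows <- purrr::map_dfr(pairs, function(pr) {
    xx <- profiles[[pr[1]]]; yy <- profiles[[pr[2]]]
    ok <- stats::complete.cases(xx, yy)
    n <- sum(ok)
    if (n < 3 || stats::sd(xx[ok]) == 0 || stats::sd(yy[ok]) == 0) {
      return(tibble::tibble(behaviour1 = pr[1], behaviour2 = pr[2],
                            r = NA_real_, p = NA_real_, n = n))
    }
    ct <- stats::cor.test(xx[ok], yy[ok], method = "pearson")
    tibble::tibble(behaviour1 = pr[1], behaviour2 = pr[2],
                   r = unname(ct$estimate), p = ct$p.value, n = n)
  })
  rows$stars <- dplyr::case_when(
    is.na(rows$p) ~ "",
    rows$p < 0.001 ~ "***",
    rows$p < 0.01 ~ "**",
    rows$p < 0.05 ~ "*",
    TRUE ~ "")
  class(rows) <- c("gp_correlation", class(rows))
  rows
}

#' Spread a correlation table into a square matrix
#'
#' @param corr a `gp_correlation` tibble.
#' @param value `"r"` or `"p"`.
#' @return A symmetric matrix with unit (r) or zero (p) diagonal.
#' @export
correlation_as_matrix <- function(corr, value = c("r", "p")) {
  value <- match.arg(value)
  vars <- unique(c(corr$behaviour1, corr$behaviour2))
  m <- matrix(if (value == "r") 1 else 0, length(vars), length(vars),
              dimnames = list(vars, vars))
  for (i in seq_len(nrow(corr))) {
    v <- corr[[value]][i]
    m[corr$behaviour1[i], corr$behaviour2[i]] <- v
    m[corr$behaviour2[i], corr$behaviour1[i]] <- v
  }
  m
}
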