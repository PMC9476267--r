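#' Run the full genotype-association suite over all behaviours
#'
#' For each behaviour: selects a random structure from the candidate list
#' (intercept-only ML fits, AIC/df/BIC compromise), then fits the three
#' variant-presence (dominance) models and the genotype model, deciding
#' the age-class fixed factor per model by ML comparison, refitting by
#' REML, and extracting marginal means, term p-values and residual
#' diagnostics. Where the genotype model is significant, a
#' Benjamini-Hochberg post-hoc with compact letters is run over
#' genotype (x age-class when retained) groups.
#'
#' Cows of rare genotypes (overall frequency below `rare_threshold`) are
#' excluded before fitting. P-values are not adjusted across behaviours;
#' each behaviour is reported on its own.
#'
#' @param daily valid daily behaviour records (the modelling table;
#'   repeated measures per cow), e.g. from [select_window()].
#' @param metadata cow metadata (`cow_id`, `genotype`, `age_class`,
#'   `farm`, `mob`, `sire`, `year`); may be omitted if the columns are
#'   already on `daily`.
#' @param behaviours behaviours to analyse (default: all eleven).
#' @param glmm_mode bounded-response strategy, see [fit_mixed_model()].
#' @param candidates random-structure candidates
#'   ([enumerate_random_structures()] by default).
#' @param random_structure optional fixed random-factor vector; skips the
#'   selection step when given.
#' @param alpha significance level for decisions and letters.
#' @param rare_threshold rare-genotype exclusion frequency.
#' @return A list of class `gp_association`: `variants` (per behaviour x
#'   variant results), `genotype` (per-behaviour genotype-model results),
#'   `random` (chosen structures), `posthoc` (named list of `gp_posthoc`),
#'   `fits` (named list of final `gp_fit` objects), `n_cows`, `alpha`.
#' @export
run_association_suite <- function(daily, metadata = NULL,
                                  behaviours = NULL,
                                  glmm_mode = c("binomial", "logit-lmm"),
                                  candidates = enumerate_random_structures(),
                                  random_structure = NULL,
                                  alpha = 0.05,
                                  rare_threshold = 0.05) {
  glmm_mode <- match.arg(glmm_mode)
  df <- tibble::as_tibble(daily)
  if (!is.null(metadata))
    df <- dplyr::inner_join(
      df, dplyr::select(metadata, -dplyr::any_of(setdiff(
        intersect(names(metadata), names(df)), "cow_id"))),
      by = "cow_id")
  need <- c("cow_id", "genotype", "age_class", "mob")
  assert_columns(df, need, "modelling table")
  df <- encode_genotypes(df, rare_threshold = rare_threshold)
  rare <- attr(df, "rare_genotypes")
  n0 <- dplyr::n_distinct(df$cow_id)
  df <- dplyr::filter(df, !.data$genotype_excluded)
  n1 <- dplyr::n_distinct(df$cow_id)
  if (length(rare) > 0)
    message(sprintf(
      "rare genotype(s) %s excluded: %d -> %d cows in the modelling table",
      paste(rare, collapse = ", "), n0, n1))
  if (dplyr::n_distinct(df$genotype) < 2)
    stop("fewer than 2 genotype groups after rare-genotype exclusion",
         call. = FALSE)
  df <- transform_responses(df)
  rmap <- attr(df, "response_map")
  df <- dplyr::mutate(df,
    genotype = factor(.data$genotype),
    age_class = factor(.data$age_class),
    mob = factor(.data$mob),
    cow_id = factor(.data$cow_id))
  for (cc in intersect(c("farm", "year", "sire"), names(df)))
    df[[cc]] <- factor(df[[cc]])

  behaviours <- behaviours %||% names(rmap)
  variants <- c("A", "B", "C")
  var_rows <- list(); gen_rows <- list(); rand_rows <- list()
  posthoc <- list(); fits <- list()

  for (b in behaviours) {
    info <- rmap[[b]]
    if (is.null(info)) { warning("behaviour not found: ", b); next }
    resp <- info$column
    family <- if (info$transform == "log") "gaussian" else "binomial"
    transform <- if (info$transform == "log") "log" else "logit"
    d <- df[!is.na(df[[resp]]), , drop = FALSE]
    if (nrow(d) == 0) {
      warning("behaviour with all-missing values skipped: ", b,
              call. = FALSE)
      next
    }
    rs <- if (is.null(random_structure)) {
      select_random_structure(d, resp, candidates = candidates,
                              family = family, glmm_mode = glmm_mode)
    } else list(random = random_structure, id = "fixed", ranking = NULL)
    rand_rows[[b]] <- tibble::tibble(
      behaviour = b, random_id = rs$id,
      random_label = paste(rs$random, collapse = " + "))

    for (v in variants) {
      term <- paste0("has_", v)
      if (dplyr::n_distinct(d[[term]]) < 2) {
        var_rows[[paste(b, v)]] <- tibble::tibble(
          behaviour = b, variant = v, n_obs = nrow(d), age_p = NA_real_,
          age_included = NA, mm_present = NA_real_, mm_se = NA_real_,
          p_value = NA_real_, resid_frac = NA_real_, resid_pass = NA)
        next
      }
      sel <- select_fixed_structure(d, resp, rs$random, term,
                                    family = family, glmm_mode = glmm_mode,
                                    transform = transform, alpha = alpha)
      mm <- marginal_means(sel$fit, term)
      present <- mm[mm[[term]] == TRUE, ]
      td <- tidy(sel$fit)
      prow <- td[grepl(paste0("^", term), td$term), ]
      rd <- residual_diagnostics(sel$fit)
      fits[[paste(b, v, sep = "_")]] <- sel$fit
      var_rows[[paste(b, v)]] <- tibble::tibble(
        behaviour = b, variant = v, n_obs = nrow(d), age_p = sel$age_p,
        age_included = sel$age_included,
        mm_present = present$response[1], mm_se = present$se[1],
        p_value = prow$p_value[1],
        resid_frac = rd$frac_beyond, resid_pass = rd$pass)
    }

    # genotype cannot be both the fixed predictor under test and a random
    # intercept; drop it from the random part for the genotype model
    rand_g <- setdiff(rs$random, "genotype")
    selg <- select_fixed_structure(d, resp, rand_g, "genotype",
                                   family = family, glmm_mode = glmm_mode,
                                   transform = transform, alpha = alpha)
    gp <- term_anova_p(selg$fit, "genotype", d)
    rdg <- residual_diagnostics(selg$fit)
    fits[[paste(b, "genotype", sep = "_")]] <- selg$fit
    gen_rows[[b]] <- tibble::tibble(
      behaviour = b, n_obs = nrow(d), age_p = selg$age_p,
      age_included = selg$age_included, p_value = gp,
      resid_frac = rdg$frac_beyond, resid_pass = rdg$pass)
    if (is.finite(gp) && gp < alpha) {
      grouping <- c("genotype", if (selg$age_included) "age_class")
      mmg <- marginal_means(selg$fit, grouping)
      posthoc[[b]] <- posthoc_bh(mmg, alpha = alpha)
      attr(posthoc[[b]], "marginal_means") <- mmg
    }
  }

  structure(
    list(variants = dplyr::bind_rows(var_rows),
         genotype = dplyr::bind_rows(gen_rows),
         random = dplyr::bind_rows(rand_rows),
         posthoc = posthoc, fits = fits,
         n_cows = n1, rare_genotypes = rare,
         glmm_mode = glmm_mode, alpha = alpha),
    class = "gp_association")
}

#' @export
print.gp_association <- function(x, ...) {
  cat(sprintf("<gp_association> %d cows, %d behaviours, glmm_mode = %s\n",
              x$n_cows, nrow(x$genotype), x$glmm_mode))
  cat("variant-presence models (marginal mean when variant present):\n")
  print(x$variants, n = Inf)
  cat("genotype models:\n")
  print(x$genotype, n = Inf)
  if (length(x$posthoc) > 0)
    cat("post-hoc letter displays for:",
        paste(names(x$posthoc), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy an association suite result
#'
#' @param x a `gp_association`.
#' @param ... unused.
#' @return The per-behaviour x variant results tibble.
#' @method tidy gp_association
#' @export
tidy.gp_association <- function(x, ...) x$variants

#' One-line-per-behaviour summary of an association suite
#'
#' @param x a `gp_association`.
#' @param ... unused.
#' @method glance gp_association
#' @export
glance.gp_association <- function(x, ...) {
  dplyr::left_join(x$genotype,
                   dplyr::select(x$random, "behaviour", "random_id",
                                 "random_label"),
                   by = "behaviour")
}
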