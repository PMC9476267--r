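#' Candidate random-intercept structures
#'
#' The default list of twelve random-factor combinations screened before
#' fixed-effect modelling. Every combination contains the cow identity
#' intercept (repeated daily measurements are nested in cow), and the list
#' includes the structures most often selected in rangeland grazing data:
#' sampling year with farm-within-year, mob alone, and mob with sire.
#'
#' @return A tibble: `id`, `label`, and a list-column `factors` of random
#'   intercept terms.
#' @export
enumerate_random_structures <- function() {
  f <- list(
    RF1  = c("cow_id"),
    RF2  = c("cow_id", "farm"),
    RF3  = c("cow_id", "year"),
    RF4  = c("cow_id", "year", "farm:year"),
    RF5  = c("cow_id", "farm", "year"),
    RF6  = c("cow_id", "mob"),
    RF7  = c("cow_id", "mob", "sire"),
    RF8  = c("cow_id", "sire"),
    RF9  = c("cow_id", "farm", "mob"),
    RF10 = c("cow_id", "genotype"),
    RF11 = c("cow_id", "mob", "genotype"),
    RF12 = c("cow_id", "farm", "year", "mob"))
  tibble::tibble(
    id = names(f),
    label = vapply(f, paste, "", collapse = " + "),
    factors = unname(f))
}

model_formula <- function(response, fixed, random) {
  rhs <- c(if (length(fixed) > 0) fixed else "1",
           if (length(random) > 0) sprintf("(1 | %s)", random))
  stats::as.formula(paste(response, "~", paste(rhs, collapse = " + ")))
}

#' Fit a (generalised) linear mixed model for a behaviour
#'
#' Gaussian responses (the log-transformed behaviours) are fitted with
#' `lmerTest::lmer()` so that fixed effects carry Satterthwaite
#' denominator degrees of freedom. Bounded 0-1 responses use a logit-link
#' binomial `lme4::glmer()` with unit weights (`glmm_mode = "binomial"`,
#' the default) or, alternatively, a Gaussian mixed model on the
#' epsilon-clipped logit of the response (`glmm_mode = "logit-lmm"`).
#' With no random factors the fit degenerates to `lm()`/`glm()`.
#'
#' @param data modelling table.
#' @param response response column name.
#' @param fixed character vector of fixed-effect terms (may be empty).
#' @param random character vector of random intercept factors.
#' @param family `"gaussian"` or `"binomial"`.
#' @param estimation `"REML"` or `"ML"` (Gaussian only; binomial fits are
#'   always ML-based).
#' @param glmm_mode bounded-response strategy, see above.
#' @param transform back-transformation tag carried to the marginal-means
#'   stage: `"identity"`, `"log"` or `"logit"` (set automatically by the
#'   association suite).
#' @return An object of class `gp_fit`.
#' @export
fit_mixed_model <- function(data, response, fixed = character(),
                            random = "cow_id",
                            family = c("gaussian", "binomial"),
                            estimation = c("REML", "ML"),
                            glmm_mode = c("binomial", "logit-lmm"),
                            transform = NULL) {
  family <- match.arg(family)
  estimation <- match.arg(estimation)
  glmm_mode <- match.arg(glmm_mode)
  data <- as.data.frame(data)
  for (rf in setdiff(unlist(strsplit(random, ":")), names(data)))
    stop("random factor not in data: ", rf, call. = FALSE)
  for (rf in random) {
    lev <- unique(interaction(data[strsplit(rf, ":")[[1]]], drop = TRUE))
    if (length(lev) < 2)
      stop("random factor ", rf, " has fewer than 2 levels", call. = FALSE)
  }
  resp_col <- response
  if (family == "binomial" && glmm_mode == "logit-lmm") {
    data$.logit_y <- stats::qlogis(clip01(data[[response]]))
    resp_col <- ".logit_y"
    transform <- transform %||% "logit"
    family <- "gaussian"
  }
  if (is.null(transform))
    transform <- if (family == "binomial") "logit" else "identity"
  fml <- model_formula(resp_col, fixed, random)

  singular <- FALSE; converged <- TRUE
  model <- withCallingHandlers(
    {
      if (length(random) == 0) {
        if (family == "gaussian") stats::lm(fml, data = data)
        else stats::glm(fml, data = data, family = stats::binomial())
      } else if (family == "gaussian") {
        lmerTest::lmer(fml, data = data, REML = estimation == "REML")
      } else {
        # PIRLS can stall on continuous proportions; escalate through
        # progressively more conservative optimizer settings
        tryCatch(
          lme4::glmer(fml, data = data, family = stats::binomial()),
          error = function(e) tryCatch(
            lme4::glmer(fml, data = data, family = stats::binomial(),
                        control = lme4::glmerControl(optimizer = "bobyqa")),
            error = function(e2) tryCatch(
              lme4::glmer(fml, data = data, family = stats::binomial(),
                          nAGQ = 0),
              error = function(e3) NULL)))
      }
    },
    message = function(m) {
      if (grepl("singular|converge", conditionMessage(m), ignore.case = TRUE))
        invokeRestart("muffleMessage")
    },
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("non-integer", msg)) {
        invokeRestart("muffleWarning")   # expected: continuous proportions
      } else if (grepl("singular|converge", msg, ignore.case = TRUE)) {
        if (grepl("singular", msg, ignore.case = TRUE)) singular <<- TRUE
        else converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    })
  if (is.null(model)) {
    # the binomial GLMM would not fit at all: fall back to the Gaussian
    # mixed model on the epsilon-clipped logit, and say so on the object
    out <- fit_mixed_model(data, response, fixed = fixed, random = random,
                           family = "binomial", estimation = estimation,
                           glmm_mode = "logit-lmm", transform = transform)
    out$fallback <- TRUE
    return(out)
  }
  if (inherits(model, "merMod") && lme4::isSingular(model, tol = 1e-5))
    singular <- TRUE
  structure(
    list(model = model, response = response, response_col = resp_col,
         fixed = fixed, random = random, family = family,
         estimation = if (family == "binomial") "ML" else estimation,
         glmm_mode = glmm_mode, transform = transform,
         converged = converged, singular = singular,
         n = stats::nobs(model)),
    class = "gp_fit")
}

#' @export
print.gp_fit <- function(x, ...) {
  cat(sprintf("<gp_fit> %s ~ %s | random: %s [%s, %s]%s%s\n",
              x$response,
              if (length(x$fixed)) paste(x$fixed, collapse = " + ") else "1",
              paste(x$random, collapse = " + "),
              x$family, x$estimation,
              if (x$singular) " (singular)" else "",
              if (!x$converged) " (non-convergence)" else ""))
  g <- generics::glance(x)
  cat(sprintf("  n = %d, logLik = %.2f, AIC = %.2f, BIC = %.2f, df = %d\n",
              g$nobs, g$logLik, g$AIC, g$BIC, g$df))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy fixed-effect estimates of a behaviour model
#'
#' One row per fixed-effect coefficient: estimate, standard error, test
#' statistic and p-value (Satterthwaite t for Gaussian mixed fits, Wald z
#' for binomial fits).
#'
#' @param x a `gp_fit`.
#' @param ... unused.
#' @method tidy gp_fit
#' @export
tidy.gp_fit <- function(x, ...) {
  cf <- stats::coef(summary(x$model))
  out <- tibble::tibble(
    term = rownames(cf),
    estimate = unname(cf[, "Estimate"]),
    std_error = unname(cf[, "Std. Error"]))
  if ("df" %in% colnames(cf)) out$df <- unname(cf[, "df"])
  tcol <- intersect(c("t value", "z value"), colnames(cf))[1]
  pcol <- intersect(c("Pr(>|t|)", "Pr(>|z|)"), colnames(cf))
  out$statistic <- unname(cf[, tcol])
  out$p_value <- if (length(pcol) > 0) unname(cf[, pcol[1]]) else NA_real_
  out
}

#' Model-level statistics of a behaviour model
#'
#' @param x a `gp_fit`.
#' @param ... unused.
#' @method glance gp_fit
#' @export
glance.gp_fit <- function(x, ...) {
  ll <- stats::logLik(x$model)
  tibble::tibble(
    logLik = as.numeric(ll),
    df = attr(ll, "df"),
    AIC = stats::AIC(x$model),
    BIC = stats::BIC(x$model),
    nobs = stats::nobs(x$model),
    converged = x$converged,
    singular = x$singular)
}

#' Select a random structure by the AIC/df/BIC compromise
#'
#' Fits every candidate random structure as an intercept-only model by
#' maximum likelihood and applies a deterministic "best compromise" rule:
#' rank by AIC; among candidates within `delta_aic` of the best, prefer
#' the fewest parameters, then the lowest BIC, then enumeration order.
#' The choice is then simplified: if a strictly nested simpler candidate
#' is not rejected by a likelihood-ratio test at `alpha`, the simplest
#' such candidate is preferred (added variance terms must earn their
#' keep).
#'
#' @param data modelling table.
#' @param response response column.
#' @param candidates candidate tibble from [enumerate_random_structures()].
#' @param family,glmm_mode passed to [fit_mixed_model()].
#' @param delta_aic AIC band treated as equivalent (default 2).
#' @param alpha LRT level for the simplification step (default 0.05).
#' @return A list: `random` (chosen factor vector), `id`, and `ranking`
#'   (per-candidate fit statistics).
#' @export
select_random_structure <- function(data, response,
                                    candidates = enumerate_random_structures(),
                                    family = "gaussian",
                                    glmm_mode = "binomial",
                                    delta_aic = 2, alpha = 0.05) {
  fits <- vector("list", nrow(candidates))
  rows <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    fit <- tryCatch(
      fit_mixed_model(data, response, fixed = character(),
                      random = candidates$factors[[i]], family = family,
                      estimation = "ML", glmm_mode = glmm_mode),
      error = function(e) NULL)
    fits[[i]] <- fit
    rows[[i]] <- if (is.null(fit)) {
      tibble::tibble(id = candidates$id[i], label = candidates$label[i],
                     df = NA_integer_, logLik = NA_real_, AIC = NA_real_,
                     BIC = NA_real_, converged = FALSE, singular = NA)
    } else {
      g <- generics::glance(fit)
      tibble::tibble(id = candidates$id[i], label = candidates$label[i],
                     df = g$df, logLik = g$logLik, AIC = g$AIC, BIC = g$BIC,
                     converged = g$converged, singular = g$singular)
    }
  }
  ranking <- dplyr::bind_rows(rows)
  ok <- which(!is.na(ranking$AIC) & ranking$converged)
  if (length(ok) == 0) stop("no candidate random structure converged",
                            call. = FALSE)
  best_aic <- min(ranking$AIC[ok])
  near <- ok[ranking$AIC[ok] <= best_aic + delta_aic]
  near <- near[order(ranking$df[near], ranking$BIC[near], near)]
  pick <- near[1]
  # simplification: prefer the simplest nested candidate the data cannot
  # distinguish from the pick
  repeat {
    chosen_set <- candidates$factors[[pick]]
    nested <- ok[vapply(ok, function(i) {
      s <- candidates$factors[[i]]
      length(s) < length(chosen_set) && all(s %in% chosen_set)
    }, logical(1))]
    nested <- nested[order(ranking$df[nested], nested)]
    moved <- FALSE
    for (i in nested) {
      lrt <- 2 * (ranking$logLik[pick] - ranking$logLik[i])
      ddf <- ranking$df[pick] - ranking$df[i]
      p <- stats::pchisq(max(lrt, 0), df = max(ddf, 1), lower.tail = FALSE)
      if (p >= alpha) { pick <- i; moved <- TRUE; break }
    }
    if (!moved) break
  }
  list(random = candidates$factors[[pick]], id = candidates$id[pick],
       ranking = ranking)
}

#' Decide the age-class fixed factor and fit the final model
#'
#' With the random structure set, compares maximum-likelihood fits with
#' and without the cow age-class factor (the genetic predictor under test
#' is always retained) and keeps age class when the likelihood-ratio
#' comparison is significant at `alpha`. The final model is refitted by
#' REML.
#'
#' @param data modelling table.
#' @param response response column.
#' @param random chosen random factor vector.
#' @param genetic_term the predictor under test (`"has_A"`, `"has_B"`,
#'   `"has_C"` or `"genotype"`).
#' @param family,glmm_mode,transform passed to [fit_mixed_model()].
#' @param alpha significance level for the age-class decision.
#' @return A list: `fit` (final REML `gp_fit`), `age_p`, `age_included`.
#' @export
select_fixed_structure <- function(data, response, random, genetic_term,
                                   family = "gaussian",
                                   glmm_mode = "binomial",
                                   transform = NULL, alpha = 0.05) {
  m0 <- fit_mixed_model(data, response, fixed = genetic_term,
                        random = random, family = family,
                        estimation = "ML", glmm_mode = glmm_mode,
                        transform = transform)
  m1 <- fit_mixed_model(data, response,
                        fixed = c(genetic_term, "age_class"),
                        random = random, family = family,
                        estimation = "ML", glmm_mode = glmm_mode,
                        transform = transform)
  if (isTRUE(m0$fallback) || isTRUE(m1$fallback)) {
    # keep the likelihoods comparable: if either model needed the logit-LMM
    # fallback, compare (and fit) both on that scale
    glmm_mode <- "logit-lmm"
    m0 <- fit_mixed_model(data, response, fixed = genetic_term,
                          random = random, family = family,
                          estimation = "ML", glmm_mode = glmm_mode,
                          transform = transform)
    m1 <- fit_mixed_model(data, response,
                          fixed = c(genetic_term, "age_class"),
                          random = random, family = family,
                          estimation = "ML", glmm_mode = glmm_mode,
                          transform = transform)
  }
  g0 <- generics::glance(m0); g1 <- generics::glance(m1)
  lrt <- 2 * (g1$logLik - g0$logLik)
  age_p <- stats::pchisq(max(lrt, 0), df = max(g1$df - g0$df, 1),
                         lower.tail = FALSE)
  age_included <- is.finite(age_p) && age_p < alpha
  fixed <- c(genetic_term, if (age_included) "age_class")
  fit <- fit_mixed_model(data, response, fixed = fixed, random = random,
                         family = family, estimation = "REML",
                         glmm_mode = glmm_mode, transform = transform)
  list(fit = fit, age_p = age_p, age_included = age_included)
}

# p-value for dropping `term` from a fitted gp_fit (ML likelihood ratio)
term_anova_p <- function(fit, term, data) {
  fixed0 <- setdiff(fit$fixed, term)
  m1 <- fit_mixed_model(data, fit$response, fixed = fit$fixed,
                        random = fit$random, family = fit$family,
                        estimation = "ML", glmm_mode = fit$glmm_mode,
                        transform = fit$transform)
  m0 <- fit_mixed_model(data, fit$response, fixed = fixed0,
                        random = fit$random, family = fit$family,
                        estimation = "ML", glmm_mode = fit$glmm_mode,
                        transform = fit$transform)
  g1 <- generics::glance(m1); g0 <- generics::glance(m0)
  stats::pchisq(max(2 * (g1$logLik - g0$logLik), 0),
                df = max(g1$df - g0$df, 1), lower.tail = FALSE)
}

#' Scaled-residual diagnostics
#'
#' Computes scaled (Pearson) residuals against fitted values and the
#' fraction falling beyond `limit` in absolute value. A model is accepted
#' when that fraction does not exceed `max_frac` (default 5% beyond +-3).
#'
#' @param fit a `gp_fit`.
#' @param limit residual limit (default 3).
#' @param max_frac acceptance threshold on the outlying fraction.
#' @return A list of class `gp_resid`: `data` (fitted, residual tibble),
#'   `frac_beyond`, `pass`, `limit`.
#' @export
residual_diagnostics <- function(fit, limit = 3, max_frac = 0.05) {
  m <- fit$model
  raw <- stats::resid(m)
  r <- if (inherits(m, "merMod"))
    stats::resid(m, type = "pearson", scaled = TRUE)
  else stats::rstandard(m)
  r <- as.numeric(r)
  # an (essentially) exact fit has no meaningful scaled residuals
  if (stats::sd(raw) < 1e-10 * (1 + stats::sd(stats::fitted(m))))
    r <- rep(0, length(r))
  r[!is.finite(r)] <- 0
  d <- tibble::tibble(fitted = stats::fitted(m), residual = r)
  frac <- mean(abs(d$residual) > limit, na.rm = TRUE)
  structure(list(data = d, frac_beyond = frac, pass = frac <= max_frac,
                 limit = limit, max_frac = max_frac),
            class = "gp_resid")
}

#' @export
print.gp_resid <- function(x, ...) {
  cat(sprintf("<gp_resid> %.2f%% of scaled residuals beyond +-%g: %s\n",
              100 * x$frac_beyond, x$limit,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Estimated marginal means, back-transformed to measured units
#'
#' Marginal means over a grouping factor (or factor pair), averaging the
#' levels of the other fixed factors with equal weights, with standard
#' errors propagated to the response scale by the delta method:
#' `exp()` for log-transformed responses, inverse logit for bounded ones.
#'
#' @param fit a `gp_fit`.
#' @param grouping character vector of grouping factor(s), e.g.
#'   `"genotype"` or `c("genotype", "age_class")`.
#' @return A tibble of class `gp_emm` (grouping columns, `emmean_link`,
#'   `response`, `se`, `df`) with the `emmGrid` stored as an attribute for
#'   post-hoc use.
#' @export
marginal_means <- function(fit, grouping) {
  spec <- stats::as.formula(paste("~", paste(grouping, collapse = " * ")))
  emm <- emmeans::emmeans(fit$model, spec,
                          lmer.df = "satterthwaite",
                          lmerTest.limit = 1e5)
  tran <- switch(fit$transform, log = "log", logit = NULL, identity = NULL)
  if (!is.null(tran)) emm <- update(emm, tran = tran)
  if (fit$transform == "logit" && fit$glmm_mode == "logit-lmm")
    emm <- update(emm, tran = "logit")
  link <- as.data.frame(summary(emm, infer = c(FALSE, FALSE)))
  resp <- as.data.frame(summary(emm, type = "response",
                                infer = c(FALSE, FALSE)))
  est_col <- intersect(c("response", "prob", "emmean"), names(resp))[1]
  out <- tibble::as_tibble(resp[grouping])
  out$emmean_link <- link$emmean
  out$response <- resp[[est_col]]
  out$se <- resp$SE
  out$df <- resp$df
  class(out) <- c("gp_emm", class(out))
  attr(out, "emmGrid") <- emm
  attr(out, "grouping") <- grouping
  attr(out, "transform") <- fit$transform
  out
}

#' Pairwise comparisons with Benjamini-Hochberg adjustment and letters
#'
#' All pairwise contrasts between marginal-mean groups on the link scale,
#' p-values adjusted over the family of pairs with the Benjamini-Hochberg
#' procedure, and a compact letter display built by insert-and-absorb so
#' that two groups share a letter exactly when their adjusted p-value is
#' at or above `alpha`.
#'
#' @param mm a `gp_emm` from [marginal_means()].
#' @param alpha significance level for the letters (default 0.05).
#' @return A list of class `gp_posthoc`: `pairs` (contrast tibble),
#'   `letters` (group, letters tibble), `alpha`.
#' @export
posthoc_bh <- function(mm, alpha = 0.05) {
  emm <- attr(mm, "emmGrid")
  if (is.null(emm)) stop("mm must come from marginal_means()", call. = FALSE)
  grouping <- attr(mm, "grouping")
  prs <- as.data.frame(summary(emmeans::contrast(emm, method = "pairwise",
                                                 adjust = "BH")))
  groups <- do.call(paste, mm[grouping])
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  stat_col <- intersect(c("t.ratio", "z.ratio"), names(prs))[1]
  pairs_tbl <- tibble::tibble(
    contrast = prs$contrast,
    estimate = prs$estimate,
    se = prs$SE,
    df = if ("df" %in% names(prs)) prs$df else NA_real_,
    statistic = prs[[stat_col]],
    p_adj = prs$p.value)
  # adjusted-p matrix over groups; "pairwise" contrasts come in combn order
  # over the grid rows, so map positionally rather than parsing labels
  pm <- matrix(NA_real_, length(groups), length(groups),
               dimnames = list(groups, groups))
  idx <- utils::combn(length(groups), 2)
  if (ncol(idx) != nrow(prs))
    stop("unexpected number of pairwise contrasts", call. = FALSE)
  for (k in seq_len(ncol(idx))) {
    g1 <- groups[idx[1, k]]; g2 <- groups[idx[2, k]]
    pm[g1, g2] <- pm[g2, g1] <- prs$p.value[k]
  }
  letters_tbl <- tibble::tibble(
    group = groups,
    letters = compact_letters(groups, pm, alpha = alpha))
  structure(list(pairs = pairs_tbl, letters = letters_tbl, alpha = alpha),
            class = "gp_posthoc")
}

#' @export
print.gp_posthoc <- function(x, ...) {
  cat(sprintf("<gp_posthoc> %d pairwise contrasts (BH-adjusted), alpha = %g\n",
              nrow(x$pairs), x$alpha))
  print(x$letters)
  invisible(x)
}

#' Compact letter display by insert-and-absorb
#'
#' Builds letter codes from a matrix of (adjusted) pairwise p-values so
#' that two groups share a letter if and only if their p-value is at or
#' above `alpha`. Starts from one class holding all groups; each
#' significant pair splits every class containing both; duplicate and
#' subset classes are absorbed.
#'
#' @param groups character vector of group names.
#' @param p_matrix symmetric matrix of pairwise p-values (dimnames =
#'   groups); `NA` off-diagonal entries are treated as non-significant.
#' @param alpha significance level.
#' @return A character vector of letter strings along `groups`.
#' @export
compact_letters <- function(groups, p_matrix, alpha = 0.05) {
  n <- length(groups)
  if (n == 1) return("a")
  classes <- list(groups)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p <- p_matrix[groups[i], groups[j]]
      if (is.na(p) || p >= alpha) next
      new_classes <- list()
      for (cl in classes) {
        if (groups[i] %in% cl && groups[j] %in% cl) {
          new_classes <- c(new_classes, list(setdiff(cl, groups[i])),
                           list(setdiff(cl, groups[j])))
        } else {
          new_classes <- c(new_classes, list(cl))
        }
      }
      # absorb: drop classes contained in another class
      keep <- rep(TRUE, length(new_classes))
      for (a in seq_along(new_classes)) {
        for (b in seq_along(new_classes)) {
          if (a == b || !keep[a]) next
          if (all(new_classes[[a]] %in% new_classes[[b]]) &&
              (length(new_classes[[a]]) < length(new_classes[[b]]) ||
               (identical(new_classes[[a]], new_classes[[b]]) && a > b))) {
            keep[a] <- FALSE
            break
          }
        }
      }
      classes <- new_classes[keep]
    }
  }
  # order classes by the first group they contain, for stable letters
  first_idx <- vapply(classes, function(cl) min(match(cl, groups)), 1)
  classes <- classes[order(first_idx)]
  letter_pool <- c(letters, paste0(rep(letters, each = 26), letters))
  out <- vapply(groups, function(g) {
    has <- vapply(classes, function(cl) g %in% cl, logical(1))
    paste(letter_pool[which(has)], collapse = "")
  }, "")
  unname(out)
}
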