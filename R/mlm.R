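#' Latent-threshold intraclass correlation for logit models
#'
#' Share of outcome variance attributable to the grouping level in a
#' random-intercept logistic model, on the latent-response scale:
#' `100 * sigma2 / (sigma2 + pi^2 / 3)`, where `pi^2/3` is the variance of
#' the standard-logistic residual.
#'
#' @param sigma2 Between-group variance (non-negative).
#' @return ICC as a percentage in `[0, 100)`.
#' @export
icc_logistic <- function(sigma2) {
  if (any(sigma2 < 0)) abort("sigma2 must be non-negative")
  100 * sigma2 / (sigma2 + pi^2 / 3)
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson statistic without continuity correction; degrees of freedom
#' `(r-1)(c-1)`. A zero marginal row or column is an error because expected
#' counts are undefined.
#'
#' @param tab Matrix of non-negative counts, at least 2x2.
#' @return List: `statistic`, `dof`, `p_value`.
#' @export
chi_square <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L) abort("table must be at least 2x2")
  if (any(tab < 0) || any(tab != round(tab))) abort("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("zero marginal row/column: expected counts undefined")
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), dof = unname(res$parameter),
       p_value = unname(res$p.value))
}

#' Model specification for the outcome models
#'
#' Fixed effects are the adherence category, SABA category, sex, age group,
#' comedication, comorbidity and GINA class, each with the most-positive
#' scenario as reference (91-100% adherence, 0 SABA prescriptions, male,
#' age 12-17, 0 comedication, 0 comorbidities, GINA class 2); the grouping
#' term is a random intercept per practice.
#'
#' @param outcome `"any_exacerbation"` or `"controlled"`.
#' @return List with `outcome`, `terms`, `reference` and `formula`.
#' @export
model_spec <- function(outcome = c("any_exacerbation", "controlled")) {
  outcome <- match.arg(outcome)
  terms <- c("adherence_cat", "saba_cat", "sex", "age_group",
             "comed_cat", "comorb_cat", "gina_class")
  reference <- c(adherence_cat = "91-100", saba_cat = "0", sex = "male",
                 age_group = "12-17", comed_cat = "0", comorb_cat = "0",
                 gina_class = "2")
  list(outcome = outcome, terms = terms, reference = reference,
       formula = stats::as.formula(paste(
         outcome, "~", paste(terms, collapse = " + "), "+ (1 | practice_id)")))
}

# relevel every spec term to its reference and drop unused levels
apply_references <- function(data, spec) {
  for (nm in spec$terms) {
    data[[nm]] <- droplevels(factor(data[[nm]]))
    if (!spec$reference[[nm]] %in% levels(data[[nm]])) {
      abort(sprintf("reference level `%s` absent from `%s`",
                    spec$reference[[nm]], nm))
    }
    data[[nm]] <- stats::relevel(data[[nm]], ref = spec$reference[[nm]])
  }
  data
}

#' Random-intercept logistic regression with practice clustering
#'
#' Fits a logit model with a normal random intercept per general practice by
#' maximising the (Laplace-approximated) marginal likelihood, and returns
#' odds ratios with Wald 95% confidence intervals, the between-practice
#' variance on the latent scale and its intraclass correlation. Patients
#' without an adherence value (GINA class 1 / no ICS) are dropped; the
#' control-outcome model additionally drops patients without an ACQ record.
#'
#' @param data Analysis dataset (one row per patient), see
#'   [build_analysis_dataset()].
#' @param spec A [model_spec()].
#' @param conf_level Confidence level for the Wald intervals.
#' @return An object of class `cma_mixed_fit`: `fit` (the merMod),
#'   `coefficients` (tibble: term, estimate, se, z, p, or, ci_low, ci_high),
#'   `sigma2_practice`, `icc_pct`, `n`, `n_practices`, `converged`.
#' @export
fit_random_intercept_logistic <- function(data, spec = model_spec(),
                                          conf_level = 0.95) {
  data <- data[!is.na(data$adherence_cat), , drop = FALSE]
  if (spec$outcome == "controlled") {
    data <- data[!is.na(data$controlled), , drop = FALSE]
  }
  if (anyNA(data[[spec$outcome]])) abort("missing outcome values")
  if (length(unique(data$practice_id)) < 2L) {
    abort("at least two practices are needed to identify the practice variance")
  }
  data <- apply_references(data, spec)
  fit <- lme4::glmer(spec$formula, data = data, family = stats::binomial(),
                     nAGQ = 1L,
                     control = lme4::glmerControl(
                       optimizer = "bobyqa",
                       optCtrl = list(maxfun = 2e5),
                       calc.derivs = FALSE))
  sm <- summary(fit)
  co <- sm$coefficients
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  coefficients <- tibble::tibble(
    term = rownames(co),
    estimate = co[, "Estimate"],
    se = co[, "Std. Error"],
    z = co[, "z value"],
    p = co[, "Pr(>|z|)"],
    or = exp(co[, "Estimate"]),
    ci_low = exp(co[, "Estimate"] - zq * co[, "Std. Error"]),
    ci_high = exp(co[, "Estimate"] + zq * co[, "Std. Error"])
  )
  sigma2 <- unname(lme4::VarCorr(fit)$practice_id[1, 1])
  conv <- length(fit@optinfo$conv$lme4$messages %||% character(0)) == 0L
  structure(
    list(fit = fit, coefficients = coefficients, sigma2_practice = sigma2,
         icc_pct = icc_logistic(sigma2), n = nrow(data),
         n_practices = length(unique(data$practice_id)),
         outcome = spec$outcome, converged = conv),
    class = "cma_mixed_fit"
  )
}

#' @export
print.cma_mixed_fit <- function(x, ...) {
  cat(sprintf("<cma_mixed_fit> outcome: %s | n = %d patients in %d practices\n",
              x$outcome, x$n, x$n_practices))
  cat(sprintf("between-practice variance %.3f, ICC %.1f%%%s\n",
              x$sigma2_practice, x$icc_pct,
              if (x$converged) "" else " (convergence warnings)"))
  print(x$coefficients, n = Inf)
  invisible(x)
}

#' Descriptive characteristics table
#'
#' Counts and percentages per level of the categorical study variables
#' (denominator: non-missing values of each variable), plus mean (SD) rows
#' for the continuous CMA7 percentage and SABA count. Variables observed on
#' a subsample (e.g. ACQ-based control) report their subsample size, not
#' zeros.
#'
#' @param data Analysis dataset.
#' @return Tibble: `variable`, `level`, `n`, `pct`, `mean`, `sd`.
#' @export
make_table1 <- function(data) {
  cat_vars <- c(sex = "sex", age = "age_group", comedication = "comed_cat",
                comorbidity = "comorb_cat", gina_class = "gina_class",
                ics_adherence = "adherence_cat", saba = "saba_cat",
                exacerbations = "exac_cat", asthma_control = "controlled")
  rows <- purrr::imap(cat_vars, function(col, label) {
    x <- data[[col]]
    x <- x[!is.na(x)]
    tab <- table(x)
    tibble::tibble(variable = label, level = names(tab), n = as.integer(tab),
                   pct = 100 * as.integer(tab) / length(x),
                   mean = NA_real_, sd = NA_real_)
  })
  cont <- tibble::tibble(
    variable = c("cma7_pct", "saba_n"),
    level = "mean_sd",
    n = c(sum(!is.na(data$cma7_pct)), sum(!is.na(data$saba_n))),
    pct = NA_real_,
    mean = c(mean(data$cma7_pct, na.rm = TRUE), mean(data$saba_n, na.rm = TRUE)),
    sd = c(stats::sd(data$cma7_pct, na.rm = TRUE), stats::sd(data$saba_n, na.rm = TRUE))
  )
  dplyr::bind_rows(dplyr::bind_rows(rows), cont)
}

#' Cross-tabulated counts for the adherence count-plots
#'
#' Full cross-tabulation of two categorical study variables including empty
#' cells, e.g. SABA category or exacerbation count per ICS adherence
#' category. Input row order does not affect the result.
#'
#' @param data Analysis dataset.
#' @param x,y Column names of the two categorical variables.
#' @return Tibble with one row per `(x, y)` level pair and a count `n`;
#'   counts sum to the number of rows with both values non-missing.
#' @export
countplot_data <- function(data, x = "adherence_cat", y = "saba_cat") {
  fx <- data[[x]]; fy <- data[[y]]
  keep <- !is.na(fx) & !is.na(fy)
  tab <- table(fx[keep], fy[keep])
  out <- tibble::as_tibble(tab, .name_repair = "minimal")
  names(out) <- c(x, y, "n")
  out$n <- as.integer(out$n)
  out
}
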