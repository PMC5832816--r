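#' Validate a long-format mass table
#'
#' The statistics operate on per-individual, per-method mass estimates in
#' long format: one row per (individual, method) pair.
#'
#' @param table data frame with columns `individual_id`, `method`,
#'   `mass_mg`.
#' @return The validated data frame (columns coerced to character /
#'   character / numeric).
#' @export
mass_table <- function(table) {
  need <- c("individual_id", "method", "mass_mg")
  if (!is.data.frame(table) || !all(need %in% names(table))) {
    abort("mass table needs columns individual_id, method, mass_mg",
          "invermass_format_error")
  }
  out <- data.frame(individual_id = as.character(table$individual_id),
                    method = as.character(table$method),
                    mass_mg = as.numeric(table$mass_mg),
                    stringsAsFactors = FALSE)
  if (any(!is.finite(out$mass_mg)) || any(out$mass_mg <= 0)) {
    abort("masses must be positive and finite", "invermass_domain_error")
  }
  if (anyDuplicated(out[, c("individual_id", "method")])) {
    abort("each (individual, method) pair must be unique", "invermass_format_error")
  }
  out
}

#' One-sample t-test against a reference mean
#'
#' Tests whether per-individual estimates from one method differ from a
#' fixed reference value — e.g. the mean individual mass obtained by direct
#' weighing of pooled sets. `t = (mean(x) - ref) / (sd(x) / sqrt(n))` with
#' `n - 1` degrees of freedom and a two-sided p-value.
#'
#' @param values numeric estimates (length >= 2, non-zero variance).
#' @param reference_mean reference value.
#' @param alpha_adjusted significance level after any multiplicity
#'   correction (default 0.05).
#' @return A `test_result`: list with `statistic`, `df`, `p_value`,
#'   `alpha_adjusted`, `significant`.
#' @examples
#' one_sample_t(c(2, 4, 6), 0)   # t = 3.464, df = 2
#' @export
one_sample_t <- function(values, reference_mean, alpha_adjusted = 0.05) {
  n <- length(values)
  if (n < 2L || any(!is.finite(values)) || !is.finite(reference_mean)) {
    abort("need >= 2 finite values and a finite reference", "invermass_degenerate_test_error")
  }
  s <- stats::sd(values)
  if (s == 0) {
    abort("zero variance: one-sample t-test is degenerate", "invermass_degenerate_test_error")
  }
  tstat <- (mean(values) - reference_mean) / (s / sqrt(n))
  p <- 2 * pt(-abs(tstat), df = n - 1)
  structure(list(statistic = tstat, df = n - 1L, p_value = p,
                 alpha_adjusted = alpha_adjusted,
                 significant = p < alpha_adjusted),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("t = %.4g, df = %d, p = %.4g (%ssignificant at alpha = %.4g)\n",
              x$statistic, x$df, x$p_value,
              if (x$significant) "" else "not ", x$alpha_adjusted))
  invisible(x)
}

#' Bonferroni decisions for a family of p-values
#'
#' Each p-value is compared against `alpha / m`, where `m` is the family
#' size; with four method comparisons at alpha = 0.05 the per-test threshold
#' is 0.0125.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param alpha family-wise error rate (default 0.05).
#' @return Data frame with `p_value`, `alpha_adjusted`, `significant`.
#' @export
bonferroni <- function(p_values, alpha = 0.05) {
  if (length(p_values) < 1L || any(!is.finite(p_values)) ||
      any(p_values < 0) || any(p_values > 1)) {
    abort("p-values must lie in [0, 1]", "invermass_domain_error")
  }
  thr <- alpha / length(p_values)
  data.frame(p_value = p_values,
             alpha_adjusted = thr,
             significant = p_values < thr)
}

#' Linear mixed-effect comparison of estimation methods
#'
#' Fits `mass ~ method + (1 | individual)`: method is the fixed factor,
#' individual specimen the random factor, so each non-reference method's
#' coefficient is its mean offset from the reference method across the same
#' individuals. For balanced complete data the fixed-effect estimates equal
#' differences of method means and the intercept equals the reference mean.
#' P-values use a residual-degrees-of-freedom approximation
#' (`N - n_methods - n_individuals + 1`) and should be read as approximate.
#'
#' @param table a [mass_table()] (or coercible data frame) with >= 2 methods
#'   and >= 2 individuals.
#' @param reference reference method label, default `"direct"`.
#' @param missing_warn_frac warn when more than this fraction of the full
#'   individuals-by-methods grid is missing (default 0.1).
#' @return A `mixed_model_result`: list with `coefficients` (data frame:
#'   term, estimate, std_error, t_value, p_value_approx), `reference_level`,
#'   `df_approx`, and the underlying `lme4` fit in `fit`.
#' @export
method_mixed_model <- function(table, reference = "direct", missing_warn_frac = 0.1) {
  tab <- mass_table(table)
  methods <- unique(tab$method)
  if (length(methods) < 2L) {
    abort("need >= 2 methods to compare", "invermass_domain_error")
  }
  if (!reference %in% methods) {
    abort(sprintf("reference method '%s' not present in table", reference),
          "invermass_domain_error")
  }
  inds <- unique(tab$individual_id)
  if (length(inds) < 2L) {
    abort("need >= 2 individuals", "invermass_domain_error")
  }
  full <- length(methods) * length(inds)
  if (nrow(tab) < (1 - missing_warn_frac) * full) {
    warning(sprintf("mass table is unbalanced: %d of %d (individual, method) cells present",
                    nrow(tab), full), call. = FALSE)
  }
  tab$method <- stats::relevel(factor(tab$method), ref = reference)
  tab$individual_id <- factor(tab$individual_id)
  fit <- suppressMessages(
    lme4::lmer(mass_mg ~ method + (1 | individual_id), data = tab)
  )
  cf <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  tval <- cf / se
  df_approx <- nrow(tab) - length(cf) - length(inds) + 1L
  term <- sub("^method", "", names(cf))
  term[term == "(Intercept)"] <- "intercept"
  coefs <- data.frame(term = term,
                      estimate = unname(cf),
                      std_error = unname(se),
                      t_value = unname(tval),
                      p_value_approx = 2 * pt(-abs(unname(tval)), df = df_approx),
                      stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, reference_level = reference,
                 df_approx = df_approx, fit = fit),
            class = "mixed_model_result")
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat(sprintf("Linear mixed-effect method comparison (reference: %s)\n",
              x$reference_level))
  print(x$coefficients, row.names = FALSE, digits = 4)
  cat(sprintf("p-values approximate (residual df = %d)\n", x$df_approx))
  invisible(x)
}

#' Overestimation ratio of one method against a reference
#'
#' Ratio of mean estimated masses, `mean(method) / mean(reference)`; a value
#' of 4 means the method overestimates mean individual mass four-fold.
#'
#' @param table a [mass_table()] (or coercible data frame).
#' @param method method label in the numerator.
#' @param reference method label in the denominator, default `"direct"`.
#' @return The ratio (dimensionless).
#' @export
overestimation_ratio <- function(table, method, reference = "direct") {
  tab <- mass_table(table)
  for (lab in c(method, reference)) {
    if (!lab %in% tab$method) {
      abort(sprintf("method '%s' not present in table", lab), "invermass_domain_error")
    }
  }
  mean(tab$mass_mg[tab$method == method]) /
    mean(tab$mass_mg[tab$method == reference])
}
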