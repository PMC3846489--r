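#' Breed-level factor table
#'
#' Loads the packaged table of breed-level inputs to the factor regression:
#' one row per breed with its allelic imputation error rate (percent),
#' training (reference) population size, validation size, mean pedigree
#' relationship between training and validation animals (R_T/V), LD level at
#' 70 kb, number of effective ancestors and breed type (dairy/beef).
#'
#' @param path Optional path to an alternative tab-separated table with the
#'   same columns.
#' @return A tibble, one row per breed.
#' @export
breed_factors <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "breed_factors.tsv", package = "hdimpute")
  }
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    breed = "c", type = "c", train_size = "i",
                    validation_size = "i", error_rate_pct = "d",
                    ld70 = "d", r_tv = "d", n_eff_ancestors = "d"
                  ))
}

#' Regress breed-level imputation error on population factors
#'
#' Ordinary least squares of the allelic imputation error rate (in percent)
#' on reference population size, training-validation relationship, LD at
#' 70 kb and number of effective ancestors, with an intercept. The part of
#' variance explained by each factor is the sequential (type-I) R-squared
#' increment in the given factor order; coefficients do not depend on that
#' order but the variance shares do.
#'
#' @param data A tibble with the response and factor columns (see
#'   [breed_factors()]).
#' @param response Response column name (default `"error_rate_pct"`).
#' @param factors Factor column names, in the order used for the sequential
#'   variance decomposition.
#' @param max_condition Condition number of the scaled design above which the
#'   fit aborts with an error naming the factors.
#' @return An object of class `factor_fit`; see [tidy.factor_fit()] and
#'   [glance.factor_fit()].
#' @export
fit_factors <- function(data,
                        response = "error_rate_pct",
                        factors = c("train_size", "r_tv", "ld70",
                                    "n_eff_ancestors"),
                        max_condition = 1e8) {
  missing_cols <- setdiff(c(response, factors), names(data))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(data) <= length(factors) + 1L) {
    stop("need more rows than model parameters", call. = FALSE)
  }
  X <- as.matrix(data[factors])
  kappa_val <- kappa(scale(X), exact = TRUE)
  if (!is.finite(kappa_val) || kappa_val > max_condition) {
    stop("collinear design among factors: ",
         paste(factors, collapse = ", "), call. = FALSE)
  }
  fml <- stats::reformulate(factors, response = response)
  model <- stats::lm(fml, data = data)
  an <- stats::anova(model)
  ss <- an$`Sum Sq`
  shares <- ss[seq_along(factors)] / sum(ss)
  coefs <- summary(model)$coefficients
  out <- list(
    model = model,
    response = response,
    factors = factors,
    coefficients = tibble::tibble(
      term = rownames(coefs),
      estimate = unname(coefs[, "Estimate"]),
      std_error = unname(coefs[, "Std. Error"]),
      statistic = unname(coefs[, "t value"]),
      p_value = unname(coefs[, "Pr(>|t|)"]),
      variance_share = c(NA_real_, shares)
    ),
    r_squared = summary(model)$r.squared,
    n = nrow(data)
  )
  class(out) <- "factor_fit"
  out
}

#' @export
print.factor_fit <- function(x, ...) {
  cat(sprintf("<factor_fit> %s ~ %s (n = %d, R^2 = %.3f)\n",
              x$response, paste(x$factors, collapse = " + "), x$n,
              x$r_squared))
  print(x$coefficients)
  invisible(x)
}

#' Tidy a factor regression fit
#'
#' @param x A `factor_fit`.
#' @param ... Unused.
#' @return A tibble with one row per term: estimate, standard error,
#'   t statistic, p-value and sequential variance share.
#' @export
tidy.factor_fit <- function(x, ...) {
  x$coefficients
}

#' One-row summary of a factor regression fit
#'
#' @param x A `factor_fit`.
#' @param ... Unused.
#' @return A tibble with `r_squared`, `adj_r_squared`, `sigma`, `n`.
#' @export
glance.factor_fit <- function(x, ...) {
  s <- summary(x$model)
  tibble::tibble(
    r_squared = s$r.squared,
    adj_r_squared = s$adj.r.squared,
    sigma = s$sigma,
    n = x$n
  )
}

#' Predicted change in error rate for a change in one factor
#'
#' Returns `coefficient * delta`, i.e. the expected change in the error rate
#' (percentage points) when the factor changes by `delta`.
#'
#' @param fit A `factor_fit`.
#' @param factor Name of a fitted factor.
#' @param delta Change in the factor's own units.
#' @return Predicted change in error-rate percentage points.
#' @export
predict_effect <- function(fit, factor, delta) {
  if (!factor %in% fit$factors) {
    stop("unknown factor: ", factor, call. = FALSE)
  }
  est <- fit$coefficients$estimate[fit$coefficients$term == factor]
  unname(est * delta)
}
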