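#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA of a numeric response against a
#' single grouping factor: between/within sum-of-squares decomposition,
#' F = (SSB/(k-1)) / (SSW/(n-k)) and the p-value from the F distribution.
#' Fitting is done through [stats::lm()] / [stats::anova()].
#'
#' @param values Numeric response vector.
#' @param group Parallel vector of group labels (at least two levels, each
#'   with at least two observations).
#' @param response Optional response name for the result table.
#' @return Object of class `anova_result`: list with `response`, `terms`
#'   (tibble: `term`, `df`, `sum_sq`, `mean_sq`, `statistic`, `p_value`)
#'   and `residual` (df, sum_sq, mean_sq).
#' @examples
#' one_way_anova(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' @export
one_way_anova <- function(values, group, response = "response") {
  values <- as.numeric(values)
  group <- as.factor(group)
  if (length(values) != length(group)) {
    stop("`values` and `group` must have equal length", call. = FALSE)
  }
  if (nlevels(droplevels(group)) < 2) {
    stop("one-way ANOVA needs at least two groups", call. = FALSE)
  }
  if (any(table(droplevels(group)) < 2)) {
    stop("every group needs at least two observations", call. = FALSE)
  }
  additive_anova(data.frame(.y = values, group = group), ".y",
                 factors = "group", response_name = response)
}

#' Additive multi-factor analysis of variance
#'
#' Fits an additive (no-interaction) linear model of one response on one
#' or more categorical factors by least squares and reports the sequential
#' (order-of-entry, type I) sum of squares, F statistic and p-value per
#' term against the residual mean square — the behaviour of a plain
#' `anova(lm(y ~ a + b + c))`. With a single factor this reduces exactly
#' to [one_way_anova()]. Constant (single-level) factors are rejected as
#' aliased rather than silently dropped.
#'
#' @param data Data frame holding the response and factor columns.
#' @param response Name of the numeric response column.
#' @param factors Character vector of factor column names, in entry order.
#' @param response_name Optional display name for the response.
#' @return An `anova_result`, see [one_way_anova()].
#' @export
additive_anova <- function(data, response, factors,
                           response_name = response) {
  stopifnot(is.data.frame(data), length(factors) >= 1)
  missing_cols <- setdiff(c(response, factors), names(data))
  if (length(missing_cols) > 0) {
    stop(sprintf("unknown column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df <- data[c(response, factors)]
  for (f in factors) {
    df[[f]] <- droplevels(as.factor(df[[f]]))
    if (nlevels(df[[f]]) < 2) {
      stop(sprintf("factor '%s' is constant: aliased term", f),
           call. = FALSE)
    }
  }
  fml <- stats::reformulate(factors, response = as.name(response))
  fit <- stats::lm(fml, data = df)
  if (fit$rank < ncol(stats::model.matrix(fit))) {
    ali <- names(which(is.na(stats::coef(fit))))
    stop(sprintf("rank-deficient model: aliased coefficient(s) %s",
                 paste(ali, collapse = ", ")), call. = FALSE)
  }
  # perfect fits are caught below; silence anova's own complaint about them
  tab <- suppressWarnings(stats::anova(fit))
  total_ss <- sum(tab[, "Sum Sq"])
  if (tab["Residuals", "Df"] < 1 ||
      tab["Residuals", "Sum Sq"] <= 1e-12 * max(total_ss, 1e-300)) {
    stop("degenerate model: no residual variance", call. = FALSE)
  }
  term_rows <- setdiff(rownames(tab), "Residuals")
  structure(
    list(
      response = response_name,
      terms = tibble::tibble(
        term = term_rows,
        df = as.integer(tab[term_rows, "Df"]),
        sum_sq = tab[term_rows, "Sum Sq"],
        mean_sq = tab[term_rows, "Mean Sq"],
        statistic = tab[term_rows, "F value"],
        p_value = tab[term_rows, "Pr(>F)"]
      ),
      residual = list(
        df = as.integer(tab["Residuals", "Df"]),
        sum_sq = tab["Residuals", "Sum Sq"],
        mean_sq = tab["Residuals", "Mean Sq"]
      )
    ),
    class = "anova_result"
  )
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("Analysis of variance: %s\n", x$response))
  tab <- x$terms
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-12s F(%d, %d) = %.4f, p = %.4g\n",
                tab$term[i], tab$df[i], x$residual$df,
                tab$statistic[i], tab$p_value[i]))
  }
  invisible(x)
}

#' Group summary table
#'
#' Per-level n, mean, sample standard deviation and range of one cohort
#' measurement — the "mean +/- SD (range)" rows of a clinical results
#' table. A single-observation level reports `NA` for the SD (zero
#' degrees of freedom) rather than 0.
#'
#' @param cohort Data frame.
#' @param response Name of the numeric column to summarise.
#' @param by Name of the grouping column.
#' @return Tibble `level`, `n`, `mean`, `sd`, `min`, `max`.
#' @export
cohort_summary <- function(cohort, response, by) {
  missing_cols <- setdiff(c(response, by), names(cohort))
  if (length(missing_cols) > 0) {
    stop(sprintf("unknown column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  cohort |>
    dplyr::group_by(level = .data[[by]]) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data[[response]]),
      sd = stats::sd(.data[[response]]),
      min = min(.data[[response]]),
      max = max(.data[[response]]),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$level)
}

#' Run the standard comparison models on a classified cohort
#'
#' Fits the study's comparison set: sinus depth against dentition and
#' gender (one-way and additive), alveolar height and opening angle
#' against sinus class, dentition and gender (one-way per factor plus the
#' additive multi-factor model). Returns a tidy table of all model terms.
#'
#' @param cohort Classified cohort tibble (needs `sinus_class`).
#' @return Tibble `response`, `model`, `term`, `df`, `statistic`,
#'   `p_value`.
#' @export
standard_models <- function(cohort) {
  if (!"sinus_class" %in% names(cohort) || anyNA(cohort$sinus_class)) {
    stop("cohort must be classified first (sinus_class column)",
         call. = FALSE)
  }
  specs <- list(
    list(resp = "sinus_depth_mm", fac = "dentition"),
    list(resp = "sinus_depth_mm", fac = "gender"),
    list(resp = "sinus_depth_mm", fac = c("dentition", "gender")),
    list(resp = "alveolar_height_mm", fac = "sinus_class"),
    list(resp = "alveolar_height_mm", fac = "dentition"),
    list(resp = "alveolar_height_mm", fac = "gender"),
    list(resp = "alveolar_height_mm", fac = c("sinus_class", "dentition", "gender")),
    list(resp = "opening_angle_deg", fac = "sinus_class"),
    list(resp = "opening_angle_deg", fac = "dentition"),
    list(resp = "opening_angle_deg", fac = "gender"),
    list(resp = "opening_angle_deg", fac = c("sinus_class", "dentition", "gender"))
  )
  rows <- lapply(specs, function(s) {
    res <- additive_anova(cohort, s$resp, s$fac)
    dplyr::mutate(res$terms,
                  response = s$resp,
                  model = paste(s$fac, collapse = " + "),
                  .before = 1)
  })
  dplyr::bind_rows(rows)[
    , c("response", "model", "term", "df", "statistic", "p_value")]
}
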