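#' Pearson correlation with p-value
#'
#' Product-moment correlation between two paired copy-number series, with
#' the usual t-transform p-value (via [stats::cor.test()]).
#'
#' @param x,y Paired numeric vectors of equal length >= 3 with non-zero
#'   variance.
#' @return A one-row tibble: `estimate`, `p_value`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("At least 3 paired observations are required")
  if (sd(x) == 0 || sd(y) == 0) abort("Correlation undefined: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble(estimate = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Least-squares fit of ddPCR copy number on aCGH copy number
#'
#' Ordinary least squares of the ddPCR estimate (response) on the
#' aCGH-assigned copy number (predictor), with an intercept by default.
#' The slope is reported as `estimate`, together with multiple and
#' adjusted R-squared and the overall F-test p-value.  The regression
#' direction follows the convention of plotting ddPCR values against the
#' aCGH-determined copy number; both direction and intercept are caller
#' choices.
#'
#' @param x Predictor (aCGH copy number).
#' @param y Response (ddPCR copy-number estimate).
#' @param intercept Include an intercept term?
#' @return An object of class `cn_ols` wrapping the [stats::lm()] fit;
#'   use [generics::tidy()] / [generics::glance()] or `$` access
#'   (`estimate`, `intercept`, `r_squared`, `adj_r_squared`, `p_value`).
#' @export
ols_fit <- function(x, y, intercept = TRUE) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("At least 3 paired observations are required")
  if (sd(x) == 0) abort("Degenerate design: predictor has zero variance")
  fit <- if (intercept) lm(y ~ x) else lm(y ~ x + 0)
  s <- summary(fit)
  f <- s$fstatistic
  structure(list(
    estimate = unname(coef(fit)[["x"]]),
    intercept = if (intercept) unname(coef(fit)[["(Intercept)"]]) else 0,
    r_squared = s$r.squared,
    adj_r_squared = s$adj.r.squared,
    p_value = unname(pf_from_fstat(f)),
    n = length(x),
    fit = fit
  ), class = "cn_ols")
}

pf_from_fstat <- function(f) {
  if (is.null(f)) return(NA_real_)
  stats::pf(f[["value"]], f[["numdf"]], f[["dendf"]], lower.tail = FALSE)
}

#' @export
print.cn_ols <- function(x, ...) {
  cat("Linear fit of ddPCR CN on aCGH CN (n =", x$n, ")\n")
  cat(sprintf("  estimate (slope): %.4f   intercept: %.4f\n",
              x$estimate, x$intercept))
  cat(sprintf("  R-squared: %.4f   adj. R-squared: %.4f   p: %.3g\n",
              x$r_squared, x$adj_r_squared, x$p_value))
  invisible(x)
}

#' @method tidy cn_ols
#' @export
tidy.cn_ols <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std_error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p_value = s[, "Pr(>|t|)"]
  )
}

#' @method glance cn_ols
#' @export
glance.cn_ols <- function(x, ...) {
  tibble(r_squared = x$r_squared, adj_r_squared = x$adj_r_squared,
         estimate = x$estimate, p_value = x$p_value, n = x$n)
}

# Agreement-weight matrix for a k-category table: 1 on the diagonal,
# decaying linearly or quadratically with category distance, or identity.
kappa_weights <- function(k, weighting) {
  d <- abs(outer(seq_len(k), seq_len(k), "-"))
  switch(weighting,
         none = (d == 0) * 1,
         linear = 1 - d / (k - 1),
         quadratic = 1 - (d / (k - 1))^2)
}

#' Cohen's kappa for a square contingency table
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with the
#' weighted generalization: observed and expected agreement are
#' weight-averaged over cells, with agreement weights of 1 on the diagonal
#' decaying linearly or quadratically with category distance.  For a 2x2
#' table every weighting reduces to the unweighted statistic.  The
#' p-value tests kappa = 0 using the large-sample standard error under
#' the null (Fleiss); an exact-conditional Monte Carlo alternative
#' resamples tables with fixed marginals.
#'
#' @param table A square numeric matrix of counts, or a
#'   [crosstab_2x2()] object.
#' @param weighting `"none"` (default), `"linear"`, or `"quadratic"`.
#' @param p_method `"asymptotic"` (default) or `"permutation"` (tables
#'   resampled with [stats::r2dtable()]; intended for n <= 200).
#' @param n_permutations Number of resampled tables for the permutation
#'   p-value.
#' @return An object of class `kappa_result` with elements `kappa`,
#'   `weighting`, `p_value`, `se0`, `band` (agreement label per
#'   [agreement_band()]), `n`, `p_observed`, `p_expected`.
#' @examples
#' # pathogenicity agreement table for the exon VIII assay
#' cohen_kappa(matrix(c(71, 7, 1, 19), nrow = 2))
#' @export
cohen_kappa <- function(table, weighting = c("none", "linear", "quadratic"),
                        p_method = c("asymptotic", "permutation"),
                        n_permutations = 2000) {
  weighting <- match.arg(weighting)
  p_method <- match.arg(p_method)
  m <- as_kappa_matrix(table)
  k <- nrow(m)
  n <- sum(m)
  if (n <= 0) abort("Contingency table is empty (n = 0)")
  w <- kappa_weights(k, weighting)
  kap <- kappa_statistic(m, w)
  if (kap$p_e >= 1) {
    abort("kappa undefined: expected agreement is 1 (degenerate marginals)")
  }
  se0 <- kappa_se0(m, w)
  p_value <- if (p_method == "asymptotic") {
    if (se0 > 0) 2 * pnorm(-abs(kap$kappa / se0)) else NA_real_
  } else {
    perm_kappa_p(m, w, kap$kappa, n_permutations)
  }
  structure(list(
    kappa = kap$kappa, weighting = weighting, p_value = p_value,
    se0 = se0, band = agreement_band(kap$kappa), n = n,
    p_observed = kap$p_o, p_expected = kap$p_e, table = m
  ), class = "kappa_result")
}

as_kappa_matrix <- function(table) {
  if (inherits(table, "crosstab_2x2")) {
    m <- matrix(c(table$a, table$c, table$b, table$d), nrow = 2,
                dimnames = list(ddpcr = c("benign", "pathogenic"),
                                acgh = c("benign", "pathogenic")))
  } else {
    m <- as.matrix(table)
  }
  if (nrow(m) != ncol(m)) abort("Contingency table must be square")
  if (any(m < 0)) abort("Counts must be non-negative")
  m
}

kappa_statistic <- function(m, w) {
  n <- sum(m)
  p <- m / n
  pr <- rowSums(p)
  pc <- colSums(p)
  p_o <- sum(w * p)
  p_e <- sum(w * outer(pr, pc))
  list(kappa = (p_o - p_e) / (1 - p_e), p_o = p_o, p_e = p_e)
}

# Large-sample SE of weighted kappa under the null of chance agreement
# (Fleiss, Cohen & Everitt 1969).
kappa_se0 <- function(m, w) {
  n <- sum(m)
  p <- m / n
  pr <- rowSums(p)
  pc <- colSums(p)
  p_e <- sum(w * outer(pr, pc))
  w_row <- as.vector(w %*% pc)   # E[w | row i]
  w_col <- as.vector(pr %*% w)   # E[w | col j]
  term <- sum(outer(pr, pc) * (w - outer(w_row, w_col, "+"))^2) - p_e^2
  sqrt(max(term, 0)) / ((1 - p_e) * sqrt(n))
}

perm_kappa_p <- function(m, w, observed, n_permutations) {
  tabs <- stats::r2dtable(n_permutations, rowSums(m), colSums(m))
  sims <- vapply(tabs, function(t) kappa_statistic(t, w)$kappa, numeric(1))
  (1 + sum(abs(sims) >= abs(observed) - 1e-12)) / (n_permutations + 1)
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa (%s weighting): %.4f [%s agreement]\n",
              x$weighting, x$kappa, x$band))
  cat(sprintf("  n = %d, p-value = %.3g\n", x$n, x$p_value))
  invisible(x)
}

#' @method tidy kappa_result
#' @export
tidy.kappa_result <- function(x, ...) {
  tibble(kappa = x$kappa, weighting = x$weighting, band = x$band,
         p_value = x$p_value, n = x$n)
}

#' Verbal agreement band for a kappa value
#'
#' Maps kappa to the conventional labels: 0.81-1.00 almost perfect,
#' 0.61-0.80 substantial, 0.41-0.60 moderate, 0.21-0.40 fair, and below
#' that slight agreement.  Band lower edges are inclusive.
#'
#' @param kappa Numeric in `[-1, 1]` (vectorized).
#' @return Character vector of band labels.
#' @examples
#' agreement_band(c(0.774, 0.558, 0.15))
#' @export
agreement_band <- function(kappa) {
  if (any(kappa < -1 - 1e-9 | kappa > 1 + 1e-9)) {
    abort("kappa must lie in [-1, 1]")
  }
  dplyr::case_when(
    kappa >= 0.81 ~ "almost perfect",
    kappa >= 0.61 ~ "substantial",
    kappa >= 0.41 ~ "moderate",
    kappa >= 0.21 ~ "fair",
    .default = "slight"
  )
}

#' Build a 2x2 benign/pathogenic cross-tabulation
#'
#' Tabulates per-sample pathogenicity calls from the ddPCR pipeline
#' against the aCGH-assigned calls: `a` both benign, `b` ddPCR-benign /
#' aCGH-pathogenic, `c` ddPCR-pathogenic / aCGH-benign, `d` both
#' pathogenic.  Samples missing either label are skipped with a warning.
#'
#' @param calls Tibble with columns `ddpcr_label` and `acgh_label`, each
#'   `"benign"` or `"pathogenic"`.
#' @return An object of class `crosstab_2x2` with fields `a`, `b`, `c`,
#'   `d`, `n`, `n_skipped`, and marginals.
#' @export
build_pathogenicity_crosstab <- function(calls) {
  stopifnot(all(c("ddpcr_label", "acgh_label") %in% names(calls)))
  ok <- !is.na(calls$ddpcr_label) & !is.na(calls$acgh_label)
  n_skipped <- sum(!ok)
  if (n_skipped > 0) {
    warn(sprintf("Skipping %d sample(s) with a missing pathogenicity label",
                 n_skipped))
  }
  calls <- calls[ok, , drop = FALSE]
  if (nrow(calls) == 0) abort("No samples with both labels present (n = 0)")
  lv <- c("benign", "pathogenic")
  bad <- setdiff(unique(c(calls$ddpcr_label, calls$acgh_label)), lv)
  if (length(bad) > 0) {
    abort(sprintf("Unknown label(s): %s", paste(bad, collapse = ", ")))
  }
  tab <- table(factor(calls$ddpcr_label, lv), factor(calls$acgh_label, lv))
  structure(list(
    a = tab["benign", "benign"], b = tab["benign", "pathogenic"],
    c = tab["pathogenic", "benign"], d = tab["pathogenic", "pathogenic"],
    n = sum(tab), n_skipped = n_skipped,
    ddpcr_benign = sum(tab["benign", ]), ddpcr_pathogenic = sum(tab["pathogenic", ]),
    acgh_benign = sum(tab[, "benign"]), acgh_pathogenic = sum(tab[, "pathogenic"])
  ), class = "crosstab_2x2")
}

#' @rdname build_pathogenicity_crosstab
#' @param a,b,c,d Cell counts for a directly specified table.
#' @export
crosstab_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) abort("Counts must be non-negative")
  n <- a + b + c + d
  if (n == 0) abort("Empty table (n = 0)")
  structure(list(a = a, b = b, c = c, d = d, n = n, n_skipped = 0L,
                 ddpcr_benign = a + b, ddpcr_pathogenic = c + d,
                 acgh_benign = a + c, acgh_pathogenic = b + d),
            class = "crosstab_2x2")
}

#' @export
print.crosstab_2x2 <- function(x, ...) {
  m <- as_kappa_matrix(x)
  cat("Pathogenicity cross-tabulation (rows: ddPCR, cols: aCGH)\n")
  print(m)
  cat("n =", x$n, if (x$n_skipped > 0) sprintf("(%d skipped)", x$n_skipped),
      "\n")
  invisible(x)
}

#' Concordance report between ddPCR and aCGH calls
#'
#' Runs the full method-comparison battery on per-sample values: Pearson
#' correlation, the linear fit of ddPCR on aCGH copy number, weighted
#' kappa on the integer copy-number table (linear and quadratic side by
#' side), unweighted kappa on the benign/pathogenic 2x2 table, and the
#' cross-tabulation itself.
#'
#' @param samples Tibble with per-sample `cn_estimate` and `acgh_cn`
#'   (e.g. from [sample_cn()]).
#' @param normal_cn,tolerance Classification parameters, see
#'   [classify_cn()].
#' @return A list of class `cn_concordance`: `pearson`, `ols`,
#'   `kappa_cn_linear`, `kappa_cn_quadratic`, `kappa_pathogenicity`,
#'   `crosstab`, `samples`.
#' @export
cn_concordance <- function(samples, normal_cn = 6, tolerance = 1) {
  stopifnot(all(c("cn_estimate", "acgh_cn") %in% names(samples)))
  samples <- filter(samples, !is.na(.data$acgh_cn))
  calls <- samples |>
    classify_runs(normal_cn = normal_cn, tolerance = tolerance) |>
    rename(ddpcr_label = "label") |>
    mutate(acgh_label = classify_cn(.data$acgh_cn, normal_cn, tolerance))
  levels_cn <- sort(union(calls$cn_integer, calls$acgh_cn))
  cn_table <- table(factor(calls$cn_integer, levels_cn),
                    factor(calls$acgh_cn, levels_cn))
  crosstab <- build_pathogenicity_crosstab(calls)
  structure(list(
    pearson = pearson_r(samples$acgh_cn, samples$cn_estimate),
    ols = ols_fit(samples$acgh_cn, samples$cn_estimate),
    kappa_cn_linear = cohen_kappa(cn_table, "linear"),
    kappa_cn_quadratic = cohen_kappa(cn_table, "quadratic"),
    kappa_pathogenicity = cohen_kappa(crosstab, "none"),
    crosstab = crosstab,
    samples = calls
  ), class = "cn_concordance")
}

#' @export
print.cn_concordance <- function(x, ...) {
  cat("ddPCR vs aCGH concordance (n =", x$pearson$n, "samples)\n")
  cat(sprintf("  Pearson r: %.3f (p = %.3g)\n",
              x$pearson$estimate, x$pearson$p_value))
  cat(sprintf("  OLS estimate: %.3f, R-squared: %.3f\n",
              x$ols$estimate, x$ols$r_squared))
  cat(sprintf("  kappa (CN, linear): %.3f [%s]\n",
              x$kappa_cn_linear$kappa, x$kappa_cn_linear$band))
  cat(sprintf("  kappa (CN, quadratic): %.3f [%s]\n",
              x$kappa_cn_quadratic$kappa, x$kappa_cn_quadratic$band))
  cat(sprintf("  kappa (pathogenicity, unweighted): %.3f [%s]\n",
              x$kappa_pathogenicity$kappa, x$kappa_pathogenicity$band))
  invisible(x)
}

#' @method glance cn_concordance
#' @export
glance.cn_concordance <- function(x, ...) {
  tibble(
    pearson_r = x$pearson$estimate,
    ols_estimate = x$ols$estimate,
    r_squared = x$ols$r_squared,
    kappa_cn_linear = x$kappa_cn_linear$kappa,
    kappa_cn_quadratic = x$kappa_cn_quadratic$kappa,
    kappa_pathogenicity = x$kappa_pathogenicity$kappa,
    n = x$pearson$n
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
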