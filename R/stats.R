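#' Wilcoxon signed-rank test (toolbox convention)
#'
#' Paired two-sided test on `x - y`. Zero differences are discarded
#' (Wilcoxon's original treatment; `zero_method = "pratt"` instead keeps
#' them in the ranking and drops their ranks from both sums). Absolute
#' differences are ranked with midranks for ties; the reported statistic is
#' `W = min(W+, W-)`.
#'
#' For `n_effective <= exact_threshold` the two-sided p-value is exact,
#' from the full null distribution of `W+` over all `2^n` sign assignments
#' of the observed (possibly tied) ranks. Above the threshold a normal
#' approximation with tie-corrected variance
#' `n(n+1)(2n+1)/24 - sum(t^3 - t)/48` is used, without continuity
#' correction — the approximate method of the MATLAB `signrank` routine the
#' cohort analysis follows, which its printed p-values reproduce.
#'
#' @param x,y equal-length paired samples
#' @param zero_method `"wilcox"` (drop zero differences, default) or
#'   `"pratt"`
#' @param exact_threshold exact enumeration when `n_effective` is at most
#'   this (default 15)
#' @return an `alps_test` (list: `method`, `variant`, `statistic`,
#'   `p_two_sided`, `n_effective`, `w_plus`, `w_minus`); see [tidy()]
#' @export
wilcoxon_signed_rank <- function(x, y, zero_method = c("wilcox", "pratt"),
                                 exact_threshold = 15) {
  zero_method <- match.arg(zero_method)
  if (length(x) != length(y)) abort("paired samples must have equal length.")
  if (length(x) < 1) abort("need at least one pair.")
  d <- x - y
  if (all(d == 0)) abort("no effective pairs: all differences are zero.")
  if (zero_method == "wilcox") {
    d <- d[d != 0]
    r <- rank(abs(d))
  } else {
    r_all <- rank(abs(d))
    r <- r_all[d != 0]
    d <- d[d != 0]
  }
  n <- length(d)
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  if (n <= exact_threshold) {
    dist <- signed_rank_null_distribution(r)
    w2 <- round(2 * min(w_plus, w_minus))
    tot <- round(2 * sum(r))
    p <- sum(dist[seq_len(w2 + 1)]) + sum(dist[seq(tot - w2 + 1, tot + 1)])
    p <- min(1, p)
    variant <- "exact"
  } else {
    mu <- sum(r) / 2
    ties <- table(r)
    v <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_plus - mu) / sqrt(v)
    p <- 2 * pnorm(-abs(z))
    variant <- "normal-approximation"
  }
  new_alps_test(
    method = "Wilcoxon signed rank", variant = variant,
    statistic = min(w_plus, w_minus), p_two_sided = p, n_effective = n,
    extra = list(w_plus = w_plus, w_minus = w_minus)
  )
}

# null pmf of 2*W+ over all sign assignments of ranks r (midranks allowed);
# index i holds P(2*W+ = i - 1)
signed_rank_null_distribution <- function(r) {
  r2 <- round(2 * r)
  tot <- sum(r2)
  f <- c(1, numeric(tot))
  for (rr in r2) {
    shifted <- c(numeric(rr), f[seq_len(tot + 1 - rr)])
    f <- f + shifted
  }
  f / 2^length(r2)
}

#' Mann-Whitney U test (toolbox convention)
#'
#' Two-sided rank-sum test for two independent samples. `U` is computed
#' from midranks (`U_a = R_a - n_a(n_a+1)/2`). When the pooled size is at
#' most `exact_threshold` and there are no ties, the p-value is exact by
#' enumeration of all `choose(n_a + n_b, n_a)` group labelings; otherwise a
#' normal approximation with tie-corrected variance and a 0.5 continuity
#' correction is used (the MATLAB `ranksum` convention, which reproduces
#' the cohort's printed subgroup p-values).
#'
#' @param a,b the two samples (non-empty)
#' @param exact_threshold exact enumeration when `n_a + n_b` is at most
#'   this and no ties are present (default 12)
#' @return an `alps_test` with `statistic = U` of the first sample
#' @export
mann_whitney_u <- function(a, b, exact_threshold = 12) {
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) abort("both groups must be non-empty.")
  r <- rank(c(a, b))
  u_a <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  has_ties <- anyDuplicated(c(a, b)) > 0
  if (na + nb <= exact_threshold && !has_ties) {
    sets <- combn(na + nb, na)
    ranks <- seq_len(na + nb)
    u_all <- colSums(matrix(ranks[sets], nrow = na)) - na * (na + 1) / 2
    u_low <- min(u_a, na * nb - u_a)
    p <- min(1, mean(u_all <= u_low) + mean(u_all >= na * nb - u_low))
    variant <- "exact"
  } else {
    mu <- na * nb / 2
    ties <- table(r)
    n <- na + nb
    v <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (u_a - mu - 0.5 * sign(u_a - mu)) / sqrt(v)
    p <- 2 * pnorm(-abs(z))
    variant <- "normal-approximation"
  }
  new_alps_test(
    method = "Mann-Whitney U", variant = variant, statistic = u_a,
    p_two_sided = p, n_effective = na + nb,
    extra = list(n1 = na, n2 = nb, u_a = u_a, u_b = na * nb - u_a)
  )
}

new_alps_test <- function(method, variant, statistic, p_two_sided,
                          n_effective, extra = list()) {
  structure(
    c(list(method = method, variant = variant, statistic = statistic,
           p_two_sided = p_two_sided, n_effective = n_effective), extra),
    class = "alps_test"
  )
}

#' @export
print.alps_test <- function(x, ...) {
  cat(sprintf("%s test (%s)\n  statistic = %g, n_effective = %d, p = %.4g\n",
              x$method, x$variant, x$statistic, x$n_effective, x$p_two_sided))
  invisible(x)
}

#' @rdname wilcoxon_signed_rank
#' @param x an `alps_test`
#' @param ... unused
#' @method tidy alps_test
#' @export
tidy.alps_test <- function(x, ...) {
  tibble(method = x$method, variant = x$variant, statistic = x$statistic,
         p_two_sided = x$p_two_sided, n_effective = x$n_effective)
}

#' Simple linear regression
#'
#' Ordinary least squares of `y` on `x` via [stats::lm()];
#' `R^2 = 1 - SSE/SST` and the slope p-value from the two-sided t test
#' with `n - 2` degrees of freedom.
#'
#' @param x predictor (not constant), `y` response; `n >= 3`
#' @param y response
#' @return an `alps_regression` (list with `slope`, `intercept`,
#'   `r_squared`, `p_slope`, `n`, and the underlying `fit`)
#' @export
linear_regression <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("need at least 3 complete observations.")
  if (diff(range(x)) == 0) abort("constant predictor.")
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # silence the perfect-fit warning
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = sm$r.squared, p_slope = unname(sm$coefficients[2, 4]),
         n = length(x), fit = fit),
    class = "alps_regression"
  )
}

#' @export
print.alps_regression <- function(x, ...) {
  cat(sprintf("linear regression (n = %d): slope = %.4g, R^2 = %.4g, p = %.4g\n",
              x$n, x$slope, x$r_squared, x$p_slope))
  invisible(x)
}

#' @rdname linear_regression
#' @param ... unused
#' @method tidy alps_regression
#' @export
tidy.alps_regression <- function(x, ...) {
  tibble(term = c("(Intercept)", "x"),
         estimate = c(x$intercept, x$slope))
}

#' @rdname linear_regression
#' @method glance alps_regression
#' @export
glance.alps_regression <- function(x, ...) {
  tibble(r_squared = x$r_squared, p_slope = x$p_slope, n = x$n)
}

#' Descriptive summary (cohort-report convention)
#'
#' Sample sd (n-1 denominator); median as the midpoint of the central
#' order statistics for even n; quartiles by the midpoint-of-halves
#' convention with the overall median excluded from both halves (Q1/Q3 are
#' the medians of the lower/upper half). The quartile convention is a
#' package choice — quantile conventions differ across tools and the
#' cohort report does not state one — so printed Q1/Q3 elsewhere need not
#' match to the last digit; medians for even n are convention-free.
#'
#' @param v numeric sample, `n >= 2` when an sd is requested
#' @param require_sd error (TRUE) or emit NA (FALSE) when `n < 2`
#' @return one-row tibble `n, mean, sd, median, q1, q3`
#' @export
describe <- function(v, require_sd = TRUE) {
  v <- v[is.finite(v)]
  n <- length(v)
  if (n == 0) abort("empty sample.")
  if (n < 2 && require_sd) abort("need n >= 2 for a standard deviation.")
  s <- sort(v)
  lower <- s[seq_len(floor(n / 2))]
  upper <- s[seq(n - floor(n / 2) + 1, n)]
  tibble(
    n = n, mean = mean(v), sd = if (n >= 2) sd(v) else NA_real_,
    median = median(v),
    q1 = if (length(lower)) median(lower) else NA_real_,
    q3 = if (length(upper)) median(upper) else NA_real_
  )
}

#' Match healthy controls to patients by sex and age
#'
#' Greedy nearest-age assignment under the study's rule: a control is
#' eligible for a patient when sexes are equal and ages differ by at most
#' `tolerance_years` (default 2). Controls may serve multiple patients.
#' Patients are processed in id order; ties in age distance go to the
#' lowest control id. `hemisphere_rule` records which control hemisphere is
#' compared against the patient (the cohort report does not state its
#' convention, so it stays a parameter): `"tumor_side"` uses the control
#' hemisphere on the patient's tumor side, `"fixed_left"`/`"fixed_right"`
#' always use that hemisphere.
#'
#' @param patients tibble with `id`, `age`, `sex` (and `tumor_side` for
#'   the `"tumor_side"` rule)
#' @param controls tibble with `id`, `age`, `sex`
#' @param tolerance_years maximum age difference
#' @param hemisphere_rule see above
#' @return tibble `patient_id, control_id, patient_age, control_age,
#'   age_diff` with attributes `tolerance_years`, `hemisphere_rule`
#' @export
match_controls <- function(patients, controls, tolerance_years = 2,
                           hemisphere_rule = c("tumor_side", "fixed_left",
                                               "fixed_right")) {
  hemisphere_rule <- match.arg(hemisphere_rule)
  if (nrow(patients) == 0) abort("empty patient list.")
  if (nrow(controls) == 0) abort("empty control list.")
  patients <- dplyr::arrange(patients, .data$id)
  rows <- purrr::map(seq_len(nrow(patients)), function(i) {
    p <- patients[i, ]
    elig <- controls[controls$sex == p$sex &
                       abs(controls$age - p$age) <= tolerance_years, ]
    if (nrow(elig) == 0) {
      abort(sprintf(
        "patient %s (%s, %g y) has no eligible control within +/- %g years.",
        p$id, p$sex, p$age, tolerance_years
      ))
    }
    elig <- elig[order(abs(elig$age - p$age), elig$id), ]
    tibble(patient_id = p$id, control_id = elig$id[1],
           patient_age = p$age, control_age = elig$age[1],
           age_diff = abs(elig$age[1] - p$age))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "tolerance_years") <- tolerance_years
  attr(out, "hemisphere_rule") <- hemisphere_rule
  out
}
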