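## Welch's t-test for length comparisons and the assembly summary /
## percentage calculator.

#' Welch's t-test
#'
#' Two-sample t-test for unequal variances: `t = (m1 - m2) /
#' sqrt(s1^2/n1 + s2^2/n2)` with Welch-Satterthwaite degrees of freedom
#' (non-integer) and a two-sided p from the t distribution. Appropriate for
#' comparing sequence-length distributions across annotation categories,
#' whose variances differ widely.
#'
#' @param a,b numeric samples, each of size >= 2.
#' @return List with `t`, `df`, `p_two_sided`, `mean_a`, `mean_b`, `var_a`,
#'   `var_b`, `n1`, `n2`. When both variances are 0 and the means equal,
#'   `t = 0`, `p = 1`; zero variances with unequal means is an error.
#' @examples
#' welchT(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))  # t = -1, df = 8
#' @export
welchT <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) stop("each sample needs n >= 2")
  m1 <- mean(a); m2 <- mean(b)
  v1 <- stats::var(a); v2 <- stats::var(b)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    if (m1 != m2) stop("zero variance in both samples with unequal means")
    return(list(t = 0, df = n1 + n2 - 2, p_two_sided = 1,
                mean_a = m1, mean_b = m2, var_a = v1, var_b = v2,
                n1 = n1, n2 = n2))
  }
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p_two_sided = p, mean_a = m1, mean_b = m2,
       var_a = v1, var_b = v2, n1 = n1, n2 = n2)
}

## half-up rounding to `digits` decimals (R's round() is banker's)
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  ## small epsilon keeps exact .5 ties from falling down via FP error
  sign(x) * floor(abs(x) * p + 0.5 + 1e-8) / p
}

#' Percentage of a count over its denominator
#'
#' @param numerator,denominator non-negative counts, numerator <=
#'   denominator.
#' @param digits decimals for the rounded report value (half-up).
#' @return List with `value` (unrounded percent) and `rounded`.
#' @export
pctOf <- function(numerator, denominator, digits = 2) {
  if (denominator <= 0) stop("denominator must be positive")
  if (numerator > denominator) stop("numerator exceeds denominator")
  v <- 100 * numerator / denominator
  list(value = v, rounded = roundHalfUp(v, digits))
}

#' Assembly summary with derived percentages
#'
#' Computes the standard report percentages of a Newbler-style assembly,
#' each over its documented denominator: the pass rate over raw reads; the
#' read fates (fully assembled, partially assembled, too short, repeat,
#' outlier, singleton) over passed reads; isotig/singleton database-hit
#' rates over their own totals; and the single-isotig-isogroup rate over
#' isogroups. When all six read fates are given they must sum to the
#' passed-read count.
#'
#' @param counts named list of available counts; recognised names:
#'   `raw_reads`, `passed_reads`, `fully_assembled`, `partially_assembled`,
#'   `too_short`, `repeat_reads`, `outliers`, `singletons`, `n_contigs`,
#'   `n_isotigs`, `n_isogroups`, `isotigs_with_hit`, `singletons_with_hit`,
#'   `single_isotig_isogroups`. Missing entries are simply omitted from the
#'   report and the conservation check.
#' @return List with `counts` (as given) and `percentages`: a data.frame
#'   (statistic, numerator, denominator, value, rounded) with unrounded
#'   values retained and half-up 2-decimal report values.
#' @export
summarizeAssembly <- function(counts) {
  g <- function(k) if (k %in% names(counts)) counts[[k]] else NULL
  fates <- c("fully_assembled", "partially_assembled", "too_short",
             "repeat_reads", "outliers", "singletons")
  if (!is.null(g("passed_reads")) && all(fates %in% names(counts))) {
    tot <- sum(unlist(counts[fates]))
    if (tot != counts$passed_reads)
      stop(sprintf("read fates sum to %d, not the %d passed reads",
                   tot, counts$passed_reads))
  }
  rows <- list()
  add <- function(stat, num, den) {
    if (is.null(num) || is.null(den)) return()
    p <- pctOf(num, den)
    rows[[length(rows) + 1]] <<- data.frame(
      statistic = stat, numerator = num, denominator = den,
      value = p$value, rounded = p$rounded)
  }
  add("pass_rate", g("passed_reads"), g("raw_reads"))
  for (f in fates) add(f, g(f), g("passed_reads"))
  add("isotigs_with_hit", g("isotigs_with_hit"), g("n_isotigs"))
  add("singletons_with_hit", g("singletons_with_hit"), g("n_singletons") %||%
        g("singletons"))
  add("single_isotig_isogroups", g("single_isotig_isogroups"),
      g("n_isogroups"))
  list(counts = counts,
       percentages = if (length(rows)) do.call(rbind, rows)
                     else data.frame())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pairwise Welch comparisons of length distributions
#'
#' Upper-triangular matrix of two-sided Welch p-values between category
#' length samples, coded in the conventional star notation
#' (`***` p < 0.0001, `**` p < 0.001, `*` p < 0.05, the numeric p
#' otherwise). Categories with fewer than 2 observations are excluded with
#' a warning.
#'
#' @param category_samples named list of numeric length vectors (>= 2
#'   categories).
#' @return List with `p` (numeric matrix, upper triangle filled) and
#'   `coded` (character matrix).
#' @export
compareLengthTables <- function(category_samples) {
  ok <- vapply(category_samples, function(s) length(s) >= 2, logical(1))
  if (any(!ok))
    warning("excluding categories with n < 2: ",
            paste(names(category_samples)[!ok], collapse = ", "))
  category_samples <- category_samples[ok]
  k <- length(category_samples)
  if (k < 2) stop("need at least 2 categories with n >= 2")
  nm <- names(category_samples)
  p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  coded <- matrix("", k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    pv <- welchT(category_samples[[i]], category_samples[[j]])$p_two_sided
    p[i, j] <- pv
    coded[i, j] <- codeP(pv)
  }
  list(p = p, coded = coded)
}

codeP <- function(p) {
  if (p < 1e-4) "***"
  else if (p < 1e-3) "**"
  else if (p < 0.05) "*"
  else format(signif(p, 4))
}
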