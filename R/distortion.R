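# Exact binomial tests for transmission distortion per rearrangement class.
#
# Unit allele frequencies are converted to chromosome counts by rounding
# the frequency per pair (one segregation event per bivalent/trivalent per
# meiosis, so pairs -- not allele copies -- are the unit of replication),
# summed within rearrangement classes, and tested against the cross-design
# expectation with a two-sided exact binomial test.

#' Expected SWE allele frequency under Mendelian segregation
#'
#' Backcross (F1 female x SWE male): every paternal copy is SWE and half
#' the maternal copies are, so autosomal units expect 0.75. Intercross
#' (F1 x F1): both meioses are 50:50, expectation 0.5. Z units are
#' monomorphic SWE in the backcross (expectation 1, no binomial test
#' possible) and are marked non-testable.
#'
#' @param cross `"backcross"` or `"intercross"`.
#' @param unit_class Rearrangement class (vectorized).
#' @return Numeric vector of expected frequencies, with attribute
#'   `testable` (logical vector; `FALSE` for `SEX_Z`).
#' @export
expected_frequency <- function(cross = c("backcross", "intercross"),
                               unit_class) {
  cross <- match.arg(cross)
  if (any(unit_class == "EXCLUDED_COMPLEX")) {
    stop("EXCLUDED_COMPLEX units have no defined expectation", call. = FALSE)
  }
  bad <- setdiff(unique(unit_class), rearrangement_classes())
  if (length(bad)) stop("unknown class: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  auto <- if (cross == "backcross") 0.75 else 0.5
  out <- ifelse(unit_class == "SEX_Z",
                if (cross == "backcross") 1.0 else NA_real_,
                auto)
  attr(out, "testable") <- unit_class != "SEX_Z"
  out
}

#' Chromosome counts from unit allele frequencies
#'
#' For each unit, the SWE count is the rounded product of its mean allele
#' frequency and the number of individuals; class totals are the sum over
#' units, with `n = units x individuals` trials ("pairs" counted once per
#' meiosis, not allele copies). Rounding is half away from zero by
#' default; half-to-even is available for sensitivity checks.
#'
#' @param af Unit mean allele frequencies (one per unit, all one class).
#' @param n_individuals Number of F2 individuals.
#' @param rounding `"half_up"` or `"half_even"`.
#' @return List with `k` (summed SWE counts), `n` (trials) and `k_unit`
#'   (per-unit counts).
#' @examples
#' counts_from_af(0.75, 4)  # k = 3, n = 4
#' @export
counts_from_af <- function(af, n_individuals,
                           rounding = c("half_up", "half_even")) {
  rounding <- match.arg(rounding)
  stopifnot(n_individuals >= 1, length(af) >= 1)
  if (any(af < 0 | af > 1)) stop("allele frequency outside [0, 1]",
                                 call. = FALSE)
  k_unit <- if (rounding == "half_up") {
    round_half_up(af * n_individuals)
  } else {
    round(af * n_individuals)
  }
  list(k = as.integer(sum(k_unit)),
       n = as.integer(length(af) * n_individuals),
       k_unit = as.integer(k_unit))
}

#' Two-sided exact binomial test with Clopper-Pearson interval
#'
#' The two-sided p-value follows the minimum-likelihood convention: the sum
#' of `P(X = x | n, p0)` over all outcomes no more probable than the
#' observed one, with relative tolerance `1 + 1e-7` on the comparison. The
#' confidence interval is the exact Clopper-Pearson interval for `k/n`.
#'
#' @param k Successes (0..n).
#' @param n Trials (>= 1).
#' @param p0 Null success probability in (0, 1).
#' @param conf_level Confidence level of the interval.
#' @return List with `p_value`, `ci_low`, `ci_high`, `estimate`.
#' @examples
#' exact_binomial_test(2, 4, 0.5)$p_value  # 1
#' @export
exact_binomial_test <- function(k, n, p0, conf_level = 0.95) {
  stopifnot(length(k) == 1, length(n) == 1, n >= 1, k >= 0, k <= n,
            p0 > 0, p0 < 1)
  d <- stats::dbinom(0:n, n, p0)
  p <- min(1, sum(d[d <= d[k + 1] * (1 + 1e-7)]))
  ci <- clopper_pearson(k, n, conf_level)
  list(p_value = p, ci_low = ci[[1]], ci_high = ci[[2]], estimate = k / n)
}

#' Exact Clopper-Pearson confidence interval
#'
#' @inheritParams exact_binomial_test
#' @return Numeric vector `c(low, high)`.
#' @export
clopper_pearson <- function(k, n, conf_level = 0.95) {
  a <- (1 - conf_level) / 2
  low <- if (k == 0) 0 else stats::qbeta(a, k, n - k + 1)
  high <- if (k == n) 1 else stats::qbeta(1 - a, k + 1, n - k)
  c(low = low, high = high)
}

# printed labels for the class-level output table
class_label <- function(klass) {
  c(FISSION_CAT = "Fission CAT", FUSION_SWE = "Fusion SWE",
    HOMOLOGOUS = "Homologous", UNKNOWN_POLARIZATION = "Unknown polarization",
    SEX_Z = "Z")[klass]
}

#' Transmission distortion scan over rearrangement classes
#'
#' Converts unit allele frequencies to chromosome counts, pools units
#' within each of the four autosomal rearrangement classes, and tests the
#' class totals against the cross-design expectation with a two-sided
#' exact binomial test. No multiple-testing correction is applied across
#' classes (a Bonferroni column is emitted for information).
#'
#' @param unit_af Output of [aggregate_unit_af()] (or any data.frame with
#'   `unit_id`, `class`, `mean_af`).
#' @param cross `"backcross"` or `"intercross"`.
#' @param n_individuals F2 individuals behind the allele frequencies.
#' @param alpha Significance level used for the `significant` flag.
#' @param rounding Passed to [counts_from_af()].
#' @return List with `classes` (one row per class: `experiment`,
#'   `chromosome_type`, `expected_frequency`, `observed_frequency`,
#'   `lower_95_CI`, `upper_95_CI`, `p_value`, `k`, `n`, `p_bonferroni`,
#'   `significant`) and `units` (per-unit frequencies with a flag for
#'   units deviating opposite to their class trend).
#' @export
run_distortion_scan <- function(unit_af, cross = c("backcross", "intercross"),
                                n_individuals, alpha = 0.05,
                                rounding = c("half_up", "half_even")) {
  cross <- match.arg(cross)
  rounding <- match.arg(rounding)
  stopifnot(n_individuals >= 1)
  unit_af <- unit_af[unit_af$class %in% autosomal_classes(), , drop = FALSE]
  if (!nrow(unit_af)) {
    empty <- data.frame(experiment = character(),
                        chromosome_type = character(),
                        expected_frequency = numeric(),
                        observed_frequency = numeric(),
                        lower_95_CI = numeric(), upper_95_CI = numeric(),
                        p_value = numeric(), k = integer(), n = integer(),
                        p_bonferroni = numeric(), significant = logical(),
                        stringsAsFactors = FALSE)
    return(list(classes = empty, units = data.frame()))
  }
  present <- intersect(autosomal_classes(), unique(unit_af$class))
  missing_classes <- setdiff(autosomal_classes(), present)
  if (length(missing_classes)) {
    warning("classes with zero units omitted: ",
            paste(missing_classes, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(present, function(klass) {
    sub <- unit_af[unit_af$class == klass, , drop = FALSE]
    exp_f <- as.numeric(expected_frequency(cross, klass))
    cts <- counts_from_af(sub$mean_af, n_individuals, rounding)
    tst <- exact_binomial_test(cts$k, cts$n, exp_f)
    data.frame(experiment = cross, chromosome_type = class_label(klass),
               expected_frequency = exp_f,
               observed_frequency = cts$k / cts$n,
               lower_95_CI = tst$ci_low, upper_95_CI = tst$ci_high,
               p_value = tst$p_value, k = cts$k, n = cts$n,
               stringsAsFactors = FALSE)
  })
  classes <- do.call(rbind, rows)
  classes$p_bonferroni <- pmin(1, classes$p_value * nrow(classes))
  classes$significant <- classes$p_value < alpha

  units <- unit_af
  units$expected_frequency <- as.numeric(
    expected_frequency(cross, units$class))
  class_dev <- classes$observed_frequency - classes$expected_frequency
  names(class_dev) <- classes$chromosome_type
  units$deviation <- units$mean_af - units$expected_frequency
  units$opposite_to_class_trend <-
    sign(units$deviation) != 0 &
    sign(units$deviation) !=
      sign(class_dev[class_label(units$class)])
  rownames(classes) <- rownames(units) <- NULL
  list(classes = classes, units = units)
}

#' Recover integer counts behind a printed frequency and interval
#'
#' Exhaustively searches `(k, n)` pairs whose frequency rounds (to
#' `digits` decimals) to the printed observed frequency and whose exact
#' Clopper-Pearson bounds round to the printed interval. Used to
#' reconstruct the counts behind published summary rows.
#'
#' @param observed Printed observed frequency, strictly inside (0, 1).
#' @param ci_low,ci_high Printed interval bounds bracketing `observed`.
#' @param n_max Largest `n` searched.
#' @param n_min Smallest `n` searched.
#' @param digits Printed precision.
#' @param conf_level Interval confidence level.
#' @return Data.frame of candidate `k`, `n`, ordered by `n` (possibly
#'   zero rows).
#' @export
recover_counts_from_summary <- function(observed, ci_low, ci_high,
                                        n_max, n_min = 10L, digits = 3L,
                                        conf_level = 0.95) {
  stopifnot(observed > 0, observed < 1, ci_low <= observed,
            ci_high >= observed)
  eq <- function(a, b) abs(a - b) < 10^(-digits) / 1e6
  n <- rep(n_min:n_max, each = 5L)
  k <- round(observed * n) + (-2:2)
  ok <- k >= 1 & k < n & eq(round(k / n, digits), observed)
  k <- k[ok]; n <- n[ok]
  if (!length(k)) return(data.frame(k = integer(), n = integer()))
  a <- (1 - conf_level) / 2
  lo <- stats::qbeta(a, k, n - k + 1)
  hi <- stats::qbeta(1 - a, k + 1, n - k)
  ok <- eq(round(lo, digits), ci_low) & eq(round(hi, digits), ci_high)
  out <- data.frame(k = as.integer(k[ok]), n = as.integer(n[ok]))
  out[order(out$n, out$k), , drop = FALSE]
}
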