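#' D'Agostino-Pearson omnibus normality test
#'
#' The K2 omnibus statistic combining the transformed sample skewness (Z1)
#' and kurtosis (Z2), K2 = Z1^2 + Z2^2, referred to a chi-squared
#' distribution with 2 degrees of freedom. Requires n >= 8 for the kurtosis
#' transformation to be defined.
#'
#' @param x numeric observations.
#' @return list with \code{statistic} (K2), \code{p.value}, \code{n}.
#' @export
dagostino_pearson <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8L) stop("D'Agostino-Pearson test requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("zero variance sample")
  b1 <- mean((x - m)^3) / m2^1.5       # sample skewness g1
  b2 <- mean((x - m)^4) / m2^2         # sample kurtosis g2 (not excess)

  # skewness: Johnson SU transformation (D'Agostino 1970)
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * asinh(y / alpha)

  # kurtosis: Anscombe-Glynn transformation (1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - eb2) / sqrt(vb2)
  sqrtb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrtb1 * (2 / sqrtb1 + sqrt(1 + 4 / sqrtb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xx * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(statistic = k2, p.value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       n = n)
}

#' Four-test normality gate
#'
#' A sample is called \code{"normal"} only if all four tests —
#' D'Agostino-Pearson, Anderson-Darling, Shapiro-Wilk and
#' Kolmogorov-Smirnov (Lilliefors-corrected, parameters estimated) — fail to
#' reject at \code{alpha}; a single rejection routes the data to
#' nonparametric tests. Samples too small for the battery (n < 8) are
#' \code{"indeterminate"}.
#'
#' @param x numeric observations.
#' @param alpha significance level for each test (default 0.05).
#' @return list with \code{verdict} ("normal" | "non-normal" |
#'   "indeterminate"), \code{detail} (data.frame of test, statistic, p), and
#'   \code{reason} when indeterminate.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8L) {
    return(list(verdict = "indeterminate", detail = NULL,
                reason = sprintf(
                  "n = %d < 8: the four-test battery is undefined", n)))
  }
  if (stats::var(x) == 0) {
    return(list(verdict = "non-normal", detail = NULL,
                reason = "zero variance"))
  }
  dp <- dagostino_pearson(x)
  ad <- nortest::ad.test(x)
  sw <- stats::shapiro.test(x)
  ks <- nortest::lillie.test(x)
  detail <- data.frame(
    test = c("dagostino_pearson", "anderson_darling", "shapiro_wilk",
             "kolmogorov_smirnov"),
    statistic = c(dp$statistic, unname(ad$statistic), unname(sw$statistic),
                  unname(ks$statistic)),
    p.value = c(dp$p.value, ad$p.value, sw$p.value, ks$p.value),
    stringsAsFactors = FALSE)
  verdict <- if (all(detail$p.value > alpha)) "normal" else "non-normal"
  list(verdict = verdict, detail = detail, reason = NULL)
}

as_group_list <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("group", "value") %in% colnames(groups)))
    groups <- split(groups$value, groups$group)
  }
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(vapply(groups, is.numeric, logical(1))))
  if (any(vapply(groups, length, integer(1)) == 0L)) stop("empty group")
  if (!all(vapply(groups, function(g) all(is.finite(g)), logical(1)))) {
    stop("non-finite observations")
  }
  if (is.null(names(groups))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  groups
}

#' Two-group comparison with normality routing
#'
#' Welch's t test when both groups pass the four-test [normality_gate()];
#' otherwise a Mann-Whitney (Wilcoxon rank-sum) test — exact by full
#' enumeration when \code{min(n) <= 8} and there are no ties, the normal
#' approximation with tie correction otherwise. The raw p-value is
#' Bonferroni-adjusted by \code{n_comparisons} (e.g. 2 when the myogenic and
#' neurogenic phases are compared in parallel), capped at 1.
#'
#' @param groups a list of exactly two numeric vectors (optionally named),
#'   or a data.frame with \code{group}/\code{value} columns.
#' @param n_comparisons Bonferroni family size (default 1).
#' @param force \code{"auto"} (gate-routed), \code{"parametric"} or
#'   \code{"nonparametric"}.
#' @return a \code{test_report} list: \code{test}, \code{statistic},
#'   \code{p.value}, \code{p.adjusted}, \code{adjustment}, \code{n},
#'   \code{normality} (per-group verdicts).
#' @export
compare_two <- function(groups, n_comparisons = 1L,
                        force = c("auto", "parametric", "nonparametric")) {
  force <- match.arg(force)
  groups <- as_group_list(groups)
  if (length(groups) != 2L) stop("compare_two requires exactly 2 groups")
  verdicts <- vapply(groups, function(g) normality_gate(g)$verdict,
                     character(1))
  parametric <- if (force == "auto") all(verdicts == "normal")
                else force == "parametric"
  x <- groups[[1L]]; y <- groups[[2L]]
  if (parametric) {
    ht <- stats::t.test(x, y, var.equal = FALSE)
    test <- "welch_t"
  } else {
    exact <- min(length(x), length(y)) <= 8L &&
      !anyDuplicated(c(x, y))
    ht <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = !exact))
    test <- if (exact) "mann_whitney_exact" else "mann_whitney_approx"
  }
  structure(list(
    test = test,
    statistic = unname(ht$statistic),
    p.value = ht$p.value,
    p.adjusted = min(1, ht$p.value * n_comparisons),
    adjustment = "bonferroni",
    n_comparisons = as.integer(n_comparisons),
    n = vapply(groups, length, integer(1)),
    normality = verdicts), class = "test_report")
}

#' Multi-group comparison battery
#'
#' When every group passes the [normality_gate()]: Welch's ANOVA and the
#' Brown-Forsythe ANOVA as omnibus tests, followed by pairwise Dunnett T3
#' comparisons (Welch-type pairwise t statistics with a
#' studentized-maximum-modulus family adjustment). Otherwise: the
#' Kruskal-Wallis test (tie-corrected) followed by Dunn's pairwise z tests
#' with Bonferroni adjustment. With a \code{control} group, pairwise
#' comparisons are restricted to control-vs-other.
#'
#' @param groups named list of >= 3 numeric vectors, or a
#'   \code{group}/\code{value} data.frame.
#' @param control optional name of the control group.
#' @param force as in [compare_two()].
#' @return list with \code{branch} ("parametric" | "nonparametric"),
#'   \code{omnibus} (data.frame of omnibus tests), \code{pairwise}
#'   (data.frame with statistic, df, raw and adjusted p per pair) and
#'   \code{normality}.
#' @export
compare_many <- function(groups, control = NULL,
                         force = c("auto", "parametric", "nonparametric")) {
  force <- match.arg(force)
  groups <- as_group_list(groups)
  if (length(groups) < 3L) stop("compare_many requires >= 3 groups")
  verdicts <- vapply(groups, function(g) normality_gate(g)$verdict,
                     character(1))
  parametric <- if (force == "auto") all(verdicts == "normal")
                else force == "parametric"
  labs <- names(groups)
  if (!is.null(control) && !control %in% labs) {
    stop("control group '", control, "' not found")
  }
  pairs <- if (is.null(control)) {
    utils::combn(labs, 2L, simplify = FALSE)
  } else {
    lapply(setdiff(labs, control), function(l) c(control, l))
  }
  m <- length(pairs)

  if (parametric) {
    if (any(vapply(groups, length, integer(1)) < 2L)) {
      stop("parametric branch requires n >= 2 in every group")
    }
    values <- unlist(groups, use.names = FALSE)
    fac <- factor(rep(labs, vapply(groups, length, integer(1))), levels = labs)
    welch <- stats::oneway.test(values ~ fac, var.equal = FALSE)
    bf <- brown_forsythe(groups)
    omnibus <- data.frame(
      test = c("welch_anova", "brown_forsythe_anova"),
      statistic = c(unname(welch$statistic), bf$statistic),
      df1 = c(unname(welch$parameter[1]), bf$df1),
      df2 = c(unname(welch$parameter[2]), bf$df2),
      p.value = c(welch$p.value, bf$p.value), stringsAsFactors = FALSE)
    pw <- do.call(rbind, lapply(pairs, function(p) {
      a <- groups[[p[1]]]; b <- groups[[p[2]]]
      se2 <- stats::var(a) / length(a) + stats::var(b) / length(b)
      t <- (mean(a) - mean(b)) / sqrt(se2)
      df <- se2^2 / ((stats::var(a) / length(a))^2 / (length(a) - 1) +
                       (stats::var(b) / length(b))^2 / (length(b) - 1))
      praw <- 2 * stats::pt(-abs(t), df)
      # studentized-maximum-modulus family adjustment (independence form)
      padj <- min(1, 1 - (2 * stats::pt(abs(t), df) - 1)^m)
      data.frame(group1 = p[1], group2 = p[2], statistic = t, df = df,
                 p.value = praw, p.adjusted = padj, stringsAsFactors = FALSE)
    }))
    method <- "dunnett_t3"
  } else {
    values <- unlist(groups, use.names = FALSE)
    fac <- factor(rep(labs, vapply(groups, length, integer(1))), levels = labs)
    if (stats::var(values) == 0) {
      # degenerate all-tied data: the tie correction removes all variance
      omnibus <- data.frame(test = "kruskal_wallis", statistic = 0,
                            df1 = length(groups) - 1, df2 = NA_real_,
                            p.value = 1, stringsAsFactors = FALSE)
    } else {
      kw <- stats::kruskal.test(values, fac)
      omnibus <- data.frame(
        test = "kruskal_wallis", statistic = unname(kw$statistic),
        df1 = unname(kw$parameter), df2 = NA_real_, p.value = kw$p.value,
        stringsAsFactors = FALSE)
    }
    pw <- dunn_pairwise(groups, pairs)
    method <- "dunn"
  }
  list(branch = if (parametric) "parametric" else "nonparametric",
       method = method, omnibus = omnibus, pairwise = pw,
       normality = verdicts)
}

# Brown-Forsythe (1974) ANOVA for means: F* with Satterthwaite df
brown_forsythe <- function(groups) {
  ni <- vapply(groups, length, integer(1))
  N <- sum(ni)
  mi <- vapply(groups, mean, numeric(1))
  vi <- vapply(groups, stats::var, numeric(1))
  grand <- sum(ni * mi) / N
  num <- sum(ni * (mi - grand)^2)
  ci <- (1 - ni / N) * vi
  den <- sum(ci)
  fstar <- num / den
  df2 <- den^2 / sum(ci^2 / (ni - 1))
  df1 <- length(groups) - 1
  list(statistic = fstar, df1 = df1, df2 = df2,
       p.value = stats::pf(fstar, df1, df2, lower.tail = FALSE))
}

# Dunn's pairwise z on pooled ranks with tie correction
dunn_pairwise <- function(groups, pairs) {
  values <- unlist(groups, use.names = FALSE)
  fac <- rep(names(groups), vapply(groups, length, integer(1)))
  rk <- rank(values)
  N <- length(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(rk, fac, mean)
  ni <- tapply(rk, fac, length)
  m <- length(pairs)
  do.call(rbind, lapply(pairs, function(p) {
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ni[p[1]] + 1 / ni[p[2]]))
    z <- if (se > 0) (rbar[p[1]] - rbar[p[2]]) / se else 0
    praw <- 2 * stats::pnorm(-abs(z))
    data.frame(group1 = p[1], group2 = p[2], statistic = unname(z),
               df = NA_real_, p.value = unname(praw),
               p.adjusted = min(1, unname(praw) * m), stringsAsFactors = FALSE)
  }))
}

#' qPCR amplification efficiency from a dilution series
#'
#' \eqn{E = d^{-1/s}} where \code{d} is the dilution factor and \code{s} the
#' slope of the CT-versus-log-dilution standard curve; an efficiency is
#' flagged as usable when it falls in the acceptance band [1.9, 2.2]
#' (perfect doubling gives E = 2).
#'
#' @param d dilution factor, > 1.
#' @param s standard-curve slope; non-zero.
#' @param band acceptance band (default \code{c(1.9, 2.2)}).
#' @return list with \code{efficiency}, \code{in_band}, \code{band}.
#' @export
qpcr_efficiency <- function(d, s, band = c(1.9, 2.2)) {
  stopifnot(is.finite(d), is.finite(s), d > 1)
  if (s == 0) stop("slope s must be non-zero")
  e <- d^(-1 / s)
  list(efficiency = e, in_band = e >= band[1] & e <= band[2], band = band)
}

#' qPCR fold change between two conditions
#'
#' \eqn{2^{\Delta CT_{goi}} / 2^{\Delta CT_{ref}}} with
#' \eqn{\Delta CT = CT_{control} - CT_{mutant}} for the gene of interest
#' (goi) and the reference gene. Invariant to adding a constant to all four
#' CT values.
#'
#' @param ct_goi_control,ct_goi_mutant CT of the gene of interest in the two
#'   conditions, cycles.
#' @param ct_ref_control,ct_ref_mutant CT of the reference gene.
#' @return scalar fold change.
#' @export
qpcr_fold_change <- function(ct_goi_control, ct_goi_mutant,
                             ct_ref_control, ct_ref_mutant) {
  cts <- c(ct_goi_control, ct_goi_mutant, ct_ref_control, ct_ref_mutant)
  if (length(cts) != 4L || !all(is.finite(cts))) {
    stop("all four CT values must be supplied and finite")
  }
  2^(ct_goi_control - ct_goi_mutant) / 2^(ct_ref_control - ct_ref_mutant)
}
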