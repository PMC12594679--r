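# Group statistics in the study's reporting style: mean +/- SEM per group,
# unpaired two-tailed Student's t (pooled variance) or Mann-Whitney U.
# p < 0.05 is the significance threshold; asterisks follow the figure-legend
# convention (* < 0.05, ** < 0.01, *** < 0.001).

#' Mean, SEM and n of a sample
#'
#' SEM is sd/sqrt(n) with the n-1 sample standard deviation; for a single
#' observation the SEM is reported as missing (NA).
#'
#' @param values numeric vector, finite, length >= 1.
#' @return list with \code{mean}, \code{sem}, \code{n}.
#' @examples
#' summarizeValues(c(1, 2, 3))   # mean 2, sem 1/sqrt(3)
#' @export
summarizeValues <- function(values) {
  if (!length(values)) stop("empty sample")
  if (any(!is.finite(values))) stop("values must be finite")
  n <- length(values)
  list(mean = mean(values), sem = if (n > 1) sd(values) / sqrt(n) else NA_real_,
       n = n)
}

starsFor <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

makeComparison <- function(a, b, testName, method, statistic, p,
                           labels = c("group_a", "group_b"),
                           metric = NA_character_) {
  sa <- summarizeValues(a); sb <- summarizeValues(b)
  p <- min(1, max(0, p))
  new("ComparisonResult", metric = metric, testName = testName,
      method = method, statistic = unname(statistic), pTwoTailed = p,
      groupLabels = labels, groupNs = c(sa$n, sb$n),
      groupMeans = c(sa$mean, sb$mean), groupSems = c(sa$sem, sb$sem),
      significantAt = c(`0.05` = p < 0.05, `0.01` = p < 0.01,
                        `0.001` = p < 0.001),
      stars = starsFor(p))
}

#' Unpaired two-tailed Student's t test (pooled variance)
#'
#' Classical pooled-variance t with \eqn{n_a + n_b - 2} degrees of freedom
#' and a two-tailed p value. When both groups have zero variance, p is 1 if
#' the means are equal (t = 0 by convention) and 0 otherwise.
#'
#' @param a,b numeric vectors, both of length >= 2.
#' @param labels character length 2, group names for the report.
#' @param metric optional metric name recorded in the result.
#' @return A \linkS4class{ComparisonResult}.
#' @examples
#' r <- studentsTUnpaired(c(1, 2, 3), c(4, 5, 6))
#' pValue(r)   # 0.0213 on 4 df
#' @export
studentsTUnpaired <- function(a, b, labels = c("group_a", "group_b"),
                              metric = NA_character_) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("both groups need n >= 2 for the t test")
  df <- na + nb - 2
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / df
  dm <- mean(a) - mean(b)
  if (sp2 == 0) {
    t <- if (dm == 0) 0 else sign(dm) * Inf
    p <- if (dm == 0) 1 else 0
  } else {
    t <- dm / sqrt(sp2 * (1 / na + 1 / nb))
    p <- 2 * pt(-abs(t), df)
  }
  makeComparison(a, b, "student_t_unpaired", "pooled_variance", t, p,
                 labels, metric)
}

# U statistic (number of (a, b) pairs with a > b; ties count 1/2)
uStatistic <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

# exact two-tailed p by full enumeration of the C(na+nb, na) rank
# assignments (tie-free samples)
mwExactP <- function(a, b) {
  pooled <- c(a, b)
  N <- length(pooled); na <- length(a)
  uObs <- uStatistic(a, b)
  sets <- combn(N, na)
  us <- apply(sets, 2, function(s) uStatistic(pooled[s], pooled[-s]))
  pLo <- mean(us <= uObs + 1e-9)
  pHi <- mean(us >= uObs - 1e-9)
  min(1, 2 * min(pLo, pHi))
}

#' Mann-Whitney U test
#'
#' Two-tailed unpaired rank test. For tie-free samples with
#' \eqn{n_a + n_b \le 14} the p value is exact, by full enumeration of all
#' rank assignments; otherwise mid-ranks are used with the tie-corrected
#' normal approximation (continuity corrected). The method actually used is
#' recorded in the result.
#'
#' @param a,b numeric vectors, both non-empty.
#' @param labels character length 2, group names.
#' @param metric optional metric name recorded in the result.
#' @return A \linkS4class{ComparisonResult} with the U statistic.
#' @examples
#' r <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
#' pValue(r)   # exact: 2/20 = 0.1
#' @export
mannWhitneyU <- function(a, b, labels = c("group_a", "group_b"),
                         metric = NA_character_) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  na <- length(a); nb <- length(b); N <- na + nb
  ties <- anyDuplicated(c(a, b)) > 0
  u <- uStatistic(a, b)
  if (!ties && N <= 14) {
    p <- mwExactP(a, b)
    method <- "exact_enumeration"
  } else {
    tt <- table(c(a, b))
    mu <- na * nb / 2
    sig2 <- na * nb / 12 * ((N + 1) - sum(tt^3 - tt) / (N * (N - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sig2)
      p <- 2 * pnorm(-abs(z))
    }
    method <- if (ties) "normal_approximation_tie_corrected"
              else "normal_approximation"
  }
  makeComparison(a, b, "mann_whitney_u", method, u, p, labels, metric)
}

#' Compare one metric between two groups of capillaries
#'
#' Extracts the per-capillary values of \code{metric} for the two groups in
#' the table and runs the chosen test. The capillary is the statistical
#' unit. With \code{test = "auto"} (default) the rule is: Mann-Whitney when
#' either group has n < 5 or fails a Shapiro-Wilk normality screen at
#' p < 0.05 (degenerate, zero-variance groups count as failing), otherwise
#' the pooled t test. The test used is always recorded in the result.
#'
#' @param table data.frame with one row per capillary, a grouping column and
#'   numeric metric columns.
#' @param metric name of the metric column.
#' @param test \code{"auto"}, \code{"student_t"} or \code{"mann_whitney"}.
#' @param groupCol name of the grouping column (default \code{"group"}).
#' @return A \linkS4class{ComparisonResult}.
#' @export
compareMetricTable <- function(table, metric,
                               test = c("auto", "student_t", "mann_whitney"),
                               groupCol = "group") {
  test <- match.arg(test)
  if (!metric %in% names(table)) stop("metric absent from table: ", metric)
  if (!groupCol %in% names(table)) stop("grouping column absent: ", groupCol)
  gl <- unique(as.character(table[[groupCol]]))
  if (length(gl) < 2) stop("missing group: need two groups, found ",
                           paste(gl, collapse = ", "))
  if (length(gl) > 2) stop("more than two groups in table")
  a <- table[[metric]][table[[groupCol]] == gl[1]]
  b <- table[[metric]][table[[groupCol]] == gl[2]]
  if (test == "auto") {
    nonNormal <- function(x) {
      if (length(x) < 5) return(TRUE)
      if (length(unique(x)) < 3) return(TRUE)   # degenerate for Shapiro-Wilk
      shapiro.test(x)$p.value < 0.05
    }
    test <- if (nonNormal(a) || nonNormal(b)) "mann_whitney" else "student_t"
  }
  if (test == "student_t") studentsTUnpaired(a, b, gl, metric)
  else mannWhitneyU(a, b, gl, metric)
}
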