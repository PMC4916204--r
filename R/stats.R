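#' Exact McNemar test for paired asystole rates
#'
#' Two-sided exact binomial test on the discordant pairs of a paired
#' 2 x 2 design (e.g. asystolic at 10 deg C vs at 22 deg C for the same
#' animals): under the null the `b + c` discordant pairs split Bin(b + c,
#' 1/2), and `p = min(1, 2 * P[Bin(b + c, 1/2) <= min(b, c)])`.
#'
#' @param n_discordant_01,n_discordant_10 the two discordant counts
#'   (non-negative integers).
#' @return the two-sided exact p-value; 1 (with attribute
#'   `zero_information = TRUE`) when there are no discordant pairs.
#' @examples
#' mcnemar_exact(8, 0)  # 0.0078125
#' mcnemar_exact(3, 0)  # 0.25
#' @export
mcnemar_exact <- function(n_discordant_01, n_discordant_10) {
  b <- n_discordant_01; c_ <- n_discordant_10
  check_scalar_num(b, "n_discordant_01", min = 0)
  check_scalar_num(c_, "n_discordant_10", min = 0)
  n <- b + c_
  if (n == 0) {
    p <- 1
    attr(p, "zero_information") <- TRUE
    return(p)
  }
  min(1, 2 * stats::pbinom(min(b, c_), n, 0.5))
}

#' Two-sided Fisher's exact test on a 2 x 2 table
#'
#' Point-probability rule: with margins fixed, the p-value sums the
#' hypergeometric probabilities of every table whose point probability does
#' not exceed the observed table's. Degenerate margins (an all-zero row or
#' column) carry no information and return 1.
#'
#' @param table a 2 x 2 matrix of non-negative integer counts (groups in
#'   rows, outcome in columns).
#' @return the two-sided exact p-value.
#' @examples
#' fisher_exact(matrix(c(8, 3, 0, 5), nrow = 2))  # 0.0256
#' @export
fisher_exact <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L))) stop_param("'table' must be 2 x 2")
  if (any(m < 0) || any(m != round(m))) stop_param("counts must be non-negative integers")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1)
  stats::fisher.test(m)$p.value
}

#' Two-way ANOVA on ranked Q10 values
#'
#' Rank-transforms the Q10 values globally (mid-ranks for ties), then runs
#' an ordinary two-way fixed-effects ANOVA of rank on acclimation group,
#' ramp phase, and their interaction — a robust alternative when Q10 is
#' not normal. Records with missing Q10 (arrested endpoints) are dropped
#' first; an empty group-by-phase cell drops the interaction with a
#' warning.
#'
#' @param q10_records a data frame with columns `q10`, `group`, `phase`
#'   (e.g. from [cohort_q10()]).
#' @return a data frame with one row per term: `term`, `df`, `F`, `p`.
#' @export
rank_anova_q10 <- function(q10_records) {
  stopifnot(all(c("q10", "group", "phase") %in% names(q10_records)))
  d <- q10_records[!is.na(q10_records$q10), , drop = FALSE]
  d$group <- factor(d$group)
  d$phase <- factor(d$phase)
  tab <- table(d$group, d$phase)
  if (any(tab < 2))
    warning("fewer than 2 observations in some group x phase cell", call. = FALSE)
  d$r <- rank(d$q10)
  if (stats::var(d$r) == 0) {
    # all values tied: no variation to partition
    terms <- c("group", "phase", "group:phase")
    return(data.frame(term = terms, df = NA_integer_, F = 0, p = 1))
  }
  form <- if (any(tab == 0)) {
    warning("empty group x phase cell; interaction dropped", call. = FALSE)
    r ~ group + phase
  } else r ~ group * phase
  fit <- stats::aov(form, data = d)
  s <- summary(fit)[[1L]]
  terms <- trimws(rownames(s))
  keep <- terms != "Residuals"
  data.frame(term = terms[keep], df = s$Df[keep],
             F = s$`F value`[keep], p = s$`Pr(>F)`[keep])
}
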