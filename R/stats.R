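## Variance-gated group comparisons, significance classes, sex-ratio
## balance.

#' F-test for homogeneity of variance
#'
#' Two-sided variance-ratio F-test: the larger sample variance goes in the
#' numerator (so F >= 1), the upper tail is doubled and capped at 1; df =
#' (n - 1, n - 1) per sample. Degenerate cases: both variances zero gives p
#' = 1 (no evidence against homogeneity); exactly one zero gives p = 0.
#'
#' @param a,b numeric samples (each n >= 2).
#' @return two-sided p-value.
#' @export
fTestVariance <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stopInsufficientData("F-test requires n >= 2 per group")
  va <- var(a); vb <- var(b)
  if (va == 0 && vb == 0) return(1)
  if (va == 0 || vb == 0) return(0)
  if (va >= vb) {
    f <- va / vb; df1 <- length(a) - 1L; df2 <- length(b) - 1L
  } else {
    f <- vb / va; df1 <- length(b) - 1L; df2 <- length(a) - 1L
  }
  min(1, 2 * pf(f, df1, df2, lower.tail = FALSE))
}

#' Significance class of a p-value
#'
#' `p > 0.05` is nonsignificant (`"n.s"`), `p < 0.05` one star, `p < 0.01`
#' two stars.
#'
#' @param p probability in `[0, 1]`.
#' @return one of `"n.s"`, `"*"`, `"**"`.
#' @export
classifySignificance <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1))
    stopValidation("p must be in [0, 1]")
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "n.s"))
}

#' Percent difference between group means
#'
#' `(larger - smaller) / smaller * 100`; the rounded integer value (as
#' reported alongside plots) is attached as attribute `"rounded"`.
#'
#' @param largerMean,smallerMean group means, \eqn{\mu m/s}; `smallerMean`
#'   must be positive.
#' @return percent difference (full precision) with attribute `rounded`.
#' @examples
#' percentDifference(3.15, 2.30)  # ~37
#' @export
percentDifference <- function(largerMean, smallerMean) {
  if (any(smallerMean <= 0))
    stopValidation("smaller mean must be > 0")
  pd <- (largerMean - smallerMean) / smallerMean * 100
  attr(pd, "rounded") <- round(pd)
  pd
}

#' Variance-gated two-sample t-test
#'
#' The F-test gate decides the branch: `f_p > 0.05` uses the pooled-variance
#' Student t-test, otherwise the Welch t-test with Welch-Satterthwaite df.
#' Both branches are two-sided. The sign of `t` follows the argument order
#' (`a` minus `b`); percent difference is always larger-vs-smaller mean.
#'
#' @param a,b numeric samples (each n >= 2).
#' @param labelA,labelB group labels.
#' @return one-row data.frame: group_a, group_b, n_a, n_b, mean_a, mean_b,
#'   f_p, variance_assumption, t_stat, df, t_p, significance,
#'   percent_difference, status.
#' @export
varianceGatedTTest <- function(a, b, labelA = "a", labelB = "b") {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L)
    stopInsufficientData("t-test requires n >= 2 per group")
  na <- length(a); nb <- length(b)
  ma <- mean(a); mb <- mean(b)
  va <- var(a); vb <- var(b)
  fp <- fTestVariance(a, b)
  if (fp > 0.05) {
    assumption <- "equal"
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    assumption <- "unequal"
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tstat <- if (se == 0) {
    if (ma == mb) 0 else sign(ma - mb) * Inf
  } else (ma - mb) / se
  tp <- if (is.infinite(tstat)) 0 else 2 * pt(abs(tstat), df,
                                              lower.tail = FALSE)
  pd <- if (min(ma, mb) > 0)
    as.numeric(percentDifference(max(ma, mb), min(ma, mb))) else NA_real_
  data.frame(group_a = labelA, group_b = labelB, n_a = na, n_b = nb,
             mean_a = ma, mean_b = mb, f_p = fp,
             variance_assumption = assumption, t_stat = tstat, df = df,
             t_p = tp, significance = classifySignificance(tp),
             percent_difference = pd, status = "ok",
             stringsAsFactors = FALSE)
}

#' Sex-ratio balance chi-square
#'
#' Goodness-of-fit chi-square of observed female/male counts against an
#' expected 50:50 split, df = 1, without continuity correction by default.
#'
#' @param nFemale,nMale counts of distinct embryos.
#' @param correct apply the Yates continuity correction (default FALSE).
#' @return list: n_female, n_male, chi2_stat, p.
#' @examples
#' chiSquareBalance(58, 25)
#' @export
chiSquareBalance <- function(nFemale, nMale, correct = FALSE) {
  n <- nFemale + nMale
  if (n < 1L) stopInsufficientData("no embryos")
  e <- n / 2
  dev <- abs(c(nFemale, nMale) - e)
  if (correct) dev <- pmax(0, dev - 0.5)
  chi2 <- sum(dev^2 / e)
  list(n_female = nFemale, n_male = nMale, chi2_stat = chi2,
       p = pchisq(chi2, df = 1L, lower.tail = FALSE))
}

insufficientRow <- function(labelA, labelB, nA, nB) {
  data.frame(group_a = labelA, group_b = labelB, n_a = nA, n_b = nB,
             mean_a = NA_real_, mean_b = NA_real_, f_p = NA_real_,
             variance_assumption = NA_character_, t_stat = NA_real_,
             df = NA_real_, t_p = NA_real_, significance = NA_character_,
             percent_difference = NA_real_, status = "insufficient-data",
             stringsAsFactors = FALSE)
}

gatedOrInsufficient <- function(a, b, labelA, labelB) {
  if (length(a) < 2L || length(b) < 2L)
    return(insufficientRow(labelA, labelB, length(a), length(b)))
  varianceGatedTTest(a, b, labelA, labelB)
}

#' Run the default comparison plan on a filtered cohort
#'
#' Executes, each through [varianceGatedTTest()]: (i) lateral vs midline
#' IRV, pooled and per sex; (ii) ML vs RC recoil within each region, pooled
#' and per sex; (iii) pairwise somite-stage bins (<=7, 8-9, >=10); and (iv)
#' the sex-ratio balance chi-square over distinct embryos. No
#' multiple-testing correction is applied (comparisons are reported
#' per-test); Benjamini-Hochberg adjusted p-values can be added with
#' `fdr = TRUE`.
#'
#' @param analysis filtered measurements joined to metadata (output
#'   `analysis` of [applyExclusions()]).
#' @param plan optional data.frame (name, factor, level_a, level_b,
#'   stratify_by) replacing the default plan; `stratify_by` may be NA.
#' @param fdr add a BH-adjusted p column (default FALSE).
#' @return list: `comparisons` (one row per comparison) and `sexBalance`
#'   (chi-square on distinct embryos).
#' @export
cohortComparisons <- function(analysis, plan = NULL, fdr = FALSE) {
  if (is.null(plan)) {
    plan <- rbind(
      data.frame(name = "region", factor = "region", level_a = "lateral",
                 level_b = "midline",
                 stratify_by = c(NA, "sex:F", "sex:M")),
      data.frame(name = "orientation_lateral", factor = "orientation",
                 level_a = "ML", level_b = "RC",
                 stratify_by = c("region:lateral",
                                 "region:lateral,sex:F",
                                 "region:lateral,sex:M")),
      data.frame(name = "orientation_midline", factor = "orientation",
                 level_a = "ML", level_b = "RC",
                 stratify_by = c("region:midline",
                                 "region:midline,sex:F",
                                 "region:midline,sex:M")),
      expand.grid(name = "stage", factor = "stage_bin",
                  level_a = c("<=7", "<=7", "8-9"),
                  level_b = c("8-9", ">=10", ">=10"),
                  stratify_by = NA, stringsAsFactors = FALSE)[, c(
                    "name", "factor", "level_a", "level_b", "stratify_by")]
    )
  }
  analysis$stage_bin <- cut(analysis$somites, c(-Inf, 7, 9, Inf),
                            labels = c("<=7", "8-9", ">=10"))
  rows <- lapply(seq_len(nrow(plan)), function(i) {
    p <- plan[i, ]
    sub <- analysis
    stratLabel <- ""
    if (!is.na(p$stratify_by) && nzchar(p$stratify_by)) {
      for (cond in strsplit(p$stratify_by, ",")[[1L]]) {
        kv <- strsplit(cond, ":")[[1L]]
        sub <- sub[!is.na(sub[[kv[1L]]]) & sub[[kv[1L]]] == kv[2L], ,
                   drop = FALSE]
      }
      stratLabel <- paste0(" | ", p$stratify_by)
    }
    fac <- as.character(sub[[p$factor]])
    a <- sub$irv[!is.na(fac) & fac == p$level_a]
    b <- sub$irv[!is.na(fac) & fac == p$level_b]
    out <- gatedOrInsufficient(a, b, paste0(p$level_a, stratLabel),
                               paste0(p$level_b, stratLabel))
    cbind(data.frame(comparison = p$name, stringsAsFactors = FALSE), out)
  })
  comparisons <- do.call(rbind, rows)
  if (fdr)
    comparisons$t_p_bh <- stats::p.adjust(comparisons$t_p, method = "BH")
  emb <- unique(analysis[, c("embryo_id", "sex")])
  balance <- chiSquareBalance(sum(emb$sex == "F", na.rm = TRUE),
                              sum(emb$sex == "M", na.rm = TRUE))
  list(comparisons = comparisons, sexBalance = balance)
}
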