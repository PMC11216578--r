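#' Normality-routed two-sample or paired test
#'
#' With `family = "auto"`, Shapiro-Wilk normality (per group, or on paired
#' differences) and Levene's homogeneity of variances at alpha = 0.05
#' route the comparison to a parametric test (paired/unpaired t, Welch when
#' variances differ) or its rank-based counterpart (Wilcoxon signed-rank /
#' rank-sum).  Two-tailed throughout.
#'
#' @param x,y Numeric samples (`y = NULL` for a one-sample test against
#'   `mu`).
#' @param paired Paired design (equal lengths required).
#' @param family `"auto"`, `"t"`, `"rank"`, `"ks"` or `"corr"`.
#' @param mu Null value for one-sample tests.
#' @param alpha Routing alpha.
#' @return list of class `routed_test`: `statistic`, `p`, `test`,
#'   `routing` (named logicals that drove the choice).
#' @export
route_test <- function(x, y = NULL, paired = FALSE,
                       family = c("auto", "t", "rank", "ks", "corr"),
                       mu = 0, alpha = 0.05) {
  family <- match.arg(family)
  stop_if(paired && (is.null(y) || length(x) != length(y)),
          "paired tests need equal-length samples")
  wrap <- function(ht, routing = NULL)
    structure(list(statistic = unname(ht$statistic), p = ht$p.value,
                   test = ht$method, routing = routing),
              class = "routed_test")
  if (paired && !is.null(y) && all(x == y)) {
    # all differences zero: no evidence against the null by convention
    return(structure(list(statistic = 0, p = 1,
                          test = "Wilcoxon signed rank test (all ties)",
                          routing = c(degenerate = TRUE)),
                     class = "routed_test"))
  }
  if (family == "ks") return(wrap(ks.test(x, y)))
  if (family == "corr") return(wrap(cor.test(x, y)))
  if (family == "t")
    return(wrap(t.test(x, y, paired = paired, mu = mu)))
  if (family == "rank")
    return(wrap(wilcox.test(x, y, paired = paired, mu = mu, exact = FALSE)))

  # auto routing
  small <- length(x) < 3 || (!is.null(y) && length(y) < 3)
  if (small) {
    warning("fewer than 3 observations: defaulting to a rank test")
    return(wrap(wilcox.test(x, y, paired = paired, mu = mu, exact = FALSE),
                routing = c(small_n = TRUE)))
  }
  normal <- if (paired) shapiro.test(x - y)$p.value >= alpha
  else if (is.null(y)) shapiro.test(x)$p.value >= alpha
  else shapiro.test(x)$p.value >= alpha && shapiro.test(y)$p.value >= alpha
  equal_var <- TRUE
  if (!paired && !is.null(y)) {
    lev <- car::leveneTest(c(x, y),
                           factor(rep(c("a", "b"), c(length(x), length(y)))))
    equal_var <- lev[["Pr(>F)"]][1] >= alpha
  }
  routing <- c(normal = normal, equal_var = equal_var)
  if (normal) {
    wrap(t.test(x, y, paired = paired, mu = mu, var.equal = equal_var),
         routing)
  } else {
    wrap(wilcox.test(x, y, paired = paired, mu = mu, exact = FALSE), routing)
  }
}

#' Pearson chi-squared test of independence
#'
#' Plain Pearson chi-squared with `(r-1)(c-1)` degrees of freedom and no
#' continuity correction.
#'
#' @param tab Contingency table (matrix/table of non-negative integer
#'   counts, at least 2 x 2).
#' @param correct Apply Yates continuity correction (default FALSE).
#' @return list with `statistic`, `df`, `p`.
#' @export
chi2_independence <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  stop_if(any(tab < 0) || any(tab != round(tab)),
          "counts must be non-negative integers")
  stop_if(nrow(tab) < 2 || ncol(tab) < 2, "need at least a 2x2 table")
  stop_if(any(rowSums(tab) == 0) || any(colSums(tab) == 0),
          "zero marginal total")
  ht <- suppressWarnings(chisq.test(tab, correct = correct))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

# Greenhouse-Geisser epsilon from the within-subject covariance matrix
gg_epsilon <- function(cov_mat) {
  k <- nrow(cov_mat)
  mean_diag <- mean(diag(cov_mat))
  grand <- mean(cov_mat)
  row_means <- rowMeans(cov_mat)
  num <- (k * (mean_diag - grand))^2
  den <- (k - 1) * (sum(cov_mat^2) - 2 * k * sum(row_means^2) +
                      k^2 * grand^2)
  min(1, max(1 / (k - 1), num / den))
}

#' Repeated-measures ANOVA with pairwise multiple comparisons
#'
#' Mixed (between x within) repeated-measures ANOVA via `aov` with an
#' `Error(subject/within)` stratum for balanced designs, with a
#' Greenhouse-Geisser sphericity correction of the within and interaction
#' p-values when Mauchly's test rejects sphericity; unbalanced designs fall
#' back to a linear mixed model (`lmerTest`), flagged in the output.
#' Pairwise comparisons of the within-factor levels (within each
#' between-factor level) come from `emmeans` with Tukey or Bonferroni
#' adjustment.
#'
#' @param data Long-format data.frame.
#' @param dv,subject,within,between Column names (between optional).
#' @param correction `"tukey"` or `"bonferroni"`.
#' @param sphericity_alpha Mauchly alpha triggering the GG correction.
#' @return list with `anova` (data.frame effect, df, statistic, p,
#'   p_corrected, gg_epsilon), `pairwise` (emmeans contrast table),
#'   `method` (`"aov"` or `"lmer"`).
#' @export
rm_anova_multcomp <- function(data, dv, subject, within, between = NULL,
                              correction = c("tukey", "bonferroni"),
                              sphericity_alpha = 0.05) {
  correction <- match.arg(correction)
  d <- data.frame(y = data[[dv]], subj = factor(data[[subject]]),
                  w = factor(data[[within]]))
  d$b <- if (!is.null(between)) factor(data[[between]]) else factor("all")
  stop_if(anyNA(d$y), "missing responses: exclude incomplete subjects first")
  counts <- table(d$subj, d$w)
  stop_if(any(counts > 1), "duplicated subject x condition cells")
  complete <- rowSums(counts == 1) == nlevels(d$w)
  if (any(!complete)) {
    warning(sum(!complete), " subject(s) missing conditions excluded")
    d <- d[d$subj %in% rownames(counts)[complete], , drop = FALSE]
    d$subj <- droplevels(d$subj)
  }
  balanced <- length(unique(table(d$b[!duplicated(d$subj)]))) == 1

  if (balanced) {
    form <- if (!is.null(between)) y ~ b * w + Error(subj / w)
    else y ~ w + Error(subj / w)
    fit <- do.call(aov, list(formula = form, data = d))
    sm <- summary(fit)
    # covariance across within-levels of subject means, pooled over groups
    wide <- tapply(d$y, list(d$subj, d$w), mean)
    grp <- d$b[match(rownames(wide), d$subj)]
    centred <- do.call(rbind, lapply(split(as.data.frame(wide), grp),
                                     function(g) scale(g, scale = FALSE)))
    eps <- gg_epsilon(stats::cov(centred))
    # Mauchly test on the orthonormal contrasts
    k <- nlevels(d$w)
    ctr <- stats::contr.helmert(k)
    ctr <- ctr %*% diag(1 / sqrt(colSums(ctr^2)))
    s_o <- t(ctr) %*% stats::cov(centred) %*% ctr
    n_eff <- nrow(centred) - nlevels(grp)
    W <- det(s_o) / (sum(diag(s_o)) / (k - 1))^(k - 1)
    mauchly_p <- if (k > 2 && W > 0 && n_eff > k) {
      f <- 1 - (2 * (k - 1)^2 + (k - 1) + 2) / (6 * (k - 1) * n_eff)
      pchisq(-n_eff * f * log(W), (k * (k - 1) / 2) - 1,
             lower.tail = FALSE)
    } else 1
    apply_gg <- mauchly_p < sphericity_alpha

    rows <- list()
    for (stratum in sm) {
      tabs <- stratum[[1]]
      for (i in seq_len(nrow(tabs) - 1)) {
        eff <- trimws(rownames(tabs)[i])
        df1 <- tabs[i, "Df"]; df2 <- tabs[nrow(tabs), "Df"]
        fv <- tabs[i, "F value"]; pv <- tabs[i, "Pr(>F)"]
        within_eff <- grepl("w", eff)
        pc <- if (within_eff && apply_gg)
          pf(fv, eps * df1, eps * df2, lower.tail = FALSE) else pv
        rows[[length(rows) + 1]] <- data.frame(
          effect = eff, df1 = df1, df2 = df2, statistic = fv,
          p = pv, p_corrected = pc)
      }
    }
    an <- do.call(rbind, rows)
    an$gg_epsilon <- eps
    em_fit <- fit
    method <- "aov"
  } else {
    warning("unbalanced between-subject design: using a mixed model")
    form <- if (!is.null(between)) y ~ b * w + (1 | subj)
    else y ~ w + (1 | subj)
    fit <- do.call(lmerTest::lmer, list(formula = form, data = d))
    at <- stats::anova(fit)
    an <- data.frame(effect = rownames(at), df1 = at$NumDF, df2 = at$DenDF,
                     statistic = at[["F value"]], p = at[["Pr(>F)"]],
                     p_corrected = at[["Pr(>F)"]], gg_epsilon = NA_real_)
    em_fit <- fit
    method <- "lmer"
  }
  spec <- if (!is.null(between)) ~ w | b else ~w
  emm <- emmeans::emmeans(em_fit, spec)
  pw <- as.data.frame(emmeans::contrast(
    emm, method = "pairwise",
    adjust = if (correction == "tukey") "tukey" else "bonferroni"))
  list(anova = an, pairwise = pw, method = method)
}
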