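#' Levenberg-Marquardt renormalisation of a log-intensity matrix
#'
#' Fits one additive offset per sample (in log space) by damped least
#' squares against the row medians, minimising sample-to-sample
#' differences; offsets are constrained to sum to zero.  Missing values
#' stay missing.
#'
#' @param m Numeric matrix, features x samples (log scale), NAs allowed.
#' @return list with `matrix` (renormalised), `factors` (per-sample
#'   offsets that were subtracted), `excluded` (samples with > 90%
#'   missingness, left untouched).
#' @export
renormalize_lm <- function(m) {
  stop_if(ncol(m) < 2, "need >= 2 samples")
  frac_na <- colMeans(is.na(m))
  excluded <- colnames(m)[frac_na > 0.9]
  if (length(excluded))
    warning("samples excluded from normalisation (>90% missing): ",
            paste(excluded, collapse = ", "))
  use <- frac_na <= 0.9
  anchor <- apply(m, 1, median, na.rm = TRUE)
  resid_fun <- function(a_free) {
    a <- c(a_free, -sum(a_free))
    r <- sweep(m[, use, drop = FALSE], 2, a) - anchor
    r[!is.na(r)]
  }
  fit <- minpack.lm::nls.lm(par = rep(0, sum(use) - 1), fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              ftol = 1e-10, maxiter = 100))
  a <- c(fit$par, -sum(fit$par))
  factors <- setNames(rep(0, ncol(m)), colnames(m))
  factors[use] <- a
  out <- sweep(m, 2, factors)
  list(matrix = out, factors = factors, excluded = excluded)
}

#' Batch correction of a peptidoform matrix
#'
#' Empirical-Bayes location/scale batch adjustment via `sva::ComBat`,
#' preserving group means through the model matrix.  Rows containing
#' missing values cannot enter ComBat and instead receive a per-batch
#' location-only centring (flagged with a warning); singleton batches also
#' trigger location-only adjustment.
#'
#' @param m Features x samples matrix (log scale).
#' @param batch Batch label per sample.
#' @param group Optional biological group per sample, protected as a
#'   covariate.
#' @return Corrected matrix.
#' @export
correct_batch <- function(m, batch, group = NULL) {
  batch <- as.factor(batch)
  stop_if(nlevels(batch) < 2, "need >= 2 batches")
  loc_only <- function(mm) {
    for (b in levels(batch)) {
      sel <- batch == b
      delta <- rowMeans(mm[, sel, drop = FALSE], na.rm = TRUE) -
        rowMeans(mm, na.rm = TRUE)
      mm[, sel] <- mm[, sel] - delta
    }
    mm
  }
  if (min(table(batch)) < 2) {
    warning("singleton batch: applying location-only adjustment")
    return(loc_only(m))
  }
  complete <- rowSums(is.na(m)) == 0
  out <- m
  if (any(complete)) {
    mod <- if (!is.null(group)) stats::model.matrix(~ as.factor(group))
    else NULL
    cc <- m[complete, , drop = FALSE]
    # ComBat needs per-row variance within batches
    degenerate <- apply(cc, 1, function(r)
      any(tapply(r, batch, var) < 1e-12))
    fixable <- which(complete)[!degenerate]
    if (length(fixable) > 1) {
      out[fixable, ] <- sva::ComBat(dat = m[fixable, , drop = FALSE],
                                    batch = batch, mod = mod,
                                    prior.plots = FALSE)
    }
  }
  if (any(!complete)) {
    warning(sum(!complete), " row(s) with missing values received ",
            "location-only batch centring")
    out[!complete, ] <- loc_only(m[!complete, , drop = FALSE])
  }
  out
}

#' Best-flyer protein-group quantification
#'
#' Two-step quantification per protein group: (i) a relative step builds a
#' mean protein-level profile across samples from the member peptidoform
#' profiles (each peptidoform centred to its own mean before averaging);
#' (ii) an absolute step shifts that profile so its mean equals the mean
#' intensity of the group's most intense peptidoform (best-flyer
#' hypothesis).  Groups with at least 3 unique peptidoforms are quantified
#' from unique peptidoforms only; otherwise razor peptidoforms are also
#' used.  Phosphopeptidoforms are excluded throughout.
#'
#' @param m Peptidoform log10 intensity matrix (rownames = peptidoform ids).
#' @param mapping data.frame with `peptidoform`, `protein`, `unique`,
#'   optionally `is_phospho`.
#' @return list with `profiles` (protein x sample matrix of log10
#'   abundances), `n_peptidoforms` (named vector of used counts),
#'   `dropped` (groups with no usable peptidoforms).
#' @export
quantify_protein_groups <- function(m, mapping) {
  stop_if(!all(rownames(m) %in% mapping$peptidoform),
          "mapping must cover every row of the matrix")
  map <- mapping[match(rownames(m), mapping$peptidoform), ]
  if (!is.null(map$is_phospho)) {
    keep <- !map$is_phospho
    m <- m[keep, , drop = FALSE]
    map <- map[keep, , drop = FALSE]
  }
  groups <- split(seq_len(nrow(m)), map$protein)
  profiles <- list(); used <- integer(0); dropped <- character(0)
  for (g in names(groups)) {
    idx <- groups[[g]]
    uni <- idx[map$unique[idx]]
    sel <- if (length(uni) >= 3) uni else idx
    sub <- m[sel, , drop = FALSE]
    ok <- rowSums(!is.na(sub)) > 0
    sub <- sub[ok, , drop = FALSE]
    if (nrow(sub) == 0) {
      dropped <- c(dropped, g)
      next
    }
    centred <- sub - rowMeans(sub, na.rm = TRUE)
    rel <- colMeans(centred, na.rm = TRUE)
    best <- which.max(rowMeans(sub, na.rm = TRUE))
    prof <- rel - mean(rel, na.rm = TRUE) + mean(sub[best, ], na.rm = TRUE)
    profiles[[g]] <- prof
    used[g] <- nrow(sub)
  }
  if (length(dropped))
    warning(length(dropped), " protein group(s) without usable ",
            "peptidoforms dropped")
  list(profiles = do.call(rbind, profiles), n_peptidoforms = used,
       dropped = dropped)
}

#' Moderated-t differential test with the regulation rule
#'
#' Two-sided moderated t test (empirical-Bayes variance shrinkage, limma)
#' per protein group on log10 abundances, Benjamini-Hochberg adjustment,
#' and the regulation flag: significant AND an absolute log2 ratio larger
#' than the 95th percentile of the control-to-average-control log2 ratios
#' (the data-driven fold-change threshold).  A volcano classification at
#' the fixed thresholds P < `volcano_p` and |log2 FC| > `volcano_fc` is
#' also reported.
#'
#' @param profiles Protein x sample log10 abundance matrix.
#' @param group Two-level factor per sample; the first level is control.
#' @param sig_adj_p BH-adjusted significance threshold for the regulation
#'   flag.
#' @param ratio_quantile Quantile of |log2(control / mean control)| used as
#'   the fold-change threshold (default 0.95, i.e. "greater than 5% of
#'   control-to-average-control ratios").
#' @param volcano_p,volcano_fc Fixed volcano thresholds.
#' @return data.frame with `protein`, `log2_fc`, `t`, `p`, `adj_p`,
#'   `regulated`, `volcano_hit`; fold-change threshold in attribute
#'   `"fc_threshold"`.
#' @export
differential_test <- function(profiles, group, sig_adj_p = 0.05,
                              ratio_quantile = 0.95,
                              volcano_p = 0.1, volcano_fc = 0.4) {
  group <- as.factor(group)
  stop_if(nlevels(group) != 2, "exactly two sample groups required")
  stop_if(min(table(group)) < 2, "need >= 2 samples per group")
  design <- stats::model.matrix(~ group)
  fit <- limma::eBayes(limma::lmFit(profiles, design))
  log2_fc <- fit$coefficients[, 2] / log10(2)
  p <- fit$p.value[, 2]
  adj <- p.adjust(p, "BH")
  ctrl <- profiles[, group == levels(group)[1], drop = FALSE]
  ctrl_ratio <- (ctrl - rowMeans(ctrl, na.rm = TRUE)) / log10(2)
  fc_thr <- quantile(abs(ctrl_ratio), ratio_quantile, na.rm = TRUE)
  out <- data.frame(protein = rownames(profiles), log2_fc = log2_fc,
                    t = fit$t[, 2], p = p, adj_p = adj,
                    regulated = adj < sig_adj_p & abs(log2_fc) > fc_thr,
                    volcano_hit = p < volcano_p & abs(log2_fc) > volcano_fc,
                    row.names = NULL)
  attr(out, "fc_threshold") <- unname(fc_thr)
  out
}
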