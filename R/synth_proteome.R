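#' Parameters for the synthetic peptidoform intensity matrix
#'
#' Log-normal peptidoform intensities built additively in log10 space:
#' protein base level + peptidoform offset + per-sample loading offset +
#' batch effect + group (differential) effect + noise, with optional
#' missing-at-random dropout.
#'
#' @param n_proteins Number of protein groups.
#' @param peptidoforms_per_protein Either a single count or a vector of
#'   candidate counts sampled per protein.
#' @param n_per_group Samples per group (control first); length-2 design.
#' @param loading_sd SD of per-sample loading offsets (log10).
#' @param n_batches Number of replicate batches (samples interleaved).
#' @param batch_sd SD of per-batch offsets (log10).
#' @param true_log2_fc Per-protein log2 fold change (group 2 vs control);
#'   recycled; 0 for nulls.
#' @param noise_sd Residual SD (log10).
#' @param missing_rate Missing-at-random dropout probability.
#' @param frac_razor Fraction of peptidoforms flagged razor (shared).
#' @param frac_phospho Fraction flagged as phosphopeptidoforms.
#' @param seed Integer seed.
#' @export
proteome_sim_params <- function(n_proteins = 500,
                                peptidoforms_per_protein = 1:6,
                                n_per_group = c(6, 6),
                                loading_sd = 0.15, n_batches = 2,
                                batch_sd = 0.1, true_log2_fc = 0,
                                noise_sd = 0.1, missing_rate = 0,
                                frac_razor = 0.05, frac_phospho = 0.03,
                                seed = 1L) {
  stop_if(any(n_per_group < 2), "group sizes must be >= 2")
  stop_if(noise_sd <= 0, "noise sd must be > 0")
  stop_if(missing_rate < 0 || missing_rate >= 1, "missing_rate in [0, 1)")
  p <- as.list(environment())
  structure(p, class = "proteome_sim_params")
}

#' Simulate a peptidoform intensity matrix with ground truth
#'
#' @param params A [proteome_sim_params()].
#' @return list with `matrix` (log10 intensities, peptidoforms x samples),
#'   `mapping` (data.frame: peptidoform, protein, unique, is_phospho),
#'   `samples` (data.frame: sample, group, batch, true_loading), and
#'   `truth` (data.frame: protein, log2_fc, regulated).
#' @export
gen_peptidoform_matrix <- function(params) {
  stop_if(!inherits(params, "proteome_sim_params"), "invalid params")
  set.seed(params$seed)
  n_s <- sum(params$n_per_group)
  group <- rep(c("control", "case"), params$n_per_group)
  batch <- rep_len(paste0("b", seq_len(params$n_batches)), n_s)
  loading <- rnorm(n_s, 0, params$loading_sd)
  batch_eff <- setNames(rnorm(params$n_batches, 0, params$batch_sd),
                        paste0("b", seq_len(params$n_batches)))
  lfc <- rep_len(params$true_log2_fc, params$n_proteins)

  n_pep <- sample(rep_len(params$peptidoforms_per_protein, 1000),
                  params$n_proteins, replace = TRUE)
  protein <- rep(paste0("P", seq_len(params$n_proteins)), n_pep)
  n_rows <- length(protein)
  base <- rep(rnorm(params$n_proteins, 6, 0.5), n_pep)
  pep_off <- rnorm(n_rows, 0, 0.5)
  grp_eff <- rep(lfc, n_pep) * log10(2)  # log2 FC expressed in log10

  m <- matrix(base + pep_off, n_rows, n_s) +
    outer(rep(1, n_rows), loading + batch_eff[batch]) +
    outer(grp_eff, as.numeric(group == "case")) +
    matrix(rnorm(n_rows * n_s, 0, params$noise_sd), n_rows)
  if (params$missing_rate > 0)
    m[matrix(runif(length(m)) < params$missing_rate, n_rows)] <- NA
  rownames(m) <- paste0("pep", seq_len(n_rows))
  colnames(m) <- paste0("s", seq_len(n_s))

  all_missing <- rowSums(!is.na(m)) == 0
  if (any(all_missing)) {
    warning(sum(all_missing), " all-missing peptidoform(s) dropped")
    m <- m[!all_missing, , drop = FALSE]
    protein <- protein[!all_missing]
  }
  n_rows <- nrow(m)
  mapping <- data.frame(peptidoform = rownames(m), protein = protein,
                        unique = runif(n_rows) >= params$frac_razor,
                        is_phospho = runif(n_rows) < params$frac_phospho)
  list(matrix = m, mapping = mapping,
       samples = data.frame(sample = colnames(m), group = group,
                            batch = batch, true_loading = loading),
       truth = data.frame(protein = paste0("P", seq_len(params$n_proteins)),
                          log2_fc = lfc, regulated = lfc != 0))
}
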