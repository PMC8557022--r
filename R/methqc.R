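# Probe-level quality control and beta <-> M conversion.

#' Filter probes by SNP/detection-p/non-CpG/sex-chromosome rules
#'
#' Probes are removed in a fixed order — (1) SNP-associated, (2) detection
#' p above `detp_threshold` in at least `min_fail` samples, (3) non-CpG,
#' (4) sex-chromosome — and each removed probe is attributed to the first
#' rule that catches it, so the report counts are deduplicated. The
#' surviving probe set is independent of the rule order.
#'
#' @param beta Beta tibble/matrix (probe id first column).
#' @param detp Detection-p table with the same probes and samples.
#' @param manifest Probe annotation with `snp_associated`, `non_cpg`,
#'   `sex_chrom`.
#' @param detp_threshold Detection-p cutoff (default 0.05).
#' @param min_fail Minimum number of failing samples for removal (default 1).
#' @return A list with `beta` (filtered tibble) and `report` (a one-row
#'   tibble of class `qc_report`: `removed_snp`, `removed_detp`,
#'   `removed_noncpg`, `removed_sexchrom`, `remaining`).
#' @export
filter_probes <- function(beta, detp, manifest, detp_threshold = 0.05,
                          min_fail = 1) {
  b <- as_value_matrix(beta)
  p <- as_value_matrix(detp)
  ids <- rownames(b)
  if (!setequal(ids, rownames(p)) || !all(ids %in% manifest$probe_id)) {
    abort("probe ids disagree across beta/detp/manifest",
          class = "inconsistent_input")
  }
  p <- p[ids, colnames(b), drop = FALSE]
  ann <- manifest[match(ids, manifest$probe_id), ]
  fail_detp <- rowSums(p > detp_threshold) >= min_fail
  rule <- rep(0L, length(ids))
  rule[ann$sex_chrom] <- 4L
  rule[ann$non_cpg] <- 3L
  rule[fail_detp] <- 2L
  rule[ann$snp_associated] <- 1L
  report <- structure(tibble(
    removed_snp = sum(rule == 1L),
    removed_detp = sum(rule == 2L),
    removed_noncpg = sum(rule == 3L),
    removed_sexchrom = sum(rule == 4L),
    remaining = sum(rule == 0L)
  ), class = c("qc_report", "tbl_df", "tbl", "data.frame"))
  list(beta = as_value_tbl(b[rule == 0L, , drop = FALSE]), report = report)
}

#' Convert beta values to M values
#'
#' Betas are clipped to `[eps, 1 - eps]` and transformed with
#' `M = log2(beta / (1 - beta))`, the variance-stabilised scale used for
#' linear modelling.
#'
#' @param beta Beta tibble/matrix.
#' @param eps Clip bound in `(0, 0.5)`.
#' @return M-value table in the same representation as the input.
#' @export
beta_to_m <- function(beta, eps = 1e-3) {
  stopifnot(eps > 0, eps < 0.5)
  b <- as_value_matrix(beta)
  b <- pmin(pmax(b, eps), 1 - eps)
  m <- log2(b / (1 - b))
  if (is.matrix(beta)) m else as_value_tbl(m)
}

#' Convert M values back to beta values
#'
#' Exact inverse of [beta_to_m()] on values inside the clip bounds.
#'
#' @param m M-value tibble/matrix.
#' @return Beta table in the same representation as the input.
#' @export
m_to_beta <- function(m) {
  v <- as_value_matrix(m)
  b <- 1 / (1 + 2^(-v))
  if (is.matrix(m)) b else as_value_tbl(b)
}
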