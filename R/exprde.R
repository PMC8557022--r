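# Expression filtering by counts-per-million and a simple log-CPM
# differential-expression model. The DE fit is an intentionally plain
# stand-in: integration stages only consume a DEG list, and a user-supplied
# DEG table with the same columns can replace it entirely.

#' Counts per million
#'
#' @param counts Count tibble/matrix (gene id first column). Library sizes
#'   are the column sums.
#' @return CPM table in the same representation as the input.
#' @export
cpm <- function(counts) {
  m <- as_value_matrix(counts)
  ls <- colSums(m)
  if (any(ls == 0)) abort("zero library size", class = "invalid_input")
  out <- sweep(m, 2, ls, "/") * 1e6
  if (is.matrix(counts)) out else as_value_tbl(out, id_col = "gene_id")
}

#' Filter lowly expressed genes by the CPM-in-a-group rule
#'
#' Keeps a gene when its CPM is at least `min_cpm` in at least `min_frac`
#' of the samples of at least one group. The filter is idempotent and
#' invariant to sample order.
#'
#' @param counts Count tibble/matrix.
#' @param sheet Sample sheet.
#' @param min_cpm CPM threshold (default 0.3).
#' @param min_frac Minimum within-group fraction (default 0.5).
#' @return The filtered count table.
#' @export
cpm_filter <- function(counts, sheet, min_cpm = 0.3, min_frac = 0.5) {
  check_sheet(sheet)
  m <- as_value_matrix(counts)
  v <- as_value_matrix(cpm(m))
  gi <- group_indices(sheet, colnames(m))
  ok_case <- rowMeans(v[, gi$case, drop = FALSE] >= min_cpm) >= min_frac
  ok_ctrl <- rowMeans(v[, gi$control, drop = FALSE] >= min_cpm) >= min_frac
  keep <- ok_case | ok_ctrl
  out <- m[keep, , drop = FALSE]
  if (is.matrix(counts)) out else as_value_tbl(out, id_col = "gene_id")
}

#' Simple differential expression on log CPM
#'
#' Per gene, `log2(CPM + 0.5)` is fitted by OLS on group plus covariates;
#' the group coefficient's t-test gives the p-value and the coefficient is
#' the log2 fold change (case over control). BH adjustment across genes.
#'
#' @param counts Count tibble/matrix (after [cpm_filter()]).
#' @param sheet Sample sheet.
#' @param covariates Sample-sheet column names used as covariates.
#' @return A tibble `gene`, `lfc`, `p`, `adj_p`, `direction` (`up`/`down`).
#' @export
simple_de <- function(counts, sheet, covariates = character()) {
  check_sheet(sheet)
  m <- as_value_matrix(counts)
  if (min(table(sheet$group[sheet$sample_id %in% colnames(m)])) < 2) {
    abort("need >= 2 samples per group", class = "insufficient_samples")
  }
  y <- log2(as_value_matrix(cpm(m)) + 0.5)
  sheet <- sheet[match(colnames(m), sheet$sample_id), ]
  dat <- data.frame(group = as.integer(sheet$group == "case"),
                    sheet[, covariates, drop = FALSE])
  X <- model.matrix(~ ., data = dat)
  if (qr(X)$rank < ncol(X)) abort("design matrix is rank deficient",
                                  class = "invalid_design")
  XtXinv <- chol2inv(chol(crossprod(X)))
  dimnames(XtXinv) <- list(colnames(X), colnames(X))
  coefs <- y %*% X %*% XtXinv
  colnames(coefs) <- colnames(X)
  res <- y - coefs %*% t(X)
  df <- nrow(X) - ncol(X)
  s2 <- rowSums(res^2) / df
  tval <- coefs[, "group"] / sqrt(s2 * XtXinv["group", "group"])
  tval[s2 == 0 & coefs[, "group"] == 0] <- 0
  p <- 2 * pt(-abs(tval), df)
  tibble(gene = rownames(m), lfc = unname(coefs[, "group"]),
         p = unname(p), adj_p = bh_adjust(unname(p)),
         direction = if_else(coefs[, "group"] >= 0, "up", "down"))
}

#' Export the DEG list at a p-value gate
#'
#' The conventional gate is raw `p < 0.01`; set `use_adjusted = TRUE` to
#' gate on the BH-adjusted p instead.
#'
#' @param de Output of [simple_de()] (or a user table with the same columns).
#' @param p_cut P-value threshold (default 0.01).
#' @param use_adjusted Gate on `adj_p` rather than `p`.
#' @return The filtered DEG tibble.
#' @export
deg_export <- function(de, p_cut = 0.01, use_adjusted = FALSE) {
  col <- if (use_adjusted) "adj_p" else "p"
  filter(de, .data[[col]] < p_cut)
}
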