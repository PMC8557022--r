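# Per-CpG differential methylation and kernel-smoothed DMR calling.

#' Per-CpG differential methylation linear model
#'
#' Fits, for every probe, an ordinary least-squares model of the M value on
#' group (case vs control) plus optional sample-sheet covariates. With
#' `moderate = TRUE` the residual variances are shrunk by empirical Bayes:
#' a scaled-F model is fitted to the distribution of residual variances by
#' method of moments, giving prior df `d0` and prior variance `s0^2`; the
#' moderated t uses the posterior variance and `df = df_res + d0`. The
#' delta-beta column is the difference of group mean betas (case minus
#' control), the effect-size unit used for region filtering.
#'
#' @param m M-value tibble/matrix (probes x samples).
#' @param beta Matching beta table (for delta-beta).
#' @param sheet Sample sheet with `sample_id`, `group`, covariate columns.
#' @param manifest Probe annotation supplying `chrom`/`pos`.
#' @param covariates Character vector of sample-sheet column names.
#' @param moderate Apply empirical-Bayes variance moderation (default TRUE).
#' @return A tibble with `probe_id`, `chrom`, `pos`, `effect` (M units,
#'   case - control), `delta_beta`, `t`, `df`, `p`, `adj_p`.
#' @export
fit_dms <- function(m, beta, sheet, manifest, covariates = character(),
                    moderate = TRUE) {
  check_sheet(sheet)
  Y <- as_value_matrix(m)
  B <- as_value_matrix(beta)[rownames(Y), colnames(Y), drop = FALSE]
  sheet <- sheet[match(colnames(Y), sheet$sample_id), ]
  if (anyNA(sheet$sample_id)) abort("samples missing from sheet")
  if (min(table(sheet$group)) < 2) {
    abort("need >= 2 samples per group", class = "insufficient_samples")
  }
  if (!all(covariates %in% names(sheet))) {
    abort("covariates missing from sample sheet", class = "invalid_design")
  }
  dat <- data.frame(group = as.integer(sheet$group == "case"),
                    sheet[, covariates, drop = FALSE])
  X <- model.matrix(~ ., data = dat)
  qx <- qr(X)
  if (qx$rank < ncol(X)) abort("design matrix is rank deficient",
                               class = "invalid_design")
  n <- nrow(X); p <- ncol(X)
  XtXinv <- chol2inv(chol(crossprod(X)))
  dimnames(XtXinv) <- list(colnames(X), colnames(X))
  coefs <- Y %*% X %*% XtXinv            # probes x p
  colnames(coefs) <- colnames(X)
  fitted <- coefs %*% t(X)
  res <- Y - fitted
  df_res <- n - p
  s2 <- rowSums(res^2) / df_res
  cg <- XtXinv["group", "group"]
  effect <- coefs[, "group"]
  if (moderate) {
    eb <- squeeze_var_mom(s2, df_res)
    s2_post <- eb$s2_post
    df_t <- df_res + eb$d0
  } else {
    s2_post <- s2
    df_t <- rep(df_res, length(s2))
  }
  tval <- effect / sqrt(s2_post * cg)
  tval[s2_post == 0] <- 0            # identical groups: define t = 0, p = 1
  pval <- 2 * pt(-abs(tval), df_t)
  gi <- group_indices(sheet, colnames(Y))
  db <- rowMeans(B[, gi$case, drop = FALSE]) -
    rowMeans(B[, gi$control, drop = FALSE])
  ann <- manifest[match(rownames(Y), manifest$probe_id), ]
  tibble(probe_id = rownames(Y), chrom = ann$chrom, pos = ann$pos,
         effect = unname(effect), delta_beta = unname(db),
         t = unname(tval), df = unname(df_t), p = unname(pval),
         adj_p = bh_adjust(unname(pval))) |>
    arrange(.data$chrom, .data$pos)
}

# Method-of-moments fit of the scaled-F model s2 ~ s0^2 * F(d, d0).
# Using E[s2] = s0^2 d0/(d0-2) and Var[s2]/E[s2]^2 = 2(d+d0-2)/(d(d0-4)):
# solving the CV equation for d0, then s0^2 from the mean. A non-positive
# denominator means no excess spread beyond chi-square sampling noise, i.e.
# d0 = Inf and complete shrinkage to the pooled variance.
squeeze_var_mom <- function(s2, d) {
  m <- mean(s2); v <- var(s2)
  if (!is.finite(v) || v <= 0 || m <= 0) {
    return(list(d0 = Inf, s0_2 = m, s2_post = rep(m, length(s2))))
  }
  cv <- v / m^2
  den <- cv * d - 2
  if (den <= 0) {
    d0 <- Inf; s0_2 <- m
    s2_post <- rep(s0_2, length(s2))
  } else {
    d0 <- (4 * cv * d + 2 * d - 4) / den
    if (d0 <= 4) d0 <- 4 + 1e-6       # keep the moment solution in-domain
    s0_2 <- m * (d0 - 2) / d0
    s2_post <- (d0 * s0_2 + d * s2) / (d0 + d)
  }
  list(d0 = d0, s0_2 = s0_2, s2_post = s2_post)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric())
  if (anyNA(p) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1]", class = "invalid_argument")
  }
  p.adjust(p, method = "BH")
}

#' Parameters for DMR calling
#'
#' @param lambda Gaussian smoothing bandwidth and merge distance, bp.
#' @param min_cpgs Minimum CpGs per region.
#' @param site_fdr Per-site significance level (adjusted p) and quantile
#'   level for the smoothed statistic.
#' @param region_fdr Region-level FDR threshold.
#' @param min_delta_beta Minimum |delta-beta| per region.
#' @param delta_filter Which region delta-beta faces the threshold:
#'   `"max"` (default) gates on the largest |delta-beta| among member
#'   probes, `"mean"` on the region mean. Kernel smoothing flags a halo of
#'   unshifted neighbours around a true region, which dilutes the mean, so
#'   the max is the more faithful reading of "the region shows a >= 10%
#'   methylation change"; both values are always reported.
#' @return A `dmr_params` list.
#' @export
dmr_params <- function(lambda = 1000, min_cpgs = 2, site_fdr = 0.05,
                       region_fdr = 0.05, min_delta_beta = 0.10,
                       delta_filter = c("max", "mean")) {
  delta_filter <- match.arg(delta_filter)
  if (lambda <= 0) abort("lambda must be > 0", class = "invalid_argument")
  for (x in c(site_fdr, region_fdr, min_delta_beta)) {
    if (x <= 0 || x >= 1) abort("thresholds must lie in (0, 1)",
                                class = "invalid_argument")
  }
  if (min_cpgs < 1) abort("min_cpgs must be >= 1", class = "invalid_argument")
  structure(list(lambda = lambda, min_cpgs = min_cpgs, site_fdr = site_fdr,
                 region_fdr = region_fdr, min_delta_beta = min_delta_beta,
                 delta_filter = delta_filter),
            class = "dmr_params")
}

#' Call differentially methylated regions
#'
#' Kernel-based region caller over a per-CpG result table: (1) squared t
#' statistics are smoothed along each chromosome with a Gaussian kernel of
#' bandwidth `lambda`; (2) a probe is flagged when its BH-adjusted p is at
#' most `site_fdr` *or* its smoothed statistic exceeds the genome-wide
#' `1 - site_fdr` quantile of smoothed statistics; (3) flagged probes within
#' `lambda` bp are merged into candidate regions; (4) regions with at least
#' `min_cpgs` CpGs are scored by Fisher's combination of member raw
#' p-values and BH-adjusted across regions; (5) regions pass with
#' `fdr < region_fdr` and a region |delta-beta| of at least
#' `min_delta_beta` (max over member probes by default, see
#' [dmr_params()]).
#'
#' @param dms Output of [fit_dms()].
#' @param params A [dmr_params()] object.
#' @return A tibble with `region_id`, `chrom`, `start`, `end` (1-based
#'   half-open), `n_cpgs`, `mean_delta_beta`, `max_delta_beta`, `direction`
#'   (`hyper`/`hypo`), `p_region`, `fdr`, and list-column `probes`.
#' @export
call_dmrs <- function(dms, params = dmr_params()) {
  stopifnot(inherits(params, "dmr_params"))
  need <- c("probe_id", "chrom", "pos", "delta_beta", "t", "p", "adj_p")
  if (!all(need %in% names(dms))) abort("dms table missing columns",
                                        class = "inconsistent_input")
  dms <- arrange(dms, .data$chrom, .data$pos)
  dms$smooth <- unlist(lapply(split(dms, dms$chrom), function(d) {
    kernel_smooth(d$pos, d$t^2, params$lambda)
  })[unique(dms$chrom)], use.names = FALSE)
  cut <- quantile(dms$smooth, 1 - params$site_fdr, type = 7, names = FALSE)
  dms$flag <- dms$adj_p <= params$site_fdr | dms$smooth > cut
  sig <- dms[dms$flag, ]
  if (!nrow(sig)) return(empty_dmr_table())
  sig <- sig |>
    group_by(.data$chrom) |>
    mutate(new_run = c(TRUE, diff(.data$pos) > params$lambda),
           run = cumsum(.data$new_run)) |>
    ungroup()
  cand <- sig |>
    group_by(.data$chrom, .data$run) |>
    summarise(
      start = min(.data$pos), end = max(.data$pos) + 1L,
      n_cpgs = n(),
      mean_delta_beta = mean(.data$delta_beta),
      max_delta_beta = .data$delta_beta[which.max(abs(.data$delta_beta))],
      p_region = fisher_combine(.data$p),
      probes = list(.data$probe_id),
      .groups = "drop"
    ) |>
    filter(.data$n_cpgs >= params$min_cpgs)
  if (!nrow(cand)) return(empty_dmr_table())
  cand$fdr <- bh_adjust(cand$p_region)
  db_col <- if (params$delta_filter == "max") "max_delta_beta" else "mean_delta_beta"
  out <- cand |>
    filter(.data$fdr < params$region_fdr,
           abs(.data[[db_col]]) >= params$min_delta_beta) |>
    mutate(direction = if_else(.data$mean_delta_beta > 0, "hyper", "hypo"),
           region_id = sprintf("%s:%d-%d", .data$chrom, .data$start,
                               .data$end)) |>
    select("region_id", "chrom", "start", "end", "n_cpgs",
           "mean_delta_beta", "max_delta_beta", "direction",
           "p_region", "fdr", "probes") |>
    arrange(.data$chrom, .data$start)
  out
}

empty_dmr_table <- function() {
  tibble(region_id = character(), chrom = character(), start = integer(),
         end = integer(), n_cpgs = integer(), mean_delta_beta = double(),
         max_delta_beta = double(), direction = character(),
         p_region = double(), fdr = double(), probes = list())
}

# Gaussian-kernel weighted mean of `stat` along positions; window truncated
# at 4 bandwidths. O(n * window) via two moving pointers.
kernel_smooth <- function(pos, stat, lambda) {
  n <- length(pos)
  out <- numeric(n)
  lo <- 1L; hi <- 1L
  for (i in seq_len(n)) {
    while (pos[i] - pos[lo] > 4 * lambda) lo <- lo + 1L
    while (hi < n && pos[hi + 1L] - pos[i] <= 4 * lambda) hi <- hi + 1L
    w <- exp(-((pos[lo:hi] - pos[i])^2) / (2 * lambda^2))
    out[i] <- sum(w * stat[lo:hi]) / sum(w)
  }
  out
}

fisher_combine <- function(p) {
  p <- pmax(p, 1e-300)
  pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}

#' Map DMRs to annotated genes
#'
#' Returns the union of the gene annotations of each region's member
#' probes; regions whose probes are all intergenic contribute nothing (such
#' regions are routed to the TF-annotation branch instead).
#'
#' @param dmrs Output of [call_dmrs()].
#' @param manifest Probe annotation with `gene`.
#' @return A tibble `gene`, `region_id` (one row per gene-region pair).
#' @export
map_dmrs_to_genes <- function(dmrs, manifest) {
  if (!nrow(dmrs)) return(tibble(gene = character(), region_id = character()))
  dmrs |>
    select("region_id", "probes") |>
    tidyr::unnest_longer("probes", values_to = "probe_id") |>
    left_join(manifest[, c("probe_id", "gene")], by = "probe_id") |>
    filter(!is.na(.data$gene)) |>
    distinct(.data$gene, .data$region_id)
}
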