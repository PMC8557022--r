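# Per-CpG linear model, BH adjustment, and the kernel DMR caller.

two_group_fixture <- function(case_vals, control_vals, probe = "cg01") {
  n1 <- length(case_vals); n2 <- length(control_vals)
  sheet <- tibble::tibble(
    sample_id = sprintf("S%02d", seq_len(n1 + n2)),
    group = rep(c("case", "control"), c(n1, n2)),
    age = 60, sex = "F")
  M <- matrix(c(case_vals, control_vals), 1,
              dimnames = list(probe, sheet$sample_id))
  beta <- m_to_beta(M)
  manifest <- tibble::tibble(probe_id = probe, chrom = "chr1", pos = 100L,
                             gene = NA_character_, feature = "intergenic",
                             snp_associated = FALSE, non_cpg = FALSE,
                             sex_chrom = FALSE)
  list(M = M, beta = beta, sheet = sheet, manifest = manifest)
}

test_that("unmoderated fit matches the hand-computed pooled OLS example", {
  fx <- two_group_fixture(c(1.0, 1.2, 0.8, 1.0), c(0.0, 0.2, -0.2, 0.0))
  dms <- fit_dms(fx$M, fx$beta, fx$sheet, fx$manifest, moderate = FALSE)
  expect_equal(dms$effect, 1.0, tolerance = 1e-12)
  expect_equal(dms$df, 6)
  expect_equal(dms$t, 1 / sqrt((0.16 / 6) * 0.5), tolerance = 1e-9)
  expect_equal(round(dms$t, 3), 8.660)
})

test_that("identical groups give zero effect and p = 1", {
  fx <- two_group_fixture(c(1, 2, 3, 4), c(1, 2, 3, 4))
  dms <- fit_dms(fx$M, fx$beta, fx$sheet, fx$manifest, moderate = FALSE)
  expect_equal(dms$effect, 0, tolerance = 1e-12)
  expect_equal(dms$p, 1, tolerance = 1e-9)
})

test_that("unmoderated fit equals the lm() oracle with covariates", {
  set.seed(42)
  mani <- sim_manifest(100, seed = 20)
  sheet <- sim_sample_sheet(6, 6, seed = 20)
  meth <- sim_methylation(mani, sheet, noise_sd = 0.2, seed = 21)
  M <- as_value_matrix(beta_to_m(meth$beta))
  dms <- fit_dms(M, meth$beta, sheet, mani, covariates = "age",
                 moderate = FALSE)
  g <- as.integer(sheet$group[match(colnames(M), sheet$sample_id)] == "case")
  a <- sheet$age[match(colnames(M), sheet$sample_id)]
  for (i in sample(nrow(dms), 25)) {
    f <- summary(lm(M[dms$probe_id[i], ] ~ g + a))$coefficients
    expect_equal(dms$t[i], f["g", "t value"], tolerance = 1e-9)
    expect_equal(dms$effect[i], f["g", "Estimate"], tolerance = 1e-9)
  }
})

test_that("unmoderated t agrees with limma's ordinary t", {
  skip_if_not_installed("limma")
  mani <- sim_manifest(200, seed = 30)
  sheet <- sim_sample_sheet(5, 5, seed = 30)
  meth <- sim_methylation(mani, sheet, noise_sd = 0.2, seed = 31)
  M <- as_value_matrix(beta_to_m(meth$beta))
  dms <- fit_dms(M, meth$beta, sheet, mani, moderate = FALSE)
  g <- as.integer(sheet$group[match(colnames(M), sheet$sample_id)] == "case")
  fit <- limma::lmFit(M, cbind(1, g))
  t_ord <- (fit$coefficients[, 2] /
              (fit$stdev.unscaled[, 2] * fit$sigma))[dms$probe_id]
  expect_equal(dms$t, unname(t_ord), tolerance = 1e-9)
})

test_that("error classes cover bad designs and small groups", {
  fx <- two_group_fixture(c(1, 2), c(1, 2, 3))
  bad_sheet <- fx$sheet; bad_sheet$group <- c("case", rep("control", 4))
  expect_error(fit_dms(fx$M, fx$beta, bad_sheet, fx$manifest),
               class = "insufficient_samples")
  const_sheet <- fx$sheet; const_sheet$age <- 50
  const_sheet$dup <- const_sheet$age
  expect_error(fit_dms(fx$M, fx$beta, const_sheet, fx$manifest,
                       covariates = c("age", "dup")),
               class = "invalid_design")
})

test_that("BH adjustment matches hand and brute-force oracles", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_error(bh_adjust(c(0.1, 1.2)), class = "invalid_argument")
  set.seed(7)
  for (i in 1:50) {
    p <- runif(sample(1:200, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
    expect_true(all(adj >= p - 1e-15))
  }
})

test_that("DMR caller separates two clusters and respects its thresholds", {
  # two planted clusters 5 kb apart on one chromosome
  pos <- c(seq(10000, 10800, by = 200), seq(15800, 16600, by = 200))
  n_extra <- 200
  mani <- tibble::tibble(
    probe_id = sprintf("cg%04d", seq_len(length(pos) + n_extra)),
    chrom = c(rep("chr1", length(pos)), rep("chr2", n_extra)),
    pos = c(pos, seq(5000, by = 1000, length.out = n_extra)),
    gene = NA_character_, feature = "intergenic",
    snp_associated = FALSE, non_cpg = FALSE, sex_chrom = FALSE)
  sheet <- sim_sample_sheet(8, 8, seed = 2)
  regions <- tibble::tibble(chrom = "chr1",
                            start = c(10000L, 15800L),
                            end = c(10801L, 16601L),
                            delta_beta = c(0.25, -0.25))
  meth <- sim_methylation(mani, sheet, dmr_regions = regions,
                          noise_sd = 0.1, seed = 3)
  dms <- fit_dms(beta_to_m(meth$beta), meth$beta, sheet, mani)
  dmrs <- call_dmrs(dms, dmr_params(lambda = 1000))
  chr1 <- dmrs[dmrs$chrom == "chr1", ]
  expect_equal(nrow(chr1), 2)
  expect_setequal(chr1$direction, c("hyper", "hypo"))
  # regions are disjoint within chromosome
  expect_true(all(chr1$end[-nrow(chr1)] <= chr1$start[-1]))
  # every reported region re-checks against all thresholds
  p <- dmr_params(lambda = 1000)
  for (i in seq_len(nrow(dmrs))) {
    expect_gte(dmrs$n_cpgs[i], p$min_cpgs)
    expect_lt(dmrs$fdr[i], p$region_fdr)
    expect_gte(abs(dmrs$max_delta_beta[i]), p$min_delta_beta)
    expect_equal(dmrs$direction[i],
                 if (dmrs$mean_delta_beta[i] > 0) "hyper" else "hypo")
    probes <- dmrs$probes[[i]]
    pp <- mani$pos[match(probes, mani$probe_id)]
    expect_true(all(pp >= dmrs$start[i] & pp < dmrs$end[i]))
  }
})

test_that("null methylation data yields no regions on average", {
  regions <- 0
  for (r in 1:3) {
    mani <- sim_manifest(1500, mean_spacing = 300, seed = 50 + r)
    sheet <- sim_sample_sheet(8, 8, seed = r)
    meth <- sim_methylation(mani, sheet, noise_sd = 0.15, seed = 60 + r)
    dms <- fit_dms(beta_to_m(meth$beta), meth$beta, sheet, mani)
    regions <- regions + nrow(call_dmrs(dms))
  }
  expect_lte(regions / 3, 0.5)
})

test_that("DMR-to-gene mapping unions member-probe annotations", {
  mani <- tibble::tibble(
    probe_id = c("p1", "p2", "p3", "p4"),
    chrom = "chr1", pos = c(100L, 200L, 300L, 400L),
    gene = c("A", "B", NA, NA), feature = c("promoter", "body",
                                            "intergenic", "intergenic"),
    snp_associated = FALSE, non_cpg = FALSE, sex_chrom = FALSE)
  dmrs <- tibble::tibble(region_id = c("r1", "r2"), chrom = "chr1",
                         start = c(100L, 300L), end = c(201L, 401L),
                         n_cpgs = 2L, mean_delta_beta = 0.2,
                         max_delta_beta = 0.2, direction = "hyper",
                         p_region = 1e-6, fdr = 1e-5,
                         probes = list(c("p1", "p2"), c("p3", "p4")))
  mapped <- map_dmrs_to_genes(dmrs, mani)
  expect_setequal(mapped$gene[mapped$region_id == "r1"], c("A", "B"))
  expect_false("r2" %in% mapped$region_id)   # all intergenic
})

test_that("dmr_params validates its domains", {
  expect_error(dmr_params(lambda = -5), class = "invalid_argument")
  expect_error(dmr_params(site_fdr = 1.5), class = "invalid_argument")
  expect_error(dmr_params(min_delta_beta = 0), class = "invalid_argument")
})
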