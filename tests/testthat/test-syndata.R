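# Generators: determinism, construction contracts, planted-truth containment.

test_that("manifest positions are sorted, flags match fractions, seeds reproduce", {
  m <- sim_manifest(100, n_chrom = 2, seed = 1)
  expect_equal(nrow(m), 100)
  by_chr <- split(m$pos, m$chrom)
  expect_true(all(vapply(by_chr, function(p) all(diff(p) > 0), logical(1))))
  expect_identical(m, sim_manifest(100, n_chrom = 2, seed = 1))
  expect_false(identical(m, sim_manifest(100, n_chrom = 2, seed = 2)))

  m2 <- sim_manifest(1000, flag_fractions = list(snp = 0.1), seed = 7)
  # 99.9% binomial bounds for Binomial(1000, 0.1)
  lo <- qbinom(5e-4, 1000, 0.1); hi <- qbinom(1 - 5e-4, 1000, 0.1)
  expect_gte(sum(m2$snp_associated), lo)
  expect_lte(sum(m2$snp_associated), hi)

  expect_error(sim_manifest(0), class = "invalid_argument")
  expect_error(sim_manifest(10, flag_fractions = list(snp = 1.4)),
               class = "invalid_argument")
})

test_that("noiseless planted shift reproduces delta-beta exactly; betas in (0,1)", {
  mani <- sim_manifest(200, seed = 3)
  sheet <- sim_sample_sheet(4, 4, seed = 1)
  planted <- tibble::tibble(probe_id = mani$probe_id[5], delta_beta = 0.2)
  meth <- sim_methylation(mani, sheet, dms_probes = planted, noise_sd = 0,
                          seed = 2)
  b <- as_value_matrix(meth$beta)
  gi <- split(sheet$sample_id, sheet$group)
  diff <- mean(b[mani$probe_id[5], gi$case]) -
    mean(b[mani$probe_id[5], gi$control])
  expect_equal(diff, 0.2, tolerance = 1e-12)
  expect_true(all(b > 0 & b < 1))
  expect_error(
    sim_methylation(mani, sheet,
                    dms_probes = tibble::tibble(probe_id = "nope",
                                                delta_beta = 0.1)),
    class = "invalid_argument")
  expect_error(
    sim_methylation(mani, sheet,
                    dmr_regions = tibble::tibble(chrom = "chr9", start = 1,
                                                 end = 10, delta_beta = 0.1)),
    class = "invalid_argument")
})

test_that("with no planted signal per-probe group comparisons are uniform", {
  mani <- sim_manifest(5000, seed = 11)
  sheet <- sim_sample_sheet(8, 8, seed = 4)
  meth <- sim_methylation(mani, sheet, noise_sd = 0.15, seed = 12)
  M <- as_value_matrix(beta_to_m(meth$beta))
  gi <- split(sheet$sample_id, sheet$group)
  p <- vapply(seq_len(nrow(M)), function(i) {
    t.test(M[i, gi$case], M[i, gi$control], var.equal = TRUE)$p.value
  }, numeric(1))
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("PPI generator respects module density and background probability", {
  genes <- sprintf("g%02d", 1:20)
  mod <- genes[1:6]
  ppi <- sim_ppi(genes, edge_prob = 0, planted_module = mod,
                 module_density = 1, seed = 5)
  expect_equal(nrow(ppi), choose(6, 2))
  expect_true(all(ppi$confidence >= 0.7))
  expect_true(all(ppi$gene_a %in% mod & ppi$gene_b %in% mod))
  expect_identical(ppi, sim_ppi(genes, edge_prob = 0, planted_module = mod,
                                module_density = 1, seed = 5))
  expect_error(sim_ppi(c("a", "a", "b")), class = "invalid_argument")
})

test_that("expression generator is deterministic and validates arguments", {
  sheet <- sim_sample_sheet(4, 4, seed = 2)
  genes <- sprintf("g%02d", 1:50)
  cnt <- sim_expression(genes, sheet, planted_lfc = c(g01 = 2), seed = 3)
  expect_identical(cnt, sim_expression(genes, sheet,
                                       planted_lfc = c(g01 = 2), seed = 3))
  m <- as_value_matrix(cnt)
  expect_true(all(m >= 0 & m == round(m)))
  expect_equal(attr(cnt, "lib_sizes"), colSums(m))
  expect_error(sim_expression(genes, sheet, dispersion = -1),
               class = "invalid_argument")
  expect_error(sim_expression(genes, sheet, planted_lfc = c(zz = 1)),
               class = "invalid_argument")
})

test_that("TF resources cover planted DMRs per the overlap fraction", {
  mani <- sim_manifest(500, seed = 6)
  regions <- plant_dmr_regions(mani, n_dmrs = 3, dmr_probes = 4,
                               delta_beta = 0.2, seed = 6)
  tfr <- sim_tf_resources(regions, tf_names = c("REST", "SP1"),
                          deg_genes = c("GA", "GB"),
                          overlap_fraction = 1, seed = 1)
  dmr_tbl <- tibble::tibble(
    region_id = sprintf("d%d", seq_len(nrow(regions))),
    chrom = regions$chrom, start = regions$start, end = regions$end)
  ann <- annotate_dmrs_to_tfs(dmr_tbl, tfr$clusters)
  expect_setequal(unique(ann$region_id), dmr_tbl$region_id)

  tfr0 <- sim_tf_resources(regions, tf_names = c("REST", "SP1"),
                           deg_genes = c("GA", "GB"),
                           overlap_fraction = 0, n_decoy = 0, seed = 1)
  expect_equal(nrow(annotate_dmrs_to_tfs(dmr_tbl, tfr0$clusters)), 0)

  tfr_rep <- sim_tf_resources(regions, tf_names = "REST",
                              deg_genes = c("GA", "GB"),
                              modes = "repression", seed = 2)
  expect_true(all(tfr_rep$targets$mode == "repression"))
  expect_error(sim_tf_resources(regions, tf_names = character(),
                                deg_genes = "GA"),
               class = "invalid_argument")
})

test_that("planted clock round-trips and degenerate clocks behave", {
  mani <- sim_manifest(300, seed = 9)
  sheet <- sim_sample_sheet(5, 5, seed = 9)
  clock <- sim_clock(mani, n_clock_probes = 20, seed = 9)
  meth <- sim_methylation(mani, sheet, seed = 10)
  beta <- plant_clock_signal(meth$beta, clock, sheet)
  pred <- predict_age(beta, clock)
  expect_equal(pred$dnam_age,
               sheet$age[match(pred$sample_id, sheet$sample_id)],
               tolerance = 1e-9)
  # one-probe clock is a valid degenerate case
  c1 <- sim_clock(mani, n_clock_probes = 1, seed = 2)
  expect_equal(length(c1$coefficients), 1)
  b1 <- plant_clock_signal(meth$beta, c1, sheet)
  expect_equal(predict_age(b1, c1)$dnam_age,
               sheet$age[match(colnames(as_value_matrix(b1)),
                               sheet$sample_id)],
               tolerance = 1e-9)
})

test_that("study bundle resolves all planted truth against its resources", {
  st <- simulate_study(n_probes = 600, n_genes = 60, n_degs = 10, seed = 3)
  expect_true(validate_truth(st$truth, st$manifest, st$ppi, st$counts))
  expect_true(all(st$truth$dms_probes$probe_id %in% st$manifest$probe_id))
  # regenerating with the same seed is byte-identical
  st2 <- simulate_study(n_probes = 600, n_genes = 60, n_degs = 10, seed = 3)
  expect_identical(st$beta, st2$beta)
  expect_identical(st$counts, st2$counts)
  expect_identical(st$ppi, st2$ppi)
})
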