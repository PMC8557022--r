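# Synthetic case-control study generator with planted truth. Every generator
# is a pure function of its arguments including `seed`, so downstream stages
# (QC, DMS/DMR calling, module detection, clock, DE, integration) can be
# tested end-to-end without any external download.

#' Simulate a case-control sample sheet
#'
#' @param n_case,n_control Samples per group.
#' @param age_range Chronological age range in years (uniform draw).
#' @param seed Integer RNG seed.
#' @return A tibble with `sample_id`, `group`, `age`, `sex`.
#' @export
sim_sample_sheet <- function(n_case = 8, n_control = 8,
                             age_range = c(50, 90), seed = 1) {
  stopifnot(n_case >= 1, n_control >= 1, age_range[1] > 0)
  with_seed(seed, {
    n <- n_case + n_control
    tibble(
      sample_id = sprintf("S%02d", seq_len(n)),
      group = rep(c("case", "control"), c(n_case, n_control)),
      age = round(runif(n, age_range[1], age_range[2]), 1),
      sex = sample(c("F", "M"), n, replace = TRUE)
    )
  })
}

#' Simulate a 450K-style probe annotation manifest
#'
#' Positions are strictly increasing within each chromosome with
#' exponential spacing; probes carry a gene symbol (or none), a feature
#' class, and the three QC flags used by [filter_probes()].
#'
#' @param n_probes Number of probes (>= 1).
#' @param n_chrom Number of autosome-like chromosomes (`chr1`..). One extra
#'   chromosome `chrX` hosts the sex-chromosome-flagged probes.
#' @param mean_spacing Mean inter-probe spacing in bp.
#' @param flag_fractions Named list with elements `snp`, `non_cpg`,
#'   `sex_chrom` giving flag probabilities in `[0, 1]`.
#' @param n_genes Size of the gene symbol pool.
#' @param frac_intergenic Fraction of probes with no gene annotation.
#' @param seed Integer RNG seed.
#' @return A tibble with columns `probe_id`, `chrom`, `pos` (1-based),
#'   `gene`, `feature`, `snp_associated`, `non_cpg`, `sex_chrom`.
#' @export
sim_manifest <- function(n_probes, n_chrom = 2, mean_spacing = 500,
                         flag_fractions = list(snp = 0.02, non_cpg = 0.02,
                                               sex_chrom = 0.02),
                         n_genes = max(20, ceiling(n_probes / 10)),
                         frac_intergenic = 0.25, seed = 1) {
  if (n_probes < 1) abort("`n_probes` must be >= 1", class = "invalid_argument")
  fr <- list(snp = 0, non_cpg = 0, sex_chrom = 0)
  fr[names(flag_fractions)] <- flag_fractions
  if (any(unlist(fr) < 0 | unlist(fr) > 1)) {
    abort("flag fractions must lie in [0, 1]", class = "invalid_argument")
  }
  with_seed(seed, {
    sexchr <- runif(n_probes) < fr$sex_chrom
    chrom <- character(n_probes)
    chrom[sexchr] <- "chrX"
    chrom[!sexchr] <- sample(paste0("chr", seq_len(n_chrom)),
                             sum(!sexchr), replace = TRUE)
    genes <- sprintf("G%04d", seq_len(n_genes))
    ann <- tibble(
      probe_id = sprintf("cg%06d", seq_len(n_probes)),
      chrom = chrom,
      gene = if_else(runif(n_probes) < frac_intergenic, NA_character_,
                     sample(genes, n_probes, replace = TRUE)),
      feature = sample(c("promoter", "body"), n_probes, replace = TRUE,
                       prob = c(0.4, 0.6)),
      snp_associated = runif(n_probes) < fr$snp,
      non_cpg = runif(n_probes) < fr$non_cpg,
      sex_chrom = sexchr
    )
    ann$feature[is.na(ann$gene)] <- "intergenic"
    # spacing drawn within chromosome so positions are strictly increasing
    ann |>
      group_by(chrom) |>
      mutate(pos = 1000L + cumsum(pmax(
        1L, as.integer(round(stats::rexp(n(), 1 / mean_spacing)))))) |>
      ungroup() |>
      select("probe_id", "chrom", "pos", "gene", "feature",
             "snp_associated", "non_cpg", "sex_chrom")
  })
}

#' Bundle planted truth for a synthetic study
#'
#' @param dms_probes Tibble (`probe_id`, `delta_beta`) of planted single-site
#'   shifts (case minus control, beta scale), or `NULL`.
#' @param dmr_regions Tibble (`chrom`, `start`, `end`, `delta_beta`) of
#'   planted regions, 1-based half-open, or `NULL`.
#' @param module_genes Character vector of planted PPI module members.
#' @param deg_genes Named numeric vector of true log2 fold changes.
#' @param clock A [clock_model()] planted in the betas, or `NULL`.
#' @param seed Seed the bundle was generated from.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(dms_probes = NULL, dmr_regions = NULL,
                            module_genes = character(), deg_genes = numeric(),
                            clock = NULL, seed = NA_integer_) {
  structure(list(dms_probes = dms_probes, dmr_regions = dmr_regions,
                 module_genes = module_genes, deg_genes = deg_genes,
                 clock = clock, seed = seed),
            class = "synthetic_truth")
}

#' Simulate beta-value and detection-p matrices
#'
#' Null probes draw a per-probe baseline from a two-component Beta mixture
#' (unmethylated mode `Beta(2,10)`, methylated mode `Beta(10,2)`, 60/40 mix);
#' planted probes/regions are shifted by their stated delta-beta in cases on
#' the beta scale and clipped to `(0.001, 0.999)`. Sample-level noise is
#' added on the M scale with standard deviation `noise_sd`, so `noise_sd = 0`
#' reproduces the planted group difference exactly.
#'
#' @param manifest Output of [sim_manifest()].
#' @param sheet Output of [sim_sample_sheet()].
#' @param dms_probes,dmr_regions Planted truth as in [synthetic_truth()].
#' @param noise_sd Per-sample noise SD in M units.
#' @param fail_frac Fraction of detection-p entries simulated as failures
#'   (detection p drawn above 0.05).
#' @param seed Integer RNG seed.
#' @return A list with tibbles `beta` and `detp` (probe id + one column per
#'   sample).
#' @export
sim_methylation <- function(manifest, sheet, dms_probes = NULL,
                            dmr_regions = NULL, noise_sd = 0.15,
                            fail_frac = 0.001, seed = 1) {
  check_sheet(sheet)
  planted <- planted_probe_table(manifest, dms_probes, dmr_regions)
  with_seed(seed, {
    np <- nrow(manifest); ns <- nrow(sheet)
    mode_methylated <- runif(np) < 0.4
    base <- ifelse(mode_methylated, rbeta(np, 10, 2), rbeta(np, 2, 10))
    # planted probes get headroom so the full shift survives clipping
    idx <- match(planted$probe_id, manifest$probe_id)
    if (length(idx)) {
      up <- planted$delta_beta > 0
      base[idx[up]]  <- runif(sum(up), 0.25, 0.55)
      base[idx[!up]] <- runif(sum(!up), 0.45, 0.75)
    }
    target <- matrix(base, np, ns)
    case_cols <- which(sheet$group == "case")
    if (length(idx)) {
      target[idx, case_cols] <- target[idx, case_cols] + planted$delta_beta
    }
    target <- pmin(pmax(target, 0.001), 0.999)
    m <- log2(target / (1 - target)) +
      matrix(rnorm(np * ns, sd = noise_sd), np, ns)
    beta <- 1 / (1 + 2^(-m))
    dimnames(beta) <- list(manifest$probe_id, sheet$sample_id)
    detp <- matrix(runif(np * ns, 0, 0.01), np, ns,
                   dimnames = dimnames(beta))
    fail <- runif(np * ns) < fail_frac
    detp[fail] <- runif(sum(fail), 0.06, 1)
    list(beta = as_value_tbl(beta), detp = as_value_tbl(detp))
  })
}

planted_probe_table <- function(manifest, dms_probes, dmr_regions) {
  out <- tibble(probe_id = character(), delta_beta = double())
  if (!is.null(dms_probes) && nrow(dms_probes)) {
    if (!all(dms_probes$probe_id %in% manifest$probe_id)) {
      abort("planted probe not in manifest", class = "invalid_argument")
    }
    out <- bind_rows(out, dms_probes[, c("probe_id", "delta_beta")])
  }
  if (!is.null(dmr_regions) && nrow(dmr_regions)) {
    for (i in seq_len(nrow(dmr_regions))) {
      r <- dmr_regions[i, ]
      hit <- manifest$chrom == r$chrom &
        manifest$pos >= r$start & manifest$pos < r$end
      if (!any(hit)) {
        abort("planted region outside manifest", class = "invalid_argument")
      }
      out <- bind_rows(out, tibble(probe_id = manifest$probe_id[hit],
                                   delta_beta = r$delta_beta))
    }
  }
  distinct(out, .data$probe_id, .keep_all = TRUE)
}

#' Simulate a confidence-scored PPI edge table
#'
#' Background edges appear independently with probability `edge_prob`
#' (confidence uniform on `[0.4, 1]`); edges internal to the planted module
#' appear with probability `module_density` and confidence `>= 0.7`.
#'
#' @param genes Character vector of node names (must be unique).
#' @param edge_prob Background edge probability.
#' @param planted_module Subset of `genes` forming the planted dense module.
#' @param module_density Probability of each internal module edge.
#' @param seed Integer RNG seed.
#' @return A tibble `gene_a`, `gene_b`, `confidence` (undirected, simple).
#' @export
sim_ppi <- function(genes, edge_prob = 0.03, planted_module = character(),
                    module_density = 1, seed = 1) {
  if (anyDuplicated(genes)) abort("duplicate gene names",
                                  class = "invalid_argument")
  stopifnot(all(planted_module %in% genes))
  with_seed(seed, {
    n <- length(genes)
    pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
    a <- genes[pairs[, 1]]; b <- genes[pairs[, 2]]
    internal <- a %in% planted_module & b %in% planted_module
    keep_bg <- !internal & runif(length(a)) < edge_prob
    keep_mod <- internal & runif(length(a)) < module_density
    edges <- tibble(
      gene_a = c(a[keep_bg], a[keep_mod]),
      gene_b = c(b[keep_bg], b[keep_mod]),
      confidence = c(runif(sum(keep_bg), 0.4, 1),
                     runif(sum(keep_mod), 0.7, 1))
    )
    arrange(edges, .data$gene_a, .data$gene_b)
  })
}

#' Simulate a linear epigenetic clock consistent with sample ages
#'
#' Returns a [clock_model()] whose probes are drawn from the manifest, with
#' positive weights summing to `weight_total` and a fixed intercept chosen so
#' that the planting rule of [plant_clock_signal()] keeps betas inside
#' `(0, 1)` for ages up to 120 years.
#'
#' @param manifest Output of [sim_manifest()].
#' @param n_clock_probes Number of clock probes (<= rows of manifest).
#' @param adult_age Calibration knot of the age transform, years.
#' @param weight_total Sum of the positive coefficients.
#' @param seed Integer RNG seed.
#' @return A `clock_model`.
#' @export
sim_clock <- function(manifest, n_clock_probes = 30, adult_age = 20,
                      weight_total = 10, seed = 1) {
  stopifnot(n_clock_probes >= 1, n_clock_probes <= nrow(manifest))
  with_seed(seed, {
    probes <- sample(manifest$probe_id, n_clock_probes)
    w <- runif(n_clock_probes, 0.5, 1.5)
    w <- w / sum(w) * weight_total
    clock_model(intercept = -4, coefficients = setNames(w, probes),
                adult_age = adult_age)
  })
}

#' Overwrite clock-probe betas so DNAm age equals chronological age
#'
#' Companion rule to [sim_clock()]: all clock probes of sample *s* are set to
#' `(F(age_s) - intercept) / sum(w)` (optionally plus M-scale noise), so the
#' linear predictor equals the transformed chronological age and
#' [predict_age()] recovers `age_s` exactly at `noise_sd = 0`.
#'
#' @param beta Beta tibble/matrix containing the clock probes.
#' @param model A `clock_model` with nonzero coefficient sum.
#' @param sheet Sample sheet with `age`.
#' @param noise_sd Optional beta-scale noise SD.
#' @param seed Seed used when `noise_sd > 0`.
#' @return The beta table with clock-probe rows replaced.
#' @export
plant_clock_signal <- function(beta, model, sheet, noise_sd = 0, seed = 1) {
  check_sheet(sheet, require_groups = FALSE)
  w <- model$coefficients
  if (abs(sum(w)) < 1e-12) abort("clock coefficient sum must be nonzero")
  b <- as_value_matrix(beta)
  if (!all(names(w) %in% rownames(b))) abort("clock probes missing from beta")
  ages <- setNames(sheet$age, sheet$sample_id)[colnames(b)]
  target <- (age_to_clock_scale(ages, model$adult_age) - model$intercept) / sum(w)
  vals <- matrix(rep(target, each = length(w)), nrow = length(w))
  if (noise_sd > 0) {
    vals <- with_seed(seed, vals + rnorm(length(vals), sd = noise_sd))
  }
  b[names(w), ] <- pmin(pmax(vals, 1e-4), 1 - 1e-4)
  if (is.matrix(beta)) b else as_value_tbl(b)
}

#' Simulate an RNA-seq count matrix with planted DEGs
#'
#' Counts are negative binomial with gene-level dispersion and log-normal
#' library size factors; case means are scaled by `2^lfc` at planted genes.
#'
#' @param genes Character vector of gene ids.
#' @param sheet Sample sheet.
#' @param planted_lfc Named numeric vector gene -> log2 fold change.
#' @param base_mean_log Mean of `log(base mean)` for the expression draw.
#' @param dispersion NB dispersion (>= 0; 0 gives Poisson counts).
#' @param lib_size_sd SD of log library size factors.
#' @param seed Integer RNG seed.
#' @return A count tibble (`gene_id` + samples) with attribute `lib_sizes`
#'   equal to the column sums.
#' @export
sim_expression <- function(genes, sheet, planted_lfc = numeric(),
                           base_mean_log = log(100), dispersion = 0.1,
                           lib_size_sd = 0.15, seed = 1) {
  check_sheet(sheet)
  if (dispersion < 0) abort("negative dispersion", class = "invalid_argument")
  if (!all(names(planted_lfc) %in% genes)) {
    abort("planted genes must be a subset of `genes`", class = "invalid_argument")
  }
  with_seed(seed, {
    ng <- length(genes); ns <- nrow(sheet)
    base <- rlnorm(ng, base_mean_log, 1)
    lfc <- setNames(rep(0, ng), genes)
    lfc[names(planted_lfc)] <- planted_lfc
    sf <- rlnorm(ns, 0, lib_size_sd)
    mu <- outer(base, sf)
    case_cols <- which(sheet$group == "case")
    mu[, case_cols] <- mu[, case_cols] * 2^lfc
    counts <- if (dispersion == 0) {
      matrix(stats::rpois(ng * ns, mu), ng, ns)
    } else {
      matrix(rnbinom(ng * ns, mu = mu, size = 1 / dispersion), ng, ns)
    }
    dimnames(counts) <- list(genes, sheet$sample_id)
    out <- as_value_tbl(counts, id_col = "gene_id")
    attr(out, "lib_sizes") <- colSums(counts)
    out
  })
}

#' Simulate TF binding-cluster intervals and a TF-target table
#'
#' A configurable fraction of the planted DMRs receive an overlapping
#' binding cluster (BED-style 0-based half-open); the TFs owning those
#' clusters are connected to a configurable subset of the DEG list with
#' interaction modes drawn from `modes`.
#'
#' @param dmr_regions Planted regions (`chrom`, `start`, `end`, 1-based
#'   half-open).
#' @param tf_names Candidate TF names (non-empty).
#' @param deg_genes DEG gene ids available as targets.
#' @param overlap_fraction Fraction of DMRs that must overlap a cluster.
#' @param target_fraction Fraction of `deg_genes` wired to each covered TF.
#' @param modes Interaction modes to draw from.
#' @param n_decoy Decoy clusters placed far from any DMR.
#' @param seed Integer RNG seed.
#' @return List with `clusters` (`chrom`, `start`, `end`, `tf`; 0-based
#'   half-open) and `targets` (`tf`, `target`, `mode`).
#' @export
sim_tf_resources <- function(dmr_regions, tf_names, deg_genes,
                             overlap_fraction = 1, target_fraction = 0.5,
                             modes = c("activation", "repression", "unknown"),
                             n_decoy = 5, seed = 1) {
  if (!length(tf_names)) abort("empty tf_names", class = "invalid_argument")
  stopifnot(all(modes %in% c("activation", "repression", "unknown")))
  with_seed(seed, {
    n <- if (is.null(dmr_regions)) 0L else nrow(dmr_regions)
    covered <- if (n) sort(sample.int(n, round(overlap_fraction * n))) else integer()
    clusters <- tibble(chrom = character(), start = integer(),
                       end = integer(), tf = character())
    if (length(covered)) {
      r <- dmr_regions[covered, ]
      clusters <- tibble(
        chrom = r$chrom,
        start = as.integer(r$start - 1),     # 1-based half-open -> BED
        end = as.integer(r$end - 1),
        tf = sample(tf_names, length(covered), replace = TRUE)
      )
    }
    if (n_decoy > 0) {
      base <- if (n) max(dmr_regions$end) + 1e6 else 1e6
      clusters <- bind_rows(clusters, tibble(
        chrom = rep("chr1", n_decoy),
        start = as.integer(base + (seq_len(n_decoy) - 1) * 5000),
        end = as.integer(base + (seq_len(n_decoy) - 1) * 5000 + 400),
        tf = sample(tf_names, n_decoy, replace = TRUE)
      ))
    }
    tfs <- unique(clusters$tf[seq_along(covered)])
    targets <- tibble(tf = character(), target = character(), mode = character())
    if (length(tfs) && length(deg_genes)) {
      k <- max(1, ceiling(target_fraction * length(deg_genes)))
      targets <- purrr::map_dfr(tfs, function(tf) {
        tibble(tf = tf,
               target = sample(deg_genes, min(k, length(deg_genes))),
               mode = sample(modes, min(k, length(deg_genes)), replace = TRUE))
      })
    }
    list(clusters = clusters, targets = targets)
  })
}

#' Check that planted truth resolves against the generated resources
#'
#' @param truth A [synthetic_truth()].
#' @param manifest,ppi,counts Generated resources (any may be `NULL` to skip).
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_truth <- function(truth, manifest = NULL, ppi = NULL, counts = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!is.null(manifest)) {
    if (!is.null(truth$dms_probes) &&
        !all(truth$dms_probes$probe_id %in% manifest$probe_id)) {
      abort("truth DMS probe missing from manifest")
    }
    if (!is.null(truth$dmr_regions)) {
      planted_probe_table(manifest, NULL, truth$dmr_regions)
    }
    if (!is.null(truth$clock) &&
        !all(names(truth$clock$coefficients) %in% manifest$probe_id)) {
      abort("truth clock probe missing from manifest")
    }
  }
  if (!is.null(ppi)) {
    nodes <- union(ppi$gene_a, ppi$gene_b)
    if (!all(truth$module_genes %in% nodes)) {
      abort("truth module gene missing from PPI graph")
    }
  }
  if (!is.null(counts) && length(truth$deg_genes) &&
      !all(names(truth$deg_genes) %in% value_ids(counts))) {
    abort("truth DEG missing from count matrix")
  }
  invisible(TRUE)
}

#' Simulate a complete synthetic study bundle
#'
#' Generates every input the pipeline consumes (manifest, sample sheet, beta
#' and detection-p matrices with planted DMRs, PPI graph with one planted
#' dense module, planted linear clock, NB counts with planted DEGs, TF
#' binding clusters and TF-target table) plus the [synthetic_truth()] object.
#'
#' @param n_probes,n_chrom,mean_spacing Manifest dimensions.
#' @param n_case,n_control Cohort sizes.
#' @param n_dmrs Planted regions (each `dmr_probes` adjacent probes).
#' @param dmr_probes,dmr_delta_beta Probes per planted region and their
#'   beta-scale shift.
#' @param noise_sd Methylation noise SD (M units).
#' @param n_module_genes Planted PPI module size; the module genes also
#'   carry differentially methylated probes (shift `module_delta_beta`) so
#'   the module is recoverable from the methylation data.
#' @param module_delta_beta Beta-scale shift at module-gene probes.
#' @param n_genes Gene universe shared by manifest, PPI and counts.
#' @param n_degs,deg_lfc Planted DEGs and their |log2 FC|; a few DEGs are
#'   drawn from the module genes so the integrated network has
#'   multi-source nodes.
#' @param edge_prob Background PPI edge probability.
#' @param seed Integer RNG seed.
#' @return A named list of inputs plus `truth`.
#' @export
simulate_study <- function(n_probes = 2000, n_chrom = 2, mean_spacing = 500,
                           n_case = 8, n_control = 8, n_dmrs = 2,
                           dmr_probes = 5, dmr_delta_beta = 0.2,
                           noise_sd = 0.15, n_module_genes = 6,
                           module_delta_beta = 0.25,
                           n_genes = 120, n_degs = 25, deg_lfc = 1.5,
                           edge_prob = 0.08, seed = 1) {
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1, 8))
  manifest <- sim_manifest(n_probes, n_chrom, mean_spacing,
                           n_genes = n_genes, seed = seeds[1])
  sheet <- sim_sample_sheet(n_case, n_control, seed = seeds[2])
  dmr_regions <- plant_dmr_regions(manifest, n_dmrs, dmr_probes,
                                   dmr_delta_beta, seed = seeds[3])
  genes <- sprintf("G%04d", seq_len(n_genes))
  probes_per_gene <- table(manifest$gene)
  rich <- names(probes_per_gene)[probes_per_gene >= 2]
  module_genes <- with_seed(seeds[5], sample(rich, n_module_genes))
  dms_probes <- with_seed(seeds[5], {
    purrr::map_dfr(seq_along(module_genes), function(i) {
      g <- module_genes[i]
      pr <- manifest$probe_id[!is.na(manifest$gene) & manifest$gene == g]
      tibble(probe_id = pr,
             delta_beta = module_delta_beta * ifelse(i %% 2 == 0, 1, -1))
    })
  })
  meth <- sim_methylation(manifest, sheet, dms_probes = dms_probes,
                          dmr_regions = dmr_regions,
                          noise_sd = noise_sd, seed = seeds[4])
  ppi <- sim_ppi(genes, edge_prob = edge_prob,
                 planted_module = module_genes,
                 module_density = 1, seed = seeds[5])
  clock <- sim_clock(manifest, n_clock_probes = 30, seed = seeds[6])
  meth$beta <- plant_clock_signal(meth$beta, clock, sheet)
  deg_lfcs <- with_seed(seeds[7], {
    n_mod_deg <- min(3, n_module_genes, n_degs)
    deg_names <- c(sample(module_genes, n_mod_deg),
                   sample(setdiff(genes, module_genes), n_degs - n_mod_deg))
    setNames(sample(c(-deg_lfc, deg_lfc), n_degs, replace = TRUE), deg_names)
  })
  counts <- sim_expression(genes, sheet, planted_lfc = deg_lfcs,
                           seed = seeds[7])
  tfres <- sim_tf_resources(dmr_regions, tf_names = c("REST", "EGR1", "SP1",
                                                      "RELA", "YY1"),
                            deg_genes = names(deg_lfcs), seed = seeds[8])
  truth <- synthetic_truth(
    dms_probes = dms_probes, dmr_regions = dmr_regions,
    module_genes = module_genes, deg_genes = deg_lfcs,
    clock = clock, seed = seed
  )
  validate_truth(truth, manifest, ppi, counts)
  list(manifest = manifest, sheet = sheet, beta = meth$beta,
       detp = meth$detp, counts = counts, ppi = ppi, clock = clock,
       tf_clusters = tfres$clusters, tf_targets = tfres$targets,
       truth = truth)
}

#' Choose runs of adjacent probes as planted DMR regions
#'
#' @param manifest Probe manifest.
#' @param n_dmrs Number of regions.
#' @param dmr_probes Adjacent probes per region.
#' @param delta_beta Planted shift (sign alternates hyper/hypo).
#' @param max_span Maximum region span in bp (regions wider than this are
#'   not selected, keeping planted probes within one smoothing window).
#' @param seed Integer RNG seed.
#' @return Tibble `chrom`, `start`, `end` (1-based half-open), `delta_beta`.
#' @export
plant_dmr_regions <- function(manifest, n_dmrs = 2, dmr_probes = 5,
                              delta_beta = 0.2, max_span = 2000, seed = 1) {
  ok <- manifest |>
    filter(!.data$snp_associated, !.data$non_cpg, !.data$sex_chrom) |>
    arrange(.data$chrom, .data$pos)
  with_seed(seed, {
    cand <- ok |>
      group_by(.data$chrom) |>
      mutate(span = dplyr::lead(.data$pos, dmr_probes - 1) - .data$pos,
             idx = row_number(), nmax = n()) |>
      ungroup() |>
      filter(!is.na(.data$span), .data$span <= max_span)
    if (nrow(cand) < n_dmrs) abort("manifest too small for requested DMRs")
    picked <- list(); used <- tibble(chrom = character(), lo = double(), hi = double())
    rows <- sample(nrow(cand))
    for (i in rows) {
      r <- cand[i, ]
      probes <- ok |> filter(.data$chrom == r$chrom) |>
        dplyr::slice(r$idx:(r$idx + dmr_probes - 1))
      lo <- min(probes$pos) - max_span; hi <- max(probes$pos) + max_span
      clash <- any(used$chrom == r$chrom & used$lo < hi & lo < used$hi)
      if (clash) next
      used <- bind_rows(used, tibble(chrom = r$chrom, lo = lo, hi = hi))
      picked[[length(picked) + 1]] <- tibble(
        chrom = r$chrom, start = min(probes$pos),
        end = max(probes$pos) + 1L,
        delta_beta = delta_beta * ifelse(length(picked) %% 2 == 0, 1, -1))
      if (length(picked) == n_dmrs) break
    }
    if (length(picked) < n_dmrs) abort("could not place non-overlapping DMRs")
    bind_rows(picked)
  })
}
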