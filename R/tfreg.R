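# DMR-anchored transcription-factor regulatory networks: overlap DMRs with
# TF binding-cluster intervals, then join the supported TFs to their
# DEG targets with the interaction mode.

#' Annotate DMRs to TF binding clusters by interval overlap
#'
#' A DMR supports a TF when their intervals overlap by at least
#' `min_overlap` bp under half-open semantics; all multi-overlaps are
#' recorded. DMRs use 1-based half-open coordinates (as produced by
#' [call_dmrs()]); clusters use BED 0-based half-open coordinates.
#'
#' @param dmrs DMR tibble with `region_id`, `chrom`, `start`, `end`.
#' @param clusters TF cluster tibble `chrom`, `start`, `end`, `tf`
#'   (0-based half-open).
#' @param min_overlap Minimum overlap in bp (default 1).
#' @param intergenic_only Optional character vector of region ids to keep
#'   (e.g. regions with no gene annotation); `NULL` keeps all.
#' @return A tibble `tf`, `region_id`, `overlap_bp`.
#' @export
annotate_dmrs_to_tfs <- function(dmrs, clusters, min_overlap = 1,
                                 intergenic_only = NULL) {
  if (!nrow(dmrs) || !nrow(clusters)) {
    return(tibble(tf = character(), region_id = character(),
                  overlap_bp = integer()))
  }
  if (!is.null(intergenic_only)) {
    dmrs <- filter(dmrs, .data$region_id %in% intergenic_only)
  }
  check_chrom_naming(dmrs$chrom, clusters$chrom)
  # common 0-based half-open coordinates
  d <- dmrs |>
    transmute_region(start0 = .data$start - 1L, end0 = .data$end - 1L)
  cl <- clusters |>
    mutate(start0 = .data$start, end0 = .data$end)
  joined <- inner_join(d, cl[, c("chrom", "start0", "end0", "tf")],
                       by = "chrom", relationship = "many-to-many",
                       suffix = c("_dmr", "_tf"))
  joined |>
    mutate(overlap_bp = pmin(.data$end0_dmr, .data$end0_tf) -
             pmax(.data$start0_dmr, .data$start0_tf)) |>
    filter(.data$overlap_bp >= min_overlap) |>
    select("tf", "region_id", "overlap_bp") |>
    arrange(.data$tf, .data$region_id)
}

transmute_region <- function(dmrs, ...) {
  dmrs |>
    mutate(...) |>
    select("region_id", "chrom", "start0", "end0")
}

check_chrom_naming <- function(a, b) {
  if (!length(intersect(unique(a), unique(b)))) {
    pa <- any(grepl("^chr", a)); pb <- any(grepl("^chr", b))
    if (pa != pb) {
      abort(paste("chromosome naming mismatch ('chr1' vs '1'):",
                  "harmonise the prefix before annotating"),
            class = "naming_mismatch")
    }
  }
  invisible(TRUE)
}

#' Build the TF -> DEG regulatory network
#'
#' Keeps the TF-target rows whose TF has DMR support and whose target is in
#' the DEG list, typed by interaction mode (activation / repression /
#' unknown) and carrying the target's regulation direction. TFs with DMR
#' support but no DEG target are listed in the `unconnected_tfs` attribute.
#'
#' @param tf_support Output of [annotate_dmrs_to_tfs()].
#' @param tf_targets Tibble `tf`, `target`, `mode` (modes case-insensitive).
#' @param degs DEG tibble with `gene` and `direction` columns
#'   (e.g. [deg_export()] output).
#' @return An object of class `regulatory_network`: a tibble with `tf`,
#'   `target`, `mode`, `target_direction`, `supporting_dmrs` (list-column).
#' @export
build_regulatory_network <- function(tf_support, tf_targets, degs) {
  modes <- tolower(tf_targets$mode)
  modes[!modes %in% c("activation", "repression")] <- "unknown"
  tf_targets$mode <- modes
  support <- tf_support |>
    group_by(.data$tf) |>
    summarise(supporting_dmrs = list(unique(.data$region_id)),
              .groups = "drop")
  edges <- tf_targets |>
    distinct(.data$tf, .data$target, .data$mode) |>
    inner_join(support, by = "tf") |>
    inner_join(degs[, c("gene", "direction")],
               by = c(target = "gene")) |>
    rename(target_direction = "direction") |>
    select("tf", "target", "mode", "target_direction", "supporting_dmrs") |>
    arrange(.data$tf, .data$target)
  unconnected <- setdiff(support$tf, edges$tf)
  structure(edges, class = c("regulatory_network", class(edges)),
            unconnected_tfs = unconnected)
}

#' @export
glance.regulatory_network <- function(x, ...) {
  tibble(n_tfs = length(unique(x$tf)),
         n_targets = length(unique(x$target)),
         n_edges = nrow(x),
         n_unconnected_tfs = length(attr(x, "unconnected_tfs")))
}

#' @export
tidy.regulatory_network <- function(x, ...) {
  as_tibble(x) |>
    mutate(supporting_dmrs = map_chr(.data$supporting_dmrs, paste,
                                     collapse = ";"))
}
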