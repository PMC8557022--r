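# Plain-text readers and writers for the formats the pipeline consumes:
# feature-by-sample TSV matrices, manifest/sample-sheet/edge-table TSVs,
# BED6 intervals, GMT gene sets, and JSON truth/QC/manifest records.

#' Read / write a feature-by-sample value table (TSV)
#'
#' First column is the feature id; remaining columns are samples.
#'
#' @param path File path.
#' @param id_col Name for the id column on read.
#' @return A tibble (read) or `path` invisibly (write).
#' @export
read_value_tsv <- function(path, id_col = "probe_id") {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  names(d)[1] <- id_col
  d
}

#' @rdname read_value_tsv
#' @param x Value tibble/matrix.
#' @export
write_value_tsv <- function(x, path) {
  if (is.matrix(x)) x <- as_value_tbl(x)
  readr::write_tsv(x, path)
  invisible(path)
}

#' Read / write a tibble as TSV
#'
#' @param path File path.
#' @return A tibble (read) or `path` invisibly (write).
#' @export
read_table_tsv <- function(path) readr::read_tsv(path, show_col_types = FALSE)

#' @rdname read_table_tsv
#' @param x A data frame; list-columns are collapsed with `";"`.
#' @export
write_table_tsv <- function(x, path) {
  flat <- x
  for (nm in names(flat)) {
    if (is.list(flat[[nm]])) {
      flat[[nm]] <- map_chr(flat[[nm]], paste, collapse = ";")
    }
  }
  readr::write_tsv(flat, path)
  invisible(path)
}

#' Write DMRs as BED6
#'
#' Coordinates convert from 1-based half-open to BED's 0-based half-open;
#' name is the region direction, score is `-log10(fdr)` capped at 1000.
#'
#' @param dmrs Output of [call_dmrs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  bed <- tibble(
    chrom = dmrs$chrom,
    start = dmrs$start - 1L,
    end = dmrs$end - 1L,
    name = dmrs$direction,
    score = round(pmin(1000, -log10(pmax(dmrs$fdr, 1e-300))), 3),
    strand = "."
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Read TF binding clusters from BED
#'
#' Expects at least chrom/start/end/name columns (0-based half-open); the
#' name column is the TF.
#'
#' @param path BED file path.
#' @return A tibble `chrom`, `start`, `end`, `tf`.
#' @export
read_tf_bed <- function(path) {
  d <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  stopifnot(ncol(d) >= 4)
  tibble(chrom = as.character(d[[1]]), start = as.integer(d[[2]]),
         end = as.integer(d[[3]]), tf = as.character(d[[4]]))
}

#' Read / write gene sets in GMT format
#'
#' @param path GMT file path (name, description, genes..., tab-separated).
#' @return A named list of character vectors (read).
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  setNames(lapply(parts, function(x) unique(x[-(1:2)])),
           vapply(parts, `[`, character(1), 1))
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}
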