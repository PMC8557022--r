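#' @importFrom rlang abort %||% .data
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   across left_join inner_join anti_join bind_rows bind_cols rename n
#'   row_number distinct pull if_else first desc
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_dbl map_int map_chr map_lgl map2 pmap imap keep
#' @importFrom stats pt qt quantile rnorm runif rbinom rbeta rnbinom rlnorm
#'   setNames lm resid coef pchisq phyper p.adjust sd var t.test ks.test
#'   fisher.test model.matrix dhyper complete.cases median
#' @importFrom utils head tail combn
#' @keywords internal
"_PACKAGE"

# Value tables (beta, M, detection p, counts) are carried as tibbles whose
# first column is the feature id and remaining columns are samples; the
# numeric work happens on matrices via these two coercions.

#' Convert a feature-by-sample tibble to a numeric matrix
#'
#' @param x A tibble whose first column holds feature ids and remaining
#'   columns one sample each, or a numeric matrix with rownames (returned
#'   unchanged).
#' @return A numeric matrix with feature rownames and sample colnames.
#' @export
as_value_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  stopifnot(is.data.frame(x), ncol(x) >= 2)
  ids <- as.character(x[[1]])
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Convert a numeric matrix back to the id-first-column tibble form
#'
#' @param m Numeric matrix with rownames.
#' @param id_col Name for the id column.
#' @return A tibble.
#' @export
as_value_tbl <- function(m, id_col = "probe_id") {
  out <- as_tibble(m, .name_repair = "minimal")
  out <- bind_cols(tibble(!!id_col := rownames(m)), out)
  out
}

value_ids <- function(x) if (is.matrix(x)) rownames(x) else as.character(x[[1]])

sample_ids <- function(x) if (is.matrix(x)) colnames(x) else names(x)[-1]

# Deterministic local RNG: every generator is a pure function of (args, seed).
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

check_sheet <- function(sheet, require_groups = TRUE) {
  stopifnot(is.data.frame(sheet))
  if (!all(c("sample_id", "group") %in% names(sheet))) {
    abort("sample sheet needs `sample_id` and `group` columns")
  }
  if (anyDuplicated(sheet$sample_id)) abort("sample ids must be unique")
  if (!all(sheet$group %in% c("case", "control"))) {
    abort("`group` must be 'case' or 'control'")
  }
  if (require_groups && length(unique(sheet$group)) < 2) {
    abort("both groups must be non-empty")
  }
  invisible(sheet)
}

group_indices <- function(sheet, samples) {
  grp <- setNames(sheet$group, sheet$sample_id)[samples]
  if (anyNA(grp)) abort("samples missing from sample sheet")
  list(case = which(grp == "case"), control = which(grp == "control"))
}
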