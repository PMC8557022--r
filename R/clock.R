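# Horvath-style epigenetic clock: a weighted linear predictor on beta
# values mapped through a calibrated age transform, plus age-acceleration
# statistics. Clock coefficients are supplied by file or generator; no
# published coefficient set is bundled.

#' Construct an epigenetic clock model
#'
#' @param intercept Intercept of the linear predictor.
#' @param coefficients Named numeric vector, probe id -> weight (>= 1 entry).
#' @param adult_age Calibration knot of the age transform, years (> 0).
#' @return An object of class `clock_model`.
#' @export
clock_model <- function(intercept, coefficients, adult_age = 20) {
  stopifnot(length(coefficients) >= 1, !is.null(names(coefficients)),
            adult_age > 0)
  structure(list(intercept = unname(intercept),
                 coefficients = coefficients,
                 adult_age = adult_age),
            class = "clock_model")
}

#' Calibrated age transform and its inverse
#'
#' `age_to_clock_scale` maps chronological age to the clock's linear scale:
#' `log(age + 1) - log(adult_age + 1)` below `adult_age` and
#' `(age - adult_age) / (adult_age + 1)` above it (continuous and
#' differentiable at the knot). `clock_scale_to_age` is the exact inverse.
#'
#' @param age Ages in years.
#' @param adult_age Calibration knot, years.
#' @return Transformed values (or ages for the inverse).
#' @export
age_to_clock_scale <- function(age, adult_age = 20) {
  ifelse(age <= adult_age,
         log(age + 1) - log(adult_age + 1),
         (age - adult_age) / (adult_age + 1))
}

#' @rdname age_to_clock_scale
#' @param x Values on the clock's linear scale.
#' @export
clock_scale_to_age <- function(x, adult_age = 20) {
  ifelse(x < 0, (adult_age + 1) * exp(x) - 1, (adult_age + 1) * x + adult_age)
}

#' Predict DNA methylation age
#'
#' Computes the linear predictor `intercept + sum(w_i * beta_i)` per sample
#' and maps it to years with the inverse age transform.
#'
#' @param beta Beta tibble/matrix containing the clock probes as rows.
#' @param model A [clock_model()].
#' @param missing Policy for clock probes absent from `beta`: `"error"`
#'   (default) or `"mean_impute"` (impute the mean beta of the available
#'   clock probes per sample).
#' @return A tibble `sample_id`, `dnam_age`.
#' @export
predict_age <- function(beta, model, missing = c("error", "mean_impute")) {
  missing <- match.arg(missing)
  stopifnot(inherits(model, "clock_model"))
  b <- as_value_matrix(beta)
  w <- model$coefficients
  absent <- setdiff(names(w), rownames(b))
  if (length(absent)) {
    if (missing == "error") {
      abort(paste0("clock probes missing from beta: ",
                   paste(absent, collapse = ", ")),
            class = "missing_probe")
    }
    present <- intersect(names(w), rownames(b))
    if (!length(present)) abort("no clock probes present",
                                class = "missing_probe")
    fill <- matrix(rep(colMeans(b[present, , drop = FALSE]),
                       each = length(absent)),
                   nrow = length(absent), dimnames = list(absent, colnames(b)))
    b <- rbind(b, fill)
  }
  x <- model$intercept + drop(crossprod(b[names(w), , drop = FALSE], w))
  tibble(sample_id = colnames(b),
         dnam_age = unname(clock_scale_to_age(x, model$adult_age)))
}

#' Age acceleration as difference and as residual
#'
#' `aa_diff` is DNAm age minus chronological age; `aa_residual` is the
#' residual of the OLS regression of DNAm age on chronological age over the
#' cohort supplied (one fit per call, so residuals are mean-zero within
#' that cohort). With fewer than 3 samples the residual fit is skipped and
#' `aa_residual` is `NA`.
#'
#' @param pred Output of [predict_age()], or a tibble with `sample_id` and
#'   `dnam_age`.
#' @param sheet Sample sheet with `sample_id` and `age`.
#' @return A tibble `sample_id`, `dnam_age`, `chrono_age`, `aa_diff`,
#'   `aa_residual`.
#' @export
age_acceleration <- function(pred, sheet) {
  stopifnot(all(c("sample_id", "dnam_age") %in% names(pred)),
            all(c("sample_id", "age") %in% names(sheet)))
  out <- pred |>
    inner_join(sheet[, c("sample_id", "age")], by = "sample_id") |>
    rename(chrono_age = "age") |>
    mutate(aa_diff = .data$dnam_age - .data$chrono_age)
  if (nrow(out) >= 3) {
    fit <- lm(dnam_age ~ chrono_age, data = out)
    out$aa_residual <- unname(resid(fit))
  } else {
    out$aa_residual <- NA_real_
  }
  out
}

#' Compare age acceleration between groups
#'
#' Per-group means/SDs and Welch two-sided t-tests on `aa_diff` and
#' `aa_residual`.
#'
#' @param aa Output of [age_acceleration()].
#' @param sheet Sample sheet with `group`.
#' @return A tibble, one row per measure, with group summaries and `p`.
#' @export
compare_groups_aa <- function(aa, sheet) {
  check_sheet(sheet)
  d <- inner_join(aa, sheet[, c("sample_id", "group")], by = "sample_id")
  if (length(unique(d$group)) < 2 || min(table(d$group)) < 2) {
    abort("both groups need >= 2 samples", class = "invalid_argument")
  }
  purrr::map_dfr(c("aa_diff", "aa_residual"), function(measure) {
    x <- d[[measure]][d$group == "case"]
    y <- d[[measure]][d$group == "control"]
    # numerically degenerate groups (e.g. residuals that are pure float
    # fuzz) are reported as p = 1 rather than a t-test on rounding noise
    tol <- 1e-10 * max(1, abs(mean(c(x, y))))
    p <- if (sd(x) < tol && sd(y) < tol) {
      if (abs(mean(x) - mean(y)) < tol) 1 else 0
    } else t.test(x, y)$p.value
    tibble(measure = measure,
           mean_case = mean(x), sd_case = sd(x),
           mean_control = mean(y), sd_control = sd(y), p = p)
  })
}

#' Read a clock coefficient file
#'
#' CSV with columns `probe_id`, `weight`; the intercept is the row whose
#' `probe_id` is `"(Intercept)"`.
#'
#' @param path File path.
#' @param adult_age Calibration knot, years.
#' @return A [clock_model()].
#' @export
read_clock_csv <- function(path, adult_age = 20) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("probe_id", "weight") %in% names(d)))
  ic <- d$probe_id == "(Intercept)"
  if (sum(ic) != 1) abort("clock file needs exactly one (Intercept) row")
  clock_model(d$weight[ic],
              setNames(d$weight[!ic], d$probe_id[!ic]), adult_age)
}

#' Write a clock coefficient file
#'
#' @param model A [clock_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clock_csv <- function(model, path) {
  readr::write_csv(tibble(
    probe_id = c("(Intercept)", names(model$coefficients)),
    weight = c(model$intercept, unname(model$coefficients))), path)
  invisible(path)
}

#' @export
tidy.clock_model <- function(x, ...) {
  tibble(term = c("(Intercept)", names(x$coefficients)),
         estimate = c(x$intercept, unname(x$coefficients)))
}

#' @export
glance.clock_model <- function(x, ...) {
  tibble(n_probes = length(x$coefficients), adult_age = x$adult_age)
}

#' @export
print.clock_model <- function(x, ...) {
  cat("<clock_model> ", length(x$coefficients), " probes, adult_age = ",
      x$adult_age, "\n", sep = "")
  invisible(x)
}
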