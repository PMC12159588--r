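#' Ordinary least-squares fit of ROM on pelvic tilt
#'
#' Simple linear regression of a limiting ROM (degrees) on pelvic tilt
#' (degrees) via `stats::lm`. Reports the slope (deg/deg), intercept (deg),
#' coefficient of determination `R^2 = 1 - SSE/SST` and the root mean
#' squared error `sqrt(SSE/n)` (denominator `n`, configurable to `n - 2`).
#'
#' @param pt numeric vector of tilt values (degrees).
#' @param rom numeric vector of ROM values (degrees), same length.
#' @param rmse_denom `"n"` (default) or `"n-2"`.
#' @return an object of class `rom_pt_fit` with `slope`, `intercept`,
#'   `r_squared`, `rmse`, `n`.
#' @export
fit_linear_rom_pt <- function(pt, rom, rmse_denom = c("n", "n-2")) {
  rmse_denom <- match.arg(rmse_denom)
  stopifnot(length(pt) == length(rom))
  n <- length(pt)
  if (n < 3L) stop("at least 3 observations are required")
  if (stats::sd(pt) == 0) stop("pelvic tilt is constant; slope is undefined")
  fit <- stats::lm(rom ~ pt)
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((rom - mean(rom))^2)
  r2 <- if (sst == 0) 0 else 1 - sse / sst
  denom <- if (rmse_denom == "n") n else n - 2L
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 rmse = sqrt(sse / denom),
                 n = n),
            class = "rom_pt_fit")
}

#' @export
print.rom_pt_fit <- function(x, ...) {
  cat(sprintf("<rom_pt_fit: ROM = %.3f + %.3f * PT; R2 = %.3f, RMSE = %.2f deg, n = %d>\n",
              x$intercept, x$slope, x$r_squared, x$rmse, x$n))
  invisible(x)
}

#' Pelvic tilt at which a fitted ROM line crosses a benchmark
#'
#' Solves `benchmark = intercept + slope * PT` for PT. Used with the
#' activities-of-daily-living reference values (110 degrees flexion, 30
#' degrees internal rotation at 90 degrees flexion, 30 extension, 45
#' external rotation, 50 abduction, 30 adduction).
#'
#' @param fit a [fit_linear_rom_pt()] result (or any list with `slope` and
#'   `intercept`).
#' @param benchmark_deg ROM benchmark (degrees).
#' @return tilt in degrees at the crossing.
#' @export
#' @examples
#' benchmark_crossing_pt(list(slope = -1, intercept = 118.1), 110) # 8.1
benchmark_crossing_pt <- function(fit, benchmark_deg) {
  if (fit$slope == 0) stop("slope is zero; the fitted line never crosses")
  (benchmark_deg - fit$intercept) / fit$slope
}

#' Clinical-relevance category of a ROM change
#'
#' Absolute ROM differences below 10 degrees are `low`, from 10 to 20
#' degrees (closed interval) `medium`, and above 20 degrees `high`.
#'
#' @param delta_deg numeric vector of ROM differences (degrees).
#' @return factor with levels `low`, `medium`, `high`.
#' @export
delta_rom_category <- function(delta_deg) {
  stopifnot(all(is.finite(delta_deg)))
  a <- abs(delta_deg)
  factor(ifelse(a < 10, "low", ifelse(a <= 20, "medium", "high")),
         levels = c("low", "medium", "high"))
}

#' Impingement-type shift table between two conditions
#'
#' For each motion, computes the share of patients (percent) limited by
#' each impingement type (including `NONE`) under condition `a` and under
#' condition `b`, and their difference in percentage points. Each patient
#' contributes exactly one type per motion and condition.
#'
#' @param results_a,results_b data frames with columns `patient_id`,
#'   `motion`, `impingement_type` covering the same patients and motions.
#' @return data frame with `motion`, `impingement_type`, `share_a`,
#'   `share_b` (percent) and `shift_pp` (percentage points, b minus a).
#' @export
impingement_shift <- function(results_a, results_b) {
  needed <- c("patient_id", "motion", "impingement_type")
  stopifnot(all(needed %in% names(results_a)), all(needed %in% names(results_b)))
  if (!setequal(unique(results_a$patient_id), unique(results_b$patient_id)))
    stop("the two slices cover different patient sets")
  if (!setequal(unique(results_a$motion), unique(results_b$motion)))
    stop("the two slices cover different motions")
  types <- c("ITII", "ITBI", "BTBI", "NONE")
  motions <- unique(results_a$motion)
  shares <- function(df, motion) {
    sl <- df[df$motion == motion, ]
    100 * table(factor(sl$impingement_type, levels = types)) / nrow(sl)
  }
  out <- do.call(rbind, lapply(motions, function(m) {
    sa <- shares(results_a, m)
    sb <- shares(results_b, m)
    data.frame(motion = m, impingement_type = types,
               share_a = as.numeric(sa), share_b = as.numeric(sb),
               shift_pp = as.numeric(sb - sa), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Paired t test
#'
#' Two-tailed paired t test via `stats::t.test`; degrees of freedom are
#' `n - 1`.
#'
#' @param x,y numeric vectors of equal length (n >= 2).
#' @return list with `t`, `df`, `p`, `mean_diff`, `sd_diff`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  d <- x - y
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(list(t = 0, df = length(x) - 1L, p = 1, mean_diff = 0, sd_diff = 0))
    stop("no variance in the paired differences")
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = mean(d), sd_diff = stats::sd(d))
}

#' Welch's two-sample t test
#'
#' Unequal-variance t test via `stats::t.test` with Welch-Satterthwaite
#' (generally fractional) degrees of freedom.
#'
#' @param x,y numeric vectors (each n >= 2).
#' @return list with `t`, `df`, `p`.
#' @export
welch_t <- function(x, y) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    stop("both groups have zero variance")
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Summarise a pelvic-tilt cohort
#'
#' Per-condition mean and SD of the standing pelvic tilt at the three time
#' points, pairwise differences and paired t tests.
#'
#' @param pt_table data frame with columns `StPT_0`, `StPT_6`, `StPT_12`
#'   (one row per patient).
#' @return list with `means`, `sds`, and a `comparisons` data frame
#'   (`pair`, `mean_diff`, `sd_diff`, `t`, `df`, `p`).
#' @export
summarize_pt <- function(pt_table) {
  cols <- c("StPT_0", "StPT_6", "StPT_12")
  missing <- setdiff(cols, names(pt_table))
  if (length(missing) > 0L)
    stop("missing pelvic tilt conditions: ", paste(missing, collapse = ", "))
  means <- vapply(pt_table[cols], mean, 0)
  sds <- vapply(pt_table[cols], stats::sd, 0)
  pairs <- list(c("StPT_0", "StPT_6"), c("StPT_0", "StPT_12"),
                c("StPT_6", "StPT_12"))
  comparisons <- do.call(rbind, lapply(pairs, function(p) {
    tt <- tryCatch(paired_t(pt_table[[p[1]]], pt_table[[p[2]]]),
                   error = function(e) list(t = NA_real_, df = NA_real_,
                                            p = NA_real_,
                                            mean_diff = mean(pt_table[[p[1]]] - pt_table[[p[2]]]),
                                            sd_diff = 0))
    data.frame(pair = paste(p, collapse = " - "), mean_diff = tt$mean_diff,
               sd_diff = tt$sd_diff, t = tt$t, df = tt$df, p = tt$p,
               stringsAsFactors = FALSE)
  }))
  list(means = means, sds = sds, comparisons = comparisons)
}

#' Simulate a cohort of hip models
#'
#' Runs [simulate_patient()] for every patient and stacks the results into
#' a cohort table. `pt_values` may be shared across patients (a list of
#' [pt_condition()]) or patient-specific (a function of the patient id /
#' index returning such a list).
#'
#' @param models named list of [hip_model()] objects (names are patient
#'   ids).
#' @param pt_values list of [pt_condition()]s, or a function
#'   `(patient_id)` returning one.
#' @param motions named list of [motion_spec()]s.
#' @param step sweep increment (degrees).
#' @return data frame (`patient_id`, `motion`, `pt_label`, `pt_deg`,
#'   `limit_deg`, `impingement_type`, `witness_a`, `witness_b`).
#' @export
simulate_cohort <- function(models, pt_values, motions = standard_motions(),
                            step = 0.5) {
  ids <- names(models)
  if (is.null(ids)) ids <- as.character(seq_along(models))
  out <- lapply(seq_along(models), function(i) {
    ptv <- if (is.function(pt_values)) pt_values(ids[i]) else pt_values
    res <- simulate_patient(models[[i]], ptv, motions, step)
    cbind(patient_id = ids[i], res, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
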