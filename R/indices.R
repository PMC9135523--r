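# Umbilical-artery hemodynamic indices and two-group comparison statistics.

#' Resistance index
#'
#' \eqn{RI = (S - D) / S}: the fractional drop from peak systolic to
#' end-diastolic velocity, a dimensionless measure of downstream vascular
#' resistance.  Lies in \[0, 1\] for valid inputs.
#'
#' @param s Peak systolic velocity (> 0), any velocity unit.
#' @param d End-diastolic velocity, `0 <= d <= s`.  Vectorised.
#' @return RI in \[0, 1\].
#' @examples
#' resistance_index(60, 20)
#' @export
resistance_index <- function(s, d) {
  if (any(!is.finite(s)) || any(!is.finite(d)) || any(s <= 0) || any(d < 0) || any(d > s))
    abort_ewt("need s > 0 and 0 <= d <= s", "invalid_parameter")
  (s - d) / s
}

#' Systolic/diastolic ratio
#'
#' \eqn{S/D}: peak systolic over end-diastolic velocity.  Undefined when
#' end-diastolic flow is absent (d = 0), a clinically meaningful state that
#' raises an error here rather than returning infinity.
#'
#' @inheritParams resistance_index
#' @return S/D ratio (>= 1 when `s >= d`).
#' @export
sd_ratio <- function(s, d) {
  if (any(!is.finite(s)) || any(!is.finite(d)) || any(d <= 0))
    abort_ewt("S/D is undefined for d <= 0 (absent end-diastolic flow)", "division_error")
  s / d
}

#' Pulsatility index
#'
#' \eqn{PI = (S - D) / V_{mean}}: the systolic-diastolic excursion relative
#' to the mean velocity over the cycle.  Always at least as large as RI
#' whenever \eqn{V_{mean} \le S}.
#'
#' @inheritParams resistance_index
#' @param v_mean Mean velocity over the cycle (> 0), same unit.
#' @return PI (>= 0 when `s >= d`).
#' @export
pulsatility_index <- function(s, d, v_mean) {
  if (any(!is.finite(v_mean)) || any(v_mean <= 0))
    abort_ewt("`v_mean` must be > 0", "invalid_parameter")
  if (any(!is.finite(s)) || any(!is.finite(d)) || any(s < d))
    abort_ewt("need s >= d", "invalid_parameter")
  (s - d) / v_mean
}

#' Mean volume flow through a cylindrical vessel
#'
#' \eqn{Q = V_{mean} \times \pi (d/2)^2}, unit-converted to mL/min from the
#' clinical measurement units (velocity in cm/s, inner diameter in mm).
#'
#' @param v_mean Mean velocity in cm/s (>= 0).
#' @param diameter Vessel inner diameter in mm (> 0).  Vectorised.
#' @return Volume flow in mL/min.
#' @examples
#' mean_flow(10, 10)   # ~471.24 mL/min
#' @export
mean_flow <- function(v_mean, diameter) {
  if (any(!is.finite(diameter)) || any(diameter <= 0))
    abort_ewt("`diameter` must be > 0", "invalid_parameter")
  if (any(!is.finite(v_mean)) || any(v_mean < 0))
    abort_ewt("`v_mean` must be >= 0", "invalid_parameter")
  area_cm2 <- pi * (diameter / 10 / 2)^2
  v_mean * area_cm2 * 60
}

#' Extract systolic/diastolic/mean velocities from a waveform
#'
#' Delimits cardiac cycles at systolic peaks (local velocity maxima
#' separated by at least 0.6 expected periods; the expected period comes
#' from `heart_rate_hint`, the waveform's own heart rate, or the dominant
#' spectral frequency, in that order).  Per cycle: VS is the peak velocity,
#' VD the minimum over the segment preceding the next systole, and V_mean
#' the time average.  Pooled values are per-cycle medians, robust to a
#' partial cycle at either end.
#'
#' A waveform with negligible pulsation (relative excursion below 1e-6)
#' degenerates gracefully: VS = VD = V_mean = the constant value.
#'
#' @param waveform A [velocity_waveform] spanning at least one full cycle.
#' @param heart_rate_hint Optional heart rate in beats/min guiding cycle
#'   delimitation.
#' @return A list with pooled `vs`, `vd`, `v_mean` and a `per_cycle`
#'   data.frame (`cycle`, `vs`, `vd`, `v_mean`).
#' @export
extract_sd <- function(waveform, heart_rate_hint = NA_real_) {
  if (!inherits(waveform, "velocity_waveform"))
    abort_ewt("`waveform` must be a velocity_waveform", "invalid_parameter")
  v <- waveform$velocity
  t <- waveform$time
  span <- max(v) - min(v)
  if (span <= 1e-6 * max(abs(v), .Machine$double.eps)) {
    val <- mean(v)
    return(list(vs = val, vd = val, v_mean = val,
                per_cycle = data.frame(cycle = 1L, vs = val, vd = val, v_mean = val)))
  }
  hr <- if (is.finite(heart_rate_hint)) heart_rate_hint else waveform$heart_rate
  if (is.na(hr)) {
    # dominant non-DC spectral frequency as the cycle rate
    n <- length(v)
    mag <- Mod(stats::fft(v - mean(v)))[2:floor(n / 2)]
    hr <- 60 * which.max(mag) * waveform$sample_rate / n
  }
  period <- 60 / hr
  min_sep <- 0.6 * period * waveform$sample_rate
  peaks <- local_maxima(v)
  if (length(peaks) > 1L) {
    ord <- peaks[order(-v[peaks], peaks)]
    kept <- integer(0)
    for (i in ord) if (!length(kept) || all(abs(kept - i) >= min_sep)) kept <- c(kept, i)
    peaks <- sort(kept)
  }
  if (length(peaks) < 2L)
    abort_ewt("no complete cardiac cycle detected in the waveform", "extraction_error")
  cycles <- lapply(seq_len(length(peaks) - 1L), function(i) {
    seg <- peaks[i]:peaks[i + 1L]
    data.frame(cycle = i, vs = max(v[seg]), vd = min(v[seg]),
               v_mean = mean(v[seg[-length(seg)]]))
  })
  per_cycle <- do.call(rbind, cycles)
  list(vs = stats::median(per_cycle$vs), vd = stats::median(per_cycle$vd),
       v_mean = stats::median(per_cycle$v_mean), per_cycle = per_cycle)
}

#' Full hemodynamic index set from a velocity waveform
#'
#' Runs [extract_sd()] and derives RI, PI, S/D and, when a vessel diameter
#' is supplied, the mean volume flow.
#'
#' @inheritParams extract_sd
#' @param diameter Optional vessel inner diameter in mm.
#' @param velocity_unit Unit of the waveform's velocities, `"m/s"`
#'   (converted to cm/s for the clinical indices) or `"cm/s"`.
#' @return A list with `vs`, `vd`, `v_mean` (cm/s), `ri`, `pi`,
#'   `sd_ratio`, and `mean_flow` (mL/min or `NA`).
#' @export
index_set <- function(waveform, heart_rate_hint = NA_real_, diameter = NULL,
                      velocity_unit = c("m/s", "cm/s")) {
  velocity_unit <- match.arg(velocity_unit)
  sdm <- extract_sd(waveform, heart_rate_hint)
  scale <- if (velocity_unit == "m/s") 100 else 1
  vs <- sdm$vs * scale; vd <- sdm$vd * scale; vm <- sdm$v_mean * scale
  list(vs = vs, vd = vd, v_mean = vm,
       ri = resistance_index(vs, vd),
       pi = pulsatility_index(vs, vd, vm),
       sd_ratio = if (vd > 0) sd_ratio(vs, vd) else NA_real_,
       mean_flow = if (is.null(diameter)) NA_real_ else mean_flow(vm, diameter))
}

#' Two-sample t-test from group summary statistics
#'
#' Standard independent-samples t-test computed from per-group mean, SD and
#' n: either the pooled-variance form (equal-variance assumption,
#' `df = n1 + n2 - 2`) or Welch's form with Satterthwaite degrees of
#' freedom.  Two-sided p-value; flagged significant at the 0.05 level.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1 (`n1 >= 2`,
#'   `sd1 >= 0`).
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @param variable Optional label stored in the result.
#' @return An object of class `group_comparison`: list with `variable`,
#'   `n1`, `mean1`, `sd1`, `n2`, `mean2`, `sd2`, `statistic`, `df`,
#'   `p_value`, `significant`.
#' @examples
#' t_test_from_summary(10, 2, 50, 12, 2, 50)
#' @export
t_test_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                variant = c("pooled", "welch"),
                                variable = NA_character_) {
  variant <- match.arg(variant)
  for (nm in c("n1", "n2")) check_number(get(nm), nm, lower = 2)
  for (nm in c("sd1", "sd2")) check_number(get(nm), nm, lower = 0)
  if (sd1 == 0 && sd2 == 0 && mean1 == mean2)
    abort_ewt("degenerate comparison: both groups constant and equal", "degenerate_error")
  if (variant == "pooled") {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(sd1^2 / n1 + sd2^2 / n2)
    df <- (sd1^2 / n1 + sd2^2 / n2)^2 /
      ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  }
  tstat <- if (se == 0) sign(mean1 - mean2) * Inf else (mean1 - mean2) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  structure(list(variable = variable, n1 = n1, mean1 = mean1, sd1 = sd1,
                 n2 = n2, mean2 = mean2, sd2 = sd2,
                 statistic = tstat, df = df, p_value = p,
                 significant = is.finite(p) && p < 0.05),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison>%s t = %.4g, df = %.4g, p = %.4g%s\n",
              if (is.na(x$variable)) "" else paste0(" ", x$variable, ":"),
              x$statistic, x$df, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Compare hemodynamic variables between cohort groups
#'
#' Runs an independent-samples t-test ([t_test_from_summary()], computed
#' from each group's raw values) for every requested variable of a cohort
#' table, FGR versus control.  No multiple-testing correction is applied by
#' default; `bonferroni = TRUE` multiplies p-values by the number of
#' variables.
#'
#' @param cohort A cohort `data.frame` as produced by [make_cohort()]: a
#'   `group` column with levels `"FGR"` and `"control"` plus numeric
#'   variable columns.
#' @param variables Character vector of column names to compare (default:
#'   all index columns).
#' @param variant Passed to [t_test_from_summary()].
#' @param bonferroni Apply a Bonferroni correction across `variables`
#'   (default `FALSE`).
#' @return A `data.frame` with one row per variable: group ns, means, SDs,
#'   `statistic`, `df`, `p_value`, `significant`.
#' @export
compare_cohort <- function(cohort,
                           variables = c("vs", "vd", "v_mean", "diameter",
                                         "cross_section_area", "mean_flow",
                                         "ri", "pi", "sd_ratio"),
                           variant = c("pooled", "welch"), bonferroni = FALSE) {
  variant <- match.arg(variant)
  if (!is.data.frame(cohort) || !"group" %in% names(cohort))
    abort_ewt("`cohort` must be a data.frame with a `group` column", "contract_error")
  missing_vars <- setdiff(variables, names(cohort))
  if (length(missing_vars))
    abort_ewt(paste("cohort is missing columns:", paste(missing_vars, collapse = ", ")),
              "contract_error")
  g <- as.character(cohort$group)
  if (sum(g == "FGR") < 2L || sum(g == "control") < 2L)
    abort_ewt("each group needs at least 2 subjects", "contract_error")
  rows <- lapply(variables, function(vn) {
    x1 <- cohort[[vn]][g == "FGR"]
    x2 <- cohort[[vn]][g == "control"]
    tt <- t_test_from_summary(mean(x1), stats::sd(x1), length(x1),
                              mean(x2), stats::sd(x2), length(x2),
                              variant = variant, variable = vn)
    data.frame(variable = vn,
               n_fgr = tt$n1, mean_fgr = tt$mean1, sd_fgr = tt$sd1,
               n_control = tt$n2, mean_control = tt$mean2, sd_control = tt$sd2,
               statistic = tt$statistic, df = tt$df, p_value = tt$p_value)
  })
  out <- do.call(rbind, rows)
  if (bonferroni) out$p_value <- pmin(out$p_value * length(variables), 1)
  out$significant <- out$p_value < 0.05
  out
}
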