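# Ratiometric HPTS fluorescence -> pH -> buffered total proton
# concentration, initial-rate fitting, and variant comparison.
#
# The calibration model is pH = -log10(A * B^Ratio - 1) with published
# constants A = 8.959e-8, B = 1.185 for the pH 3-9 range; the buffer
# correction adds the protons bound to monobasic phosphate,
# H_total = h + P_total * h / (Ka + h) with h = 10^-pH, Ka = 6.31e-8 and
# P_total = 0.03 M.

#' Calibration curve for the ratiometric pH model
#'
#' @param A positive prefactor (default 8.959e-8).
#' @param B base of the exponential term, > 1 (default 1.185).
#' @param fitted logical, whether the constants came from a fit.
#' @param fit_residual RMS residual of the fit in Ratio units (NA when not
#'   fitted).
#' @return object of class `calibration_curve`.
#' @export
calibration_curve <- function(A = 8.959e-8, B = 1.185, fitted = FALSE,
                              fit_residual = NA_real_) {
  stopifnot(A > 0, B > 1)
  structure(list(A = A, B = B, fitted = fitted,
                 fit_residual = fit_residual),
            class = "calibration_curve")
}

#' Fit the calibration constants from (pH, Ratio) points
#'
#' Least squares in Ratio space (the measured quantity): the model is
#' inverted to Ratio(pH) = log((10^-pH + 1) / A) / log(B) and A, B are
#' fitted by Levenberg-Marquardt, initialised at the published constants.
#'
#' @param points data.frame with columns `pH` and `ratio` (>= 4 points
#'   spanning >= 2 pH units).
#' @param start optional starting [calibration_curve()].
#' @return a fitted `calibration_curve`.
#' @export
fit_calibration <- function(points, start = calibration_curve()) {
  stopifnot(all(c("pH", "ratio") %in% names(points)))
  if (nrow(points) < 4L || diff(range(points$pH)) < 2)
    stop("fit_calibration: need >= 4 points spanning >= 2 pH units",
         call. = FALSE)
  df <- data.frame(pH = points$pH, ratio = points$ratio)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      ratio ~ log((10^(-pH) + 1) / A) / log(B),
      data = df,
      start = list(A = start$A, B = start$B),
      lower = c(1e-12, 1 + 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("fit_calibration: fit did not converge from A=", start$A,
           ", B=", start$B, " (", conditionMessage(e), ")", call. = FALSE))
  co <- stats::coef(fit)
  calibration_curve(A = unname(co["A"]), B = unname(co["B"]),
                    fitted = TRUE,
                    fit_residual = sqrt(mean(stats::resid(fit)^2)))
}

#' Convert fluorescence ratio to pH
#'
#' `pH = -log10(A * B^ratio - 1)`; defined only where `A * B^ratio > 1`
#' (the calibration floor).
#'
#' @param ratio F460/F417 excitation ratio.
#' @param calib a `calibration_curve`.
#' @return pH values.
#' @export
ratio_to_pH <- function(ratio, calib = calibration_curve()) {
  # expm1 form: A*B^ratio - 1 = expm1(ratio*log(B) + log(A)), which avoids
  # one cancellation step where A*B^ratio is barely above 1
  arg <- expm1(ratio * log(calib$B) + log(calib$A))
  if (any(arg <= 0))
    stop("ratio_to_pH: signal below the calibration floor (A*B^ratio <= 1)",
         call. = FALSE)
  -log10(arg)
}

#' Convert pH to fluorescence ratio (inverse calibration)
#'
#' @param pH pH values.
#' @inheritParams ratio_to_pH
#' @return ratio values.
#' @export
pH_to_ratio <- function(pH, calib = calibration_curve()) {
  (log1p(10^(-pH)) - log(calib$A)) / log(calib$B)
}

#' Phosphate buffer model
#'
#' @param Ka acid dissociation constant, M (default 6.31e-8, the effective
#'   phosphate pKa ~7.2 for pH 3-9).
#' @param P_total total phosphate concentration, M (default 0.03).
#' @return object of class `buffer_model`.
#' @export
buffer_model <- function(Ka = 6.31e-8, P_total = 0.03) {
  stopifnot(Ka > 0, P_total >= 0)
  structure(list(Ka = Ka, P_total = P_total), class = "buffer_model")
}

#' Total proton concentration at a given pH
#'
#' Free protons plus protons bound to monobasic phosphate:
#' `H_total = h + P_total * h / (Ka + h)` with `h = 10^-pH`.
#'
#' @param pH pH values.
#' @param buffer a `buffer_model`.
#' @return total proton concentration, M.
#' @export
total_proton <- function(pH, buffer = buffer_model()) {
  h <- 10^(-pH)
  h + buffer$P_total * h / (buffer$Ka + h)
}

#' Assemble a flux trace from time and ratio data
#'
#' @param time time points, seconds (strictly increasing).
#' @param ratio F460/F417 at each time point.
#' @param t_val valinomycin addition time, seconds.
#' @param t_cccp optional CCCP addition time, seconds.
#' @param calib a `calibration_curve`.
#' @param buffer a `buffer_model`.
#' @param label optional well/replicate label.
#' @return data.frame of class `flux_trace` with columns `time`, `ratio`,
#'   `pH`, `H_total`; attributes `t_val`, `t_cccp`, `label`.
#' @export
flux_trace <- function(time, ratio, t_val, t_cccp = NULL,
                       calib = calibration_curve(),
                       buffer = buffer_model(), label = NULL) {
  stopifnot(length(time) == length(ratio), all(diff(time) > 0))
  pH <- ratio_to_pH(ratio, calib)
  structure(data.frame(time = time, ratio = ratio, pH = pH,
                       H_total = total_proton(pH, buffer)),
            class = c("flux_trace", "data.frame"),
            t_val = t_val, t_cccp = t_cccp, label = label,
            calib = calib, buffer = buffer)
}

#' Baseline-subtracted pH trace
#'
#' `dpH(t) = pH(t) - mean pH over t < t_val` (all pre-valinomycin points).
#'
#' @param trace a `flux_trace`.
#' @return the trace with a `dpH` column added.
#' @export
delta_pH <- function(trace) {
  t_val <- attr(trace, "t_val")
  pre <- trace$time < t_val
  if (sum(pre) < 2L)
    stop("delta_pH: need >= 2 pre-valinomycin points", call. = FALSE)
  trace$dpH <- trace$pH - mean(trace$pH[pre])
  trace
}

#' Initial proton-flux rate
#'
#' Ordinary least-squares slope of total proton concentration versus time
#' over the window `(t_val, t_val + window]` seconds.
#'
#' @param trace a `flux_trace`.
#' @param window window length after valinomycin addition, seconds
#'   (default 60).
#' @return list with `rate` (M/s), `se`, `n`, `window`.
#' @export
initial_rate <- function(trace, window = 60) {
  t_val <- attr(trace, "t_val")
  sel <- trace$time > t_val & trace$time <= t_val + window
  if (sum(sel) < 3L)
    stop("initial_rate: need >= 3 points in the rate window", call. = FALSE)
  fit <- stats::lm(H_total ~ time, data = trace[sel, ])
  # suppress summary.lm's perfect-fit warning on exact synthetic traces
  sm <- suppressWarnings(summary(fit)$coefficients)
  list(rate = unname(sm["time", "Estimate"]),
       se = unname(sm["time", "Std. Error"]),
       n = sum(sel), window = window)
}

#' Compare variant flux rates: one-way ANOVA and Tukey HSD
#'
#' Fixed-effects one-way ANOVA followed by Tukey honestly-significant-
#' difference pairwise comparisons. Biological replicates are the
#' statistical units. When all values are identical (zero between- and
#' within-group variance) F is reported as 0 with p = 1.
#'
#' @param rates numeric vector of rates.
#' @param groups vector of group labels, same length.
#' @return list with `anova` (data.frame F, df_between, df_within, p) and
#'   `tukey` (data.frame comparison, diff, lwr, upr, p_adj).
#' @export
compare_rates <- function(rates, groups) {
  stopifnot(length(rates) == length(groups))
  groups <- factor(groups)
  if (nlevels(groups) < 2L)
    stop("compare_rates: need >= 2 groups", call. = FALSE)
  sizes <- table(groups)
  if (any(sizes < 2L))
    stop("compare_rates: every group needs >= 2 values (offending: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), ")",
         call. = FALSE)
  df <- data.frame(rate = rates, group = groups)
  fit <- stats::aov(rate ~ group, data = df)
  an <- summary(fit)[[1L]]
  ssb <- an["group", "Sum Sq"]
  ssw <- an["Residuals", "Sum Sq"]
  if (ssb <= .Machine$double.eps * max(1, sum(rates^2))) {
    Fv <- 0; pv <- 1
  } else {
    Fv <- an["group", "F value"]
    pv <- an["group", "Pr(>F)"]
  }
  tk <- stats::TukeyHSD(fit)$group
  tukey <- data.frame(comparison = rownames(tk),
                      diff = tk[, "diff"], lwr = tk[, "lwr"],
                      upr = tk[, "upr"], p_adj = tk[, "p adj"],
                      stringsAsFactors = FALSE)
  if (ssw <= .Machine$double.eps * max(1, sum(rates^2)) &&
      ssb <= .Machine$double.eps * max(1, sum(rates^2)))
    tukey$p_adj <- 1
  rownames(tukey) <- NULL
  list(anova = data.frame(F = Fv,
                          df_between = an["group", "Df"],
                          df_within = an["Residuals", "Df"],
                          p = pv),
       tukey = tukey)
}

#' Read a plate-reader table
#'
#' Expects columns `time_s`, `well`, `F460`, `F417`.
#'
#' @param path CSV file path.
#' @return data.frame with a `ratio` column added.
#' @export
read_plate <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "well", "F460", "F417")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_plate: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$ratio <- df$F460 / df$F417
  df
}

#' Read a plate layout table
#'
#' Expects columns `well`, `variant`, `biological_replicate`,
#' `technical_replicate`.
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_layout <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "variant", "biological_replicate",
            "technical_replicate")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_layout: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}

#' Plate to per-replicate rates
#'
#' Averages technical triplicates within each biological replicate (ratio
#' averaged point-wise before conversion), builds flux traces and fits
#' initial rates.
#'
#' @param plate plate table from [read_plate()].
#' @param layout layout table from [read_layout()].
#' @param t_val valinomycin addition time, seconds.
#' @param calib a `calibration_curve`.
#' @param buffer a `buffer_model`.
#' @param window rate window, seconds.
#' @param average_technical average technical replicates before fitting
#'   (default TRUE; FALSE fits each well separately).
#' @return data.frame with columns `variant`, `biological_replicate`,
#'   `rate`, `se`, `n_points`.
#' @export
plate_rates <- function(plate, layout, t_val,
                        calib = calibration_curve(),
                        buffer = buffer_model(), window = 60,
                        average_technical = TRUE) {
  m <- merge(plate, layout, by = "well")
  if (is.null(m$ratio)) m$ratio <- m$F460 / m$F417
  unit_cols <- if (average_technical)
    c("variant", "biological_replicate")
  else c("variant", "biological_replicate", "technical_replicate")
  m$unit <- do.call(paste, c(m[unit_cols], sep = "|"))
  out <- lapply(split(m, m$unit), function(d) {
    agg <- stats::aggregate(ratio ~ time_s, data = d, FUN = mean)
    agg <- agg[order(agg$time_s), ]
    tr <- flux_trace(agg$time_s, agg$ratio, t_val = t_val,
                     calib = calib, buffer = buffer)
    r <- initial_rate(tr, window = window)
    data.frame(variant = d$variant[1L],
               biological_replicate = d$biological_replicate[1L],
               rate = r$rate, se = r$se, n_points = r$n,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$variant, res$biological_replicate), ]
}
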