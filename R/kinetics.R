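# Unidirectional blood-to-brain transfer-constant (K_in) estimation.

kin_result <- function(kin, kin_se, v0, v0_se, n, method, extra = list()) {
  structure(
    c(list(kin = kin, kin_se = kin_se, v0 = v0, v0_se = v0_se, n = n,
           method = method,
           units = c(kin = "uL/s/g", v0 = "mL/g")), extra),
    class = "kin_fit"
  )
}

check_records <- function(records) {
  need <- c("qstar_ug_per_g", "cstar_ug_per_ml", "time_s")
  if (!all(need %in% names(records))) {
    stop("perfusion records need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  check_positive(records$qstar_ug_per_g, "qstar_ug_per_g", strict = FALSE)
  check_positive(records$cstar_ug_per_ml, "cstar_ug_per_ml")
  check_positive(records$time_s, "time_s")
  for (grp in c("tracer", "region", "inhibitor")) {
    if (grp %in% names(records) && length(unique(records[[grp]])) > 1L) {
      stop(sprintf("records mix several `%s` groups; fit each group %s",
                   grp, "separately"), call. = FALSE)
    }
  }
  invisible(records)
}

#' Fit the linear uptake model to multi-time-point perfusion records
#'
#' Ordinary least squares of the tissue distribution volume
#' `Q*/C*` (mL/g) on perfusion time T (s) over the linear portion of the
#' uptake curve. The slope is the unidirectional transfer constant, reported
#' in uL/s/g (mL/s/g x 1000); the extrapolated T = 0 intercept is the
#' vascular volume V0 in mL/g. Standard errors come from the OLS fit.
#'
#' @param records data.frame of perfusion records for a single
#'   tracer/region/inhibitor group, with columns `qstar_ug_per_g` (Q*,
#'   ug/g), `cstar_ug_per_ml` (C*, ug/mL), `time_s` (T, s).
#' @return object of class `kin_fit` with fields `kin`, `kin_se` (uL/s/g),
#'   `v0`, `v0_se` (mL/g), `n`, `r_squared`, `method = "multipoint"`, and
#'   the underlying `lm` fit.
#' @seealso [kin_single_timepoint()] for a single perfusion time,
#'   [vascular_volume()] for an impermeant-tracer V0 estimate.
#' @examples
#' rec <- generate_perfusion_series(0.12, 0.015, 50, noise_cv = 0, seed = 1)
#' fit_kin(rec)
#' @export
fit_kin <- function(records) {
  check_records(records)
  if (length(unique(records$time_s)) < 2L) {
    stop("only one distinct perfusion time; use kin_single_timepoint()",
         call. = FALSE)
  }
  d <- data.frame(
    vol = records$qstar_ug_per_g / records$cstar_ug_per_ml, # mL/g
    time = records$time_s
  )
  fit <- stats::lm(vol ~ time, data = d)
  cf <- suppressWarnings(summary(fit))$coefficients
  kin_result(
    kin = unname(cf["time", "Estimate"]) * 1000,
    kin_se = unname(cf["time", "Std. Error"]) * 1000,
    v0 = unname(cf["(Intercept)", "Estimate"]),
    v0_se = unname(cf["(Intercept)", "Std. Error"]),
    n = nrow(d), method = "multipoint",
    extra = list(r_squared = suppressWarnings(summary(fit)$r.squared), fit = fit,
                 v0_source = "intercept")
  )
}

#' Single-time-point transfer constant with vascular-volume correction
#'
#' For a perfusion time inside the linear uptake window, the transfer
#' constant follows directly from one measurement after subtracting the
#' intravascular tracer: `K_in = (Q* - V0 * C*) / (C* * T)` (mL/s/g),
#' reported in uL/s/g. With several replicate records, K_in is computed per
#' record and summarized as mean +/- SEM, matching per-animal reporting.
#' Negative estimates (tissue signal below the vascular component) are
#' returned unclamped and flagged.
#'
#' @param qstar tissue tracer quantity Q* in ug/g (vectorized over
#'   replicates).
#' @param cstar perfusate concentration C* in ug/mL (> 0).
#' @param time_s perfusion time T in s (> 0).
#' @param v0 vascular volume in mL/g (>= 0), e.g. from [vascular_volume()].
#' @return a `kin_fit` with `method = "single_timepoint"`; `kin_se` is the
#'   SEM over replicates (0 for a single record).
#' @examples
#' kin_single_timepoint(1.47, 50, 120, 0.015)  # 0.12 uL/s/g
#' @export
kin_single_timepoint <- function(qstar, cstar, time_s, v0) {
  check_positive(qstar, "qstar", strict = FALSE)
  check_positive(cstar, "cstar")
  check_positive(time_s, "time_s")
  check_positive(v0, "v0", strict = FALSE)
  per_record <- (qstar - v0 * cstar) / (cstar * time_s) * 1000 # uL/s/g
  neg <- per_record < 0
  if (any(neg)) {
    warning(sprintf("%d negative K_in estimate(s) (Q* < V0*C*); %s",
                    sum(neg), "returned unclamped and flagged"))
  }
  res <- kin_result(
    kin = mean(per_record), kin_se = sem(per_record),
    v0 = v0, v0_se = NA_real_, n = length(per_record),
    method = "single_timepoint",
    extra = list(per_record_kin = per_record,
                 flagged_negative = which(neg), v0_source = "supplied")
  )
  res
}

#' Vascular volume from an impermeant reference tracer
#'
#' For a tracer that does not cross the barrier (K_in = 0) the distribution
#' volume `Q*/C*` equals the vascular space at every perfusion time; its
#' mean across records estimates V0, with SEM (0 when n = 1).
#'
#' @param records perfusion records of the impermeant tracer (same columns
#'   as [fit_kin()]).
#' @return list with `v0` (mL/g), `v0_se`, `n`.
#' @examples
#' suc <- generate_perfusion_series(0, 0.015, 10, noise_cv = 0,
#'                                  tracer = "sucrose", seed = 1)
#' vascular_volume(suc)
#' @export
vascular_volume <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("no impermeant-tracer records", call. = FALSE)
  }
  check_records(records)
  vol <- records$qstar_ug_per_g / records$cstar_ug_per_ml
  list(v0 = mean(vol), v0_se = sem(vol), n = length(vol))
}

#' Fold change in K_in under transporter inhibition
#'
#' @param kin_with K_in with the inhibitor co-perfused (uL/s/g).
#' @param kin_baseline baseline K_in (uL/s/g, > 0).
#' @return dimensionless ratio `kin_with / kin_baseline`.
#' @examples
#' inhibitor_fold(2.4, 0.12)  # 20-fold
#' @export
inhibitor_fold <- function(kin_with, kin_baseline) {
  check_positive(kin_baseline, "kin_baseline")
  kin_with / kin_baseline
}

#' @export
print.kin_fit <- function(x, ...) {
  cat(sprintf("K_in fit (%s, n = %d)\n", x$method, x$n))
  cat(sprintf("  K_in: %.4g +/- %.3g uL/s/g\n", x$kin, x$kin_se))
  if (is.na(x$v0_se)) {
    cat(sprintf("  V0:   %.4g mL/g (%s)\n", x$v0, x$v0_source))
  } else {
    cat(sprintf("  V0:   %.4g +/- %.3g mL/g (%s)\n", x$v0, x$v0_se,
                x$v0_source))
  }
  if (!is.null(x$r_squared)) cat(sprintf("  r^2:  %.4f\n", x$r_squared))
  if (length(x$flagged_negative)) {
    cat("  flagged negative estimates:",
        paste(x$flagged_negative, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.kin_fit <- function(object, ...) c(kin = object$kin, v0 = object$v0)

#' @export
summary.kin_fit <- function(object, ...) {
  if (!is.null(object$fit)) summary(object$fit, ...) else object
}

#' Predicted distribution volume Q*/C* (mL/g) at given perfusion times
#' @param object a `kin_fit`.
#' @param time_s perfusion times in seconds.
#' @param ... unused.
#' @export
predict.kin_fit <- function(object, time_s, ...) {
  object$kin / 1000 * time_s + object$v0
}

#' @export
confint.kin_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- rbind(
    kin = object$kin + c(-1, 1) * z * object$kin_se,
    v0 = object$v0 + c(-1, 1) * z * object$v0_se
  )
  colnames(out) <- sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  out
}

#' Uptake plot: distribution volume against perfusion time
#' @param x a `kin_fit` from [fit_kin()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.kin_fit <- function(x, ...) {
  if (is.null(x$fit)) {
    stop("uptake plot requires a multipoint fit", call. = FALSE)
  }
  d <- x$fit$model
  graphics::plot(d$time, d$vol, xlab = "Perfusion time (s)",
                 ylab = "Q*/C* (mL/g)", ...)
  graphics::abline(x$fit)
  invisible(x)
}
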