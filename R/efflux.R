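# Efflux-substrate profiling from the passive LogD - Log K_in relationship.

#' Log-transform a transfer constant for lipophilicity profiling
#'
#' Compounds that enter brain by passive diffusion fall on a line when
#' log10 of K_in (expressed in mL/s/g) is plotted against LogD, so transfer
#' constants measured in uL/s/g are divided by 1000 before taking log10.
#'
#' @param kin_ul_s_g transfer constant(s) in uL/s/g (> 0).
#' @return log10 of K_in in mL/s/g.
#' @examples
#' log_kin(0.12)   # -3.92
#' log_kin(1000)   # 0
#' @export
log_kin <- function(kin_ul_s_g) {
  check_positive(kin_ul_s_g, "kin_ul_s_g")
  log10(kin_ul_s_g / 1000)
}

#' Fit the passive-diffusion reference line
#'
#' OLS of `log_kin` on LogD over compounds known to cross the barrier by
#' passive diffusion. The residual SD quantifies the scatter of passive
#' compounds about the line, against which efflux deviations are judged.
#'
#' @param compounds data.frame with columns `logd`, and either `log_kin`
#'   (log10 mL/s/g) or `kin_ul_s_g`, and optionally `known_class`; when
#'   `known_class` is present only rows with `known_class == "passive"`
#'   enter the fit.
#' @return object of class `passive_line` with `slope`, `intercept`
#'   (log10 units), `residual_sd`, `n`, and the underlying `lm` fit.
#' @export
fit_passive_line <- function(compounds) {
  d <- as.data.frame(compounds)
  if ("known_class" %in% names(d)) {
    d <- d[d$known_class == "passive", , drop = FALSE]
  }
  if (!"log_kin" %in% names(d)) d$log_kin <- log_kin(d$kin_ul_s_g)
  if (nrow(d) < 2L || length(unique(d$logd)) < 2L) {
    stop("need >= 2 passive compounds with distinct LogD", call. = FALSE)
  }
  fit <- stats::lm(log_kin ~ logd, data = d)
  structure(
    list(slope = unname(stats::coef(fit)["logd"]),
         intercept = unname(stats::coef(fit)["(Intercept)"]),
         residual_sd = if (fit$df.residual > 0)
           suppressWarnings(summary(fit)$sigma) else 0,
         n = nrow(d), fit = fit),
    class = "passive_line"
  )
}

#' @export
print.passive_line <- function(x, ...) {
  cat("Passive-diffusion line: log10 K_in(mL/s/g) =",
      sprintf("%.4g * LogD + %.4g", x$slope, x$intercept), "\n")
  cat(sprintf("  residual SD %.3g log units, n = %d passive compounds\n",
              x$residual_sd, x$n))
  invisible(x)
}

#' @export
coef.passive_line <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept)
}

#' Predicted passive log10 K_in (mL/s/g) at given LogD values
#' @param object a `passive_line`.
#' @param logd LogD values.
#' @param ... unused.
#' @export
predict.passive_line <- function(object, logd, ...) {
  object$slope * logd + object$intercept
}

#' Deviation of compounds below the passive line, with efflux flag
#'
#' A compound extruded by an efflux transporter shows an observed log K_in
#' well below the value its lipophilicity predicts. Deviation is defined as
#' predicted minus observed log10 K_in, so positive values lie below the
#' line; a compound is flagged as an efflux suspect when its deviation
#' reaches `threshold` log units.
#'
#' @param compounds data.frame with `name`, `logd`, and `log_kin` or
#'   `kin_ul_s_g`.
#' @param line a fitted [fit_passive_line()].
#' @param threshold flag level in log10 units (default 1.0: well clear of
#'   passive-compound scatter, robustly below the ~3-unit deviation of a
#'   strong efflux substrate).
#' @return data.frame with `name`, `logd`, `log_kin`, `predicted`,
#'   `deviation`, `efflux_suspect`.
#' @export
efflux_deviation <- function(compounds, line, threshold = 1.0) {
  stopifnot(inherits(line, "passive_line"))
  d <- as.data.frame(compounds)
  if (!"log_kin" %in% names(d)) d$log_kin <- log_kin(d$kin_ul_s_g)
  pred <- predict(line, d$logd)
  dev <- pred - d$log_kin
  data.frame(
    name = if ("name" %in% names(d)) d$name else seq_len(nrow(d)),
    logd = d$logd, log_kin = d$log_kin, predicted = pred,
    deviation = dev, efflux_suspect = dev >= threshold
  )
}

#' Screen a compound table against the passive-diffusion line
#'
#' Convenience wrapper: fits the line on the `known_class == "passive"`
#' compounds and reports every compound's deviation and flag.
#'
#' @inheritParams efflux_deviation
#' @param compounds compound table with `name`, `logd`, `kin_ul_s_g` (or
#'   `log_kin`) and `known_class`.
#' @return list with `line` (the [fit_passive_line()]) and `deviations`
#'   (the [efflux_deviation()] table).
#' @export
efflux_screen <- function(compounds, threshold = 1.0) {
  line <- fit_passive_line(compounds)
  list(line = line,
       deviations = efflux_deviation(compounds, line, threshold = threshold))
}

#' Reference compound table for efflux screening
#'
#' Loads the packaged synthetic reference table of passive-permeability
#' compounds and known efflux substrates (columns `name`, `logd`,
#' `kin_ul_s_g`, `known_class`). The table is configuration, not ground
#' truth: LogD values are literature-typical and the transfer constants are
#' synthetic, placed on (passive) or below (efflux) a representative
#' passive-diffusion line. Replace it with measured values via `path`.
#'
#' @param path optional path to an alternative CSV with the same columns;
#'   lines starting with `#` are ignored.
#' @return data.frame of compounds.
#' @export
load_reference_compounds <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "reference_compounds_synthetic.csv",
                        package = "btbquant", mustWork = TRUE)
  }
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
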