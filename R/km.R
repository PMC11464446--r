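#' Kaplan-Meier curve container
#'
#' Ordered `(time, survival)` coordinate pairs, optionally with numbers at
#' risk, as produced by digitizing a published figure or by
#' [km_estimate()].  Times are months; survival in `[0, 1]`.
#'
#' @param time Strictly increasing times (months).
#' @param survival Survival probabilities, non-increasing after cleaning.
#' @param n_risk Optional numbers at risk at each time.
#' @param clean If `TRUE` (default) apply [clean_km_curve()] before
#'   validation.
#' @return A data frame of class `km_curve`.
#' @export
km_curve <- function(time, survival, n_risk = NULL, clean = TRUE) {
  stopifnot(length(time) == length(survival),
            is.null(n_risk) || length(n_risk) == length(time))
  o <- order(time)
  out <- data.frame(time = time[o], survival = survival[o])
  if (!is.null(n_risk)) out$n_risk <- n_risk[o]
  if (clean) out <- clean_km_curve(out)
  if (any(out$time < 0)) stop("times must be non-negative", call. = FALSE)
  if (any(out$survival < 0 | out$survival > 1)) {
    stop("survival must lie in [0, 1]", call. = FALSE)
  }
  if (is.unsorted(rev(out$survival))) {
    stop("survival must be non-increasing", call. = FALSE)
  }
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Clean a digitized survival curve
#'
#' Digitized coordinates carry jitter: this enforces monotone
#' non-increasing survival by isotonic clipping (running minimum), clamps
#' to `[0, 1]`, and drops duplicate time points keeping the lower survival.
#'
#' @param curve A data frame with `time` and `survival` columns.
#' @export
clean_km_curve <- function(curve) {
  curve <- curve[order(curve$time, curve$survival), , drop = FALSE]
  curve <- curve[!duplicated(curve$time), , drop = FALSE]  # keep lower S
  s <- pmin(pmax(curve$survival, 0), 1)
  if (length(s) > 1 && is.unsorted(rev(s))) {
    # pool-adjacent-violators projection onto the non-increasing cone;
    # unlike a running minimum this does not bias the curve downwards
    s <- pmin(pmax(-stats::isoreg(curve$time, -s)$yf, 0), 1)
  }
  curve$survival <- s
  rownames(curve) <- NULL
  curve
}

#' Read / write a Kaplan-Meier curve as CSV
#'
#' Two-column CSV (`time_months`, `survival`) with an optional third
#' `n_at_risk` column.
#'
#' @param path File path.
#' @rdname km_curve_io
#' @export
read_km_curve <- function(path) {
  d <- utils::read.csv(path)
  names(d) <- tolower(names(d))
  if (!all(c("time_months", "survival") %in% names(d))) {
    stop("expected columns time_months, survival", call. = FALSE)
  }
  km_curve(d$time_months, d$survival,
           n_risk = if ("n_at_risk" %in% names(d)) d$n_at_risk)
}

#' @param curve A `km_curve`.
#' @rdname km_curve_io
#' @export
write_km_curve <- function(curve, path) {
  d <- data.frame(time_months = curve$time, survival = curve$survival)
  if (!is.null(curve$n_risk)) d$n_at_risk <- curve$n_risk
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Interpolate a step-function survival curve
#'
#' Right-continuous step interpolation with `S(0) = 1` before the first
#' event time.
#'
#' @param curve A `km_curve`.
#' @param t Times at which to evaluate.
#' @export
km_survival_at <- function(curve, t) {
  stats::approx(c(0, curve$time), c(1, curve$survival), xout = t,
                method = "constant", rule = 2, f = 0)$y
}
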