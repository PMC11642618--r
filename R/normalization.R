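# Developmental-stage normalization. uCT measures in growing fish scale
# with standard length (SL, snout tip to caudal-fin base, mm); the
# dependence is well described by a power law y = c * SL^alpha, so measures
# are normalized by dividing by SL^alpha. alpha = 1 is plain SL division;
# alpha is otherwise estimated by ordinary least squares in log-log space.
# For mutants where SL no longer stages the fish, an alternative covariate
# (commonly orbit diameter) can be used instead.

#' Normalize measures by standard length
#'
#' `y / sl^alpha`, elementwise. When the fitted scaling exponent of the
#' measure is negative (the neural-arch-angle case, which decreases with
#' SL), dividing by SL is not meaningful; a negative `alpha` is allowed but
#' warned about.
#'
#' @param y numeric measure values.
#' @param sl standard lengths (mm, > 0), same length as `y`.
#' @param alpha scaling exponent (default 1 = plain SL normalization;
#'   0 leaves values unchanged).
#' @return Normalized values with attribute `alpha`.
#' @export
normalize_by_length <- function(y, sl, alpha = 1) {
  if (length(y) != length(sl)) stop("y and sl lengths differ", call. = FALSE)
  if (any(!is.finite(sl)) || any(sl <= 0))
    stop("standard lengths must be positive", call. = FALSE)
  if (alpha < 0)
    warning("alpha < 0: measure decreases with SL; SL division may be inappropriate",
            call. = FALSE)
  structure(y / sl^alpha, alpha = alpha)
}

#' Fit the allometric power law y = c * SL^alpha
#'
#' Ordinary least squares of log(y) on log(SL). Noiseless power-law data are
#' recovered exactly; the exponent, intercept and r-squared are returned for
#' reporting.
#'
#' @param y positive measure values (>= 3).
#' @param sl positive standard lengths, same length.
#' @return An `allometric_fit` list: `alpha`, `log_c`, `r2`, `n`.
#' @export
fit_power_law <- function(y, sl) {
  if (length(y) != length(sl)) stop("y and sl lengths differ", call. = FALSE)
  if (length(y) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (any(!is.finite(y)) || any(y <= 0) || any(!is.finite(sl)) || any(sl <= 0))
    stop("power-law fit needs strictly positive y and sl", call. = FALSE)
  if (diff(range(sl)) == 0) stop("degenerate SL spread", call. = FALSE)
  fit <- stats::lm(log(y) ~ log(sl))
  # summary() warns on an essentially perfect fit; noiseless power laws are
  # a legitimate input here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(alpha = unname(stats::coef(fit)[2]),
                 log_c = unname(stats::coef(fit)[1]),
                 r2 = if (is.nan(r2)) 1 else r2, n = length(y)),
            class = "allometric_fit")
}

#' @export
print.allometric_fit <- function(x, ...) {
  cat(sprintf("<allometric_fit> y = exp(%.4g) * SL^%.4g (n = %d, r2 = %.4f)\n",
              x$log_c, x$alpha, x$n, x$r2))
  invisible(x)
}

#' Normalize by an alternative covariate
#'
#' Plain division by a positive covariate such as orbit diameter, for cases
#' where standard length is no longer an independent staging measure
#' (growth mutants with altered body proportions). The covariate name is
#' recorded for reporting.
#'
#' @param y numeric measure values.
#' @param covariate positive values, same length as `y`.
#' @param covariate_name recorded label (default `"orbit_diameter"`).
#' @return Normalized values with attribute `covariate`.
#' @export
normalize_alternative <- function(y, covariate,
                                  covariate_name = "orbit_diameter") {
  if (length(y) != length(covariate))
    stop("y and covariate lengths differ", call. = FALSE)
  if (any(!is.finite(covariate)) || any(covariate <= 0))
    stop("covariate must be positive", call. = FALSE)
  structure(y / covariate, covariate = covariate_name)
}
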