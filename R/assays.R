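# Auxiliary quantifications: single-hit clonogenic survival (D0) and
# delta-delta-Ct relative expression.

#' Fit D0 from a clonogenic survival curve
#'
#' Single-hit exponential model SF(D) = exp(-D / D0), fitted by least squares
#' on the log scale through the origin. D0 is the dose at which the surviving
#' fraction falls to 1/e (~ 36.8%, conventionally quoted as 37%).
#'
#' @param doses radiation doses in Gy, strictly increasing, including 0.
#' @param surviving_fraction survival fractions in (0, 1], with SF(0) = 1.
#' @return list with `d0` (Gy), `slope` (per Gy, = -1/D0) and `sf_at_d0`
#'   (the model's surviving fraction at D = D0, always 1/e).
#' @export
fit_d0 <- function(doses, surviving_fraction) {
  if (length(doses) != length(surviving_fraction))
    stop("doses and surviving_fraction must have the same length")
  if (any(diff(doses) <= 0)) stop("doses must be strictly increasing")
  if (sum(doses > 0) < 2) stop("need at least 2 positive-dose points")
  if (any(surviving_fraction <= 0))
    stop("surviving fractions must be positive (log fit undefined at 0)")
  pos <- doses > 0
  if (any(surviving_fraction[pos] > 1) &&
      stats::cor(doses[pos], surviving_fraction[pos]) >= 0)
    warning("survival does not decrease with dose; single-hit fit is suspect")
  fit <- stats::lm(log(surviving_fraction) ~ doses - 1)
  slope <- unname(stats::coef(fit)[1])
  if (slope >= 0)
    stop("fitted slope is non-negative; no exponential kill to estimate")
  list(d0 = -1 / slope, slope = slope, sf_at_d0 = exp(-1))
}

#' Delta-delta-Ct relative expression fold change
#'
#' fold = 2^-[(Ct_target - Ct_ref)_test - (Ct_target - Ct_ref)_control],
#' the standard relative quantification against an internal reference gene
#' (e.g. GAPDH).
#'
#' @param ct_target_test,ct_ref_test target and reference-gene Ct in the
#'   test sample.
#' @param ct_target_ctrl,ct_ref_ctrl the same in the control sample.
#' @return fold change (scalar, vectorized over inputs).
#' @export
ddct_fold_change <- function(ct_target_test, ct_ref_test,
                             ct_target_ctrl, ct_ref_ctrl) {
  vals <- c(ct_target_test, ct_ref_test, ct_target_ctrl, ct_ref_ctrl)
  if (!all(is.finite(vals))) stop("all Ct values must be finite")
  ddct <- (ct_target_test - ct_ref_test) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}
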