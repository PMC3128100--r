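#' Tukey biweight location estimate
#'
#' Robust location estimator used to scale the two channels of a tiling
#' array against each other.  Starting from the median, the estimate m is
#' iteratively reweighted with the bisquare weights
#' `w = (1 - u^2)^2` for `|u| < 1` and 0 otherwise, where
#' `u = (x - m) / (c * MAD)` and MAD is the (unscaled) median absolute
#' deviation of the data from its median.  Iteration stops when the
#' estimate moves by less than `tol` or after `max_iter` sweeps.
#'
#' @param x numeric values (at least one finite value).
#' @param c tuning constant; 5 keeps ~4 MADs of data at non-zero weight.
#' @param tol convergence tolerance on the location estimate.
#' @param max_iter iteration cap.
#' @return the location estimate (scalar).  If the MAD is zero (more than
#'   half the data identical) the median is returned.
#' @examples
#' tukey_biweight_location(c(0, 0, 0, 0, 100)) # close to 0, outlier ignored
#' @export
tukey_biweight_location <- function(x, c = 5, tol = 1e-6, max_iter = 50L) {
  x <- x[is.finite(x)]
  if (!length(x)) stop("tukey_biweight_location: no finite values")
  m <- median(x)
  s <- median(abs(x - m))
  if (s == 0) return(m)
  for (i in seq_len(max_iter)) {
    u <- (x - m) / (c * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w) == 0) return(m)
    m_new <- sum(w * x) / sum(w)
    if (abs(m_new - m) < tol) return(m_new)
    m <- m_new
  }
  m
}

#' Scale a probe track by its Tukey biweight mean
#'
#' Between-channel scaling of the log2 ratios: the biweight location over
#' all probes of the condition (array-wide, not per chromosome) is
#' subtracted from every log2 ratio, so the scaled track is robustly
#' centred at zero.  Idempotent up to the convergence tolerance and
#' invariant to adding a constant to all ratios.
#'
#' @param track a [probe_track()].
#' @param condition which condition to scale (default: all conditions,
#'   each centred with its own biweight mean).
#' @param ... passed to [tukey_biweight_location()].
#' @return the track with scaled ratios and attribute `scaled = TRUE`.
#' @export
scale_track <- function(track, condition = NULL, ...) {
  if (!is.null(condition)) track <- track[track$condition == condition, ]
  if (!nrow(track)) stop("scale_track: empty track")
  for (cond in unique(track$condition)) {
    sel <- track$condition == cond
    m <- tukey_biweight_location(track$log2_ratio[sel], ...)
    track$log2_ratio[sel] <- track$log2_ratio[sel] - m
  }
  attr(track, "scaled") <- TRUE
  track
}
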