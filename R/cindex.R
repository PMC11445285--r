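#' Harrell concordance index
#'
#' Fraction of comparable patient pairs whose risk ordering matches their
#' survival ordering. A pair is comparable when the shorter observed time is
#' an event (a patient censored before another's event is not comparable);
#' concordance means the shorter survivor carries the higher risk score, and
#' risk ties count 1/2.
#'
#' @param risk Numeric risk scores (higher = worse prognosis).
#' @param time Observed times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @return C-index in \[0, 1\], or `NA` when no pair is comparable.
#' @export
harrell_c_index <- function(risk, time, event) {
  if (any(!is.finite(risk))) stop("risk scores must be finite")
  n <- length(risk)
  stopifnot(length(time) == n, length(event) == n)
  num <- 0; den <- 0
  for (i in which(event == 1L)) {
    later <- time > time[i]
    m <- sum(later)
    if (!m) next
    den <- den + m
    num <- num + sum(risk[i] > risk[later]) + 0.5 * sum(risk[i] == risk[later])
  }
  if (den == 0) return(NA_real_)
  num / den
}
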