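#' CIRG color index from CIELAB readings
#'
#' The color index of red grapes, a single-number summary of red color
#' development in CIELAB space:
#' \deqn{CIRG = (180 - H) / (L^* + C)}
#' with chroma \eqn{C = \sqrt{a^{*2} + b^{*2}}} and hue angle \eqn{H} the
#' four-quadrant arctangent of \eqn{(b^*, a^*)} in degrees, mapped to
#' `[0, 360)`. Higher values mean darker red. The four-quadrant hue angle is
#' used because a plain `arctan(b*/a*)` is ill-defined for `a* <= 0`; for
#' ripening fruit (`a* > 0`) the two coincide.
#'
#' @param L_star,a_star,b_star CIELAB lightness, red-green and yellow-blue
#'   coordinates (vectorized).
#' @return Numeric CIRG values.
#' @examples
#' cirg(50, 1, 0)  # 180 / 51
#' @export
cirg <- function(L_star, a_star, b_star) {
  C <- sqrt(a_star^2 + b_star^2)
  if (any(L_star + C <= 0)) {
    stop("CIRG undefined: L* + C must be positive", call. = FALSE)
  }
  H <- atan2(b_star, a_star) * 180 / pi
  H <- ifelse(H < 0, H + 360, H)
  (180 - H) / (L_star + C)
}

#' Per-stage CIRG summary with replicate averaging
#'
#' Computes CIRG for every replicate reading, averages replicates within
#' fruit, then averages fruit means within stage, reporting the stage mean
#' with the standard error over fruit.
#'
#' @param readings Data frame with columns `stage`, `fruit`, `replicate`,
#'   `L_star`, `a_star`, `b_star` (as from [simulate_colorimetry()]).
#' @return Data frame `stage`, `n_fruit`, `mean_cirg`, `se_cirg`, ordered by
#'   stage.
#' @export
summarize_color <- function(readings) {
  need <- c("stage", "fruit", "L_star", "a_star", "b_star")
  stopifnot(all(need %in% names(readings)))
  if (nrow(readings) == 0) {
    warning("no readings; empty summary", call. = FALSE)
    return(data.frame(stage = integer(0), n_fruit = integer(0),
                      mean_cirg = numeric(0), se_cirg = numeric(0)))
  }
  readings$cirg <- cirg(readings$L_star, readings$a_star, readings$b_star)
  fruit_means <- stats::aggregate(cirg ~ stage + fruit, data = readings,
                                  FUN = mean)
  out <- do.call(rbind, lapply(split(fruit_means, fruit_means$stage),
    function(d) {
      data.frame(stage = d$stage[1], n_fruit = nrow(d),
                 mean_cirg = mean(d$cirg),
                 se_cirg = if (nrow(d) > 1) {
                   stats::sd(d$cirg) / sqrt(nrow(d))
                 } else 0)
    }))
  out <- out[order(out$stage), , drop = FALSE]
  rownames(out) <- NULL
  out
}
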