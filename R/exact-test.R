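#' Exact two-library tag-count test
#'
#' Probability model for comparing a gene's mapped clean-read counts between
#' two sequencing libraries without biological replicates. Conditional on the
#' count `x` observed in library 1 (total clean reads `n1`), the count `y` in
#' library 2 (total `n2`) has point probability
#' \deqn{p(y \mid x) = \frac{(n_2/n_1)^y \, (x+y)!}{x!\,y!\,(1+n_2/n_1)^{x+y+1}}}
#' and a gene is called differentially expressed from the folded two-sided
#' tail of this distribution. All arithmetic is carried out in log space
#' (log-gamma plus a multiplicative recurrence), so the functions stay finite
#' and positive for counts up to at least 1e6.
#'
#' @param x,y Nonnegative integer read counts for the gene in library 1 and 2.
#'   Vectorized; recycled against each other.
#' @param n1,n2 Positive totals of clean reads in library 1 and 2.
#' @return `point_prob()`: the point probability `p(y|x)`. `two_sided_p()`:
#'   the folded two-sided p-value in `(0, 1]`.
#' @examples
#' point_prob(1, 1, 1e6, 1e6)   # 0.25
#' two_sided_p(5, 0, 1e6, 1e6)  # 2 * 2^-6 = 0.03125
#' @export
point_prob <- function(x, y, n1, n2) {
  .check_counts(x, y, n1, n2)
  log_r <- log(n2) - log(n1)
  lp <- y * log_r + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
    (x + y + 1) * log1p(exp(log_r))
  exp(lp)
}

#' @rdname point_prob
#' @export
two_sided_p <- function(x, y, n1, n2) {
  .check_counts(x, y, n1, n2)
  args <- data.frame(x = x, y = y, n1 = n1, n2 = n2)
  vapply(seq_len(nrow(args)), function(i) {
    .two_sided_p_one(args$x[i], args$y[i], args$n1[i], args$n2[i])
  }, numeric(1))
}

.check_counts <- function(x, y, n1, n2) {
  if (any(x < 0) || any(y < 0)) {
    stop("counts 'x' and 'y' must be nonnegative", call. = FALSE)
  }
  if (any(n1 <= 0) || any(n2 <= 0)) {
    stop("library totals 'n1' and 'n2' must be positive", call. = FALSE)
  }
  invisible(NULL)
}

# Log point probabilities log p(i|x) for i = 0..y, built from
# p(0|x) = (1+r)^-(x+1) and the recurrence
#   p(i+1|x) = p(i|x) * r * (x+i+1) / ((i+1) * (1+r)).
.log_point_probs <- function(x, y, log_r) {
  lp0 <- -(x + 1) * log1p(exp(log_r))
  if (y == 0) return(lp0)
  i <- seq_len(y)
  steps <- log_r + log(x + i) - log(i) - log1p(exp(log_r))
  cumsum(c(lp0, steps))
}

.logsumexp <- function(lp) {
  m <- max(lp)
  m + log(sum(exp(lp - m)))
}

.two_sided_p_one <- function(x, y, n1, n2) {
  log_r <- log(n2) - log(n1)
  lp <- .log_point_probs(x, y, log_r)
  s_lower <- exp(.logsumexp(lp))
  if (s_lower <= 0.5) {
    p <- 2 * s_lower
  } else {
    # 1 - S computed as the upper tail directly: summing the recurrence from
    # i = y+1 keeps relative accuracy when S is close to 1.
    p <- 2 * .upper_tail(x, y, log_r, lp[length(lp)])
  }
  # values that underflow to 0 are reported as the smallest positive normal
  # so downstream FDR adjustment stays well-defined
  min(max(p, .Machine$double.xmin), 1)
}

# Upper tail sum_{i > y} p(i|x), continued from log p(y|x) in chunks until the
# remaining geometric tail is negligible relative to the accumulated sum.
.upper_tail <- function(x, y, log_r, lp_y, chunk = 256L) {
  total <- 0
  i0 <- y
  lp <- lp_y
  ratio_log_const <- log_r - log1p(exp(log_r))
  repeat {
    i <- i0 + seq_len(chunk)
    steps <- ratio_log_const + log(x + i) - log(i)
    lps <- lp + cumsum(steps)
    total <- total + sum(exp(lps))
    lp <- lps[chunk]
    i0 <- i0 + chunk
    # once past the mode the term ratio is below q < 1; bound the remainder
    q <- exp(ratio_log_const + log(x + i0 + 1) - log(i0 + 1))
    if (q < 1) {
      rem <- exp(lp) * q / (1 - q)
      if (rem <= total * 1e-15 || rem < .Machine$double.xmin) break
    }
  }
  total
}
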