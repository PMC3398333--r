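# Exact rational-arithmetic oracle for the two-library test, evaluated with
# arbitrary-precision rationals through the system python (fractions module).
# For each library-size ratio r = n2/n1 it emits, for every x,y in 0..max_xy,
# the exact point probability p(y|x) and the folded two-sided p-value of the
# printed formulas, correctly rounded to double precision.
exact_rational_oracle <- function(max_xy = 200,
                                  ratios = c("1/2", "1/1", "2/1")) {
  script <- sprintf('
import sys
from fractions import Fraction
M = %d
ratios = [%s]
out = sys.stdout
for r in ratios:
    one_plus = 1 + r
    for x in range(M + 1):
        p = Fraction(1) / one_plus ** (x + 1)   # p(0|x)
        s = p
        for y in range(M + 1):
            if y > 0:
                p = p * r * (x + y) / (y * one_plus)
                s += p
            p2 = 2 * s if s <= Fraction(1, 2) else 2 * (1 - s)
            if p2 > 1:
                p2 = Fraction(1)
            out.write("%%.17e %%.17e\\n" %% (float(p), float(p2)))
', max_xy, paste(sprintf("Fraction(%s)", ratios), collapse = ", "))
  tf <- tempfile(fileext = ".py")
  writeLines(script, tf)
  on.exit(unlink(tf))
  raw <- system2("python", tf, stdout = TRUE)
  vals <- matrix(scan(text = raw, quiet = TRUE), ncol = 2, byrow = TRUE)
  grid <- expand.grid(y = 0:max_xy, x = 0:max_xy,
                      ratio = ratios, stringsAsFactors = FALSE)
  data.frame(x = grid$x, y = grid$y, ratio = grid$ratio,
             point = vals[, 1], p2 = vals[, 2])
}
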