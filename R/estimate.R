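# Hybridization-rate estimation from offspring counts. Within a maternal
# line of an interspecific pair the offspring genotype is a Bernoulli trial:
# a cross-fertilized aA ovum gives aAF, a (facilitated) self-fertilized one
# gives aAA, so the hybrid fraction is the binomial MLE of the rate.

#' Estimate the hybridization rate of a maternal line
#'
#' For the `a` line, the estimate is `n_aAF / (n_aAF + n_aAA)`; for the `f`
#' line, `n_fFA / (n_fFA + n_fFF)` (only codes of the line's mitochondrial
#' clade enter the count — the clade fixes the ovum parent). The 95% interval
#' is Clopper–Pearson. When `fFA` offspring survive only with probability
#' `viability`, the observed hybrid fraction underestimates the rate; setting
#' `viability < 1` applies the correction
#' `h = p / (v + p (1 - v))` to the point estimate and interval bounds
#' (off by default: `viability = 1`).
#'
#' @param offspring Character vector of offspring genotype codes, or a data
#'   frame with a `code` column (e.g. the `offspring` element of a
#'   [simulate_experiment()] result).
#' @param line Maternal line: `"a"` or `"f"`.
#' @param viability Survival probability of the line's hybrid class, used to
#'   de-bias the estimate (default 1, no correction).
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `hyb_rate_est`: list with `line`, `h_hat`,
#'   `ci_low`, `ci_high`, `n_offspring`, `n_hybrid`, `conf_level`.
#' @export
#' @examples
#' estimate_hybridization_rate(c(rep("aAF", 2), rep("aAA", 8)), line = "a")
estimate_hybridization_rate <- function(offspring, line = c("a", "f"),
                                        viability = 1, conf_level = 0.95) {
  line <- match.arg(line)
  codes <- if (is.data.frame(offspring)) {
    if (!"code" %in% names(offspring)) {
      abort_input("offspring data frame must have a 'code' column")
    }
    offspring$code
  } else {
    offspring
  }
  parse_genotype_code(codes)
  if (viability <= 0 || viability > 1) {
    abort_input("viability must be in (0, 1]")
  }
  hybrid_code <- if (line == "a") "aAF" else "fFA"
  pure_code <- if (line == "a") "aAA" else "fFF"
  n_hyb <- sum(codes == hybrid_code)
  n_pure <- sum(codes == pure_code)
  n <- n_hyb + n_pure
  if (n == 0) {
    abort_input(sprintf(
      "hybridization rate undefined: no %s or %s offspring in the %s line",
      hybrid_code, pure_code, line
    ))
  }
  ci <- binom.test(n_hyb, n, conf.level = conf_level)$conf.int
  debias <- function(p) p / (viability + p * (1 - viability))
  structure(
    list(
      line = line,
      h_hat = debias(n_hyb / n),
      ci_low = debias(ci[1]),
      ci_high = debias(ci[2]),
      n_offspring = n,
      n_hybrid = n_hyb,
      conf_level = conf_level
    ),
    class = "hyb_rate_est"
  )
}

#' @export
print.hyb_rate_est <- function(x, ...) {
  cat(sprintf(
    "<hyb_rate_est> %s line: h = %.3f [%.3f, %.3f] (%d hybrids / %d offspring)\n",
    x$line, x$h_hat, x$ci_low, x$ci_high, x$n_hybrid, x$n_offspring
  ))
  invisible(x)
}

#' @export
tidy.hyb_rate_est <- function(x, ...) {
  tibble(
    line = x$line,
    estimate = x$h_hat,
    conf.low = x$ci_low,
    conf.high = x$ci_high
  )
}

#' @export
glance.hyb_rate_est <- function(x, ...) {
  tibble(
    line = x$line,
    estimate = x$h_hat,
    conf.low = x$ci_low,
    conf.high = x$ci_high,
    n_offspring = x$n_offspring,
    n_hybrid = x$n_hybrid,
    conf.level = x$conf_level
  )
}
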