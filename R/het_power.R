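#' Heterozygosity probability under Hardy-Weinberg equilibrium
#'
#' For a biallelic site with allele frequency `af`, the probability that a
#' randomly drawn individual is heterozygous is `2*af*(1-af)`. At `af = 0.5`
#' this peaks at 0.5; averaged over a uniform allele-frequency spectrum it is
#' 1/3, i.e. one person is expected to be heterozygous at a third of common
#' polymorphisms.
#'
#' @param af Allele frequency, strictly inside (0, 1). Vectorized.
#' @return Heterozygote probability in (0, 0.5].
#' @export
het_prob <- function(af) {
  if (any(af <= 0 | af >= 1)) stop("af must be strictly inside (0, 1)")
  2 * af * (1 - af)
}

#' Probability of observing at least one heterozygote among n individuals
#'
#' `1 - (1 - 2*af*(1-af))^n` under Hardy-Weinberg equilibrium and independent
#' (unrelated) individuals.
#'
#' @inheritParams het_prob
#' @param n Number of individuals (integer >= 0).
#' @return Probability in \\[0, 1). Vectorized over `af`.
#' @export
prob_any_het <- function(af, n) {
  if (length(n) != 1L || n < 0 || n != floor(n)) {
    stop("n must be a single non-negative integer")
  }
  1 - (1 - het_prob(af))^n
}

#' Expected fraction of polymorphisms heterozygous in at least one of n people
#'
#' Integrates `prob_any_het` over a uniform allele-frequency density on (0, 1):
#' `1 - integral_0^1 (1 - 2p(1-p))^n dp`. The substitution `u = 2p - 1` turns
#' the integrand into `((1 + u^2)/2)^n`, giving the closed form
#' `1 - 2^(-n) * sum_k C(n, k) / (2k + 1)` — an all-positive sum, numerically
#' stable for the whole supported range. An alternative allele-frequency
#' density can be supplied, in which case the integral is computed by
#' adaptive quadrature.
#'
#' @param n Number of individuals (integer >= 1).
#' @param af_density Optional density function on (0, 1) (need not be
#'   normalized; it is renormalized internally). `NULL` means uniform, which
#'   uses the exact closed form.
#' @return Expected covered fraction in (0, 1).
#' @export
expected_het_fraction <- function(n, af_density = NULL) {
  if (length(n) != 1L || n < 1 || n != floor(n)) {
    stop("n must be a single integer >= 1")
  }
  if (is.null(af_density)) {
    k <- 0:n
    return(1 - 2^(-n) * sum(choose(n, k) / (2 * k + 1)))
  }
  norm <- stats::integrate(af_density, 0, 1, rel.tol = 1e-10)$value
  miss <- stats::integrate(function(p) af_density(p) * (1 - 2 * p * (1 - p))^n,
                           0, 1, rel.tol = 1e-10)$value
  1 - miss / norm
}

#' Heterozygote-discovery power curve
#'
#' Probability of finding at least one heterozygote among `n` individuals as a
#' function of allele frequency, plus the expected covered fraction under a
#' uniform allele-frequency spectrum (the area-under-curve summary).
#'
#' @param n Number of individuals (integer >= 1).
#' @param af_grid Allele frequencies strictly inside (0, 1).
#' @return A list of class `power_curve` with elements `n`, `af_grid`,
#'   `probabilities` and `auc`.
#' @export
power_curve <- function(n, af_grid) {
  if (length(af_grid) == 0L) stop("af_grid must be non-empty")
  if (any(af_grid <= 0 | af_grid >= 1)) stop("af_grid values must be in (0, 1)")
  structure(
    list(n = as.integer(n), af_grid = as.numeric(af_grid),
         probabilities = prob_any_het(af_grid, n),
         auc = expected_het_fraction(n)),
    class = "power_curve"
  )
}

#' @export
print.power_curve <- function(x, ...) {
  cat("Heterozygote-discovery power curve, n =", x$n, "individuals\n")
  cat("  grid:", length(x$af_grid), "allele frequencies in [",
      format(min(x$af_grid)), ",", format(max(x$af_grid)), "]\n")
  cat("  expected covered fraction (uniform AF):",
      format(x$auc, digits = 4), "\n")
  invisible(x)
}

#' Summary table of expected heterozygote coverage for several cohort sizes
#'
#' @param n_values Integer vector of cohort sizes.
#' @return `data.frame` with columns `n`, `expected_fraction` and `percent`
#'   (integer percent, rounded half away from zero).
#' @export
het_power_table <- function(n_values) {
  frac <- vapply(n_values, expected_het_fraction, numeric(1))
  data.frame(n = as.integer(n_values), expected_fraction = frac,
             percent = round_percent(frac))
}

#' Round a proportion to an integer percent, half away from zero
#'
#' `0.875 -> 88`, matching conventional report rounding (R's `round` rounds
#' half to even, which would give 87.5% -> 88 too but 0.885 -> 88 instead
#' of 89 at intermediate digits).
#'
#' @param x Proportions in \\[0, 1\\]. Vectorized.
#' @return Integer percents.
#' @export
round_percent <- function(x) {
  as.integer(trunc(100 * x + 0.5 * sign(x)))
}
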