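#' @importFrom stats dbinom rmultinom median
NULL

# Terrestrial 13C natural abundance used throughout unless overridden.
P13C_NATURAL <- 0.0107

#' Default natural 13C abundance
#'
#' The probability (0.0107) that any carbon position carries 13C absent
#' labeling, the IUPAC representative terrestrial value. Every function that
#' needs a natural-abundance background takes a `p_nat` argument defaulting
#' to this constant.
#'
#' @return A length-one numeric.
#' @export
natural_13c_abundance <- function() P13C_NATURAL

check_prob <- function(p, what, allow_one = TRUE) {
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1 || (!allow_one && p == 1)) {
    stop("'", what, "' must be a probability in [0, ",
         if (allow_one) "1]" else "1)", call. = FALSE)
  }
  as.numeric(p)
}

#' Validate a mass-isotopomer distribution vector
#'
#' A MID is the vector of relative abundances M0..MK of a fragment's
#' isotopologues, where Mk carries k heavy isotopes. Entries must be
#' non-negative and, when `normalized`, sum to 1 within `tol`.
#'
#' @param mid Numeric vector M0..MK.
#' @param normalized Require the entries to sum to 1 (default `TRUE`).
#' @param tol Tolerance on the sum (default 1e-9).
#' @return The vector, invisibly, if valid; otherwise an error.
#' @export
validate_mid <- function(mid, normalized = TRUE, tol = 1e-9) {
  if (!is.numeric(mid) || length(mid) < 1L || anyNA(mid)) {
    stop("a MID must be a non-empty numeric vector without NAs", call. = FALSE)
  }
  if (any(mid < -tol)) {
    stop("MID entries must be non-negative", call. = FALSE)
  }
  if (normalized && abs(sum(mid) - 1) > tol) {
    stop("MID is not normalized: sum = ", format(sum(mid), digits = 12),
         call. = FALSE)
  }
  invisible(mid)
}

#' Natural-abundance MID of a carbon skeleton
#'
#' Binomial model: entry k is the probability that k of `n_carbons`
#' independent positions carry the heavy isotope at background abundance
#' `p_nat`.
#'
#' @param n_carbons Number of carbon positions (>= 0).
#' @param p_nat Background 13C abundance in `[0, 1)`.
#' @return Numeric MID of length `n_carbons + 1`, normalized.
#' @examples
#' natural_abundance_mid(6)          # hexose backbone
#' @export
natural_abundance_mid <- function(n_carbons, p_nat = natural_13c_abundance()) {
  n_carbons <- check_count(n_carbons, "n_carbons")
  p_nat <- check_prob(p_nat, "p_nat", allow_one = FALSE)
  dbinom(0:n_carbons, n_carbons, p_nat)
}

#' MID of a single isotopomer population
#'
#' One population is a subpool of molecules sharing an isotopic abundance
#' `p`: each labelable position carries the label with probability `p`,
#' independently, while the remaining backbone positions and all
#' derivatization carbons stay at natural abundance. The population MID is
#' the convolution of `binomial(n_labelable, p)` with
#' `binomial(n_background, p_nat)`.
#'
#' @param fragment A [fragment_spec()].
#' @param p Isotopic abundance over labelable positions, in `[0, 1]`.
#' @param p_nat Background abundance on non-labelable carbons.
#' @return Numeric MID of length `fragment_carbons(fragment) + 1`.
#' @examples
#' population_mid(fragment_spec("16:0", 16, 8), p = 0.9)
#' @export
population_mid <- function(fragment, p, p_nat = natural_13c_abundance()) {
  stopifnot(inherits(fragment, "fragment_spec"))
  p <- check_prob(p, "p")
  n_bg <- (fragment$n_analyte_carbons - fragment$n_labelable) +
    fragment$n_derivatization_carbons
  lab <- dbinom(0:fragment$n_labelable, fragment$n_labelable, p)
  if (n_bg == 0L) return(lab)
  bg <- dbinom(0:n_bg, n_bg, p_nat)
  convolve_mids(lab, bg)
}

#' Convolve two MIDs
#'
#' The MID of a molecule made of two independent carbon blocks is the
#' discrete convolution of the blocks' MIDs (mass shifts add). Both inputs
#' must be normalized; the result has length `length(a) + length(b) - 1`.
#'
#' @param a,b Normalized numeric MIDs.
#' @param tol Normalization tolerance.
#' @return The convolved, normalized MID.
#' @export
convolve_mids <- function(a, b, tol = 1e-9) {
  validate_mid(a, tol = tol)
  validate_mid(b, tol = tol)
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out / sum(out)
}

#' Construct a set of isotopomer populations
#'
#' @param p Numeric vector of isotopic abundances, one per population.
#' @param f Numeric vector of mixture fractions; must sum to 1 within `tol`
#'   when `require_unit_sum` is `TRUE`.
#' @param require_unit_sum Enforce `sum(f) == 1` (default `TRUE`).
#' @param tol Tolerance on the fraction sum.
#' @return A `data.frame` with columns `p` and `f`, class
#'   `label_populations`.
#' @examples
#' label_populations(p = c(0.0107, 0.9), f = c(0.93, 0.07))
#' @export
label_populations <- function(p, f, require_unit_sum = TRUE, tol = 1e-9) {
  stopifnot(is.numeric(p), is.numeric(f), length(p) == length(f),
            length(p) >= 1L)
  if (anyNA(p) || anyNA(f) || any(p < 0 | p > 1) || any(f < 0 | f > 1)) {
    stop("population 'p' and 'f' must lie in [0, 1]", call. = FALSE)
  }
  if (require_unit_sum && abs(sum(f) - 1) > tol) {
    stop("population fractions must sum to 1 (got ",
         format(sum(f), digits = 12), ")", call. = FALSE)
  }
  structure(data.frame(p = as.numeric(p), f = as.numeric(f)),
            class = c("label_populations", "data.frame"))
}

#' MID of a mixture of isotopomer populations
#'
#' The observed MID of a pool is modeled as a fraction-weighted mixture of
#' population MIDs: an unlabeled (natural abundance) population plus one or
#' more labeled populations, each with its own `p`.
#'
#' @param fragment A [fragment_spec()].
#' @param populations A [label_populations()] object (fractions sum to 1).
#' @param p_nat Background abundance.
#' @return Normalized numeric MID.
#' @export
mixture_mid <- function(fragment, populations,
                        p_nat = natural_13c_abundance()) {
  stopifnot(inherits(fragment, "fragment_spec"))
  if (!inherits(populations, "label_populations")) {
    populations <- label_populations(populations$p, populations$f)
  }
  if (abs(sum(populations$f) - 1) > 1e-9) {
    stop("population fractions must sum to 1", call. = FALSE)
  }
  comps <- lapply(populations$p, population_mid, fragment = fragment,
                  p_nat = p_nat)
  out <- Reduce(`+`, Map(`*`, comps, populations$f))
  out / sum(out)
}

#' Mean mass shift of a MID
#'
#' First moment `sum(k * Mk)`; for a mixture it equals
#' `sum(f_j * n_labelable * p_j) + n_background * p_nat` exactly.
#'
#' @param mid Numeric MID.
#' @return Mean number of heavy isotopes per molecule.
#' @export
mid_mean_shift <- function(mid) {
  validate_mid(mid, normalized = FALSE)
  sum((seq_along(mid) - 1L) * mid) / sum(mid)
}
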