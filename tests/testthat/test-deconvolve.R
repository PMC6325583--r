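test_that("stripping recovers the unlabeled fraction of noiseless mixtures", {
  # fully unlabeled observation
  nat <- natural_abundance_mid(6, 0.0107)
  s <- strip_natural_abundance(nat, galactose)
  expect_equal(s$f_unlabeled, 1, tolerance = 1e-8)
  expect_equal(s$labeled_mass, 0, tolerance = 1e-8)
  # no unlabeled component at all
  pure <- population_mid(galactose, 0.95, p_nat = 0)
  s2 <- strip_natural_abundance(pure, galactose, p_nat = 0)
  expect_equal(s2$f_unlabeled, 0, tolerance = 1e-6)
  expect_equal(s2$residual, pure, tolerance = 1e-6)
  # round trip through mixture_mid
  obs <- mixture_mid(galactose, two_pop(0.9, 0.07))
  s3 <- strip_natural_abundance(obs, galactose)
  expect_equal(s3$f_unlabeled, 0.93, tolerance = 1e-6)
  expect_error(strip_natural_abundance(nat[1:5], galactose), "length")
})

test_that("isotopomer classification applies the strict p > 0.5 rule", {
  # residual entirely at the saturated shift
  obs <- mixture_mid(galactose, two_pop(1, 0.2, p_nat = 0), p_nat = 0)
  d <- classify_isotopomers(strip_natural_abundance(obs, galactose,
                                                    p_nat = 0))
  expect_equal(d$highly_labeled_fraction, d$total_labeled_fraction,
               tolerance = 1e-9)
  expect_equal(d$total_labeled_fraction, 20, tolerance = 1e-6)
  # shifts 2 and 3 on a six-carbon backbone: 3/6 = 0.5 is NOT highly labeled
  obs23 <- c(0.9, 0, 0.05, 0.05, 0, 0, 0)
  d23 <- classify_isotopomers(strip_natural_abundance(obs23, galactose,
                                                      p_nat = 0))
  expect_equal(d23$highly_labeled_fraction, 0)
  expect_equal(d23$total_labeled_fraction, 10, tolerance = 1e-6)
  # empty residual: all labeled fractions zero
  d0 <- classify_isotopomers(strip_natural_abundance(
    natural_abundance_mid(6, 0.0107), galactose))
  expect_equal(d0$highly_labeled_fraction, 0, tolerance = 1e-6)
  expect_equal(d0$total_labeled_fraction, 0, tolerance = 1e-6)
})

test_that("stripping plus classification conserves total probability", {
  set.seed(11)
  for (i in 1:20) {
    f_lab <- runif(1, 0, 0.5)
    p_lab <- runif(1, 0.3, 1)
    obs <- mixture_mid(galactose, two_pop(p_lab, f_lab))
    d <- classify_isotopomers(strip_natural_abundance(obs, galactose))
    expect_equal(sum(d$populations$f), 1, tolerance = 1e-9)
    expect_lte(d$highly_labeled_fraction,
               d$total_labeled_fraction + 1e-9)
    expect_gte(d$residual_norm, 0)
  }
})

test_that("grid mixture fit recovers noiseless fractions on the grid", {
  obs <- mixture_mid(galactose, two_pop(0.9, 0.1))
  d <- fit_mixture(obs, galactose)
  pops <- d$populations
  expect_equal(pops$f[pops$p == 0.9], 0.1, tolerance = 1e-6)
  expect_equal(pops$f[1], 0.9, tolerance = 1e-6)
  expect_equal(d$highly_labeled_fraction, 10, tolerance = 1e-4)
  # pure natural observation: single population at the natural component
  dn <- fit_mixture(natural_abundance_mid(6, 0.0107), galactose)
  expect_equal(dn$populations$f[1], 1, tolerance = 1e-6)
  expect_equal(dn$total_labeled_fraction, 0, tolerance = 1e-4)
  # duplicate grid entries are deduplicated with a warning, not an error
  expect_warning(fit_mixture(obs, galactose, p_grid = c(0.5, 0.5, 0.9)),
                 "duplicate")
})

test_that("the two estimators agree on noiseless single-population data", {
  # total labeled mass: the estimators agree at any enrichment
  for (p_lab in c(0.5, 0.7, 0.9, 1)) {
    for (f_lab in c(0.03, 0.1, 0.3)) {
      obs <- mixture_mid(galactose, two_pop(p_lab, f_lab))
      d_strip <- deconvolve_mid(obs, galactose, method = "strip")
      d_fit <- deconvolve_mid(obs, galactose, method = "fit")
      expect_lt(abs(d_strip$total_labeled_fraction -
                      d_fit$total_labeled_fraction), 1)
      # highly labeled mass: agreement within 1 point holds in the
      # high-enrichment regime of newly synthesized material (p >= 0.9);
      # at moderate p the population's own below-threshold binomial tail
      # separates the shift-level and population-level criteria.
      if (p_lab >= 0.9) {
        expect_lt(abs(d_strip$highly_labeled_fraction -
                        d_fit$highly_labeled_fraction), 1)
      }
    }
  }
})

test_that("highly labeled fraction is monotone in true fraction and threshold", {
  fractions <- c(0.02, 0.05, 0.1, 0.2, 0.4)
  got <- vapply(fractions, function(f) {
    obs <- mixture_mid(galactose, two_pop(0.9, f))
    deconvolve_mid(obs, galactose)$highly_labeled_fraction
  }, numeric(1))
  expect_true(all(diff(got) > 0))
  # lowering the threshold never decreases the highly labeled fraction
  obs <- mixture_mid(galactose,
                     label_populations(c(0.0107, 0.4, 0.9),
                                       c(0.8, 0.1, 0.1)))
  by_thr <- vapply(c(0.7, 0.5, 0.3, 0.1), function(thr) {
    deconvolve_mid(obs, galactose, threshold = thr)$highly_labeled_fraction
  }, numeric(1))
  expect_true(all(diff(by_thr) >= -1e-9))
})

test_that("noisy mixture fit is calibrated: f within 0.01 in >= 95% of replicates", {
  n_rep <- 200
  hits <- 0L
  for (r in seq_len(n_rep)) {
    obs <- simulate_mid(galactose, two_pop(0.9, 0.07), n_ions = 1e5,
                        seed = 1000 + r)
    d <- fit_mixture(obs, galactose)
    f_hat <- 1 - d$populations$f[1]
    hits <- hits + (abs(f_hat - 0.07) <= 0.01)
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("deconvolution errors are informative", {
  no_lab <- fragment_spec("inert", 4, 0)
  obs <- c(0.7, 0.1, 0.1, 0.05, 0.05)
  expect_error(
    classify_isotopomers(strip_natural_abundance(obs, no_lab, p_nat = 0)),
    "no labelable"
  )
  expect_error(fit_mixture(obs, galactose), "length")
})
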