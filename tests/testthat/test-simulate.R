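test_that("simulated MIDs are deterministic and concentrate on the truth", {
  pops <- two_pop(0.9, 0.1)
  # noiseless limit is exactly the mixture model
  expect_equal(simulate_mid(galactose, pops, n_ions = 0),
               mixture_mid(galactose, pops), tolerance = 1e-12)
  # identical seed, identical draw; different seed differs
  a <- simulate_mid(galactose, pops, n_ions = 1e4, seed = 3)
  b <- simulate_mid(galactose, pops, n_ions = 1e4, seed = 3)
  c <- simulate_mid(galactose, pops, n_ions = 1e4, seed = 4)
  expect_identical(a, b)
  expect_false(identical(a, c))
  expect_equal(sum(a), 1, tolerance = 1e-12)
  expect_error(simulate_mid(galactose, pops, n_ions = 100), "seed")
  # a pure natural-abundance scenario draws from the natural MID
  nat_only <- label_populations(natural_13c_abundance(), 1)
  expect_equal(simulate_mid(galactose, nat_only, n_ions = 0),
               natural_abundance_mid(6), tolerance = 1e-12)
  # multinomial concentration at 1e7 ions: TV distance < 0.005
  truth <- mixture_mid(galactose, pops)
  for (s in 1:5) {
    noisy <- simulate_mid(galactose, pops, n_ions = 1e7, seed = s)
    expect_lt(sum(abs(noisy - truth)) / 2, 0.005)
  }
})

test_that("simulate_mid leaves the caller's RNG state untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_mid(galactose, two_pop(0.9, 0.1), n_ions = 1e3,
                         seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("labeling time course follows 1 - exp(-kt)", {
  expect_equal(simulate_labeling_timecourse(0, c(1, 5, 24)), c(0, 0, 0))
  expect_equal(simulate_labeling_timecourse(0.092, 1), 1 - exp(-0.092))
  # asymptote
  expect_equal(simulate_labeling_timecourse(0.5, 1e6), 1)
  # round trip with the rates module (fraction reported in percent)
  f <- simulate_labeling_timecourse(0.092, 1)
  expect_equal(turnover_rate(100 * f), 0.092, tolerance = 1e-12)
  expect_error(simulate_labeling_timecourse(0.1, -1), "non-negative")
  expect_error(simulate_labeling_timecourse(-0.1, 1), "non-negative")
})

test_that("acetate-labeled fragments never exceed the even-carbon shift", {
  # p = 1 on N/2 labelable positions, no background: support ends at N/2
  m <- simulate_mid(palmitate_acetate,
                    label_populations(c(0, 1), c(0.3, 0.7)),
                    p_nat = 0, n_ions = 1e5, seed = 8)
  expect_true(all(m[(8 + 2):17] == 0))
})

test_that("scenario construction validates its inputs", {
  frags <- list(galactose = galactose, glycerol = glycerol)
  expect_error(simulation_scenario(frags, c(galactose = 0.1)),
               "turnover_rates")
  expect_error(simulation_scenario(frags,
                                   c(galactose = 0.1, glycerol = 0.1),
                                   timepoints = c(2, 1)),
               "strictly increasing")
  sc <- simulation_scenario(frags, c(galactose = 0.092, glycerol = 0.063),
                            timepoints = c(0.5, 1), n_ions = 0, seed = 2)
  expect_s3_class(sc, "simulation_scenario")
  expect_equal(sc$p_label, c(galactose = 0.99, glycerol = 0.99))
})

test_that("simulated experiments are reproducible and self-consistent", {
  frags <- list(galactose = galactose, glycerol = glycerol)
  sc <- simulation_scenario(frags, c(galactose = 0.092, glycerol = 0.063),
                            timepoints = c(0.5, 1), n_ions = 1e4, seed = 2)
  e1 <- simulate_experiment(sc)
  e2 <- simulate_experiment(sc)
  expect_identical(e1, e2)
  expect_equal(nrow(e1$mids), 4L)          # 2 fragments x 2 timepoints
  expect_equal(nrow(e1$truth), 4L)
  # ragged padding: glycerol rows stop at m3
  gly <- e1$mids[e1$mids$fragment_name == "glycerol", ]
  expect_true(all(is.na(gly$m5)))
  expect_equal(e1$truth$f_labeled_true,
               1 - exp(-e1$truth$k_true * e1$truth$time_h))
  # a zero-label scenario yields zero fractions and zero rates everywhere
  sc0 <- simulation_scenario(frags, c(galactose = 0, glycerol = 0),
                             timepoints = 1, n_ions = 0, seed = 1)
  out0 <- run_scenario_pipeline(sc0)
  expect_equal(out0$labeled_fraction_pct, c(0, 0), tolerance = 1e-6)
  expect_equal(out0$k_recovered, c(0, 0), tolerance = 1e-6)
})

test_that("adding a fragment does not perturb the other substreams", {
  frags2 <- list(galactose = galactose, glycerol = glycerol)
  frags3 <- c(frags2, list(`16:0` = palmitate_acetate))
  k2 <- c(galactose = 0.092, glycerol = 0.063)
  k3 <- c(k2, `16:0` = 0.073)
  e2 <- simulate_experiment(simulation_scenario(frags2, k2, n_ions = 1e4,
                                                seed = 5))
  e3 <- simulate_experiment(simulation_scenario(frags3, k3, n_ions = 1e4,
                                                seed = 5))
  shared <- e3$mids$fragment_name %in% names(frags2)
  expect_equal(e3$mids[shared, names(e2$mids)], e2$mids,
               ignore_attr = TRUE)
})

test_that("noiseless pipeline recovery is exact with the model-based estimator", {
  path <- system.file("extdata", "scenario_bicarbonate_mid.yaml",
                      package = "midtrace")
  sc <- read_scenario(path)
  out <- run_scenario_pipeline(sc, method = "fit",
                               p_grid = c(seq(0.05, 0.95, 0.05), 0.99))
  expect_equal(out$k_recovered, out$k_true, tolerance = 1e-6)
  # default stripping estimator agrees to its shift-truncation bias
  out_strip <- run_scenario_pipeline(sc)
  expect_equal(out_strip$k_recovered, out_strip$k_true, tolerance = 1e-3)
})

test_that("noisy recovery error shrinks as the ion count grows", {
  frags <- list(galactose = galactose)
  errs <- vapply(c(1e3, 1e5, 1e7), function(n_ions) {
    per_seed <- vapply(1:10, function(s) {
      sc <- simulation_scenario(frags, c(galactose = 0.092),
                                n_ions = n_ions, seed = s)
      abs(run_scenario_pipeline(sc)$rel_error)
    }, numeric(1))
    mean(per_seed)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("scenario YAML round trips", {
  sc <- simulation_scenario(list(galactose = galactose),
                            c(galactose = 0.092), n_ions = 1e5, seed = 42)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(sc, path)
  sc2 <- read_scenario(path)
  expect_equal(sc2$turnover_rates, sc$turnover_rates)
  expect_equal(sc2$n_ions, sc$n_ions)
  expect_equal(sc2$seed, sc$seed)
  expect_identical(simulate_experiment(sc2), simulate_experiment(sc))
})
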