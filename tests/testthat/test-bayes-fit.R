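# Small, fast fixtures: one or two synthetic single-site titrations.
fit_fixture <- function(seed = 1, n_exp = 2, sigma = 0.75e-9) {
  thermo <- thermo_params("single_site", Kd1 = 1.81, dH1 = -3.4)
  nu <- nuisance_params(f_comp = 1.43, dH_dil = -0.5, q_int = 1e-9,
                        sigma = sigma)
  lapply(seq_len(n_exp), function(e) {
    s <- test_schedule(syringe_conc = 15 * 60, cell_conc = 60)
    generate_experiment(thermo, nu, s, seed = seed * 100 + e)
  })
}

truth_theta <- function(n_exp, sigma = 0.75e-9) {
  c(log10(1.81), -3.4, rep(c(1.43, -0.5, 1e-9, log10(sigma)), n_exp))
}

test_that("log posterior contract: bounds, maximum, and layout", {
  exps <- fit_fixture()
  pr <- prior_spec()
  th <- truth_theta(2)
  expect_true(is.finite(log_posterior(th, exps, "single_site", pr)))

  # any bound violation gives -Inf
  bad <- th; bad[1] <- 5 # log10 Kd above its prior
  expect_identical(log_posterior(bad, exps, "single_site", pr), -Inf)
  bad <- th; bad[3] <- 2.5 # f_comp above 2
  expect_identical(log_posterior(bad, exps, "single_site", pr), -Inf)

  # wrong layout length errors
  expect_error(log_posterior(th[-1], exps, "single_site", pr), "length")

  # zero-noise data evaluated at the generating parameters attains the
  # analytic likelihood maximum for the stated sigma
  exps0 <- fit_fixture(sigma = 1e-300)
  sig <- 1e-10
  th0 <- c(log10(1.81), -3.4, rep(c(1.43, -0.5, 1e-9, log10(sig)), 2))
  n_obs <- sum(lengths(lapply(exps0, `[[`, "heats")))
  analytic_max <- -n_obs * (log(sig) + 0.5 * log(2 * pi))
  expect_equal(log_posterior(th0, exps0, "single_site", pr), analytic_max,
               tolerance = 1e-6)
})

test_that("fast likelihood path agrees with the plain-R forward model", {
  exps <- fit_fixture()
  pr <- prior_spec()
  set.seed(3)
  for (i in 1:10) {
    th <- truth_theta(2) * runif(10, 0.9, 1.1)
    th[3] <- min(th[3], 2); th[7] <- min(th[7], 2)
    th[4] <- max(min(th[4], -0.01), -2.9); th[8] <- max(min(th[8], -0.01), -2.9)
    ll <- 0
    for (e in 1:2) {
      nu <- nuisance_params(f_comp = th[2 + 4 * (e - 1) + 1],
                            dH_dil = th[2 + 4 * (e - 1) + 2],
                            q_int = th[2 + 4 * (e - 1) + 3],
                            sigma = 10^th[2 + 4 * (e - 1) + 4])
      pred <- injection_heats(thermo_params("single_site", Kd1 = 10^th[1],
                                            dH1 = th[2]),
                              nu, exps[[e]]$schedule, engine = "R")
      ll <- ll + sum(dnorm(exps[[e]]$heats, pred, nu$sigma, log = TRUE))
    }
    expect_equal(log_posterior(th, exps, "single_site", pr), ll,
                 tolerance = 1e-10)
  }
})

test_that("log posterior responds consistently to finite parameter steps", {
  # central-difference gradient at two step sizes (Richardson consistency)
  exps <- fit_fixture()
  pr <- prior_spec()
  th <- truth_theta(2)
  grad_fd <- function(h) {
    sapply(seq_along(th), function(k) {
      up <- th; up[k] <- up[k] + h
      dn <- th; dn[k] <- dn[k] - h
      (log_posterior(up, exps, "single_site", pr) -
       log_posterior(dn, exps, "single_site", pr)) / (2 * h)
    })
  }
  g1 <- grad_fd(1e-5)
  g2 <- grad_fd(5e-6)
  expect_equal(g1, g2, tolerance = 1e-3)
})

test_that("maximum-likelihood start recovers noise-free truth within 1%", {
  # varied injection volumes so the per-mole dilution heat and the constant
  # intercept are separately identifiable
  thermo <- thermo_params("single_site", Kd1 = 1.81, dH1 = -3.4)
  nu <- nuisance_params(f_comp = 1.43, dH_dil = -0.5, q_int = 1e-9,
                        sigma = 1e-300)
  exps <- lapply(1:2, function(e) {
    s <- injection_schedule(V0 = 1.4e-3, dV = rep(c(5e-6, 10e-6, 15e-6), 9),
                            syringe_conc = 900, cell_conc = 60)
    generate_experiment(thermo, nu, s, seed = e)
  })
  mle <- max_likelihood_start(exps, "single_site")
  expect_equal(10^mle[["log10_Kd1"]], 1.81, tolerance = 0.01)
  expect_equal(mle[["dH1"]], -3.4, tolerance = 0.01)
  expect_equal(mle[["f_comp[1]"]], 1.43, tolerance = 0.01)
  expect_equal(mle[["dH_dil[1]"]], -0.5, tolerance = 0.01)
})

test_that("maximum-likelihood start respects arbitrary prior support", {
  exps <- fit_fixture(n_exp = 1)
  expect_error(max_likelihood_start(list(), "single_site"), "at least one")
  set.seed(11)
  for (i in 1:5) {
    lo <- runif(1, -2, 0); hi <- lo + runif(1, 0.5, 3)
    pr <- prior_spec(log10_Kd = c(lo, hi),
                     dH = sort(runif(2, -10, 10)),
                     f_comp = c(0.5, 1.8))
    mle <- max_likelihood_start(exps, "single_site", pr)
    layout_names <- fit_param_names("single_site", 1, pr)
    expect_named(mle, layout_names)
    expect_gte(mle[["log10_Kd1"]], lo)
    expect_lte(mle[["log10_Kd1"]], hi)
    expect_gte(mle[["f_comp[1]"]], 0.5)
    expect_lte(mle[["f_comp[1]"]], 1.8)
  }
})

test_that("sampling is bit-reproducible for a fixed seed", {
  exps <- fit_fixture(n_exp = 1)
  st <- mcmc_settings(n_walkers = 20, n_steps = 200, seed = 99)
  p1 <- run_mcmc(exps, "single_site", settings = st)
  p2 <- run_mcmc(exps, "single_site", settings = st)
  expect_identical(p1$samples, p2$samples)
  expect_identical(p1$log_prob, p2$log_prob)
  # and a different seed gives a different chain
  p3 <- run_mcmc(exps, "single_site",
                 settings = mcmc_settings(n_walkers = 20, n_steps = 200,
                                          seed = 100))
  expect_false(identical(p1$samples, p3$samples))
})

test_that("walker count must accommodate the free-parameter dimension", {
  exps <- fit_fixture(n_exp = 2) # 10 free parameters
  expect_error(run_mcmc(exps, "single_site",
                        settings = mcmc_settings(n_walkers = 10,
                                                 n_steps = 100)),
               "twice")
})

test_that("independent chains agree on the credibility region", {
  exps <- fit_fixture(seed = 5)
  cr <- lapply(c(21, 22), function(sd) {
    post <- run_mcmc(exps, "single_site",
                     settings = mcmc_settings(n_walkers = 20, n_steps = 1500,
                                              seed = sd))
    credibility_region(post, "Kd1")
  })
  # medians within a few percent, interval ends within Monte-Carlo error
  expect_equal(cr[[1]][["median"]], cr[[2]][["median"]], tolerance = 0.05)
  expect_equal(log(cr[[1]][["low"]]), log(cr[[2]][["low"]]), tolerance = 0.15)
  expect_equal(log(cr[[1]][["high"]]), log(cr[[2]][["high"]]),
               tolerance = 0.15)
})

test_that("credibility regions follow the quantile contract", {
  # hand-built degenerate posterior: every draw identical
  fake <- structure(list(
    samples = matrix(c(rep(2, 100), 1:100), ncol = 2,
                     dimnames = list(NULL, c("log10_Kd1", "dH1"))),
    param_names = c("log10_Kd1", "dH1"), model_id = "single_site",
    kd_log = TRUE), class = "itc_posterior")
  expect_equal(credibility_region(fake, "log10_Kd1"),
               c(low = 2, median = 2, high = 2))
  # Kd requested on the natural scale back-transforms the log draws
  expect_equal(credibility_region(fake, "Kd1"),
               c(low = 100, median = 100, high = 100))

  # uniform grid 1..10000: type-7 quantile oracle
  fake2 <- structure(list(
    samples = matrix(as.numeric(1:10000), ncol = 1,
                     dimnames = list(NULL, "dH1")),
    param_names = "dH1", model_id = "single_site", kd_log = TRUE),
    class = "itc_posterior")
  cr <- credibility_region(fake2, "dH1")
  expect_equal(cr[["low"]], 250.975)
  expect_equal(cr[["median"]], 5000.5)
  expect_equal(cr[["high"]], 9750.025)
  expect_error(credibility_region(fake2, "nope"), "unknown parameter")

  # report string matches the table style
  expect_equal(format_credibility(0.94, 1.81, 3.90), "0.94≤1.8≤3.9")
})

test_that("two-site summaries are canonically ordered per draw", {
  # synthetic posterior in which the two steps are randomly relabelled
  set.seed(8)
  n <- 2000
  kd_a <- rnorm(n, log10(0.5), 0.05); kd_b <- rnorm(n, log10(6.3), 0.05)
  dh_a <- rnorm(n, -1.4, 0.05); dh_b <- rnorm(n, -4.6, 0.05)
  flip <- runif(n) < 0.5
  S <- cbind(ifelse(flip, kd_b, kd_a), ifelse(flip, kd_a, kd_b),
             ifelse(flip, dh_b, dh_a), ifelse(flip, dh_a, dh_b),
             rnorm(n, 0.66, 0.01))
  colnames(S) <- c("log10_Kd1", "log10_Kd2", "dH1", "dH2", "f_comp[1]")
  fake <- structure(list(samples = S, param_names = colnames(S),
                         model_id = "two_site", kd_log = TRUE),
                    class = "itc_posterior")
  k1 <- credibility_region(fake, "Kd1")
  k2 <- credibility_region(fake, "Kd2")
  d1 <- credibility_region(fake, "dH1")
  expect_equal(k1[["median"]], 0.5, tolerance = 0.05)
  expect_equal(k2[["median"]], 6.3, tolerance = 0.05)
  expect_equal(d1[["median"]], -1.4, tolerance = 0.05)
})

test_that("pooling replicates narrows the Kd credibility interval", {
  exps <- fit_fixture(seed = 31, n_exp = 2)
  st <- function(sd) mcmc_settings(n_walkers = 20, n_steps = 1200, seed = sd)
  post1 <- run_mcmc(exps[1], "single_site", settings = st(7))
  post2 <- run_mcmc(exps, "single_site", settings = st(7))
  w1 <- diff(log(credibility_region(post1, "Kd1")[c("low", "high")]))
  w2 <- diff(log(credibility_region(post2, "Kd1")[c("low", "high")]))
  expect_lt(w2, w1)
})

test_that("prior-only sampling reproduces the uniform marginals", {
  # strict KS check on the minimal (two-parameter) layout, where the
  # ensemble decorrelates quickly enough for thinned draws to be close to
  # independent
  post <- run_mcmc(list(), "single_site",
                   settings = mcmc_settings(n_walkers = 20, n_steps = 20000,
                                            seed = 17),
                   prior_only = TRUE)
  for (par in c("log10_Kd1", "dH1")) {
    x <- post$samples[, par]
    x <- x[seq(1, length(x), by = 100)]
    rng <- if (par == "log10_Kd1") c(-3, 4) else c(-20, 20)
    ks <- suppressWarnings(ks.test(x, "punif", rng[1], rng[2]))
    expect_gt(ks$p.value, 0.01)
  }
  # with per-experiment nuisance dimensions added, mixing is slower; check
  # that the marginals still fill their support with roughly central mass
  exps <- fit_fixture(n_exp = 1)
  post6 <- run_mcmc(exps, "single_site",
                    settings = mcmc_settings(n_walkers = 20, n_steps = 4000,
                                             seed = 18),
                    prior_only = TRUE)
  f <- post6$samples[, "f_comp[1]"]
  expect_gt(min(f), 0); expect_lt(max(f), 2)
  expect_equal(mean(f), 1, tolerance = 0.3)
  expect_equal(mean(post6$samples[, "dH1"]), 0, tolerance = 4)
})

test_that("acceptance-rate bookkeeping is sane on a healthy fit", {
  exps <- fit_fixture(n_exp = 1)
  post <- run_mcmc(exps, "single_site",
                   settings = mcmc_settings(n_walkers = 20, n_steps = 300,
                                            seed = 2))
  expect_gt(post$acceptance_rate, 0.01)
  expect_lte(post$acceptance_rate, 1)
  expect_true(all(is.finite(post$log_prob)))
})

test_that("the 95% region covers the generating Kd across repeat studies", {
  # repeated-simulation coverage at desk scale: one replicate per study,
  # reduced sampler; the generating Kd should fall inside the 95% region
  # in at least 90% of repeats
  hits <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    exps <- fit_fixture(seed = 300 + r, n_exp = 1)
    post <- run_mcmc(exps, "single_site",
                     settings = mcmc_settings(n_walkers = 16, n_steps = 800,
                                              seed = r))
    cr <- credibility_region(post, "Kd1")
    if (cr[["low"]] <= 1.81 && 1.81 <= cr[["high"]]) hits <- hits + 1L
  }
  expect_gte(hits, 0.9 * n_rep)
})
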