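test_that("chronic daily intake follows the exposure equation", {
  sc <- exposure_scenario("x", ir_veg = 100, ef = 365, ed = 1, bw = 60,
                          rfd = setNames(rep(1, 6), metal_ids()))
  expect_equal(cdi(1, sc), 0.1 * 1 * 365 * 1 / (60 * 365))
  expect_equal(cdi(0, sc), 0)
  # with AT = ED * 365 the duration cancels
  sc30 <- exposure_scenario("x", ir_veg = 100, ef = 365, ed = 30, bw = 60,
                            rfd = setNames(rep(1, 6), metal_ids()))
  expect_equal(cdi(2.5, sc30), cdi(2.5, sc))
  expect_error(exposure_scenario("x", ir_veg = -1, ef = 365, ed = 1, bw = 60,
                                 rfd = setNames(rep(1, 6), metal_ids())),
               "positive")
})

test_that("hazard quotient and hazard index are exact ratios and sums", {
  expect_equal(hq(1e-3, 1e-3), 1)
  expect_equal(hq(2e-3, 1e-3), 2)
  expect_error(hq(1, 0), "positive")
  res <- hi(c(1, 2, 3))
  expect_equal(res$hi, 6)
  expect_false(res$safe)
  expect_true(hi(rep(0, 6))$safe)
  expect_equal(hi(c(3, 1, 2))$hi, hi(c(1, 2, 3))$hi)
  expect_error(hi(c(-1, 1)), "negative")
})

test_that("method-of-moments log-normal fit inverts exactly", {
  f <- fit_lognormal(22.1, 19.6)
  expect_equal(f$sigma, 0.762, tolerance = 1e-3)
  expect_equal(f$mu, 2.806, tolerance = 1e-3)
  # analytic moments of the fitted distribution reproduce the inputs
  expect_equal(exp(f$mu + f$sigma^2 / 2), 22.1, tolerance = 1e-9)
  expect_equal(sqrt((exp(f$sigma^2) - 1) * exp(2 * f$mu + f$sigma^2)), 19.6,
               tolerance = 1e-9)
  expect_equal(fit_lognormal(1, 1)$sigma, sqrt(log(2)))
  expect_equal(fit_lognormal(5, 0)$sigma, 0)
  expect_error(fit_lognormal(0, 1), "positive")
})

test_that("content sampling is reproducible, bounded and quantile-correct", {
  # moments of LN(0,1): mean e^0.5, sd sqrt((e-1)e)
  d <- content_distribution("Cd", "all",
                            mean = exp(0.5), sd = sqrt((exp(1) - 1) * exp(1)))
  expect_equal(d$mu, 0, tolerance = 1e-12)
  expect_equal(d$sigma, 1, tolerance = 1e-12)
  x1 <- sample_contents(d, 1000, seed = 4)
  x2 <- sample_contents(d, 1000, seed = 4)
  expect_identical(x1, x2)
  p90 <- quantile(sample_contents(d, 1e5, seed = 5), 0.9, type = 7)
  expect_lt(abs(p90 - exp(1.2816)) / exp(1.2816), 0.02)

  # truncation keeps draws inside bounds
  dt <- content_distribution("Cd", "all", mean = 1, sd = 1,
                             minimum = 0.5, maximum = 2)
  xt <- sample_contents(dt, 500, seed = 6)
  expect_true(all(xt >= 0.5 & xt <= 2))
  # sigma = 0 collapses to the (clipped) mean
  d0 <- content_distribution("Cd", "all", mean = 5, sd = 0,
                             minimum = 0, maximum = 4)
  expect_equal(sample_contents(d0, 10), rep(4, 10))
  # infeasible bounds: acceptance probability below 1e-4
  dbad <- content_distribution("Cd", "all", mean = 1, sd = 1,
                               minimum = 500, maximum = 501)
  expect_error(sample_contents(dbad, 10, seed = 1), "bounds")
})

test_that("Monte Carlo risk obeys its structural invariants", {
  sc <- default_scenario("adult")
  dists <- lapply(metal_ids(), function(m)
    content_distribution(m, "all", mean = 0.2, sd = 0.15))
  names(dists) <- metal_ids()
  rd <- mc_risk(dists, sc, n_iter = 2000, seed = 9)
  expect_equal(rd$hi_draws, rowSums(rd$hq_draws), tolerance = 1e-12)
  expect_true(all(rd$hq_draws >= 0))
  # bit-identical reproducibility
  rd2 <- mc_risk(dists, sc, n_iter = 2000, seed = 9)
  expect_identical(rd$hq_draws, rd2$hq_draws)
  # doubling every RfD halves every draw under the same seed
  sc2 <- sc
  sc2$rfd <- 2 * sc$rfd
  rdh <- mc_risk(dists, sc2, n_iter = 2000, seed = 9)
  expect_equal(rdh$hq_draws, rd$hq_draws / 2, tolerance = 1e-12)
  expect_equal(rdh$hi_draws, rd$hi_draws / 2, tolerance = 1e-12)
})

test_that("degenerate distributions collapse Monte Carlo to the point estimate", {
  sc <- default_scenario("child")
  contents <- c(Cd = 0.3, Cr = 0.05, Cu = 0.4, Pb = 0.2, V = 0.5, Zn = 8)
  dists <- lapply(metal_ids(), function(m)
    content_distribution(m, "all", mean = contents[[m]], sd = 0))
  names(dists) <- metal_ids()
  rd <- mc_risk(dists, sc, n_iter = 500, seed = 1)
  det <- deterministic_risk(contents, sc)
  expect_equal(unique(rd$hi_draws), det$hi, tolerance = 1e-12)
  rs <- summarize_risk(rd)
  expect_equal(rs$hi_p, det$hi, tolerance = 1e-12)
  expect_equal(rs$hq_p, det$hq, tolerance = 1e-12)
})

test_that("single-metal HI P90 matches the closed-form log-normal quantile", {
  sc <- default_scenario("adult")
  dist <- content_distribution("Cd", "all", mean = 0.5, sd = 0.4)
  rd <- mc_risk(list(Cd = dist), sc, n_iter = 10000, seed = 13)
  konst <- (sc$ir_veg / 1000) * sc$ef * sc$ed / (sc$bw * sc$at) / sc$rfd[["Cd"]]
  analytic <- konst * qlnorm(0.9, dist$mu, dist$sigma)
  p90 <- summarize_risk(rd, 0.9)$hi_p
  expect_lt(abs(p90 - analytic) / analytic, 0.02)
})

test_that("risk summary percentiles and contributions behave", {
  sc <- default_scenario("adult")
  d <- content_distribution("Cd", "all", mean = 0.2, sd = 0.1)
  rd1 <- mc_risk(list(Cd = d), sc, n_iter = 1, seed = 3)
  rs1 <- summarize_risk(rd1, 0.9)
  expect_equal(rs1$hi_p, rd1$hi_draws[1])

  dists <- list(Cd = content_distribution("Cd", "all", 0.2, 0.1),
                Pb = content_distribution("Pb", "all", 0.2, 0.1))
  sc_eq <- sc
  sc_eq$rfd[] <- 1e-3
  rs <- summarize_risk(mc_risk(dists, sc_eq, n_iter = 10000, seed = 21))
  expect_equal(sum(rs$contribution), 1, tolerance = 1e-9)
  expect_equal(unname(rs$contribution["Cd"]), 0.5, tolerance = 0.02)
  expect_error(summarize_risk(rd1, 1.5))
})

test_that("receptor scaling: child table is adult table times one constant", {
  adult <- default_scenario("adult")
  child <- default_scenario("child")
  dists <- content_distributions_from_data(
    generate_dataset(generator_config(seed = 12))$veg)
  ra <- mc_risk(dists, adult, n_iter = 2000, seed = 5)
  rc <- mc_risk(dists, child, n_iter = 2000, seed = 5)
  konst <- (child$ir_veg / child$bw) / (adult$ir_veg / adult$bw)
  expect_equal(rc$hq_draws, ra$hq_draws * konst, tolerance = 1e-12)
})

test_that("mc_risk refuses a metal without a reference dose", {
  sc <- default_scenario("adult")
  sc$rfd <- sc$rfd[names(sc$rfd) != "Zn"]
  dists <- list(Zn = content_distribution("Zn", "all", 5, 2))
  expect_error(mc_risk(dists, sc, n_iter = 10, seed = 1), "Zn")
})
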