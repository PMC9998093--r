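test_that("closed-form protomer concentration matches the mass-balance oracle", {
  ctots <- c(1e-3, 0.1, 1, 5, 20, 100)
  kas <- c(1e-3, 0.01, 0.1, 0.625, 2, 10)
  for (ct in ctots) {
    for (ka in kas) {
      c1 <- isodesmic_protomer_conc(ct, ka)
      expect_equal(c1, oracle_protomer_conc(ct, ka), tolerance = 1e-8)
      expect_gte(c1, 0)
      expect_lte(c1, ct)
    }
  }
})

test_that("protomer concentration limits and input validation", {
  expect_equal(isodesmic_protomer_conc(20, 0), 20)
  expect_lt(isodesmic_protomer_conc(20, 1e9), 1e-3)
  # small-KA series branch is continuous with the closed form
  expect_equal(isodesmic_protomer_conc(1, 1e-10),
               oracle_protomer_conc(1, 1e-10), tolerance = 1e-10)
  expect_error(isodesmic_protomer_conc(-1, 1), "non-negative")
  expect_error(isodesmic_protomer_conc(1, -1), "non-negative")
})

test_that("species distribution has geometric decay, unit phi sum and mass balance", {
  d <- isodesmic_distribution(20, KA = 0.625, nmax = 30)
  ratios <- d$conc[-1] / d$conc[-30]
  expect_equal(ratios, rep(ratios[1], 29), tolerance = 1e-12)
  expect_lt(ratios[1], 1)
  expect_equal(sum(d$phi), 1, tolerance = 1e-9)
  mass <- sum(d$i * d$conc)
  expect_lte(mass, 20 + 1e-12)
  # closed-form infinite-series mass: c1 / (1 - KA c1)^2
  c1 <- d$conc[1]
  expect_equal(sum(d$i * d$conc) + 0 * mass, mass)
  mass_inf <- c1 / (1 - 0.625 * c1)^2
  expect_equal(mass_inf, 20, tolerance = 1e-3)
  expect_lt(abs(attr(d, "mass_residual")), 0.01)
})

test_that("distribution degenerate cases and errors", {
  d0 <- isodesmic_distribution(20, KA = 0, nmax = 5)
  expect_equal(d0$conc, c(20, 0, 0, 0, 0))
  expect_equal(d0$phi, c(1, 0, 0, 0, 0))
  expect_error(isodesmic_distribution(20, KA = 1, nmax = 0), "nmax")
  expect_error(isodesmic_distribution(20), "supply")
  # KD route equals KA route
  expect_equal(isodesmic_distribution(10, KD = 2)$conc,
               isodesmic_distribution(10, KA = 0.5)$conc)
})

test_that("dimer-oligomer mass balance agrees with a bisection oracle", {
  # oracle: bisect f(cd) = KA cd^(i/2) - (ctot - cd)/(i/2) on [0, ctot]
  bisect <- function(ctot, ka, i) {
    f <- function(cd) ka * cd^(i / 2) - (ctot - cd) / (i / 2)
    lo <- 0; hi <- ctot
    for (k in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) < 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  m <- solve_dimer_oligomer(10, 1, 8)
  expect_equal(m$c_dimer, bisect(10, 1, 8), tolerance = 1e-10)
  # both the equilibrium and conservation equations hold
  expect_equal(1 * m$c_dimer^4, m$c_i, tolerance = 1e-9)
  expect_lt(abs(m$c_dimer + 4 * m$c_i - 10), 1e-9 * 10)
  expect_equal(m$phi_dimer + m$phi_i, 1)
})

test_that("dimer-oligomer degenerate cases and validation", {
  m0 <- solve_dimer_oligomer(10, 0, 8)
  expect_equal(m0$c_dimer, 10)
  expect_equal(m0$c_i, 0)
  z <- solve_dimer_oligomer(0, 1, 8)
  expect_equal(c(z$c_dimer, z$c_i), c(0, 0))
  expect_error(solve_dimer_oligomer(10, 1, 7), "even")
  expect_error(solve_dimer_oligomer(10, 1, 2), "even")
})

test_that("weight-average molecular weight behaves like the MALS observable", {
  # monodisperse limit
  d0 <- isodesmic_distribution(20, KA = 0, nmax = 10)
  expect_equal(average_mw(d0, 80), 80)
  # two species at equal mass concentration: sizes 1 and 2, c2 = c1/2
  d <- tibble::tibble(i = c(1, 2), conc = c(1, 0.5))
  # direct hand sum: (1*80^2 + 0.5*160^2) / (1*80 + 0.5*160)
  expect_equal(average_mw(d, 80), (1 * 80^2 + 0.5 * 160^2) / (1 * 80 + 0.5 * 160))
  # non-decreasing in KA at fixed ctot
  kas <- c(0, 0.1, 0.5, 1, 5)
  mws <- vapply(kas, function(ka) {
    average_mw(isodesmic_distribution(20, KA = ka, nmax = 30), 80)
  }, numeric(1))
  expect_true(all(diff(mws) > 0))
  expect_error(average_mw(tibble::tibble(i = 1:2, conc = c(0, 0)), 80), "undefined")
})

test_that("CG-MALS fit recovers the generative KD from noiseless data", {
  conc <- c(1, 2, 5, 10, 20, 40, 80)
  mw <- vapply(conc, function(cc) {
    average_mw(isodesmic_distribution(monomer_to_protomer(cc), KD = 1.6, nmax = 30), 80)
  }, numeric(1))
  fit <- fit_cgmals(data.frame(conc_monomer = conc, mw = mw))
  expect_equal(fit$kd, 1.6, tolerance = 1e-6)
  expect_equal(unname(fit$mw_protomer), 80, tolerance = 1e-6)
  expect_s3_class(glance(fit), "tbl_df")
})

test_that("CG-MALS fit handles merged datasets and the no-association regime", {
  conc <- c(1, 2, 5, 10, 20, 40)
  mw1 <- vapply(conc, function(cc) {
    average_mw(isodesmic_distribution(cc / 2, KD = 2, nmax = 30), 80)
  }, numeric(1))
  mw2 <- vapply(conc, function(cc) {
    average_mw(isodesmic_distribution(cc / 2, KD = 2, nmax = 30), 84)
  }, numeric(1))
  fit <- fit_cgmals(data.frame(conc_monomer = rep(conc, 2), mw = c(mw1, mw2),
                               dataset = rep(c("a", "b"), each = length(conc))))
  expect_equal(fit$kd, 2, tolerance = 1e-4)
  expect_equal(unname(fit$mw_protomer), c(80, 84), tolerance = 1e-4)
  # weak-association regime: the protomer mass tends to the plateau value
  weak <- vapply(conc, function(cc) {
    average_mw(isodesmic_distribution(cc / 2, KD = 1e3, nmax = 30), 80)
  }, numeric(1))
  fit0 <- fit_cgmals(data.frame(conc_monomer = conc, mw = weak), kd_start = 1e3)
  expect_equal(unname(fit0$mw_protomer), 80, tolerance = 1e-2)
  expect_gt(fit0$kd, 100)
  expect_error(fit_cgmals(data.frame(conc_monomer = 1:2, mw = c(80, 81))), ">= 3")
})

test_that("distribution export writes the table and JSON summary", {
  d <- isodesmic_distribution(10, KD = 1.6, nmax = 10)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_distribution(d, path)
  tab <- utils::read.table(path, header = TRUE)
  expect_equal(tab$conc, d$conc)
  js <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(js$KD, 1.6)
  expect_equal(js$nmax, 10)
})
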