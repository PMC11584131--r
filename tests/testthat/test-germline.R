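test_that("resolve_susceptible_allele follows the repair tree", {
  # no nuclease source, or no cutting
  expect_equal(resolve_susceptible_allele(germline_params(), FALSE)[["W"]], 1)
  p0 <- germline_params(q = 0, p = 0.3, delta = 0.9)
  expect_equal(resolve_susceptible_allele(p0, TRUE)[["W"]], 1)
  # complete conversion
  p1 <- germline_params(q = 1, p = 1)
  expect_equal(resolve_susceptible_allele(p1, TRUE)[["G"]], 1)
  # hand-enumerated branch products
  pp <- germline_params(q = 0.9, p = 0.8, delta = 0.4)
  d <- resolve_susceptible_allele(pp, TRUE)
  expect_equal(d[["W"]], 0.10)
  expect_equal(d[["G"]], 0.72)
  expect_equal(d[["U"]], 0.072)
  expect_equal(d[["R"]], 0.108)
})

test_that("resolve_drive_allele follows the excision tree", {
  inert <- germline_params(alpha_female = 0, alpha_male = 0, gamma = 0)
  expect_equal(resolve_drive_allele(inert, "female")[["G"]], 1)
  # branch products at the empirically motivated rates
  pp <- germline_params(alpha_female = 0.1, gamma = 0.001, epsilon = 1)
  d <- resolve_drive_allele(pp, "female")
  expect_equal(d[["V"]], 0.1)
  expect_equal(d[["S"]], 0.001)
  expect_equal(d[["G"]], 0.899)
  expect_equal(d[["W"]], 0)
  # full excision with full marker reversion
  rev <- germline_params(alpha_female = 1, gamma = 0, epsilon = 0)
  expect_equal(resolve_drive_allele(rev, "female")[["W"]], 1)
  # sex selects alpha
  ss <- germline_params(alpha_female = 0.4, alpha_male = 0.02, epsilon = 1)
  expect_equal(resolve_drive_allele(ss, "male")[["V"]], 0.02)
})

test_that("parameter domain is enforced", {
  expect_error(germline_params(q = 1.2), "\\[0, 1\\]")
  expect_error(germline_params(alpha_female = 0.7, gamma = 0.5),
               "alpha_female")
  expect_error(zygotic_params(z_maternal = -0.1), "z_maternal")
  expect_error(gamete_distribution(c("G", "W", "W"), "female",
                                   germline_params()), "2 X allele")
  expect_error(gamete_distribution(c("G", "W"), "male", germline_params()),
               "1 X allele")
})

test_that("gamete_distribution: segregation, homing, hand-derived law", {
  mendel <- germline_params(q = 0, alpha_female = 0, alpha_male = 0,
                            gamma = 0)
  d <- gamete_distribution(c("G", "W"), "female", mendel)
  expect_equal(d[["G"]], 0.5)
  expect_equal(d[["W"]], 0.5)
  full <- germline_params(q = 1, p = 1, alpha_female = 0, gamma = 0)
  expect_equal(gamete_distribution(c("G", "W"), "female", full)[["G"]], 1)
  # 0.5*resolve(G) + 0.5*resolve(W), hand-enumerated (~87% transmission)
  cal <- germline_params(q = 0.95, p = 0.78, delta = 0.4,
                         alpha_female = 0, alpha_male = 0, gamma = 0)
  d <- gamete_distribution(c("G", "W"), "female", cal)
  expect_equal(d[["G"]], 0.8705)
  expect_equal(d[["W"]], 0.025)
  expect_equal(d[["U"]], 0.0418)
  expect_equal(d[["R"]], 0.0627)
  # males: no homing target, but SSA still acts on the drive
  dm <- gamete_distribution("G", "male",
                            germline_params(alpha_male = 0.01, epsilon = 1,
                                            gamma = 0))
  expect_equal(dm[["V"]], 0.01)
  expect_equal(dm[["G"]], 0.99)
  expect_equal(gamete_distribution("W", "male", germline_params())[["W"]], 1)
  # S is a nuclease source for W but never excises
  ds <- gamete_distribution(c("S", "W"), "female", cal)
  expect_equal(ds[["S"]], 0.5)
  expect_equal(ds[["G"]], 0.5 * 0.741)
})

test_that("epsilon pins the SSA product class", {
  e1 <- germline_params(alpha_female = 0.3, epsilon = 1, gamma = 0)
  expect_equal(resolve_drive_allele(e1, "female")[["W"]], 0)
  e0 <- germline_params(alpha_female = 0.3, epsilon = 0, gamma = 0)
  expect_equal(resolve_drive_allele(e0, "female")[["V"]], 0)
})

test_that("every gamete law is a distribution (property sweep)", {
  set.seed(11)
  fg <- female_genotypes()
  for (i in 1:40) {
    par <- germline_params(q = runif(1), p = runif(1), delta = runif(1),
                           alpha_female = runif(1, 0, 0.5),
                           alpha_male = runif(1, 0, 0.5),
                           gamma = runif(1, 0, 0.4),
                           epsilon = runif(1))
    g <- fg[sample.int(nrow(fg), 1L), ]
    d <- gamete_distribution(g, "female", par)
    expect_true(all(d >= 0))
    expect_equal(sum(d), 1, tolerance = 1e-12)
    dm <- gamete_distribution(sample(allele_states(), 1), "male", par)
    expect_true(all(dm >= 0))
    expect_equal(sum(dm), 1, tolerance = 1e-12)
  }
})

test_that("analytic gamete law matches event-level Monte-Carlo oracle", {
  par <- germline_params(q = 0.9, p = 0.7, delta = 0.4,
                         alpha_female = 0.15, alpha_male = 0.02,
                         gamma = 0.01, epsilon = 0.6)
  n <- 1e5
  set.seed(42)
  for (case in list(list(g = c("G", "W"), sex = "female"),
                    list(g = c("G", "U"), sex = "female"),
                    list(g = "G", sex = "male"))) {
    emp <- oracle_gamete_freqs(case$g, case$sex, par, n)
    law <- gamete_distribution(case$g, case$sex, par)
    expect_distribution_equal(as.numeric(emp), as.numeric(law), n)
  }
})

test_that("zygotic effects act on the right alleles", {
  gl <- germline_params(delta = 0)
  # inert channels are the identity
  z0 <- zygotic_params(0, 0)
  expect_identical(
    apply_zygotic_effects(c("G", "W"), c("G", "W"), "W", z0, gl),
    c("G", "W"))
  # forced branch: drive mother, z_maternal = 1, delta = 0 -> paternal R
  z1 <- zygotic_params(z_maternal = 1)
  expect_identical(
    apply_zygotic_effects(c("U", "W"), c("G", "W"), "W", z1, gl)[2],
    "R")
  # maternal allele of a drive-father daughter is exposed via z_paternal
  zp <- zygotic_params(z_paternal = 1)
  out <- apply_zygotic_effects(c("W", "G"), c("W", "W"), "G", zp,
                               germline_params(delta = 1))
  expect_identical(out[1], "U")
  # non-drive father leaves the maternal W alone
  out2 <- apply_zygotic_effects(c("W", "U"), c("W", "W"), "U", zp, gl)
  expect_identical(out2[1], "W")
})

test_that("per-allele zygotic law matches its Monte-Carlo realization", {
  # drive mother, z = 0.86, delta = 0.4: paternal W -> {W .14, U .344, R .516}
  gl <- germline_params(delta = 0.4)
  zz <- zygotic_params(z_maternal = 0.86)
  set.seed(7)
  n <- 2e4
  draws <- replicate(n, apply_zygotic_effects(c("G", "W"), c("G", "W"), "W",
                                              zz, gl)[2])
  emp <- table(factor(draws, levels = allele_states())) / n
  expected <- c(W = 0.14, G = 0, U = 0.344, R = 0.516, V = 0, S = 0)
  expect_distribution_equal(as.numeric(emp),
                            as.numeric(expected[allele_states()]), n)
})
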