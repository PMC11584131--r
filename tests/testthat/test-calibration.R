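one_cat_table <- function(seq_class, count, origin = "maternal") {
  data.frame(cross_id = "c1", sex = "male", body = "yellow", egfp = TRUE,
             rfp = TRUE, seq_class = seq_class, origin = origin,
             count = count)
}

test_that("cross_loglikelihood closed forms", {
  z0 <- zygotic_params()
  # params making the observed category certain -> log-likelihood 0
  sure <- germline_params(q = 1, p = 1, alpha_female = 0, alpha_male = 0,
                          gamma = 0)
  expect_equal(cross_loglikelihood(sure, z0, one_cat_table("drive", 10),
                                   "maternal"), 0)
  # probability one half, n = 10 -> 10 log(1/2)
  half <- germline_params(q = 0, alpha_female = 0, alpha_male = 0,
                          gamma = 0)
  expect_equal(cross_loglikelihood(half, z0, one_cat_table("drive", 10),
                                   "maternal"), 10 * log(0.5))
  # zero-probability category with nonzero count -> -Inf, no exception
  expect_identical(cross_loglikelihood(half, z0, one_cat_table("TcG", 1),
                                       "maternal"), -Inf)
  # origin-unassigned counts are refused
  expect_error(cross_loglikelihood(half, z0,
                                   one_cat_table("TGG", 3, "unassigned"),
                                   "maternal"),
               "origin-resolved")
})

test_that("the likelihood peaks at the generating parameters", {
  # n = 1e4 multinomial draws from the law at truth; the log-likelihood at
  # truth beats alpha shifted by +/- 0.05 in at least 95 of 100 simulations
  truth <- germline_params(q = 0.95, p = 0.78, delta = 0.4,
                           alpha_female = 0.1, alpha_male = 0.01,
                           gamma = 0, epsilon = 1)
  z0 <- zygotic_params()
  law <- remede:::.cross_category_law(truth, z0, "maternal")$maternal
  up <- germline_params(q = 0.95, p = 0.78, delta = 0.4,
                        alpha_female = 0.15, alpha_male = 0.01,
                        gamma = 0, epsilon = 1)
  dn <- germline_params(q = 0.95, p = 0.78, delta = 0.4,
                        alpha_female = 0.05, alpha_male = 0.01,
                        gamma = 0, epsilon = 1)
  set.seed(77)
  wins <- 0L
  for (i in 1:100) {
    cts <- as.integer(rmultinom(1, 1e4, law))
    tb <- do.call(rbind, lapply(which(cts > 0), function(j)
      one_cat_table(names(law)[j], cts[j])))
    lls <- vapply(list(truth, up, dn), cross_loglikelihood, numeric(1),
                  zparams = z0, table = tb, cross_design = "maternal")
    if (lls[1] >= max(lls[2:3])) wins <- wins + 1L
  }
  expect_gte(wins, 95L)
})

test_that("noiseless inversion recovers the conversion probability", {
  # q fixed at 1, conversion free: expected counts at p = 0.6 invert exactly
  truth <- germline_params(q = 1, p = 0.6, delta = 0.4, alpha_female = 0,
                           alpha_male = 0, gamma = 0)
  z0 <- zygotic_params()
  law <- remede:::.cross_category_law(truth, z0, "maternal")$maternal
  cts <- round(law * 1e6)
  tb <- do.call(rbind, lapply(which(cts > 0), function(j)
    one_cat_table(names(law)[j], cts[j])))
  base <- germline_params(q = 1, p = 0.5, delta = 0.4, alpha_female = 0,
                          alpha_male = 0, gamma = 0)
  fit <- fit_params(tb, free_params = "qp", params = base, n_boot = 0,
                    seed = 2)
  expect_lt(abs(fit$estimates[["qp"]] - 0.6), 1e-3)
})

test_that("estimates are invariant to row order", {
  par <- germline_params(alpha_female = 0.12, epsilon = 1, gamma = 0)
  tab <- generate_cross_dataset(par, n_crosses = 20, seed = 10)
  base <- germline_params(alpha_female = 0.5, epsilon = 1, gamma = 0)
  f1 <- fit_params(tab, "alpha_female", params = base, n_boot = 0, seed = 1)
  f2 <- fit_params(tab[rev(seq_len(nrow(tab))), ], "alpha_female",
                   params = base, n_boot = 0, seed = 1)
  expect_equal(f1$estimates, f2$estimates, tolerance = 1e-9)
})

test_that("non-identifiable requests are refused with a diagnostic", {
  tab <- generate_cross_dataset(germline_params(), n_crosses = 2, seed = 1)
  expect_error(fit_params(tab, c("q", "qp")), "jointly")
  expect_error(fit_params(tab, "p"), "identifiable")
  expect_error(fit_params(tab, "nonsense"), "unknown free parameter")
})

test_that("bootstrap confidence intervals cover the truth (desk scale)", {
  # 1-D alpha fit; 200 datasets with 40 bootstrap resamples each;
  # nominal 95% coverage must stay above the loose 85% floor
  truth <- germline_params(alpha_female = 0.1, epsilon = 1, gamma = 0)
  z0 <- zygotic_params()
  law <- remede:::.cross_category_law(truth, z0, "maternal")$maternal
  base <- germline_params(alpha_female = 0.5, epsilon = 1, gamma = 0)
  set.seed(13)
  seeds <- sample.int(1e6, 200)
  covered <- vapply(seq_along(seeds), function(i) {
    cts <- as.integer(rmultinom(1, 2000, law))
    tb <- do.call(rbind, lapply(which(cts > 0), function(j)
      one_cat_table(names(law)[j], cts[j])))
    fit <- fit_params(tb, "alpha_female", params = base, n_boot = 40,
                      seed = seeds[i])
    fit$conf_int["alpha_female", 1] <= 0.1 &&
      0.1 <= fit$conf_int["alpha_female", 2]
  }, logical(1))
  expect_gte(mean(covered), 0.85)
})
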