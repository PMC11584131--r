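# Event-level simulation of the germline repair tree, independent of the
# analytic laws in the package: every branch is drawn with its own runif.
# Used as the Monte-Carlo oracle for gamete_distribution().

oracle_resolve_W <- function(par, drive_present) {
  if (!drive_present) return("W")
  if (runif(1) >= par$q) return("W")           # not cut
  if (runif(1) < par$p) return("G")            # HR conversion
  if (runif(1) < par$delta) "U" else "R"       # NHEJ
}

oracle_resolve_G <- function(par, sex) {
  a <- if (sex == "female") par$alpha_female else par$alpha_male
  u <- runif(1)
  if (u < a) {                                  # SSA excision
    if (runif(1) < par$epsilon) "V" else "W"
  } else if (u < a + par$gamma) {               # second-site NHEJ
    "S"
  } else {
    "G"
  }
}

oracle_sample_gamete <- function(genotype, sex, par) {
  drive <- any(genotype %in% c("G", "S"))
  a <- if (length(genotype) == 2L) genotype[sample.int(2L, 1L)] else genotype
  if (a == "W" && sex == "female") {
    oracle_resolve_W(par, drive)
  } else if (a == "G") {
    oracle_resolve_G(par, sex)
  } else {
    a
  }
}

# frequency table of n oracle gametes over the six states
oracle_gamete_freqs <- function(genotype, sex, par, n) {
  draws <- replicate(n, oracle_sample_gamete(genotype, sex, par))
  table(factor(draws, levels = allele_states())) / n
}

expect_distribution_equal <- function(observed, expected, n, sigma = 4) {
  tol <- sigma * sqrt(pmax(expected * (1 - expected), 1e-12) / n)
  expect_true(all(abs(observed - expected) <= tol + 1e-12),
              info = paste0("max dev ", max(abs(observed - expected))))
}
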