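#' Phenotype-dependent mating costs
#'
#' A phenotypically yellow individual mates with weight `1 - cost` relative
#' to a wild-bodied one. Defaults are the empirically determined costs for
#' yellow males (0.97, from competitive mating assays) and yellow females
#' (0.31).
#'
#' @param cost_yellow_male,cost_yellow_female Fractional reductions in
#'   mating success, in `[0, 1]`.
#' @return An object of class `mating_costs`.
#' @export
mating_costs <- function(cost_yellow_male = 0.97, cost_yellow_female = 0.31) {
  for (nm in c("cost_yellow_male", "cost_yellow_female")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
      stop(sprintf("'%s' must lie in [0, 1]", nm), call. = FALSE)
  }
  structure(list(cost_yellow_male = as.numeric(cost_yellow_male),
                 cost_yellow_female = as.numeric(cost_yellow_female)),
            class = "mating_costs")
}

#' Simulation configuration
#'
#' Bundles every knob of the population and cage engines. Defaults
#' describe a low-threshold release (10% of flies carrying one drive
#' allele, both sexes, balanced sex ratio) into a census-regulated
#' population of 1000.
#'
#' @param population_size Census size (constant across generations).
#' @param generations Number of generations to iterate.
#' @param replicates Number of independent stochastic chains.
#' @param release_fraction Fraction of founding individuals carrying the
#'   drive.
#' @param release_sex `"both"`, `"female"`, or `"male"`.
#' @param release_zygosity `"heterozygous"` (females `G/W`, males
#'   hemizygous `G`) or `"homozygous"` (females `G/G`).
#' @param seed Master seed; per-replicate child seeds are derived from it.
#' @param germline A [germline_params()] object.
#' @param zygotic A [zygotic_params()] object.
#' @param costs A [mating_costs()] object, or `NULL` for no costs.
#' @param variant A [drive_variant()] object.
#' @param brood_size Offspring produced per cage generation before pool
#'   sampling (cage protocol only).
#' @param pool_size Size of each of the score and seed pools (cage
#'   protocol only).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(population_size = 1000L,
                              generations = 60L,
                              replicates = 100L,
                              release_fraction = 0.10,
                              release_sex = c("both", "female", "male"),
                              release_zygosity = c("heterozygous",
                                                   "homozygous"),
                              seed = 1L,
                              germline = germline_params(),
                              zygotic = zygotic_params(),
                              costs = mating_costs(0, 0),
                              variant = drive_variant("yReMEDE"),
                              brood_size = 600L,
                              pool_size = 150L) {
  release_sex <- match.arg(release_sex)
  release_zygosity <- match.arg(release_zygosity)
  if (population_size < 2) stop("population_size must be at least 2")
  if (release_fraction < 0 || release_fraction > 1)
    stop("release_fraction must lie in [0, 1]")
  if (is.null(costs)) costs <- mating_costs(0, 0)
  stopifnot(inherits(germline, "germline_params"),
            inherits(zygotic, "zygotic_params"),
            inherits(costs, "mating_costs"),
            inherits(variant, "drive_variant"))
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 replicates = as.integer(replicates),
                 release_fraction = release_fraction,
                 release_sex = release_sex,
                 release_zygosity = release_zygosity,
                 seed = as.integer(seed),
                 germline = germline, zygotic = zygotic, costs = costs,
                 variant = variant,
                 brood_size = as.integer(brood_size),
                 pool_size = as.integer(pool_size)),
            class = "simulation_config")
}

# round half away from zero (commercial rounding), used for release counts
.round_half_up <- function(x) floor(x + 0.5)

#' Initialize a population state
#'
#' Builds the founding genotype-by-sex counts: `release_fraction` of
#' individuals carry the drive (per `release_sex` and `release_zygosity`),
#' the remainder are wild type (`W/W` females, `W` males), with a balanced
#' sex ratio. Integer rounding is half-up and preserves the census total.
#'
#' @param config A [simulation_config()] object.
#' @return An object of class `population_state`: list with named integer
#'   vectors `female` (21 diplotype counts) and `male` (6 genotype counts).
#' @export
initialize_population <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  N <- config$population_size
  n_f <- N %/% 2L
  n_m <- N - n_f
  fg <- female_genotypes()
  female <- stats::setNames(integer(nrow(fg)), rownames(fg))
  male <- stats::setNames(integer(6L), .ALLELES)
  n_drive <- as.integer(.round_half_up(config$release_fraction * N))
  drv <- switch(config$release_sex,
                both = {
                  df <- as.integer(.round_half_up(n_drive / 2))
                  c(female = df, male = n_drive - df)
                },
                female = c(female = n_drive, male = 0L),
                male = c(female = 0L, male = n_drive))
  if (drv["female"] > n_f || drv["male"] > n_m)
    stop("release_fraction incompatible with a balanced sex ratio")
  f_geno <- if (config$release_zygosity == "homozygous") "G/G" else "W/G"
  female[f_geno] <- drv[["female"]]
  female["W/W"] <- n_f - drv[["female"]]
  male["G"] <- drv[["male"]]
  male["W"] <- n_m - drv[["male"]]
  structure(list(female = female, male = male), class = "population_state")
}

# ---------------------------------------------------------------------------
# internal engine: precomputed laws for one parameter set

# list with gamete law matrices, genotype metadata and mating weights
.engine <- function(config) {
  par <- .effective_params(config$germline, config$variant)
  fg <- female_genotypes()
  Lf <- t(vapply(seq_len(nrow(fg)),
                 function(i) gamete_distribution(fg[i, ], "female", par),
                 numeric(6L)))
  rownames(Lf) <- rownames(fg)
  Lm <- t(vapply(.ALLELES,
                 function(a) gamete_distribution(a, "male", par),
                 numeric(6L)))
  ph <- .phenotype_tables(config$variant)
  cm <- config$costs
  w_f <- ifelse(ph$female$yellow, 1 - cm$cost_yellow_female, 1)
  w_m <- ifelse(ph$male$yellow, 1 - cm$cost_yellow_male, 1)
  f_drive <- ph$female$drive          # female genotype contains G or S
  m_drive <- ph$male$drive
  # index pairs of the 21 diplotypes for assembling daughter laws
  idx <- matrix(match(fg, .ALLELES), ncol = 2L)
  # allele-copy matrix: A[i, j] = copies of allele j in diplotype i
  A <- matrix(0, nrow(fg), 6L, dimnames = list(rownames(fg), .ALLELES))
  A[cbind(seq_len(nrow(fg)), idx[, 1])] <- A[cbind(seq_len(nrow(fg)), idx[, 1])] + 1
  A[cbind(seq_len(nrow(fg)), idx[, 2])] <- A[cbind(seq_len(nrow(fg)), idx[, 2])] + 1
  list(par = par, fg = fg, Lf = Lf, Lm = Lm, ph = ph,
       w_f = w_f, w_m = w_m, f_drive = f_drive, m_drive = m_drive,
       zy = config$zygotic, idx = idx, A = A)
}

# move zygotic-cut mass of the W state into U/R
.apply_zyg_law <- function(law, z, delta) {
  if (z <= 0 || law["W"] <= 0) return(law)
  cut <- z * law[["W"]]
  law["W"] <- law[["W"]] - cut
  law["U"] <- law[["U"]] + cut * delta
  law["R"] <- law[["R"]] + cut * (1 - delta)
  law
}

# offspring genotype law given parental genotype frequencies.
# f: 21-vector of female genotype weights, m: 6-vector of male weights
# (either counts or frequencies). Returns list(daughter = 21 probs,
# son = 6 probs). Mothers and fathers are drawn proportionally to
# frequency times mating weight; the mother/father drive-carrier classes
# are tracked exactly so zygotic effects condition on the right parent.
.offspring_law <- function(eng, f, m) {
  wf <- f * eng$w_f
  wm <- m * eng$w_m
  if (sum(wf) <= 0) wf <- f  # degenerate: all mothers fully penalized
  if (sum(wm) <= 0) wm <- m
  wf <- wf / sum(wf)
  wm <- wm / sum(wm)
  delta <- eng$par$delta
  zm <- eng$zy$z_maternal
  zp <- eng$zy$z_paternal
  # maternal gamete law conditional on mother drive class
  p_mD <- sum(wf[eng$f_drive])
  g_D <- if (p_mD > 0) colSums(wf[eng$f_drive] * eng$Lf[eng$f_drive, , drop = FALSE]) / p_mD else .empty_dist()
  g_N <- if (p_mD < 1) colSums(wf[!eng$f_drive] * eng$Lf[!eng$f_drive, , drop = FALSE]) / (1 - p_mD) else .empty_dist()
  # paternal X-allele law conditional on father drive class
  p_fD <- sum(wm[eng$m_drive])
  h_D <- if (p_fD > 0) colSums(wm[eng$m_drive] * eng$Lm[eng$m_drive, , drop = FALSE]) / p_fD else .empty_dist()
  h_N <- if (p_fD < 1) colSums(wm[!eng$m_drive] * eng$Lm[!eng$m_drive, , drop = FALSE]) / (1 - p_fD) else .empty_dist()
  daughter <- numeric(21L)
  for (mc in c(TRUE, FALSE)) {
    pm <- if (mc) p_mD else 1 - p_mD
    if (pm <= 0) next
    g <- if (mc) g_D else g_N
    for (fc in c(TRUE, FALSE)) {
      pf <- if (fc) p_fD else 1 - p_fD
      if (pf <= 0) next
      h <- if (fc) h_D else h_N
      # zygotic channels: deposition (mother drive) hits the paternal W;
      # paternal zygotic expression (father drive) hits the maternal W
      if (mc) h <- .apply_zyg_law(h, zm, delta)
      if (fc) g <- .apply_zyg_law(g, zp, delta)
      pair <- outer(g, h)                      # maternal x paternal
      sym <- pair + t(pair)
      contrib <- sym[cbind(eng$idx[, 1], eng$idx[, 2])]
      diag_idx <- eng$idx[, 1] == eng$idx[, 2]
      contrib[diag_idx] <- contrib[diag_idx] / 2
      daughter <- daughter + pm * pf * contrib
    }
  }
  son <- p_mD * g_D + (1 - p_mD) * g_N
  daughter <- daughter / sum(daughter)
  son <- son / sum(son)
  list(daughter = stats::setNames(daughter, rownames(eng$fg)),
       son = son)
}

# allele frequencies over all X chromosomes plus phenotype-class
# frequencies for one state given as weights (counts or freqs)
.state_summary <- function(eng, f, m) {
  tot_x <- 2 * sum(f) + sum(m)
  av <- (colSums(f * eng$A) + m) / tot_x
  names(av) <- .ALLELES
  n_ind <- sum(f) + sum(m)
  ph_drive <- (sum(f[eng$f_drive]) + sum(m[eng$m_drive])) / n_ind
  yellow_f <- eng$ph$female$yellow
  yellow_m <- eng$ph$male$yellow
  ph_yellow <- (sum(f[yellow_f & !eng$f_drive]) +
                sum(m[yellow_m & !eng$m_drive])) / n_ind
  ph_wild <- 1 - ph_drive - ph_yellow
  c(av, pheno_drive = ph_drive, pheno_wild = ph_wild,
    pheno_yellow = ph_yellow)
}

.new_trajectory <- function(rows, extinct = FALSE) {
  df <- as.data.frame(do.call(rbind, rows))
  df <- cbind(generation = seq_len(nrow(df)) - 1L, df)
  df$drive <- df$G + df$S
  attr(df, "extinct") <- extinct
  class(df) <- c("drive_trajectory", class(df))
  df
}

#' Advance a population one generation
#'
#' Offspring are formed by drawing, for each of `population_size` slots, a
#' mother and a father proportionally to mating weight (wild-bodied weight
#' 1, yellow-bodied weight `1 - cost` for the respective sex), a gamete
#' from each parental germline law, and zygotic effects; sexes are
#' assigned with equal probability. Implemented as one exact multinomial
#' draw over the 27 sex-by-genotype categories. A generation with zero
#' males or zero females is terminal ("extinct").
#'
#' @param state A `population_state`.
#' @param config A [simulation_config()] object.
#' @return A new `population_state`; attribute `extinct` is `TRUE` when the
#'   input state lacked one sex (the input is then returned unchanged).
#' @export
next_generation <- function(state, config) {
  stopifnot(inherits(state, "population_state"),
            inherits(config, "simulation_config"))
  eng <- .engine(config)
  .next_generation_impl(state, eng, config$population_size)
}

.next_generation_impl <- function(state, eng, N) {
  if (sum(state$female) == 0 || sum(state$male) == 0) {
    attr(state, "extinct") <- TRUE
    return(state)
  }
  law <- .offspring_law(eng, as.numeric(state$female),
                        as.numeric(state$male))
  p27 <- c(0.5 * law$daughter, 0.5 * law$son)
  draw <- as.integer(stats::rmultinom(1L, N, p27))
  out <- structure(list(
    female = stats::setNames(draw[1:21], rownames(eng$fg)),
    male = stats::setNames(draw[22:27], .ALLELES)),
    class = "population_state")
  attr(out, "extinct") <- sum(out$female) == 0 || sum(out$male) == 0
  out
}

# deterministic child seeds below 2^31 derived from one master seed
.child_seeds <- function(seed, n) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run replicate stochastic simulations
#'
#' Runs `config$replicates` independent chains, each seeded with a child
#' seed derived deterministically from `config$seed`, and records per
#' generation the frequency of each allele state among all X chromosomes
#' (females carry two, males one) and the phenotype-class frequencies.
#'
#' @param config A [simulation_config()] object.
#' @return Object of class `drive_simulation`: list with `trajectories`
#'   (one `drive_trajectory` data frame per replicate), `mean` (pointwise
#'   mean trajectory), `config`, and `seeds`.
#' @examples
#' cfg <- simulation_config(population_size = 200, generations = 5,
#'                          replicates = 3)
#' sim <- simulate_drive(cfg)
#' sim$mean$drive
#' @export
simulate_drive <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  eng <- .engine(config)
  seeds <- .child_seeds(config$seed, config$replicates)
  init <- initialize_population(config)
  trajs <- vector("list", config$replicates)
  for (r in seq_len(config$replicates)) {
    set.seed(seeds[r])
    state <- init
    rows <- vector("list", config$generations + 1L)
    rows[[1L]] <- .state_summary(eng, as.numeric(state$female),
                                 as.numeric(state$male))
    extinct <- FALSE
    for (g in seq_len(config$generations)) {
      state <- .next_generation_impl(state, eng, config$population_size)
      if (isTRUE(attr(state, "extinct"))) {
        extinct <- TRUE
        # carry the last composition forward so trajectories stay rectangular
        rows[g + 1L] <- rows[g]
        next
      }
      rows[[g + 1L]] <- .state_summary(eng, as.numeric(state$female),
                                       as.numeric(state$male))
    }
    trajs[[r]] <- .new_trajectory(rows, extinct)
  }
  mean_rows <- Reduce(`+`, lapply(trajs, function(t)
    as.matrix(t[, setdiff(names(t), "generation")]))) / length(trajs)
  mean_df <- cbind(generation = trajs[[1L]]$generation,
                   as.data.frame(mean_rows))
  class(mean_df) <- c("drive_trajectory", class(mean_df))
  structure(list(trajectories = trajs, mean = mean_df, config = config,
                 seeds = seeds),
            class = "drive_simulation")
}

#' Deterministic (infinite-population) trajectory
#'
#' Iterates the exact genotype-frequency recursion induced by the same
#' gamete laws, mating weights and zygotic effects as the stochastic
#' engine, without sampling. Serves as the expectation oracle for
#' [simulate_drive()].
#'
#' @param config A [simulation_config()] object.
#' @return A `drive_trajectory` data frame (one row per generation).
#' @export
expected_trajectory <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  eng <- .engine(config)
  init <- initialize_population(config)
  f <- as.numeric(init$female) / sum(init$female)
  m <- as.numeric(init$male) / sum(init$male)
  rows <- vector("list", config$generations + 1L)
  rows[[1L]] <- .state_summary(eng, f / 2, m / 2)
  for (g in seq_len(config$generations)) {
    law <- .offspring_law(eng, f, m)
    f <- as.numeric(law$daughter)
    m <- as.numeric(law$son)
    rows[[g + 1L]] <- .state_summary(eng, f / 2, m / 2)
  }
  .new_trajectory(rows)
}

#' @export
print.drive_simulation <- function(x, ...) {
  peak <- max(x$mean$drive)
  cat(sprintf(
    "drive_simulation: %d replicates, N = %d, %d generations\n",
    length(x$trajectories), x$config$population_size,
    x$config$generations))
  cat(sprintf("  peak mean drive-allele frequency: %.1f%% (generation %d)\n",
              100 * peak, x$mean$generation[which.max(x$mean$drive)]))
  invisible(x)
}
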