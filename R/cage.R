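#' Run one population-cage trial
#'
#' Emulates the discrete cage protocol: a founding seed pool (default 200
#' flies, `release_fraction` of them drive carriers at the configured
#' zygosity) produces a brood of `brood_size` offspring per generation via
#' the same mating/gamete model as [next_generation()]. From each brood two
#' disjoint uniform random pools of `pool_size` flies are drawn: one is
#' phenotype-scored and recorded, the other seeds the next generation. If
#' the brood holds fewer than twice `pool_size` flies, both pools shrink
#' proportionally (with a warning).
#'
#' @param config A [simulation_config()] object; `population_size` is the
#'   founding cage size, `brood_size` and `pool_size` the cage protocol
#'   knobs.
#' @param generations Number of scored generations (defaults to
#'   `config$generations`).
#' @param seed Seed for this run (defaults to `config$seed`).
#' @return A data frame of class `cage_series` with columns `generation`
#'   (1-based: first scored brood is generation 1), `n_drive` (fluorescent
#'   flies), `n_wild` (non-fluorescent wild-bodied), `n_yellow`
#'   (non-fluorescent yellow-bodied), and `n_scored`.
#' @export
run_cage_trial <- function(config, generations = config$generations,
                           seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  eng <- .engine(config)
  set.seed(seed)
  state <- initialize_population(config)
  pool <- config$pool_size
  rows <- vector("list", generations)
  warned <- FALSE
  for (g in seq_len(generations)) {
    if (sum(state$female) == 0 || sum(state$male) == 0) {
      rows[[g]] <- c(n_drive = 0L, n_wild = 0L, n_yellow = 0L,
                     n_scored = 0L)
      next
    }
    brood <- .next_generation_impl(state, eng, config$brood_size)
    counts <- c(brood$female, brood$male)
    n_off <- sum(counts)
    take <- min(2L * pool, n_off)
    if (take < 2L * pool && !warned) {
      warning(sprintf(
        "brood of %d smaller than twice the pool size (%d); pools shrink proportionally",
        n_off, pool), call. = FALSE)
      warned <- TRUE
    }
    # disjoint uniform score/seed pools drawn without replacement
    ind <- rep.int(seq_along(counts), counts)
    pick <- sample(n_off, take)
    half <- take %/% 2L
    score_ct <- tabulate(ind[pick[seq_len(half)]], nbins = 27L)
    seed_ct <- tabulate(ind[pick[half + seq_len(take - half)]], nbins = 27L)
    sf <- score_ct[1:21]; sm <- score_ct[22:27]
    drive <- sum(sf[eng$f_drive]) + sum(sm[eng$m_drive])
    yellow <- sum(sf[eng$ph$female$yellow & !eng$f_drive]) +
      sum(sm[eng$ph$male$yellow & !eng$m_drive])
    rows[[g]] <- c(n_drive = drive, n_wild = half - drive - yellow,
                   n_yellow = yellow, n_scored = half)
    state <- structure(list(
      female = stats::setNames(seed_ct[1:21], rownames(eng$fg)),
      male = stats::setNames(seed_ct[22:27], .ALLELES)),
      class = "population_state")
  }
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(generation = seq_len(nrow(out)), out)
  class(out) <- c("cage_series", class(out))
  out
}

#' First generation at which a phenotype class is gone for good
#'
#' Returns the first recorded generation at which the class count is zero
#' and remains zero in every later recorded generation; transient zeros are
#' ignored. Returns `NA` if the class is never eliminated.
#'
#' @param series Either a `cage_series` data frame from
#'   [run_cage_trial()] or a bare numeric vector of per-generation counts
#'   (then taken to start at generation 0).
#' @param phenotype_class For a `cage_series`: one of `"drive"`, `"wild"`,
#'   `"yellow"`.
#' @return Integer generation label, or `NA_integer_`.
#' @examples
#' elimination_generation(c(5, 3, 1, 0, 0))   # 3
#' elimination_generation(c(5, 0, 2, 0, 0))   # 3 (transient zero ignored)
#' elimination_generation(c(5, 4, 3))         # NA
#' @export
elimination_generation <- function(series,
                                   phenotype_class = c("drive", "wild",
                                                       "yellow")) {
  if (inherits(series, "cage_series") || is.data.frame(series)) {
    phenotype_class <- match.arg(phenotype_class)
    counts <- series[[paste0("n_", phenotype_class)]]
    gens <- series$generation
  } else {
    counts <- as.numeric(series)
    gens <- seq_along(counts) - 1L
  }
  if (length(counts) == 0) stop("empty series", call. = FALSE)
  tail_sum <- rev(cumsum(rev(counts)))
  i <- which(tail_sum == 0)
  if (length(i) == 0) return(NA_integer_)
  as.integer(gens[min(i)])
}
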