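#' Resolve a susceptible wild-type allele in a drive-bearing germline
#'
#' One passage of the repair-outcome tree acting on a `W` allele. If no
#' nuclease source is present the allele is untouched. Otherwise it is cut
#' with probability `q`; a cut converts to `G` by HR with probability `p`,
#' and otherwise is resolved by NHEJ into an in-frame `U` (probability
#' `delta`) or an out-of-frame `R`.
#'
#' @param params A [germline_params()] object.
#' @param drive_present Logical: does the germline genotype contain a
#'   nuclease source (`G` or `S` allele)?
#' @return Named numeric allele distribution over the six states.
#' @examples
#' resolve_susceptible_allele(germline_params(q = 0.9, p = 0.8, delta = 0.4),
#'                            drive_present = TRUE)
#' @export
resolve_susceptible_allele <- function(params, drive_present) {
  stopifnot(inherits(params, "germline_params"),
            is.logical(drive_present), length(drive_present) == 1L)
  if (!drive_present) return(.point_dist("W"))
  x <- .empty_dist()
  x["W"] <- 1 - params$q
  x["G"] <- params$q * params$p
  x["U"] <- params$q * (1 - params$p) * params$delta
  x["R"] <- params$q * (1 - params$p) * (1 - params$delta)
  x
}

#' Resolve a drive allele (SSA excision / second-site disruption)
#'
#' One germline passage of an intact drive allele `G`. SSA excises the
#' element with the sex-specific probability `alpha`, leaving the marked
#' wild-type `V` (probability `epsilon`) or a reverted plain `W`; NHEJ at
#' the second-nuclease site produces the SSA-immune drive `S` with
#' probability `gamma`; otherwise the drive is passed on intact. An `S`
#' allele always resolves to itself.
#'
#' @inheritParams resolve_susceptible_allele
#' @param sex `"female"` or `"male"`; selects `alpha_female` or
#'   `alpha_male`.
#' @return Named numeric allele distribution.
#' @export
resolve_drive_allele <- function(params, sex = c("female", "male")) {
  stopifnot(inherits(params, "germline_params"))
  sex <- match.arg(sex)
  a <- if (sex == "female") params$alpha_female else params$alpha_male
  g <- params$gamma
  if (a + g > 1) stop("alpha + gamma exceeds 1", call. = FALSE)
  x <- .empty_dist()
  x["V"] <- a * params$epsilon
  x["W"] <- a * (1 - params$epsilon)
  x["S"] <- g
  x["G"] <- 1 - a - g
  x
}

# per-allele resolution law within a germline; returns 6-vector
.resolve_allele <- function(allele, sex, params, drive_present) {
  switch(allele,
         W = if (sex == "female") {
           resolve_susceptible_allele(params, drive_present)
         } else {
           # hemizygous X has no homolog: no homing target in males
           .point_dist("W")
         },
         G = resolve_drive_allele(params, sex),
         .point_dist(allele))
}

#' Gamete allele distribution for a parental genotype
#'
#' Resolves every parental allele through one germline passage (homing of
#' `W`, SSA/second-site resolution of `G`; `U`, `R`, `V`, `S` transmit
#' unchanged, with `S` remaining a nuclease source) and segregates. A
#' female gamete draws each resolved allele with weight 1/2; a male
#' X-gamete is the resolved single allele (the Y is tracked implicitly).
#' Male germlines perform no homing (there is no homologous target) but
#' male drive alleles still undergo SSA at `alpha_male`.
#'
#' @param genotype Character vector of allele codes: two for females, one
#'   for males.
#' @param sex `"female"` or `"male"`.
#' @param params A [germline_params()] object.
#' @return Named numeric allele distribution of the transmitted X allele.
#' @examples
#' gamete_distribution(c("G", "W"), "female",
#'                     germline_params(q = 0, alpha_female = 0))
#' @export
gamete_distribution <- function(genotype, sex = c("female", "male"), params) {
  sex <- match.arg(sex)
  .check_genotype(genotype, sex)
  stopifnot(inherits(params, "germline_params"))
  drive <- any(.is_drive_allele(genotype))
  laws <- lapply(genotype, .resolve_allele, sex = sex, params = params,
                 drive_present = drive)
  Reduce(`+`, laws) / length(laws)
}

# analytic law of one zygotically exposed W allele: stays W with
# probability 1 - z, else NHEJ with the germline in-frame split
.zygotic_allele_law <- function(z, delta) {
  x <- .empty_dist()
  x["W"] <- 1 - z
  x["U"] <- z * delta
  x["R"] <- z * (1 - delta)
  x
}

#' Apply zygotic nuclease effects to one offspring genotype
#'
#' After gamete union, maternally deposited nuclease (mother carrying `G`
#' or `S`) cuts each paternally inherited `W` allele with probability
#' `z_maternal`; symmetrically, when the father carried a drive, zygotic
#' expression cuts the maternally inherited `W` allele with probability
#' `z_paternal`. Zygotic cuts resolve by NHEJ only: `U` with probability
#' `delta`, else `R`. Non-`W` alleles are unchanged. This is a stochastic
#' per-zygote operation; the population engines use the equivalent analytic
#' law.
#'
#' @param offspring_genotype Character vector of allele codes; for females
#'   the first element is the maternally inherited allele, the second the
#'   paternally inherited one. Males carry the maternal allele only.
#' @param maternal_genotype,paternal_genotype Parental genotypes (two and
#'   one allele codes respectively).
#' @param zparams A [zygotic_params()] object.
#' @param params A [germline_params()] object (supplies `delta`).
#' @return The (possibly modified) offspring genotype.
#' @export
apply_zygotic_effects <- function(offspring_genotype, maternal_genotype,
                                  paternal_genotype, zparams, params) {
  stopifnot(inherits(zparams, "zygotic_params"),
            inherits(params, "germline_params"))
  .check_genotype(maternal_genotype, "female")
  .check_genotype(paternal_genotype, "male")
  geno <- offspring_genotype
  cut_w <- function(z) {
    if (stats::runif(1) >= z) return("W")
    if (stats::runif(1) < params$delta) "U" else "R"
  }
  mother_drive <- any(.is_drive_allele(maternal_genotype))
  father_drive <- any(.is_drive_allele(paternal_genotype))
  if (length(geno) == 2L) {
    if (mother_drive && geno[2L] == "W" && zparams$z_maternal > 0)
      geno[2L] <- cut_w(zparams$z_maternal)
    if (father_drive && geno[1L] == "W" && zparams$z_paternal > 0)
      geno[1L] <- cut_w(zparams$z_paternal)
  }
  # males inherit no paternal X, and carry no paternally inherited drive,
  # so neither channel applies
  geno
}
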