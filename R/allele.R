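#' Allele state codes
#'
#' The six-way classification of alleles at the drive target locus:
#' \describe{
#'   \item{W}{susceptible wild type (cleavable TGG PAM).}
#'   \item{G}{intact drive allele, SSA-capable (carries the excision
#'     machinery between direct repeats).}
#'   \item{U}{in-frame NHEJ indel: functional, drive-resistant.}
#'   \item{R}{out-of-frame NHEJ indel: null, drive-resistant.}
#'   \item{V}{SSA-excised wild-type allele retaining the engineered silent
#'     TcG PAM marker; functional and drive-resistant.}
#'   \item{S}{drive allele whose second-nuclease target site was disrupted
#'     by NHEJ: still a full drive/nuclease source but immune to SSA
#'     excision.}
#' }
#'
#' @return Character vector of the six allele codes, in canonical order.
#' @export
allele_states <- function() c("W", "G", "U", "R", "V", "S")

# canonical order used by every internal law/matrix
.ALLELES <- c("W", "G", "U", "R", "V", "S")

.check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single probability in [0, 1], got %s",
                 name, deparse(substitute(x))), call. = FALSE)
  }
  as.numeric(x)
}

#' Germline repair-outcome parameters
#'
#' Probabilities of the per-allele repair-outcome tree acting in a
#' drive-bearing germline. A susceptible wild-type allele (`W`) is cut with
#' probability `q`; a cut is resolved by homology-directed repair
#' (conversion to `G`) with probability `p`, otherwise by NHEJ, yielding an
#' in-frame functional allele (`U`) with probability `delta` or an
#' out-of-frame null (`R`) otherwise. Independently, an intact drive allele
#' (`G`) suffers a second double-strand break that is resolved by SSA with
#' per-sex probability `alpha_*` (excising the element) or by NHEJ at the
#' second-nuclease site with probability `gamma` (producing the SSA-immune
#' drive `S`). An SSA excision retains the engineered TcG marker with
#' probability `epsilon` (yielding `V`), otherwise the marker reverts and a
#' plain susceptible `W` is restored.
#'
#' @param q Cut probability per susceptible `W` allele per germline passage.
#' @param p Probability a cut is repaired by HR (allelic conversion).
#' @param delta In-frame fraction of NHEJ repairs.
#' @param alpha_female,alpha_male Per-passage SSA excision probability of a
#'   `G` allele in the female / male germline.
#' @param gamma Probability of NHEJ disruption of the second-nuclease site
#'   (`G` to `S`).
#' @param epsilon Probability an SSA excision retains the TcG marker.
#' @return An object of class `germline_params`.
#' @examples
#' germline_params()                       # defaults calibrated to ~87%
#' germline_params(alpha_female = 0.05, epsilon = 0.25)
#' @export
germline_params <- function(q = 0.95, p = 0.78, delta = 0.4,
                            alpha_female = 0.1, alpha_male = 0.01,
                            gamma = 0, epsilon = 1) {
  pars <- list(q = q, p = p, delta = delta, alpha_female = alpha_female,
               alpha_male = alpha_male, gamma = gamma, epsilon = epsilon)
  for (nm in names(pars)) {
    x <- pars[[nm]]
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
      stop(sprintf("germline parameter '%s' must lie in [0, 1]", nm),
           call. = FALSE)
    pars[[nm]] <- as.numeric(x)
  }
  if (pars$alpha_female + pars$gamma > 1)
    stop("alpha_female + gamma must not exceed 1 (exclusive outcomes on one drive allele)",
         call. = FALSE)
  if (pars$alpha_male + pars$gamma > 1)
    stop("alpha_male + gamma must not exceed 1 (exclusive outcomes on one drive allele)",
         call. = FALSE)
  structure(pars, class = "germline_params")
}

#' Zygotic deposition parameters
#'
#' Maternally deposited nuclease can cut the paternally inherited
#' susceptible allele in the zygote (`z_maternal`); symmetrically, zygotic
#' expression from a paternally inherited drive can cut the maternally
#' inherited susceptible allele (`z_paternal`). Zygotic cuts are resolved by
#' NHEJ only, using the same in-frame split `delta` as the germline model.
#'
#' @param z_maternal,z_paternal Per-allele zygotic cut probabilities in
#'   `[0, 1]`. Both default to 0 (population-dynamic simulations model the
#'   germline only).
#' @return An object of class `zygotic_params`.
#' @export
zygotic_params <- function(z_maternal = 0, z_paternal = 0) {
  for (nm in c("z_maternal", "z_paternal")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
      stop(sprintf("zygotic parameter '%s' must lie in [0, 1]", nm),
           call. = FALSE)
  }
  structure(list(z_maternal = as.numeric(z_maternal),
                 z_paternal = as.numeric(z_paternal)),
            class = "zygotic_params")
}

# empty distribution over the six allele states
.empty_dist <- function() stats::setNames(numeric(6L), .ALLELES)

# point mass on a single allele
.point_dist <- function(allele) {
  x <- .empty_dist()
  x[allele] <- 1
  x
}

#' Validate an allele distribution
#'
#' Checks that a named numeric vector is a probability distribution over the
#' six allele states: nonnegative entries summing to 1 within `1e-12`.
#' Missing states are filled with zero mass.
#'
#' @param x Named numeric vector with names among [allele_states()].
#' @return The completed six-state distribution (invisibly the same law).
#' @export
as_allele_distribution <- function(x) {
  if (is.null(names(x)) || !all(names(x) %in% .ALLELES))
    stop("allele distribution must be named by allele states W,G,U,R,V,S",
         call. = FALSE)
  out <- .empty_dist()
  out[names(x)] <- as.numeric(x)
  if (any(out < 0))
    stop("allele distribution has negative mass", call. = FALSE)
  if (abs(sum(out) - 1) > 1e-12)
    stop("allele distribution does not sum to 1 (within 1e-12)", call. = FALSE)
  out
}

.is_drive_allele <- function(a) a %in% c("G", "S")

.check_genotype <- function(genotype, sex) {
  sex <- match.arg(sex, c("female", "male"))
  if (!is.character(genotype) || !all(genotype %in% .ALLELES))
    stop("genotype must be a character vector of allele codes (W,G,U,R,V,S)",
         call. = FALSE)
  n_expected <- if (sex == "female") 2L else 1L
  if (length(genotype) != n_expected)
    stop(sprintf("%s genotype must carry %d X allele(s), got %d",
                 sex, n_expected, length(genotype)), call. = FALSE)
  invisible(genotype)
}

#' Enumerate female diplotypes
#'
#' All 21 unordered pairs of the six allele states, used as the genotype
#' categories of the population engines.
#'
#' @return Character matrix with 21 rows and columns `a1`, `a2`; row names
#'   are `"a1/a2"` labels.
#' @export
female_genotypes <- function() {
  pairs <- which(upper.tri(matrix(0, 6, 6), diag = TRUE), arr.ind = TRUE)
  m <- cbind(a1 = .ALLELES[pairs[, "row"]], a2 = .ALLELES[pairs[, "col"]])
  rownames(m) <- paste(m[, 1], m[, 2], sep = "/")
  m
}
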