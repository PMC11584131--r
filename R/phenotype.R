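#' Drive variant definition
#'
#' A drive construct variant determines which fluorescent markers report
#' the presence of a drive allele and whether the SSA self-excision
#' machinery is present. The plain homing drive (`"yMCR"`) carries EGFP
#' only and cannot excise itself (`ssa_enabled = FALSE`, which forces
#' `alpha = gamma = 0` in the dynamics); the self-excising variant
#' (`"yReMEDE"`) carries both EGFP and RFP.
#'
#' @param name `"yReMEDE"` (default) or `"yMCR"`.
#' @return An object of class `drive_variant` with fields `name`,
#'   `markers`, `ssa_enabled`.
#' @export
drive_variant <- function(name = c("yReMEDE", "yMCR")) {
  name <- match.arg(name)
  if (name == "yMCR") {
    structure(list(name = name, markers = "EGFP", ssa_enabled = FALSE),
              class = "drive_variant")
  } else {
    structure(list(name = name, markers = c("EGFP", "RFP"),
                   ssa_enabled = TRUE),
              class = "drive_variant")
  }
}

# force alpha (and gamma) to zero when the variant carries no excision
# machinery; returns possibly modified germline_params
.effective_params <- function(params, variant) {
  if (!is.null(variant) && !variant$ssa_enabled) {
    params$alpha_female <- 0
    params$alpha_male <- 0
    params$gamma <- 0
  }
  params
}

#' Score the visible phenotype of a genotype
#'
#' Body colour is wild type iff at least one allele is functional at the
#' target gene (`W`, `V`, or in-frame `U`); genotypes composed solely of
#' `G`, `S`, `R` score yellow. Any drive allele (`G` or `S`) makes the fly
#' fluorescent for the variant's markers.
#'
#' @param genotype Character vector of allele codes (two for females, one
#'   for males).
#' @param sex `"female"` or `"male"`.
#' @param variant A [drive_variant()] object.
#' @return List with elements `body` (`"wild"` or `"yellow"`), `egfp`,
#'   `rfp` (logicals).
#' @examples
#' score_phenotype(c("G", "W"), "female", drive_variant("yReMEDE"))
#' score_phenotype("V", "male", drive_variant("yReMEDE"))
#' @export
score_phenotype <- function(genotype, sex = c("female", "male"),
                            variant = drive_variant()) {
  sex <- match.arg(sex)
  .check_genotype(genotype, sex)
  stopifnot(inherits(variant, "drive_variant"))
  functional <- any(genotype %in% c("W", "V", "U"))
  fluorescent <- any(.is_drive_allele(genotype))
  list(body = if (functional) "wild" else "yellow",
       egfp = fluorescent && "EGFP" %in% variant$markers,
       rfp  = fluorescent && "RFP" %in% variant$markers)
}

# vectorized phenotype metadata for the 21 female / 6 male genotype
# categories, used by the population engines
.phenotype_tables <- function(variant) {
  fg <- female_genotypes()
  f_fun <- fg[, 1] %in% c("W", "V", "U") | fg[, 2] %in% c("W", "V", "U")
  f_drv <- .is_drive_allele(fg[, 1]) | .is_drive_allele(fg[, 2])
  m_fun <- .ALLELES %in% c("W", "V", "U")
  m_drv <- .is_drive_allele(.ALLELES)
  list(female = data.frame(yellow = !f_fun, drive = f_drv,
                           row.names = rownames(fg)),
       male = data.frame(yellow = !m_fun, drive = m_drv,
                         row.names = .ALLELES))
}
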