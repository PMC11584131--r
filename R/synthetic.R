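# allele code -> sequenced class, by parental origin
.seq_class_of <- function(allele, paternal = FALSE) {
  if (paternal && allele == "W") return("uncut_paternal")
  switch(allele,
         G = "drive", S = "drive", V = "TcG", W = "TGG",
         U = "indel_in_frame", R = "indel_out_frame")
}

#' Generate synthetic pair-mated cross datasets
#'
#' Draws replicate single-pair crosses from the exact offspring-category
#' law induced by the germline and zygotic models, and emits them in the
#' cross-outcome table schema (see [read_cross_table()]). The default
#' design is a "master female" cross: a heterozygous drive female (`G/W`)
#' mated to a wild-type male; the paternal design crosses a hemizygous
#' drive male to a `W/W` female.
#'
#' Parental origin is recorded truthfully when `full_genotyping = TRUE`
#' (emulating genotyping across the whole construct span, which resolves
#' zygosity in females). Otherwise male X alleles are `maternal`, female
#' drive alleles are `maternal` (the cross design identifies the drive
#' parent), and all other female alleles are `unassigned`.
#'
#' @param params A [germline_params()] object.
#' @param zparams A [zygotic_params()] object.
#' @param variant A [drive_variant()] object.
#' @param design `"maternal"` or `"paternal"`: which parent carries the
#'   drive.
#' @param n_crosses Number of crosses (>= 1).
#' @param brood_size_law Either `list(type = "poisson", mean = 50)` or
#'   `list(type = "fixed", size = n)`. Poisson broods are resampled until
#'   nonempty.
#' @param seed Integer seed.
#' @param full_genotyping Logical; see Details.
#' @return A cross-outcome data frame covering all crosses.
#' @examples
#' tab <- generate_cross_dataset(germline_params(q = 0), n_crosses = 2,
#'                               seed = 1)
#' @export
generate_cross_dataset <- function(params,
                                   zparams = zygotic_params(),
                                   variant = drive_variant("yReMEDE"),
                                   design = c("maternal", "paternal"),
                                   n_crosses = 10L,
                                   brood_size_law = list(type = "poisson",
                                                         mean = 50),
                                   seed = 1L,
                                   full_genotyping = TRUE) {
  design <- match.arg(design)
  stopifnot(inherits(params, "germline_params"),
            inherits(zparams, "zygotic_params"),
            inherits(variant, "drive_variant"))
  if (n_crosses < 1) stop("n_crosses must be at least 1", call. = FALSE)
  par <- .effective_params(params, variant)
  set.seed(seed)
  mother <- if (design == "maternal") c("G", "W") else c("W", "W")
  father <- if (design == "maternal") "W" else "G"
  g0 <- gamete_distribution(mother, "female", par)
  h0 <- gamete_distribution(father, "male", par)
  mother_drive <- any(.is_drive_allele(mother))
  father_drive <- any(.is_drive_allele(father))
  g_f <- if (father_drive) .apply_zyg_law(g0, zparams$z_paternal, par$delta) else g0
  h_f <- if (mother_drive) .apply_zyg_law(h0, zparams$z_maternal, par$delta) else h0
  pair_law <- outer(g_f, h_f)   # maternal x paternal, female offspring
  draw_brood <- function() {
    if (identical(brood_size_law$type, "fixed")) {
      as.integer(brood_size_law$size)
    } else {
      n <- 0L
      while (n < 1L) n <- stats::rpois(1L, brood_size_law$mean)
      n
    }
  }
  rows <- list()
  emit <- function(cross_id, sex, geno, allele, origin_true, paternal) {
    ph <- score_phenotype(geno, sex, variant)
    origin <- if (sex == "male") {
      "maternal"
    } else if (full_genotyping) {
      origin_true
    } else if (.is_drive_allele(allele)) {
      "maternal"
    } else {
      "unassigned"
    }
    data.frame(cross_id = cross_id, sex = sex, body = ph$body,
               egfp = ph$egfp, rfp = ph$rfp,
               seq_class = .seq_class_of(allele, paternal),
               origin = origin, count = 1L,
               stringsAsFactors = FALSE)
  }
  for (k in seq_len(n_crosses)) {
    cid <- sprintf("cross_%03d", k)
    n <- draw_brood()
    n_male <- stats::rbinom(1L, n, 0.5)
    n_female <- n - n_male
    if (n_male > 0) {
      mcounts <- as.integer(stats::rmultinom(1L, n_male, g0))
      for (j in which(mcounts > 0)) {
        a <- .ALLELES[j]
        r <- emit(cid, "male", a, a, "maternal", paternal = FALSE)
        r$count <- mcounts[j]
        rows[[length(rows) + 1L]] <- r
      }
    }
    if (n_female > 0) {
      fcounts <- matrix(stats::rmultinom(1L, n_female, pair_law), 6L, 6L)
      for (i in which(rowSums(fcounts) > 0)) {
        for (j in which(fcounts[i, ] > 0)) {
          geno <- c(.ALLELES[i], .ALLELES[j])
          n_ij <- fcounts[i, j]
          r1 <- emit(cid, "female", geno, .ALLELES[i], "maternal",
                     paternal = FALSE)
          r2 <- emit(cid, "female", geno, .ALLELES[j], "paternal",
                     paternal = TRUE)
          r1$count <- n_ij
          r2$count <- n_ij
          rows[[length(rows) + 1L]] <- r1
          rows[[length(rows) + 1L]] <- r2
        }
      }
    }
  }
  tab <- do.call(rbind, rows)
  agg <- stats::aggregate(count ~ cross_id + sex + body + egfp + rfp +
                            seq_class + origin, data = tab, FUN = sum)
  agg <- agg[order(agg$cross_id, agg$sex, agg$origin, agg$seq_class), ]
  rownames(agg) <- NULL
  .validate_cross_table(agg[, .CROSS_COLS])
}

#' Generate synthetic courtship assay records
#'
#' Emits single-pair courtship assay rows with the statistical structure
#' assumed by [courtship_index()] and [estimate_mating_cost()]: a
#' per-pairing courtship index drawn from a Beta law matched to the stated
#' mean and standard deviation (degenerate at the mean when `sd = 0`), and
#' an independent Bernoulli copulation outcome.
#'
#' @param index_law List with `mean` (mean courtship index), `sd`
#'   (standard deviation, default 0), and `copulation_prob`.
#' @param n Number of assays (0 allowed).
#' @param seed Integer seed.
#' @param observation_time Observation period per assay, seconds.
#' @return Data frame with columns `courting_time`, `observation_time`,
#'   `copulated`.
#' @export
generate_courtship_assays <- function(index_law = list(mean = 0.5, sd = 0,
                                                       copulation_prob = 1 / 30),
                                      n = 30L, seed = 1L,
                                      observation_time = 600) {
  set.seed(seed)
  if (n == 0)
    return(data.frame(courting_time = numeric(0),
                      observation_time = numeric(0),
                      copulated = logical(0)))
  mu <- index_law$mean
  sd <- if (is.null(index_law$sd)) 0 else index_law$sd
  if (sd <= 0) {
    idx <- rep(mu, n)
  } else {
    # beta by moment matching; falls back to clipping when infeasible
    v <- min(sd^2, mu * (1 - mu) * 0.999)
    k <- mu * (1 - mu) / v - 1
    idx <- stats::rbeta(n, mu * k, (1 - mu) * k)
  }
  data.frame(courting_time = idx * observation_time,
             observation_time = rep(observation_time, n),
             copulated = stats::runif(n) < index_law$copulation_prob)
}
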