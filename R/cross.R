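#' @title Cross-outcome tables
#' @description A cross-outcome table records pair-mated cross results as
#'   one row per (cross, sex, phenotype, sequenced allele class, parental
#'   origin) with a nonnegative integer `count`. Sequenced allele classes:
#'   `drive` (intact drive, or second-site-disrupted drive), `TcG`
#'   (SSA-excised marked wild type), `TGG` (plain wild-type sequence),
#'   `gGG` (silent variant of indeterminate biogenesis), `indel_in_frame`,
#'   `indel_out_frame`, and `uncut_paternal` (paternally inherited intact
#'   wild type). Origins: `maternal`, `paternal`, `unassigned`.
#' @name cross_tables
NULL

.SEQ_CLASSES <- c("drive", "TcG", "TGG", "gGG", "indel_in_frame",
                  "indel_out_frame", "uncut_paternal")
.ORIGINS <- c("maternal", "paternal", "unassigned")
.CROSS_COLS <- c("cross_id", "sex", "body", "egfp", "rfp", "seq_class",
                 "origin", "count")

.validate_cross_table <- function(tab) {
  if (!is.data.frame(tab) || !all(.CROSS_COLS %in% names(tab)))
    stop("cross table must contain columns: ",
         paste(.CROSS_COLS, collapse = ", "), call. = FALSE)
  if (nrow(tab) == 0) stop("empty cross table", call. = FALSE)
  if (any(tab$count < 0) || any(tab$count != round(tab$count)))
    stop("counts must be nonnegative integers", call. = FALSE)
  bad <- setdiff(unique(tab$seq_class), .SEQ_CLASSES)
  if (length(bad))
    stop("unknown seq_class value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(tab$origin), .ORIGINS)
  if (length(bad))
    stop("unknown origin value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(tab)
}

#' Read / write cross-outcome CSV files
#'
#' The on-disk schema is one UTF-8 comma-separated file with a header row
#' and the columns `cross_id, sex, body, egfp, rfp, seq_class, origin,
#' count`.
#'
#' @param path File path.
#' @return `read_cross_table()` returns a validated data frame.
#' @export
read_cross_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$egfp <- as.logical(tab$egfp)
  tab$rfp <- as.logical(tab$rfp)
  .validate_cross_table(tab)
}

#' @rdname read_cross_table
#' @param tab A cross-outcome data frame.
#' @export
write_cross_table <- function(tab, path) {
  .validate_cross_table(tab)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Map a sequenced allele class to a model allele state
#'
#' `TcG` identifies the marked excision product `V`; `TGG` a plain wild
#' type `W`; in-frame and out-of-frame indels the resistant classes `U`
#' and `R`; `drive` the intact drive `G` (or the SSA-immune drive `S` when
#' `isite_disrupted` is set); `uncut_paternal` a paternal `W`. The rare
#' `gGG` class has indeterminate biogenesis and maps to `"unclassified"`:
#' tabulation reports it but the dynamics ignore it.
#'
#' @param record_class One of the table's sequence classes.
#' @param isite_disrupted Logical flag: the sequenced drive allele carries
#'   a disrupted second-nuclease site.
#' @return A single allele code, or `"unclassified"`.
#' @export
classify_sequenced_allele <- function(record_class, isite_disrupted = FALSE) {
  if (!is.character(record_class) || length(record_class) != 1L ||
      !record_class %in% .SEQ_CLASSES)
    stop("unknown sequence class: ", record_class, call. = FALSE)
  switch(record_class,
         drive = if (isTRUE(isite_disrupted)) "S" else "G",
         TcG = "V",
         TGG = "W",
         uncut_paternal = "W",
         indel_in_frame = "U",
         indel_out_frame = "R",
         gGG = "unclassified")
}

#' Summarize pair-mated cross outcomes
#'
#' Computes, per cross and averaged across crosses (mean and standard
#' error), the drive-transmission fraction (fluorescent offspring), the
#' wild-phenotype and yellow-phenotype fractions, and the allele-class
#' fractions among sequenced alleles split by parental origin.
#'
#' @param tables A single cross-outcome data frame or a list of them
#'   (concatenated; `cross_id` values must be distinct across list
#'   elements to be meaningful).
#' @return List with `per_cross` (data frame: cross_id, n, drive, wild,
#'   yellow), `phenotype` (data frame: class, mean, se), and `alleles`
#'   (data frame: origin, seq_class, count, fraction within origin).
#' @export
tabulate_crosses <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  if (length(tables) == 0) stop("at least one cross required", call. = FALSE)
  tab <- do.call(rbind, lapply(tables, .validate_cross_table))
  # one offspring contributes one maternal record (and possibly a second,
  # paternal/unassigned, record in females): count individuals through the
  # maternal-or-single-allele records
  ind <- tab[tab$origin == "maternal" | tab$sex == "male", , drop = FALSE]
  if (nrow(ind) == 0) ind <- tab
  per <- lapply(split(ind, ind$cross_id), function(d) {
    n <- sum(d$count)
    if (n == 0) stop("cross with zero offspring", call. = FALSE)
    fluor <- d$egfp | d$rfp
    data.frame(cross_id = d$cross_id[1], n = n,
               drive = sum(d$count[fluor]) / n,
               wild = sum(d$count[!fluor & d$body == "wild"]) / n,
               yellow = sum(d$count[!fluor & d$body == "yellow"]) / n)
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  pheno <- data.frame(
    class = c("drive", "wild", "yellow"),
    mean = c(mean(per$drive), mean(per$wild), mean(per$yellow)),
    se = c(se(per$drive), se(per$wild), se(per$yellow)))
  agg <- stats::aggregate(count ~ origin + seq_class, data = tab, FUN = sum)
  agg$fraction <- agg$count / stats::ave(agg$count, agg$origin, FUN = sum)
  list(per_cross = per, phenotype = pheno,
       alleles = agg[order(agg$origin, agg$seq_class), ])
}

#' Courtship index
#'
#' The proportion of the observation period during which a male was
#' engaged in courtship activity.
#'
#' @param courting_time,observation_time Durations in the same units;
#'   `0 <= courting_time <= observation_time`, `observation_time > 0`.
#' @return The ratio, in `[0, 1]`.
#' @export
courtship_index <- function(courting_time, observation_time) {
  if (any(observation_time <= 0))
    stop("observation_time must be positive", call. = FALSE)
  if (any(courting_time < 0) || any(courting_time > observation_time))
    stop("courting_time must lie in [0, observation_time]", call. = FALSE)
  courting_time / observation_time
}

#' Mating cost from a competitive assay
#'
#' In each trial a focal male competes against a reference male for one
#' female; the cost is the fraction of trials the focal male lost,
#' `(trials - focal_successes) / trials`, with an exact (Clopper-Pearson)
#' binomial confidence interval.
#'
#' @param focal_successes Number of trials won by the focal male.
#' @param trials Total number of trials (> 0).
#' @param conf_level Confidence level of the exact interval.
#' @return List with `cost`, `conf_int` (length-2 vector), `successes`,
#'   `trials`.
#' @examples
#' estimate_mating_cost(1, 30)$cost   # 29/30, i.e. 0.97 at two decimals
#' @export
estimate_mating_cost <- function(focal_successes, trials,
                                 conf_level = 0.95) {
  if (length(trials) != 1L || trials <= 0 || trials != round(trials))
    stop("trials must be a positive integer", call. = FALSE)
  if (focal_successes < 0 || focal_successes > trials ||
      focal_successes != round(focal_successes))
    stop("focal_successes must be an integer in [0, trials]", call. = FALSE)
  failures <- trials - focal_successes
  bt <- stats::binom.test(failures, trials, conf.level = conf_level)
  list(cost = failures / trials,
       conf_int = as.numeric(bt$conf.int),
       successes = focal_successes, trials = as.integer(trials))
}
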