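#' Named scenario presets
#'
#' Ready-made [simulation_config()] objects for the canonical scenarios:
#' \describe{
#'   \item{`fig6b`}{Self-excising drive in a low-threshold release (10%),
#'     no mating costs; SSA at female 0.1 / male 0.01 with full marker
#'     retention (`epsilon = 1`); resistant alleles form at the empirical
#'     preset (`delta = 0.4`, cutting calibrated to ~87% heterozygous
#'     female transmission).}
#'   \item{`fig6c`}{No resistant-allele formation (cut alleles repair by
#'     HR only, preserving the calibrated conversion rate q*p); SSA ~30%
#'     with `epsilon = 0.25`.}
#'   \item{`fig6d`}{No resistant alleles; SSA ~10%, `epsilon = 1`.}
#'   \item{`fig6e`}{No resistant alleles; SSA ~5%, `epsilon = 0.25`.}
#'   \item{`cage_ymcr`}{Cage protocol, plain homing drive (EGFP only, no
#'     excision), 200 founders with 75% drive homozygotes, empirical
#'     yellow mating costs (male 0.97, female 0.31).}
#'   \item{`cage_yremede`}{As `cage_ymcr` but the self-excising variant
#'     with SSA at female 0.1 / male 0.01.}
#' }
#'
#' "No resistant alleles" presets set `q` to the calibrated product
#' `0.95 * 0.78 = 0.741` with `p = 1`: cut alleles either convert by HR or
#' are left intact, so the effective super-Mendelian transmission (~87%
#' from heterozygous females at `alpha = 0`) is unchanged while the NHEJ
#' channel is off.
#'
#' @param name Preset name.
#' @param seed Master seed stored in the config.
#' @return A [simulation_config()] object.
#' @export
drive_preset <- function(name = c("fig6b", "fig6c", "fig6d", "fig6e",
                                  "cage_ymcr", "cage_yremede"),
                         seed = 1L) {
  name <- match.arg(name)
  no_costs <- mating_costs(0, 0)
  yellow_costs <- mating_costs(0.97, 0.31)
  qp <- 0.95 * 0.78
  switch(name,
    fig6b = simulation_config(
      population_size = 1000L, generations = 60L, replicates = 100L,
      release_fraction = 0.10, release_sex = "both",
      release_zygosity = "heterozygous", seed = seed,
      germline = germline_params(q = 0.95, p = 0.78, delta = 0.4,
                                 alpha_female = 0.1, alpha_male = 0.01,
                                 gamma = 0, epsilon = 1),
      costs = no_costs, variant = drive_variant("yReMEDE")),
    fig6c = simulation_config(
      population_size = 1000L, generations = 60L, replicates = 100L,
      release_fraction = 0.10, seed = seed,
      germline = germline_params(q = qp, p = 1, delta = 0.4,
                                 alpha_female = 0.3, alpha_male = 0.03,
                                 gamma = 0, epsilon = 0.25),
      costs = no_costs, variant = drive_variant("yReMEDE")),
    fig6d = simulation_config(
      population_size = 1000L, generations = 60L, replicates = 100L,
      release_fraction = 0.10, seed = seed,
      germline = germline_params(q = qp, p = 1, delta = 0.4,
                                 alpha_female = 0.1, alpha_male = 0.01,
                                 gamma = 0, epsilon = 1),
      costs = no_costs, variant = drive_variant("yReMEDE")),
    fig6e = simulation_config(
      population_size = 1000L, generations = 60L, replicates = 100L,
      release_fraction = 0.10, seed = seed,
      germline = germline_params(q = qp, p = 1, delta = 0.4,
                                 alpha_female = 0.05, alpha_male = 0.005,
                                 gamma = 0, epsilon = 0.25),
      costs = no_costs, variant = drive_variant("yReMEDE")),
    cage_ymcr = simulation_config(
      population_size = 200L, generations = 20L, replicates = 3L,
      release_fraction = 0.75, release_sex = "both",
      release_zygosity = "homozygous", seed = seed,
      germline = germline_params(q = 0.95, p = 0.78, delta = 0.4,
                                 alpha_female = 0, alpha_male = 0,
                                 gamma = 0, epsilon = 1),
      costs = yellow_costs, variant = drive_variant("yMCR"),
      brood_size = 600L, pool_size = 150L),
    cage_yremede = simulation_config(
      population_size = 200L, generations = 25L, replicates = 3L,
      release_fraction = 0.75, release_sex = "both",
      release_zygosity = "homozygous", seed = seed,
      germline = germline_params(q = 0.95, p = 0.78, delta = 0.4,
                                 alpha_female = 0.1, alpha_male = 0.01,
                                 gamma = 0, epsilon = 1),
      costs = yellow_costs, variant = drive_variant("yReMEDE"),
      brood_size = 600L, pool_size = 150L))
}

# flat scalar keys accepted in config files and where they land
.CONFIG_KEYS <- list(
  preset = "preset", variant = "variant",
  population_size = "top", generations = "top", replicates = "top",
  release_fraction = "top", release_sex = "top", release_zygosity = "top",
  seed = "top", brood_size = "top", pool_size = "top",
  q = "germline", p = "germline", delta = "germline",
  alpha_female = "germline", alpha_male = "germline",
  gamma = "germline", epsilon = "germline",
  z_maternal = "zygotic", z_paternal = "zygotic",
  cost_yellow_male = "costs", cost_yellow_female = "costs")

# minimal flat "key: value" reader (YAML subset: scalars, comments, no
# nesting); full YAML is deliberately out of scope
.read_flat_yaml <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L)
      stop("cannot parse config line: ", ln, call. = FALSE)
    val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[m[2]]] <- if (!is.na(num)) num else gsub('^"|"$', "", val)
  }
  out
}

#' Load a simulation configuration from a file
#'
#' Reads a flat `key: value` YAML-subset file or a JSON object. A
#' `preset:` key expands to the corresponding [drive_preset()]; all other
#' keys override individual fields (germline, zygotic, cost, and top-level
#' names are accepted without prefixes, matching the parameter names of
#' the constructors). Unknown keys are rejected; out-of-range
#' probabilities raise an error naming the key. An empty file yields the
#' all-defaults configuration.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` config file.
#' @return A [simulation_config()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    .read_flat_yaml(path)
  }
  unknown <- setdiff(names(raw), names(.CONFIG_KEYS))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- if (!is.null(raw$preset)) drive_preset(raw$preset)
         else simulation_config()
  if (!is.null(raw$variant)) cfg$variant <- drive_variant(raw$variant)
  germ <- unclass(cfg$germline)
  zyg <- unclass(cfg$zygotic)
  cst <- unclass(cfg$costs)
  top <- cfg[c("population_size", "generations", "replicates",
               "release_fraction", "release_sex", "release_zygosity",
               "seed", "brood_size", "pool_size")]
  for (key in setdiff(names(raw), c("preset", "variant"))) {
    dest <- .CONFIG_KEYS[[key]]
    val <- raw[[key]]
    if (dest %in% c("germline", "zygotic", "costs") &&
        (!is.numeric(val) || val < 0 || val > 1))
      stop(sprintf("config key '%s' must be a probability in [0, 1]", key),
           call. = FALSE)
    switch(dest,
           top = top[[key]] <- val,
           germline = germ[[key]] <- val,
           zygotic = zyg[[key]] <- val,
           costs = cst[[key]] <- val)
  }
  simulation_config(
    population_size = top$population_size, generations = top$generations,
    replicates = top$replicates, release_fraction = top$release_fraction,
    release_sex = top$release_sex, release_zygosity = top$release_zygosity,
    seed = top$seed, germline = do.call(germline_params, germ),
    zygotic = do.call(zygotic_params, zyg),
    costs = do.call(mating_costs, cst), variant = cfg$variant,
    brood_size = top$brood_size, pool_size = top$pool_size)
}

#' Write a reproducibility manifest
#'
#' Serializes the configuration, derived per-replicate seeds, and package
#' version to JSON next to a run's outputs; together with the master seed
#' this reproduces every stochastic output bit for bit.
#'
#' @param config A [simulation_config()] object.
#' @param path Output JSON path.
#' @param seeds Optional integer vector of child seeds actually used.
#' @return The path, invisibly.
#' @export
write_manifest <- function(config, path, seeds = NULL) {
  cfg <- unclass(config)
  cfg$germline <- unclass(cfg$germline)
  cfg$zygotic <- unclass(cfg$zygotic)
  cfg$costs <- unclass(cfg$costs)
  cfg$variant <- unclass(cfg$variant)
  manifest <- list(
    package = "remede",
    version = as.character(utils::packageVersion("remede")),
    config = cfg,
    seeds = seeds)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Export trajectories as tidy CSV
#'
#' One row per (replicate, generation, state) with the state's frequency;
#' allele states and the three phenotype classes are both included, in the
#' `state` column.
#'
#' @param sim A `drive_simulation` from [simulate_drive()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_trajectories <- function(sim, path) {
  stopifnot(inherits(sim, "drive_simulation"))
  long <- do.call(rbind, lapply(seq_along(sim$trajectories), function(r) {
    t <- sim$trajectories[[r]]
    states <- setdiff(names(t), c("generation", "drive"))
    do.call(rbind, lapply(states, function(s)
      data.frame(replicate = r, generation = t$generation, state = s,
                 frequency = t[[s]])))
  }))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
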