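# analytic law of sequenced-allele classes by parental origin for a
# single-pair cross design; returns list(maternal = , paternal = ) of
# probability vectors over .SEQ_CLASSES
.cross_category_law <- function(params, zparams, design) {
  mother <- if (design == "maternal") c("G", "W") else c("W", "W")
  father <- if (design == "maternal") "W" else "G"
  g <- gamete_distribution(mother, "female", params)
  h <- gamete_distribution(father, "male", params)
  if (any(.is_drive_allele(father)))
    g <- .apply_zyg_law(g, zparams$z_paternal, params$delta)
  if (any(.is_drive_allele(mother)))
    h <- .apply_zyg_law(h, zparams$z_maternal, params$delta)
  to_classes <- function(d, paternal) {
    x <- stats::setNames(numeric(length(.SEQ_CLASSES)), .SEQ_CLASSES)
    x["drive"] <- d[["G"]] + d[["S"]]
    x["TcG"] <- d[["V"]]
    x[if (paternal) "uncut_paternal" else "TGG"] <- d[["W"]]
    x["indel_in_frame"] <- d[["U"]]
    x["indel_out_frame"] <- d[["R"]]
    x
  }
  list(maternal = to_classes(g, paternal = FALSE),
       paternal = to_classes(h, paternal = TRUE))
}

#' Multinomial log-likelihood of a cross-outcome table
#'
#' Scores the observed sequenced-allele class counts (split by parental
#' origin) against the law implied by the germline and zygotic models for
#' a single-pair cross in which the stated parent carries the drive.
#' Maternal-origin alleles follow the maternal gamete law; paternal-origin
#' alleles in female offspring follow the paternal gamete law after
#' zygotic deposition. The log-likelihood omits the multinomial
#' coefficient (it does not depend on the parameters). A category with
#' model probability zero but a nonzero observed count yields `-Inf`.
#'
#' Origin-unassigned records cannot be scored; tables must be origin
#' resolved (see `full_genotyping` in [generate_cross_dataset()]).
#'
#' @param params A [germline_params()] object.
#' @param zparams A [zygotic_params()] object.
#' @param table A cross-outcome data frame.
#' @param cross_design `"maternal"` or `"paternal"`.
#' @return A single numeric log-likelihood.
#' @export
cross_loglikelihood <- function(params, zparams, table,
                                cross_design = c("maternal", "paternal")) {
  cross_design <- match.arg(cross_design)
  stopifnot(inherits(params, "germline_params"),
            inherits(zparams, "zygotic_params"))
  .validate_cross_table(table)
  if (any(table$count[table$origin == "unassigned"] > 0))
    stop("table contains origin-unassigned counts; calibration requires ",
         "origin-resolved (full-genotyped) tables", call. = FALSE)
  law <- .cross_category_law(params, zparams, cross_design)
  ll <- 0
  for (org in c("maternal", "paternal")) {
    d <- table[table$origin == org, , drop = FALSE]
    if (nrow(d) == 0) next
    counts <- tapply(d$count, factor(d$seq_class, levels = .SEQ_CLASSES),
                     sum, default = 0)
    p <- law[[org]]
    nz <- counts > 0
    if (any(nz & p == 0)) return(-Inf)
    ll <- ll + sum(counts[nz] * log(p[nz]))
  }
  as.numeric(ll)
}

.FREE_PARAMS <- c("q", "qp", "delta", "alpha_female", "epsilon", "gamma")

# build a germline_params from base values + free-parameter vector
.theta_to_params <- function(theta, free, base) {
  vals <- unclass(base)
  for (nm in free) {
    if (nm == "qp") {
      vals$p <- theta[["qp"]] / vals$q
    } else {
      vals[[nm]] <- theta[[nm]]
    }
  }
  do.call(germline_params, vals[c("q", "p", "delta", "alpha_female",
                                  "alpha_male", "gamma", "epsilon")])
}

#' Fit germline parameters by maximum likelihood
#'
#' Bounded multi-start numerical maximization of the summed
#' [cross_loglikelihood()] over one or more cross-outcome tables, with
#' parametric-bootstrap confidence intervals. Cutting and conversion are
#' identifiable only through their product, so the free parameter is the
#' aggregate `"qp"` (with `q` held at its base value, which the uncut
#' `TGG` fraction pins down when sequencing data are present); requesting
#' `"q"` and `"qp"` jointly, or `"p"`, is refused.
#'
#' @param tables A cross-outcome data frame or list of them.
#' @param free_params Character subset of
#'   `c("q", "qp", "delta", "alpha_female", "epsilon", "gamma")`.
#' @param params Base [germline_params()] supplying fixed values.
#' @param zparams A [zygotic_params()] object.
#' @param cross_design `"maternal"` or `"paternal"`.
#' @param bounds Optional named list of `c(lower, upper)` per free
#'   parameter (defaults to `[0, 1]`, `qp` capped at `q`).
#' @param n_starts Random multi-starts for the optimizer (default 10).
#' @param n_boot Parametric bootstrap resamples for the confidence
#'   intervals (default 200; 0 disables).
#' @param conf_level Bootstrap interval level.
#' @param seed Seed controlling starts and bootstrap.
#' @return Object of class `drive_fit`: list with `estimates`, `loglik`,
#'   `conf_int` (rows = free parameters), `free_params`, `params` (fitted
#'   full parameter object), `n_boot`.
#' @export
fit_params <- function(tables, free_params,
                       params = germline_params(),
                       zparams = zygotic_params(),
                       cross_design = c("maternal", "paternal"),
                       bounds = NULL, n_starts = 10L, n_boot = 200L,
                       conf_level = 0.95, seed = 1L) {
  cross_design <- match.arg(cross_design)
  if (is.data.frame(tables)) tables <- list(tables)
  free_params <- unique(free_params)
  if ("p" %in% free_params)
    stop("'p' is not separately identifiable; free the aggregate 'qp' instead",
         call. = FALSE)
  bad <- setdiff(free_params, .FREE_PARAMS)
  if (length(bad))
    stop("unknown free parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (all(c("q", "qp") %in% free_params))
    stop("'q' and 'qp' cannot be freed jointly: only their product and the ",
         "uncut fraction are identifiable from one cross design",
         call. = FALSE)
  if (length(free_params) == 0) stop("no free parameters requested")
  k <- length(free_params)
  lower <- stats::setNames(rep(0, k), free_params)
  upper <- stats::setNames(rep(1, k), free_params)
  if ("qp" %in% free_params) upper["qp"] <- params$q
  for (nm in names(bounds)) {
    lower[nm] <- bounds[[nm]][1]
    upper[nm] <- bounds[[nm]][2]
  }
  # fold each table into pooled (origin x class) counts once; the
  # optimizer's objective then avoids per-evaluation table handling
  pool_counts <- function(tabs) {
    out <- list()
    for (org in c("maternal", "paternal")) {
      cts <- stats::setNames(numeric(length(.SEQ_CLASSES)), .SEQ_CLASSES)
      for (tb in tabs) {
        d <- tb[tb$origin == org, , drop = FALSE]
        if (nrow(d)) {
          add <- tapply(d$count, factor(d$seq_class, levels = .SEQ_CLASSES),
                        sum, default = 0)
          cts <- cts + add
        }
      }
      out[[org]] <- cts
    }
    out
  }
  negll_for <- function(counts) {
    function(th) {
      th <- stats::setNames(th, free_params)
      par <- tryCatch(.theta_to_params(th, free_params, params),
                      error = function(e) NULL)
      if (is.null(par)) return(1e10)
      law <- .cross_category_law(par, zparams, cross_design)
      ll <- 0
      for (org in c("maternal", "paternal")) {
        cts <- counts[[org]]
        p <- law[[org]]
        nz <- cts > 0
        if (any(nz & p == 0)) return(1e10)
        ll <- ll + sum(cts[nz] * log(p[nz]))
      }
      -ll
    }
  }
  fit_once <- function(counts) {
    negll_local <- negll_for(counts)
    if (k == 1L) {
      o <- stats::optimize(negll_local, lower = lower, upper = upper,
                           tol = 1e-9)
      return(stats::setNames(o$minimum, free_params))
    }
    starts <- rbind((lower + upper) / 2,
                    matrix(stats::runif((n_starts - 1L) * k,
                                        rep(lower, each = n_starts - 1L),
                                        rep(upper, each = n_starts - 1L)),
                           ncol = k, byrow = FALSE))
    best <- NULL
    for (s in seq_len(nrow(starts))) {
      res <- tryCatch(
        stats::optim(starts[s, ], negll_local, method = "L-BFGS-B",
                     lower = lower + 1e-12, upper = upper - 1e-12,
                     control = list(factr = 1e-8 / .Machine$double.eps)),
        error = function(e) NULL)
      if (is.null(res)) next
      if (is.null(best) || res$value < best$value - 1e-8 ||
          (abs(res$value - best$value) <= 1e-8 &&
           .lex_less(res$par, best$par))) {
        best <- res
      }
    }
    stats::setNames(best$par, free_params)
  }
  for (tb in tables) {
    .validate_cross_table(tb)
    if (any(tb$count[tb$origin == "unassigned"] > 0))
      stop("tables contain origin-unassigned counts; calibration requires ",
           "origin-resolved (full-genotyped) tables", call. = FALSE)
  }
  set.seed(seed)
  est <- fit_once(pool_counts(tables))
  fitted_par <- .theta_to_params(est, free_params, params)
  ll_hat <- sum(vapply(tables, function(tb)
    cross_loglikelihood(fitted_par, zparams, tb, cross_design), numeric(1L)))
  ci <- NULL
  if (n_boot > 0) {
    law <- .cross_category_law(fitted_par, zparams, cross_design)
    totals <- lapply(c(maternal = "maternal", paternal = "paternal"),
                     function(org) {
                       sum(vapply(tables, function(tb)
                         sum(tb$count[tb$origin == org]), numeric(1L)))
                     })
    boot <- matrix(NA_real_, n_boot, k, dimnames = list(NULL, free_params))
    zero <- stats::setNames(numeric(length(.SEQ_CLASSES)), .SEQ_CLASSES)
    for (b in seq_len(n_boot)) {
      counts_b <- list(maternal = zero, paternal = zero)
      for (org in c("maternal", "paternal")) {
        n_org <- totals[[org]]
        if (n_org == 0) next
        counts_b[[org]] <- stats::setNames(
          as.numeric(stats::rmultinom(1L, n_org, law[[org]])), .SEQ_CLASSES)
      }
      boot[b, ] <- fit_once(counts_b)
    }
    a <- (1 - conf_level) / 2
    ci <- t(apply(boot, 2, stats::quantile, probs = c(a, 1 - a),
                  na.rm = TRUE))
  }
  structure(list(estimates = est, loglik = ll_hat, conf_int = ci,
                 free_params = free_params, params = fitted_par,
                 n_boot = n_boot),
            class = "drive_fit")
}

.lex_less <- function(a, b) {
  d <- sign(a - b)
  i <- which(d != 0)
  length(i) > 0 && d[i[1]] < 0
}

#' @export
print.drive_fit <- function(x, ...) {
  cat("Maximum-likelihood germline parameter fit\n")
  for (nm in x$free_params) {
    ci <- if (!is.null(x$conf_int))
      sprintf("  [%.4f, %.4f]", x$conf_int[nm, 1], x$conf_int[nm, 2])
    else ""
    cat(sprintf("  %-14s %.4f%s\n", nm, x$estimates[[nm]], ci))
  }
  cat(sprintf("  log-likelihood: %.3f\n", x$loglik))
  invisible(x)
}
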