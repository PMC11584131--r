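.STATE_COLS <- c(W = "#777777", G = "#2ca02c", U = "#1f77b4",
                 R = "#111111", V = "#d62728", S = "#9467bd")

.plot_panel <- function(trajs, main) {
  gens <- trajs[[1]]$generation
  graphics::plot(range(gens), c(0, 1), type = "n",
                 xlab = "generation", ylab = "allele frequency",
                 main = main)
  for (t in trajs) {
    for (s in names(.STATE_COLS)) {
      graphics::lines(t$generation, t[[s]], col = .STATE_COLS[s],
                      lwd = if (length(trajs) == 1) 2 else 1)
    }
  }
  graphics::legend("topright", legend = tolower(names(.STATE_COLS)),
                   col = .STATE_COLS, lty = 1, bty = "n", cex = 0.8)
}

#' Plot replicate and mean allele-frequency trajectories
#'
#' Renders the standard two-panel layout: up to five replicates drawn at
#' random from the supplied trajectories (left), and the pointwise mean of
#' all of them (right), one line per allele class.
#'
#' @param trajectories A `drive_simulation` object, or a list of
#'   `drive_trajectory` data frames.
#' @param out_path Output file; the device is chosen from the extension
#'   (`.pdf` or `.png`).
#' @param seed Seed for the random choice of displayed replicates.
#' @return `out_path`, invisibly.
#' @export
plot_trajectories <- function(trajectories, out_path, seed = 1L) {
  if (inherits(trajectories, "drive_simulation")) {
    trajs <- trajectories$trajectories
    mean_traj <- trajectories$mean
  } else {
    trajs <- trajectories
    if (length(trajs) == 0) stop("at least one trajectory required")
    mats <- lapply(trajs, function(t)
      as.matrix(t[, setdiff(names(t), "generation")]))
    mean_traj <- cbind(generation = trajs[[1]]$generation,
                       as.data.frame(Reduce(`+`, mats) / length(mats)))
  }
  set.seed(seed)
  shown <- if (length(trajs) > 5) trajs[sort(sample(length(trajs), 5))]
           else trajs
  if (grepl("\\.png$", out_path, ignore.case = TRUE)) {
    grDevices::png(out_path, width = 1400, height = 600, res = 120)
  } else {
    grDevices::pdf(out_path, width = 11, height = 5)
  }
  on.exit(grDevices::dev.off())
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old), add = TRUE)
  .plot_panel(shown, sprintf("%d random replicates", length(shown)))
  .plot_panel(list(mean_traj), "mean of all replicates")
  invisible(out_path)
}
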