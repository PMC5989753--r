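#' Plot a positional variance diagram
#'
#' Greyscale heatmap of a positional variance matrix: rows are biomarkers in
#' the maximum-likelihood order, columns sequence positions, and cell
#' darkness the proportion of samples placing that biomarker at that
#' position (0 = white, 1 = black).
#'
#' @param pv A positional variance matrix from [positional_variance()].
#' @param file Optional PNG path; when given, the plot is written there.
#' @param main Plot title.
#' @return The input, invisibly.
#' @export
plot_pvd <- function(pv, file = NULL, main = "Positional variance diagram") {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 700)
    on.exit(grDevices::dev.off())
  }
  I <- nrow(pv)
  op <- graphics::par(mar = c(4, 12, 3, 1))
  on.exit(graphics::par(op), add = TRUE)
  # image() draws row 1 at the bottom; flip so the earliest event is on top
  graphics::image(seq_len(I), seq_len(I), t(pv[I:1, , drop = FALSE]),
                  col = grDevices::gray(seq(1, 0, length.out = 256)),
                  zlim = c(0, 1), axes = FALSE, xlab = "Sequence position",
                  ylab = "", main = main)
  graphics::axis(1, at = seq_len(I))
  graphics::axis(2, at = seq_len(I), labels = rev(rownames(pv)), las = 2,
                 cex.axis = 0.8)
  graphics::box()
  invisible(pv)
}

#' Plot stage histograms split by a grouping variable
#'
#' Side-by-side histograms of assigned stages for the levels of a grouping
#' column (age group, dementia status, APOE group).
#'
#' @param stages An `ebm_stage_assignments` data frame.
#' @param cohort The cohort data frame.
#' @param by Name of the grouping column in `cohort`.
#' @param file Optional PNG path.
#' @param drop_levels Levels of `by` to exclude (e.g. `"APOE24"`).
#' @return A table of stage counts per group, invisibly.
#' @export
plot_stage_histogram <- function(stages, cohort, by = "age_group",
                                 file = NULL, drop_levels = character()) {
  d <- merge(cohort, as.data.frame(stages)[, c("participant_id", "stage")],
             by = "participant_id")
  d <- d[!d[[by]] %in% drop_levels, , drop = FALSE]
  I <- max(d$stage)
  lv <- sort(unique(d[[by]]))
  counts <- sapply(lv, function(l) {
    tabulate(d$stage[d[[by]] == l] + 1L, nbins = I + 1L)
  })
  rownames(counts) <- 0:I
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 500)
    on.exit(grDevices::dev.off())
  }
  graphics::barplot(t(counts), beside = TRUE, legend.text = lv,
                    xlab = "Model stage", ylab = "Participants",
                    main = paste("Stages by", by))
  invisible(counts)
}
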