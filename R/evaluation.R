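## Per-cell F-score evaluation and cumulative curves.
##
## Each reference cell is matched to the predicted region with the largest
## pixel overlap; the F-score is the harmonic mean of the pixel precision
## and recall of that match, 2|A∩B| / (|A| + |B|). Cumulative curves report
## the fraction of reference cells at or above each F-score threshold, and
## per-site summaries give elementwise min/median/max across sites.

#' Per-cell F-scores between a reference and a predicted label image
#'
#' Each reference cell `A` is matched to the predicted label `B` maximizing
#' `|A∩B|` (ties broken toward the larger `B`, then the lower id);
#' `F = 2|A∩B| / (|A| + |B|)`. Reference cells with no overlapping
#' prediction get `F = 0` and `pred_id = 0`. Predicted labels may match
#' several reference cells.
#'
#' @param reference,predicted label matrices of equal size.
#' @return data.frame with one row per reference cell: `gt_id`, `pred_id`,
#'   `intersection`, `gt_area`, `pred_area`, `fscore`.
#' @export
per_cell_fscore <- function(reference, predicted) {
  reference <- validate_label_image(reference)
  predicted <- validate_label_image(predicted)
  assert_same_dim(reference, predicted, "reference and predicted")
  gt_ids <- sort(unique(reference[reference > 0]))
  empty <- data.frame(gt_id = integer(0), pred_id = integer(0),
                      intersection = integer(0), gt_area = integer(0),
                      pred_area = integer(0), fscore = numeric(0))
  if (length(gt_ids) == 0) return(empty)
  gt_area <- tabulate(reference, nbins = max(gt_ids))
  pred_area <- if (any(predicted > 0)) tabulate(predicted, nbins = max(predicted))
               else integer(0)
  ## joint counts over pixels where both are foreground
  sel <- reference > 0 & predicted > 0
  res <- data.frame(gt_id = gt_ids, pred_id = 0L, intersection = 0L,
                    gt_area = gt_area[gt_ids], pred_area = 0L, fscore = 0)
  if (any(sel)) {
    g <- reference[sel]; p <- predicted[sel]
    ov <- stats::aggregate(list(n = rep.int(1L, length(g))),
                           by = list(gt = g, pred = p), FUN = sum)
    for (i in seq_along(gt_ids)) {
      cand <- ov[ov$gt == gt_ids[i], , drop = FALSE]
      if (nrow(cand) == 0) next
      cand$parea <- pred_area[cand$pred]
      cand <- cand[order(-cand$n, -cand$parea, cand$pred), , drop = FALSE]
      best <- cand[1, ]
      res$pred_id[i] <- best$pred
      res$intersection[i] <- best$n
      res$pred_area[i] <- best$parea
      res$fscore[i] <- 2 * best$n / (res$gt_area[i] + best$parea)
    }
  }
  res
}

#' Cumulative F-score curve
#'
#' `fraction(t) = |{F >= t}| / n` over a threshold grid: the fraction of
#' reference cells segmented with an F-score at or above each threshold.
#'
#' @param fscores numeric vector of per-cell F-scores in `[0, 1]`.
#' @param threshold_grid thresholds (default 0 to 1, step 0.01).
#' @return data.frame of class `evaluation_curve` with `threshold` and
#'   `fraction`.
#' @export
cumulative_curve <- function(fscores, threshold_grid = seq(0, 1, by = 0.01)) {
  if (length(fscores) == 0) stopf("no F-scores to summarize")
  if (any(fscores < 0 | fscores > 1)) stopf("F-scores must lie in [0, 1]")
  fraction <- vapply(threshold_grid,
                     function(t) mean(fscores >= t), numeric(1))
  structure(data.frame(threshold = threshold_grid, fraction = fraction),
            class = c("evaluation_curve", "data.frame"))
}

#' Per-threshold min/median/max across site curves
#'
#' @param per_site_curves list of [cumulative_curve()] results sharing one
#'   threshold grid.
#' @return data.frame with `threshold`, `min`, `median`, `max`.
#' @export
summarize_sites <- function(per_site_curves) {
  if (length(per_site_curves) == 0) stopf("need at least one site curve")
  grid <- per_site_curves[[1]]$threshold
  for (cv in per_site_curves)
    if (!isTRUE(all.equal(cv$threshold, grid)))
      stopf("site curves use different threshold grids")
  m <- sapply(per_site_curves, function(cv) cv$fraction)
  m <- matrix(m, nrow = length(grid))
  data.frame(threshold = grid,
             min = apply(m, 1, min),
             median = apply(m, 1, stats::median),
             max = apply(m, 1, max))
}

#' Plot cumulative evaluation curves
#'
#' Line plot of the fraction (as a percentage) of cells at or above each
#' F-score threshold, optionally with a min/median/max ribbon across sites.
#'
#' @param curves a single curve, or a named list of curves; with
#'   `summary = TRUE` the list is summarized via [summarize_sites()] and
#'   drawn as a median line with a min-max ribbon.
#' @param summary draw the across-site summary instead of individual lines.
#' @return a ggplot object.
#' @export
plot_evaluation_curves <- function(curves, summary = FALSE) {
  if (inherits(curves, "evaluation_curve")) curves <- list(site = curves)
  if (summary) {
    s <- summarize_sites(curves)
    return(ggplot2::ggplot(s, ggplot2::aes(x = .data$threshold)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = 100 * .data$min,
                                        ymax = 100 * .data$max),
                           fill = "steelblue", alpha = 0.3) +
      ggplot2::geom_line(ggplot2::aes(y = 100 * .data$median),
                         color = "steelblue") +
      ggplot2::labs(x = "F-score threshold",
                    y = "% cells with F-score >= threshold") +
      ggplot2::theme_minimal())
  }
  if (is.null(names(curves)))
    names(curves) <- paste0("site", seq_along(curves))
  df <- do.call(rbind, lapply(names(curves), function(nm)
    data.frame(site = nm, threshold = curves[[nm]]$threshold,
               fraction = curves[[nm]]$fraction)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold,
                                   y = 100 * .data$fraction,
                                   color = .data$site)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "F-score threshold",
                  y = "% cells with F-score >= threshold") +
    ggplot2::theme_minimal()
}
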