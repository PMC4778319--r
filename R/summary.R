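#' Annotate a vesicle set with spatial statistics
#'
#' Adds per-vesicle nucleus distance (um), mean 4-nearest-neighbour distance
#' (nm) and size class to a vesicle table. Sets with fewer than two vesicles
#' get `NA` neighbour distances.
#'
#' @param vesicles data frame with `x_nm, y_nm, z_nm, diameter_nm`.
#' @param nucleus_mask an [sxt_volume()] nucleus mask, or `NULL` to skip the
#'   nucleus distances.
#' @param k neighbour count for [knn_mean_distance()].
#' @return the vesicle data frame with added columns `ndist_um`, `nn_nm`,
#'   `nn_flagged`, `size_class`.
#' @export
annotate_vesicles <- function(vesicles, nucleus_mask = NULL, k = 4) {
  vesicles <- as.data.frame(vesicles)
  n <- nrow(vesicles)
  vesicles$ndist_um <- if (!is.null(nucleus_mask) && n > 0)
    distance_to_nucleus(vesicles, nucleus_mask) else rep(NA_real_, n)
  if (n >= 2) {
    nn <- knn_mean_distance(vesicles, k = k)
    vesicles$nn_nm <- as.numeric(nn)
    vesicles$nn_flagged <- attr(nn, "flagged")
  } else {
    vesicles$nn_nm <- rep(NA_real_, n)
    vesicles$nn_flagged <- rep(NA, n)
  }
  vesicles$size_class <- if (n > 0) assign_size_class(vesicles$diameter_nm)
                         else character(0)
  vesicles
}

stat_block <- function(x, prefix) {
  x <- x[!is.na(x)]
  out <- if (length(x) == 0)
    c(avg = NA_real_, max = NA_real_, min = NA_real_, sd = NA_real_)
  else
    c(avg = mean(x), max = max(x), min = min(x),
      sd = if (length(x) > 1) stats::sd(x) else NA_real_)
  stats::setNames(as.list(out), paste0(prefix, "_", names(out)))
}

#' Per-cell summary of vesicle statistics
#'
#' One row per cell with the four statistic blocks (AVG/MAX/MIN/SD, sample
#' SD with n-1 denominator) for vesicle diameter (nm), distance to the
#' nuclear surface (um) and mean 4-NN distance (nm), plus the vesicle count,
#' accumulated equivalent-sphere volume (um^3) and cell volume fraction (%).
#' An empty vesicle set yields `n_vesicles = 0` with `NA` statistics; a
#' single vesicle has `MIN = AVG = MAX` and `NA` SDs.
#'
#' @param vesicles vesicle data frame (annotated or not; see
#'   [annotate_vesicles()]).
#' @param nucleus_mask an [sxt_volume()] nucleus mask (or `NULL`).
#' @param condition condition label stored in the row.
#' @param cell_volume_um3 cell volume for the volume fraction; default is
#'   the 20 um x 5 um cylinder model.
#' @return one-row data frame of class `cell_summary`.
#' @export
summarize_cell <- function(vesicles, nucleus_mask = NULL, condition = NA,
                           cell_volume_um3 = cell_volume_model(20, 5)) {
  vesicles <- as.data.frame(vesicles)
  if (nrow(vesicles) > 0 && !"ndist_um" %in% names(vesicles))
    vesicles <- annotate_vesicles(vesicles, nucleus_mask)
  acc <- if (nrow(vesicles) > 0) accumulated_volume(vesicles$diameter_nm) else 0
  out <- data.frame(condition = condition, n_vesicles = nrow(vesicles))
  blocks <- c(
    stat_block(if (nrow(vesicles) > 0) vesicles$diameter_nm else numeric(0), "diam_nm"),
    stat_block(if (nrow(vesicles) > 0) vesicles$ndist_um else numeric(0), "ndist_um"),
    stat_block(if (nrow(vesicles) > 0) vesicles$nn_nm else numeric(0), "nn_nm"))
  out <- cbind(out, as.data.frame(blocks))
  out$accumulated_volume_um3 <- acc
  out$volume_fraction_pct <- volume_fraction(acc, cell_volume_um3)
  class(out) <- c("cell_summary", class(out))
  out
}

#' Aggregate per-cell summaries of one condition
#'
#' Condition-level row: the mean over cells of every per-cell statistic plus
#' the between-cell SD, mirroring a per-condition summary table built from
#' five cells per treatment.
#'
#' @param summaries a list of [summarize_cell()] rows, or their `rbind`.
#' @return one-row data frame with `<stat>_mean` and `<stat>_cellsd` columns.
#' @export
aggregate_condition <- function(summaries) {
  if (is.data.frame(summaries)) df <- summaries
  else df <- do.call(rbind, summaries)
  if (nrow(df) < 1) stop("at least one cell summary is required")
  if (length(unique(df$condition)) != 1)
    stop("summaries mix conditions: ",
         paste(unique(df$condition), collapse = ", "))
  num <- vapply(df, is.numeric, logical(1))
  means <- vapply(df[num], mean, numeric(1), na.rm = TRUE)
  sds <- vapply(df[num], function(x) {
    x <- x[!is.na(x)]
    if (length(x) > 1) stats::sd(x) else NA_real_
  }, numeric(1))
  out <- data.frame(condition = df$condition[1], n_cells = nrow(df))
  for (nm in names(means)) {
    out[[paste0(nm, "_mean")]] <- means[[nm]]
    out[[paste0(nm, "_cellsd")]] <- sds[[nm]]
  }
  out
}

#' Pooled condition statistics table
#'
#' The headline per-condition table: for each condition, AVG/MAX/MIN/SD of
#' the per-cell vesicle counts and of the pooled per-vesicle diameters (nm),
#' nucleus distances (um) and mean 4-NN distances (nm), all vesicles of the
#' condition's cells pooled together.
#'
#' @param annotated data frame of annotated vesicles (see
#'   [annotate_vesicles()]) with columns `condition` and `cell`.
#' @return long-format data frame: `condition, quantity, avg, max, min, sd`.
#' @export
condition_table <- function(annotated) {
  stopifnot(all(c("condition", "cell") %in% names(annotated)))
  rows <- list()
  for (cond in unique(annotated$condition)) {
    sub <- annotated[annotated$condition == cond, , drop = FALSE]
    counts <- as.numeric(table(factor(sub$cell)))
    for (q in list(list("count_per_cell", counts),
                   list("diameter_nm", sub$diameter_nm),
                   list("nucleus_distance_um", sub$ndist_um),
                   list("nn4_nm", sub$nn_nm))) {
      x <- q[[2]][!is.na(q[[2]])]
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, quantity = q[[1]],
        avg = if (length(x)) mean(x) else NA_real_,
        max = if (length(x)) max(x) else NA_real_,
        min = if (length(x)) min(x) else NA_real_,
        sd = if (length(x) > 1) stats::sd(x) else NA_real_)
    }
  }
  do.call(rbind, rows)
}
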