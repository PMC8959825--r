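# Whole-genome-duplication epoch classification by Ks interval.
#
# Populus-type defaults: the recent WGD (rWGD, ~K-Pg boundary), the core
# eudicot gamma triplication, and the ancient seed-plant WGD.  Observed Ks
# ranges reported for these events fall inside the default bins; the bins
# themselves are configuration, not inference, and fully user-settable.

#' Define Ks epoch bins
#'
#' Half-open intervals `[ks_low, ks_high)`, non-overlapping and increasing.
#'
#' @param labels character vector of epoch labels.
#' @param ks_low,ks_high numeric interval bounds, same length as `labels`.
#' @return tibble of class `epoch_bins`.
#' @export
epoch_bins <- function(labels = c("rWGD", "gamma-WGT", "ancient-WGD"),
                       ks_low = c(0.10, 0.90, 3.00),
                       ks_high = c(0.50, 2.20, 5.00)) {
  stopifnot(length(labels) == length(ks_low), length(ks_low) == length(ks_high))
  if (any(ks_high <= ks_low)) abort("each bin needs ks_high > ks_low")
  ord <- order(ks_low)
  labels <- labels[ord]; ks_low <- ks_low[ord]; ks_high <- ks_high[ord]
  if (any(utils::head(ks_high, -1) > utils::tail(ks_low, -1))) {
    abort("epoch bins must not overlap")
  }
  out <- tibble(label = labels, ks_low = ks_low, ks_high = ks_high)
  class(out) <- c("epoch_bins", class(out))
  out
}

#' Classify duplicate pairs into WGD epochs by Ks
#'
#' Each pair gets the label of the first bin containing its Ks; saturated
#' pairs and pairs outside every bin are labelled `"unassigned"`.
#'
#' @param estimates a `ks_tbl` from [ks_estimate()] (needs `pair_id`, `Ks`,
#'   `saturated`).
#' @param bins an [epoch_bins()] table.
#' @return `estimates` with an added `epoch` column.
#' @export
classify_epochs <- function(estimates, bins = epoch_bins()) {
  stopifnot(all(c("pair_id", "Ks") %in% names(estimates)))
  sat <- if ("saturated" %in% names(estimates)) estimates$saturated else is.na(estimates$Ks)
  label_of <- function(ks, saturated) {
    if (saturated || is.na(ks)) return("unassigned")
    hit <- which(ks >= bins$ks_low & ks < bins$ks_high)
    if (length(hit) == 0L) "unassigned" else bins$label[hit[1]]
  }
  mutate(estimates, epoch = map_chr(seq_len(nrow(estimates)),
                                    ~ label_of(estimates$Ks[.x], sat[.x])))
}

#' Count pairs per epoch
#'
#' @param classified output of [classify_epochs()].
#' @return tibble `epoch`, `n_pairs`.
#' @export
epoch_summary <- function(classified) {
  classified |>
    group_by(.data$epoch) |>
    summarise(n_pairs = n(), .groups = "drop") |>
    arrange(.data$epoch)
}

#' Histogram of Ks values coloured by epoch
#'
#' @param object a `ks_tbl` (Ks estimates), with or without `epoch`.
#' @param bins passed to [epoch_bins()] classification when `epoch` absent.
#' @param binwidth histogram bin width on the Ks axis.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ks_tbl <- function(object, bins = epoch_bins(), binwidth = 0.1, ...) {
  if (!"epoch" %in% names(object)) object <- classify_epochs(object, bins)
  df <- filter(object, !is.na(.data$Ks))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$Ks, fill = .data$epoch)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0) +
    ggplot2::labs(
      x = "Ks (synonymous substitutions per synonymous site)",
      y = "duplicate pairs", fill = "epoch"
    ) +
    ggplot2::theme_minimal()
}
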