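# Occupancy-based superenhancer calling: stitch occupancy peaks near
# transcribed enhancers into regions, rank by width-normalized signal, and
# flag regions above a rank-curve elbow. This is the occupancy-based
# construct that the function-based synergy classification is contrasted
# with.

#' Stitch occupancy peaks near enhancers into regions
#'
#' Keeps peaks within `proximity` bp of any enhancer and single-linkage
#' merges them when they fall within `stitch_dist` of each other. Region
#' signal is width-normalized: sum of peak signals divided by the sum of
#' peak widths.
#'
#' @param peaks Peak tibble (`chrom`, `start`, `end`, `signal`).
#' @param enhancers Enhancer tibble (`chrom`, `start`, `end`).
#' @param stitch_dist Maximal gap for stitching in bp (default 12500).
#' @param proximity Maximal gap between a peak and an enhancer (default 1000).
#' @return Tibble `region_id`, `chrom`, `start`, `end`, `n_peaks`, `signal`.
#' @export
stitch_regions <- function(peaks, enhancers, stitch_dist = 12500,
                           proximity = 1000) {
  stopifnot_cols(peaks, c("chrom", "start", "end", "signal"))
  empty <- tibble(region_id = character(), chrom = character(),
                  start = numeric(), end = numeric(), n_peaks = integer(),
                  signal = numeric())
  if (nrow(peaks) == 0L) return(empty)
  near <- min_gap_distance(peaks, enhancers) <= proximity
  kept <- peaks[near, ]
  if (nrow(kept) == 0L) return(empty)
  red <- reduce_intervals(kept, stitch_dist)
  red |>
    arrange(.data$chrom, .data$start) |>
    mutate(region_id = sprintf("se_region%03d", row_number()),
           n_peaks = lengths(.data$members),
           signal = map_dbl(.data$members, function(ix) {
             sum(kept$signal[ix]) / sum(kept$end[ix] - kept$start[ix])
           })) |>
    select("region_id", "chrom", "start", "end", "n_peaks", "signal")
}

#' Elbow cutoff on a ranked signal curve
#'
#' Sorts signals ascending, min-max scales both rank and signal to \[0, 1\],
#' and sets the cutoff at the signal of the first rank where the discrete
#' scaled slope exceeds 1; entries above the cutoff are flagged. On a
#' perfectly linear ramp the slope never exceeds 1 and nothing is flagged
#' (conservative tie rule).
#'
#' @param signals Numeric vector (>= 3 values).
#' @return List `cutoff_signal`, `is_super` (logical, in input order).
#' @examples
#' elbow_cutoff((0:10)^2)$cutoff_signal  # 25
#' @export
elbow_cutoff <- function(signals) {
  if (length(signals) < 3) abort("need >= 3 regions for an elbow cutoff")
  s <- sort(signals)
  n <- length(s)
  if (s[n] == s[1]) {
    warn("constant signals: no superenhancers called")
    return(list(cutoff_signal = Inf, is_super = rep(FALSE, length(signals))))
  }
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - s[1]) / (s[n] - s[1])
  slope <- diff(y) / diff(x)
  cross <- which(slope > 1)
  if (length(cross) == 0L) {
    return(list(cutoff_signal = Inf, is_super = rep(FALSE, length(signals))))
  }
  cutoff <- s[cross[1]]
  list(cutoff_signal = cutoff, is_super = signals > cutoff)
}

#' Call superenhancers from occupancy peaks
#'
#' Runs [stitch_regions()] and [elbow_cutoff()] and returns ranked regions.
#'
#' @inheritParams stitch_regions
#' @return Tibble of class `encoop_superenhancers` with `rank` (1 = highest
#'   signal), `is_super`, and the cutoff in attribute `cutoff_signal`.
#' @export
call_superenhancers <- function(peaks, enhancers, stitch_dist = 12500,
                                proximity = 1000) {
  regions <- stitch_regions(peaks, enhancers, stitch_dist, proximity)
  if (nrow(regions) < 3L) {
    warn("fewer than 3 stitched regions: no cutoff computed")
    regions$rank <- rank(-regions$signal)
    regions$is_super <- FALSE
    attr(regions, "cutoff_signal") <- Inf
    class(regions) <- c("encoop_superenhancers", class(regions))
    return(regions)
  }
  eb <- elbow_cutoff(regions$signal)
  regions <- regions |>
    mutate(rank = as.integer(rank(-.data$signal, ties.method = "first")),
           is_super = eb$is_super) |>
    arrange(.data$rank)
  attr(regions, "cutoff_signal") <- eb$cutoff_signal
  class(regions) <- c("encoop_superenhancers", class(regions))
  regions
}
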