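# Binned coverage and amplified-segment calling.

#' Bin a depth track
#'
#' Mean per-base depth in fixed-width bins (default 3 kb) tiling each
#' chromosome from position 1 to the last covered base; `log2_depth` is
#' `NA` for empty bins.
#'
#' @param track a `depth_track` tibble (1-based inclusive runs).
#' @param bin_size bin width, bp (>= 1).
#' @param chrom_lengths optional named vector fixing the tiled extent per
#'   chromosome (defaults to the last covered position).
#' @return tibble of class `coverage_bins`: `chrom`, `start`, `end`, `depth`
#'   (mean per-base), `log2_depth`, and a `bin_size` attribute.
#' @export
bin_depth <- function(track, bin_size = 3000, chrom_lengths = NULL) {
  if (bin_size < 1) abort("bin_size must be >= 1")
  track <- as_tibble(track)
  out <- list()
  chroms <- if (!is.null(chrom_lengths)) names(chrom_lengths) else
    unique(track$chrom)
  for (ch in chroms) {
    runs <- track[track$chrom == ch, , drop = FALSE]
    len <- if (!is.null(chrom_lengths)) chrom_lengths[[ch]] else
      if (nrow(runs) > 0) max(runs$end) else 0
    if (len < 1) next
    n_bins <- ceiling(len / bin_size)
    starts <- (seq_len(n_bins) - 1) * bin_size + 1
    ends <- pmin(starts + bin_size - 1, len)
    sums <- numeric(n_bins)
    if (nrow(runs) > 0) {
      for (i in seq_len(nrow(runs))) {
        b1 <- (runs$start[i] - 1) %/% bin_size + 1
        b2 <- (runs$end[i] - 1) %/% bin_size + 1
        for (b in b1:b2) {
          ov <- min(runs$end[i], ends[b]) - max(runs$start[i], starts[b]) + 1
          sums[b] <- sums[b] + ov * runs$depth[i]
        }
      }
    }
    mean_depth <- sums / (ends - starts + 1)
    out[[length(out) + 1]] <- tibble(chrom = ch, start = starts, end = ends,
                                     depth = mean_depth,
                                     log2_depth = ifelse(mean_depth > 0,
                                                         log2(mean_depth),
                                                         NA_real_))
  }
  bins <- bind_rows(out)
  attr(bins, "bin_size") <- bin_size
  class(bins) <- unique(c("coverage_bins", class(bins)))
  bins
}

#' Estimate the unamplified baseline depth
#'
#' Median bin depth outside user-declared candidate amplified regions (or
#' over all bins when none are declared).
#'
#' @param bins a `coverage_bins` tibble.
#' @param exclude optional tibble (`chrom`, `start`, `end`) of candidate
#'   amplified regions to leave out of the estimate.
#' @return scalar baseline depth.
#' @export
estimate_baseline <- function(bins, exclude = NULL) {
  bins <- as_tibble(bins)
  keep <- rep(TRUE, nrow(bins))
  if (!is.null(exclude) && nrow(exclude) > 0) {
    for (i in seq_len(nrow(exclude))) {
      keep <- keep & !(bins$chrom == exclude$chrom[i] &
                         bins$start <= exclude$end[i] &
                         bins$end >= exclude$start[i])
    }
  }
  if (!any(keep)) abort("no bins left to estimate a baseline from")
  median(bins$depth[keep])
}

#' Call amplified segments from binned coverage
#'
#' Maximal runs of bins with depth at least `min_fold` times the baseline;
#' runs separated by at most `merge_gap` bins are merged, and merged runs
#' shorter than `min_len` bins are dropped.
#'
#' @param bins a `coverage_bins` tibble.
#' @param baseline unamplified depth (> 0); see [estimate_baseline()].
#' @param min_fold calling threshold as fold over baseline (> 1).
#' @param merge_gap maximum number of sub-threshold bins bridged, in bins.
#' @param min_len minimum segment length, in bins.
#' @return tibble of segments: `chrom`, `start`, `end` (1-based inclusive),
#'   `n_bins`, `mean_depth`, `fold`.
#' @export
call_amplified_segments <- function(bins, baseline, min_fold = 3,
                                    merge_gap = 2, min_len = 2) {
  if (baseline <= 0) abort("baseline must be > 0")
  if (min_fold <= 1) abort("min_fold must be > 1")
  bins <- as_tibble(bins)
  out <- list()
  for (ch in unique(bins$chrom)) {
    sub <- bins[bins$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start), ]
    hot <- sub$depth >= min_fold * baseline
    if (!any(hot)) next
    idx <- which(hot)
    # merge runs of hot bins separated by <= merge_gap cold bins
    grp <- cumsum(c(1, diff(idx) > merge_gap + 1))
    for (g in unique(grp)) {
      members <- idx[grp == g]
      span <- seq(min(members), max(members))
      if (length(span) < min_len) next
      out[[length(out) + 1]] <- tibble(
        chrom = ch, start = sub$start[min(members)],
        end = sub$end[max(members)], n_bins = length(span),
        mean_depth = mean(sub$depth[span]),
        fold = mean(sub$depth[span]) / baseline)
    }
  }
  if (length(out) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  n_bins = integer(), mean_depth = numeric(),
                  fold = numeric()))
  }
  bind_rows(out) %>% arrange(.data$chrom, .data$start)
}

#' Total amplified length per chromosome
#'
#' @param segments tibble of amplified segments (`chrom`, `start`, `end`,
#'   1-based inclusive).
#' @return tibble with `chrom`, `n_segments`, `total_bp`.
#' @export
amplified_length_summary <- function(segments) {
  segments <- as_tibble(segments)
  if (nrow(segments) == 0) {
    return(tibble(chrom = character(), n_segments = integer(),
                  total_bp = numeric()))
  }
  segments %>%
    group_by(.data$chrom) %>%
    summarise(n_segments = dplyr::n(),
              total_bp = sum(.data$end - .data$start + 1), .groups = "drop")
}

intervals_to_iranges <- function(x) {
  split(IRanges::IRanges(start = x$start, end = x$end), x$chrom)
}

#' Compare two amplified-segment sets
#'
#' Interval algebra between an earlier (`a`) and a later (`b`) amplified
#' state: retained intervals (`a` intersect `b`), lost intervals (`a`
#' minus `b`) and the lost fraction of `a`, per chromosome.
#'
#' @param a,b tibbles of segments (`chrom`, `start`, `end`, 1-based
#'   inclusive).
#' @return list with `$retained`, `$lost` (interval tibbles) and
#'   `$summary` (per-chrom `bp_a`, `bp_retained`, `bp_lost`,
#'   `fraction_lost`).
#' @export
compare_amplified_segments <- function(a, b) {
  a <- merge_intervals(as_tibble(a)[, c("chrom", "start", "end")])
  b <- merge_intervals(as_tibble(b)[, c("chrom", "start", "end")])
  chroms <- unique(a$chrom)
  retained <- list(); lost <- list(); summary <- list()
  for (ch in chroms) {
    ra <- IRanges::IRanges(start = a$start[a$chrom == ch],
                           end = a$end[a$chrom == ch])
    rb <- IRanges::IRanges(start = b$start[b$chrom == ch],
                           end = b$end[b$chrom == ch])
    keep <- IRanges::intersect(ra, rb)
    gone <- IRanges::setdiff(ra, rb)
    if (length(keep) > 0) {
      retained[[length(retained) + 1]] <- tibble(
        chrom = ch, start = IRanges::start(keep), end = IRanges::end(keep))
    }
    if (length(gone) > 0) {
      lost[[length(lost) + 1]] <- tibble(
        chrom = ch, start = IRanges::start(gone), end = IRanges::end(gone))
    }
    bp_a <- sum(IRanges::width(ra))
    bp_lost <- sum(IRanges::width(gone))
    summary[[length(summary) + 1]] <- tibble(
      chrom = ch, bp_a = bp_a, bp_retained = sum(IRanges::width(keep)),
      bp_lost = bp_lost,
      fraction_lost = if (bp_a > 0) bp_lost / bp_a else NA_real_)
  }
  empty <- tibble(chrom = character(), start = numeric(), end = numeric())
  list(retained = if (length(retained)) bind_rows(retained) else empty,
       lost = if (length(lost)) bind_rows(lost) else empty,
       summary = bind_rows(summary))
}

#' Rebuild a step depth track from called segments
#'
#' Utility for idempotence checks: a track that is `baseline` everywhere and
#' `mean_depth` over each segment.
#'
#' @param segments called segments (with `mean_depth`).
#' @param baseline unamplified depth.
#' @param chrom_lengths named vector of chromosome lengths.
#' @return a `depth_track`.
#' @export
segments_to_track <- function(segments, baseline, chrom_lengths) {
  runs <- list()
  for (ch in names(chrom_lengths)) {
    sub <- segments[segments$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start), ]
    bounds <- sort(unique(c(1, sub$start, sub$end + 1, chrom_lengths[[ch]] + 1)))
    starts <- bounds[-length(bounds)]
    ends <- bounds[-1] - 1
    depth <- vapply(starts, function(s) {
      hit <- sub$mean_depth[sub$start <= s & sub$end >= s]
      if (length(hit) > 0) hit[1] else baseline
    }, numeric(1))
    runs[[length(runs) + 1]] <- tibble(chrom = ch, start = starts,
                                       end = ends, depth = depth)
  }
  depth_track(bind_rows(runs))
}
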