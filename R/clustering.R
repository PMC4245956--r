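# Max-gap single-linkage breakpoint clustering.

#' Cluster breakpoints by single linkage at a maximum gap
#'
#' Sorts breakends per chromosome and chains consecutive positions whose
#' distance is at most `max_gap`; chains of two or more breakends are
#' clusters, the rest singletons. Deterministic. The default
#' `max_gap = 2000` bp separates published within-cluster gaps (largest
#' 1823 bp) from between-cluster separations (all above 2 kb).
#'
#' @param breakends tibble with `chrom`, `pos` (and optionally `label`,
#'   carried through).
#' @param max_gap maximum within-cluster gap, bp (>= 1).
#' @return `breakends` sorted, with `cluster` (id, `NA` for singletons) and
#'   `gap_to_prev` (distance to the previous member within a cluster) added.
#' @export
cluster_breakpoints <- function(breakends, max_gap = 2000) {
  if (max_gap < 1) abort("max_gap must be >= 1")
  b <- as_tibble(breakends) %>% arrange(.data$chrom, .data$pos)
  if (nrow(b) == 0) {
    b$cluster <- character(0)
    b$gap_to_prev <- numeric(0)
    return(b)
  }
  b <- b %>%
    group_by(.data$chrom) %>%
    mutate(gap = .data$pos - lag(.data$pos),
           new_group = is.na(.data$gap) | .data$gap > max_gap,
           grp = cumsum(.data$new_group)) %>%
    ungroup() %>%
    mutate(grp_key = paste0(.data$chrom, ":", .data$grp))
  sizes <- table(b$grp_key)
  multi <- names(sizes)[sizes >= 2]
  cluster_ids <- setNames(paste0("C", seq_along(multi)), multi)
  b$cluster <- unname(cluster_ids[b$grp_key])
  b$gap_to_prev <- ifelse(!is.na(b$cluster) & !b$new_group, b$gap, NA_real_)
  b %>% select(-"gap", -"new_group", -"grp", -"grp_key")
}

#' Per-cluster report table
#'
#' One row per cluster: ordered member labels with the gaps between
#' consecutive members, the span (last minus first position) and the anchor
#' (first position).
#'
#' @param clustered output of [cluster_breakpoints()].
#' @return tibble with `cluster`, `chrom`, `n_members`, `members` (labels
#'   with parenthesized gaps), `span`, `anchor`, plus list-columns
#'   `positions` and `gaps`.
#' @export
cluster_summary <- function(clustered) {
  b <- as_tibble(clustered) %>% filter(!is.na(.data$cluster))
  if (nrow(b) == 0) {
    return(tibble(cluster = character(), chrom = character(),
                  n_members = integer(), members = character(),
                  span = numeric(), anchor = numeric(),
                  positions = list(), gaps = list()))
  }
  labels <- b[["label"]] %||% paste0(b$chrom, ":", format_pos(b$pos))
  b$`.label` <- labels
  b %>%
    group_by(.data$cluster, .data$chrom) %>%
    arrange(.data$pos, .by_group = TRUE) %>%
    summarise(
      n_members = dplyr::n(),
      members = paste0(.data$.label,
                       ifelse(is.na(lead(.data$pos)), "",
                              paste0(" (", lead(.data$pos) - .data$pos, ")")),
                       collapse = " "),
      span = max(.data$pos) - min(.data$pos),
      anchor = min(.data$pos),
      positions = list(.data$pos),
      gaps = list(diff(.data$pos)),
      .groups = "drop") %>%
    arrange(.data$chrom, .data$anchor)
}

#' Fraction of breakends lying in clusters
#'
#' @param clustered output of [cluster_breakpoints()].
#' @return scalar: members of groups of two or more, over all breakends.
#' @export
clustered_fraction <- function(clustered) {
  b <- as_tibble(clustered)
  if (nrow(b) == 0) return(NA_real_)
  mean(!is.na(b$cluster))
}

#' Assign new breakends to existing clusters or form new ones
#'
#' Each new breakend within `max_gap` of an existing cluster's span is
#' assigned to (and extends) that cluster; the remainder are pooled and
#' re-clustered among themselves into new clusters and singletons.
#'
#' @param clusters_ref cluster report from [cluster_summary()] on the
#'   reference passage.
#' @param breakends_new tibble with `chrom`, `pos` (optional `label`) of
#'   the new passage's novel breakends.
#' @param max_gap maximum gap, bp.
#' @return list with `$assigned` (new breakends mapped to existing
#'   clusters), `$new_clusters` (cluster report of the leftover pool) and
#'   `$new_singletons`.
#' @export
assign_new_breakpoints <- function(clusters_ref, breakends_new,
                                   max_gap = 2000) {
  new <- as_tibble(breakends_new)
  if (nrow(new) == 0) {
    return(list(assigned = new, new_clusters = cluster_summary(
      cluster_breakpoints(new, max_gap)), new_singletons = new))
  }
  ref <- as_tibble(clusters_ref)
  assigned_to <- rep(NA_character_, nrow(new))
  for (i in seq_len(nrow(new))) {
    same <- ref$chrom == new$chrom[i]
    if (!any(same)) next
    lo <- ref$anchor - max_gap
    hi <- ref$anchor + ref$span + max_gap
    hit <- same & new$pos[i] >= lo & new$pos[i] <= hi
    if (any(hit)) {
      # closest cluster wins if several are in reach
      d <- pmax(0, pmax(lo - new$pos[i], new$pos[i] - hi))
      d[!hit] <- Inf
      assigned_to[i] <- ref$cluster[which.min(d)]
    }
  }
  assigned <- new[!is.na(assigned_to), , drop = FALSE]
  assigned$cluster <- assigned_to[!is.na(assigned_to)]
  rest <- new[is.na(assigned_to), , drop = FALSE]
  rec <- cluster_breakpoints(rest, max_gap)
  list(assigned = assigned,
       new_clusters = cluster_summary(rec),
       new_singletons = rec %>% filter(is.na(.data$cluster)) %>%
         select(-"cluster", -"gap_to_prev"))
}
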