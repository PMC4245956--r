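# Junction-arm adjacency links, contig assembly, coordinated pairs.

#' Candidate arm links between junctions
#'
#' Finds all pairs of facing breakends from distinct junctions that delimit
#' a short retained reference fragment: on one chromosome, the
#' lower-coordinate breakend must retain rightwards (`"-"`) and the higher
#' one leftwards (`"+"`), at most `max_link` bp apart. Such a fragment is
#' carried intact inside the amplicon, chaining its two junctions. Fragment
#' length is the breakend position difference, the same arithmetic as
#' published cluster gaps. A breakend may appear in several candidate links.
#'
#' @param x a `jx_tbl` junction tibble.
#' @param max_link maximum fragment length, bp.
#' @return tibble of links sorted by `frag_len`: `id_low`, `arm_low`,
#'   `id_high`, `arm_high`, `chrom`, `start`, `end`, `frag_len`.
#' @export
build_arm_links <- function(x, max_link = 5000) {
  b <- junction_breakends(x)
  out <- list()
  for (ch in unique(b$chrom)) {
    lows <- b[b$chrom == ch & b$orient == "-", , drop = FALSE]
    highs <- b[b$chrom == ch & b$orient == "+", , drop = FALSE]
    if (nrow(lows) == 0 || nrow(highs) == 0) next
    grid <- tidyr::expand_grid(i = seq_len(nrow(lows)),
                               j = seq_len(nrow(highs)))
    # len 0 is a single-base fragment: both arms at the same coordinate
    len <- highs$pos[grid$j] - lows$pos[grid$i]
    ok <- len >= 0 & len <= max_link & lows$id[grid$i] != highs$id[grid$j]
    if (!any(ok)) next
    out[[length(out) + 1]] <- tibble(
      id_low = lows$id[grid$i[ok]], arm_low = lows$arm[grid$i[ok]],
      id_high = highs$id[grid$j[ok]], arm_high = highs$arm[grid$j[ok]],
      chrom = ch, start = lows$pos[grid$i[ok]], end = highs$pos[grid$j[ok]],
      frag_len = len[ok])
  }
  if (length(out) == 0) {
    return(tibble(id_low = character(), arm_low = character(),
                  id_high = character(), arm_high = character(),
                  chrom = character(), start = numeric(), end = numeric(),
                  frag_len = numeric()))
  }
  bind_rows(out) %>% arrange(.data$frag_len)
}

#' Assemble contigs from arm links
#'
#' Greedy link resolution followed by path extraction. Each breakend keeps
#' only its shortest candidate link; a link survives when both of its
#' breakends keep it. A breakend whose shortest candidates tie is ambiguous
#' and is handled per `ambiguity_policy`: `"break"` (default) drops all its
#' links and flags it, so the chain is interrupted there. Surviving links
#' form a graph on junctions in which every junction has at most one link
#' per arm; connected components are simple paths (linear contigs) or
#' cycles (circular contigs, flagged — the closed-circle topology of
#' extrachromosomal amplicons).
#'
#' @param links candidate links from [build_arm_links()].
#' @param junctions the characterized junction tibble the links were built
#'   from (used to report per-junction microhomology when available).
#' @param ambiguity_policy `"break"` or `"keep_first"` (keep the first of
#'   the tied shortest links, in sorted order).
#' @return tibble of class `contig_tbl`: one row per contig with
#'   `contig_id`, `n_junctions`, `circular`, `chrom`, and list-columns
#'   `junction_ids`, `mh`, `frag_lengths`, `distances` (bp gaps between
#'   consecutive fragments in the normal genome; for a single-fragment
#'   contig, the distance between the two outer arms). The ambiguous
#'   breakends, if any, are in `attr(, "ambiguous")`.
#' @export
assemble_contigs <- function(links, junctions,
                             ambiguity_policy = c("break", "keep_first")) {
  ambiguity_policy <- match.arg(ambiguity_policy)
  jx <- as_tibble(junctions)
  empty <- tibble(contig_id = character(), n_junctions = integer(),
                  circular = logical(), chrom = character(),
                  junction_ids = list(), mh = list(), frag_lengths = list(),
                  distances = list())
  class(empty) <- unique(c("contig_tbl", class(empty)))
  if (nrow(links) == 0) return(empty)
  links <- links %>% arrange(.data$frag_len)
  links$link_id <- seq_len(nrow(links))
  ends_of <- function(l) c(paste0(l$id_low, ":", l$arm_low),
                           paste0(l$id_high, ":", l$arm_high))
  # choose the shortest link per breakend
  be_links <- bind_rows(
    tibble(be = paste0(links$id_low, ":", links$arm_low),
           link_id = links$link_id, frag_len = links$frag_len),
    tibble(be = paste0(links$id_high, ":", links$arm_high),
           link_id = links$link_id, frag_len = links$frag_len))
  ambiguous <- character(0)
  chosen <- be_links %>%
    group_by(.data$be) %>%
    arrange(.data$frag_len, .data$link_id, .by_group = TRUE) %>%
    summarise(best = first(.data$link_id),
              tie = dplyr::n() > 1 &&
                sum(.data$frag_len == first(.data$frag_len)) > 1,
              .groups = "drop")
  if (ambiguity_policy == "break") {
    ambiguous <- chosen$be[chosen$tie]
    chosen <- chosen[!chosen$tie, , drop = FALSE]
  }
  keep_of <- setNames(chosen$best, chosen$be)
  survives <- vapply(seq_len(nrow(links)), function(i) {
    e <- ends_of(links[i, ])
    all(e %in% names(keep_of)) && all(keep_of[e] == links$link_id[i])
  }, logical(1))
  sl <- links[survives, , drop = FALSE]
  if (nrow(sl) == 0) {
    attr(empty, "ambiguous") <- ambiguous
    return(empty)
  }
  # graph on junctions; each junction has <= 2 surviving links (one per arm)
  edges <- sl
  adj <- lapply(split(c(seq_len(nrow(edges)), seq_len(nrow(edges))),
                      c(edges$id_low, edges$id_high)), unique)
  nodes <- names(adj)
  visited_edge <- rep(FALSE, nrow(edges))
  visited_node <- setNames(rep(FALSE, length(nodes)), nodes)
  contigs <- list()
  walk <- function(start) {
    # returns ordered node and edge sequences from a terminal or cycle start
    node_seq <- start
    edge_seq <- integer(0)
    cur <- start
    repeat {
      nxt_edges <- setdiff(adj[[cur]], edge_seq)
      nxt_edges <- nxt_edges[!visited_edge[nxt_edges]]
      if (length(nxt_edges) == 0) break
      e <- nxt_edges[1]
      visited_edge[e] <<- TRUE
      other <- if (edges$id_low[e] == cur) edges$id_high[e] else edges$id_low[e]
      edge_seq <- c(edge_seq, e)
      if (other == node_seq[1] && length(node_seq) > 1) {
        # cycle closed
        return(list(nodes = node_seq, edges = edge_seq, circular = TRUE))
      }
      node_seq <- c(node_seq, other)
      cur <- other
    }
    list(nodes = node_seq, edges = edge_seq, circular = FALSE)
  }
  degree <- vapply(adj, length, integer(1))
  order_starts <- c(nodes[degree == 1], nodes[degree != 1])
  cid <- 0
  for (start in order_starts) {
    if (visited_node[start]) next
    w <- walk(start)
    if (length(w$edges) == 0) { visited_node[start] <- TRUE; next }
    visited_node[w$nodes] <- TRUE
    cid <- cid + 1
    contigs[[cid]] <- w
  }
  mh_of <- if ("mh_len" %in% names(jx)) setNames(jx$mh_len, jx$id) else NULL
  rows <- purrr::map(contigs, function(w) {
    le <- edges[w$edges, , drop = FALSE]
    dist <- contig_distances(w, le, jx)
    tibble(n_junctions = length(w$nodes), circular = w$circular,
           chrom = paste(unique(le$chrom), collapse = ","),
           junction_ids = list(w$nodes),
           mh = list(if (is.null(mh_of)) rep(NA_real_, length(w$nodes))
                     else unname(mh_of[w$nodes])),
           frag_lengths = list(le$frag_len),
           distances = list(dist))
  })
  out <- bind_rows(rows)
  out$contig_id <- paste0("ctg", seq_len(nrow(out)))
  out <- out[, c("contig_id", "n_junctions", "circular", "chrom",
                 "junction_ids", "mh", "frag_lengths", "distances")]
  class(out) <- unique(c("contig_tbl", class(out)))
  attr(out, "ambiguous") <- ambiguous
  out
}

# genomic distances between consecutive contig fragments; single-fragment
# contigs get the distance between the two outer (non-bordering) arms.
contig_distances <- function(w, le, jx) {
  if (nrow(le) >= 2) {
    vapply(seq_len(nrow(le) - 1), function(i) {
      if (le$chrom[i] != le$chrom[i + 1]) return(NA_real_)
      max(0, max(le$start[i + 1] - le$end[i], le$start[i] - le$end[i + 1]))
    }, numeric(1))
  } else if (nrow(le) == 1 && length(w$nodes) == 2) {
    b <- junction_breakends(jx[jx$id %in% w$nodes, , drop = FALSE])
    inner <- paste0(c(le$id_low, le$id_high), ":", c(le$arm_low, le$arm_high))
    outer <- b[!(paste0(b$id, ":", b$arm) %in% inner), , drop = FALSE]
    if (nrow(outer) == 2 && length(unique(outer$chrom)) == 1) {
      abs(diff(outer$pos))
    } else {
      NA_real_
    }
  } else {
    numeric(0)
  }
}

#' Contig report and microhomology summary
#'
#' Formats assembled (or replayed) contigs as one row per contig and
#' summarizes their junction microhomologies: the fraction of blunt
#' junctions (mh 0) and the fraction with microhomology above 2 bp, over
#' all microhomology values in the contigs.
#'
#' @param contigs a `contig_tbl` (from [assemble_contigs()]) or any tibble
#'   with list-columns `mh` and `frag_lengths`.
#' @return list with `$table` (one formatted row per contig: junctions,
#'   microhomologies, fragment lengths, distances as strings) and `$stats`
#'   (one-row tibble: `n_contigs`, `n_junction_mh`, `frac_blunt`,
#'   `frac_mh_gt2`, `n_frag_gt10kb`).
#' @export
contig_summary <- function(contigs) {
  x <- as_tibble(contigs)
  fmt <- function(v) vapply(v, function(e) paste(e, collapse = " - "),
                            character(1))
  tab <- tibble(
    contig_id = x[["contig_id"]] %||% paste0("ctg", seq_len(nrow(x))),
    n_junctions = x[["n_junctions"]] %||%
      purrr::map_int(x$mh, length),
    junctions = if ("junction_ids" %in% names(x)) fmt(x$junction_ids) else
      NA_character_,
    mh = fmt(x$mh),
    frag_lengths = fmt(x$frag_lengths),
    distances = if ("distances" %in% names(x)) fmt(x$distances) else
      NA_character_)
  mh_all <- unlist(x$mh)
  mh_all <- mh_all[!is.na(mh_all)]
  frags <- unlist(x$frag_lengths)
  stats <- tibble(
    n_contigs = nrow(x),
    n_junction_mh = length(mh_all),
    frac_blunt = if (length(mh_all)) mean(mh_all == 0) else NA_real_,
    frac_mh_gt2 = if (length(mh_all)) mean(mh_all > 2) else NA_real_,
    n_frag_gt10kb = sum(frags > 1e4, na.rm = TRUE))
  list(table = tab, stats = stats)
}

#' Detect coordinated junction pairs
#'
#' Finds pairs of junctions whose arms are pairwise co-located at two remote
#' loci: one arm of each junction within `max_intra` bp of the other's arm
#' at locus X, the remaining two arms within `max_intra` at locus Y, with X
#' and Y at least `min_inter` apart (different chromosomes count as remote).
#' Such geometry suggests the two double-strand breaks were repaired
#' concomitantly while the remote regions were held together.
#'
#' @param x a `jx_tbl` junction tibble.
#' @param max_intra maximum arm co-location distance, bp.
#' @param min_inter minimum separation of the two loci, bp.
#' @return tibble with `id1`, `id2`, locus coordinates and distances:
#'   `chrom_x`, `d_x`, `chrom_y`, `d_y`, `separation` (`NA` when the loci
#'   are on different chromosomes).
#' @export
find_coordinated_pairs <- function(x, max_intra = 2000, min_inter = 1e5) {
  x <- as_tibble(x)
  n <- nrow(x)
  if (n < 2) {
    return(tibble(id1 = character(), id2 = character(),
                  chrom_x = character(), d_x = numeric(),
                  chrom_y = character(), d_y = numeric(),
                  separation = numeric()))
  }
  arm <- function(row, which) {
    if (which == 1) list(chrom = x$chrom1[row], pos = x$pos1[row])
    else list(chrom = x$chrom2[row], pos = x$pos2[row])
  }
  close_arms <- function(u, v) {
    u$chrom == v$chrom && abs(u$pos - v$pos) <= max_intra
  }
  remote <- function(u, v) {
    u$chrom != v$chrom || abs(u$pos - v$pos) >= min_inter
  }
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      for (pairing in list(c(1, 2), c(2, 1))) {
        a1 <- arm(i, 1); b1 <- arm(i, 2)
        a2 <- arm(j, pairing[1]); b2 <- arm(j, pairing[2])
        if (close_arms(a1, a2) && close_arms(b1, b2) &&
            remote(a1, b1)) {
          out[[length(out) + 1]] <- tibble(
            id1 = x$id[i], id2 = x$id[j],
            chrom_x = a1$chrom, d_x = abs(a1$pos - a2$pos),
            chrom_y = b1$chrom, d_y = abs(b1$pos - b2$pos),
            separation = if (a1$chrom == b1$chrom) abs(a1$pos - b1$pos)
                         else NA_real_)
          break
        }
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(id1 = character(), id2 = character(),
                  chrom_x = character(), d_x = numeric(),
                  chrom_y = character(), d_y = numeric(),
                  separation = numeric()))
  }
  bind_rows(out)
}
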