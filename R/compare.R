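# Cross-passage junction-set algebra.

jx_key <- function(x) {
  a <- paste0(x$chrom1, ":", format_pos(x$pos1), ":", x$orient1)
  b <- paste0(x$chrom2, ":", format_pos(x$pos2), ":", x$orient2)
  ifelse(a <= b, paste(a, b, sep = "|"), paste(b, a, sep = "|"))
}

#' Match junctions between two samples
#'
#' Pairs junctions of set `a` (e.g. the dmin passage) with junctions of set
#' `b` (e.g. the hsr passage) whose arms agree in chromosome and
#' orientation and differ by at most `tol` bp per arm (arm order ignored).
#' With `tol = 0` matching is exact; with `tol > 0` candidate pairs are
#' accepted greedily by increasing summed arm distance, each junction
#' matching at most once.
#'
#' @param a,b `jx_tbl` junction tibbles on the same reference.
#' @param tol per-arm position tolerance, bp (default 0: breakends mapped
#'   to the base).
#' @return object of class `junction_comparison`: list with `$shared`
#'   (`id_a`, `id_b`, `dist`), `$lost` (rows of `a` without a match),
#'   `$gained` (rows of `b` without a match), `$tol` and `$counts`.
#' @export
match_junctions <- function(a, b, tol = 0) {
  if (tol < 0) abort("tol must be >= 0")
  a <- as_tibble(a)
  b <- as_tibble(b)
  if (tol == 0) {
    ka <- jx_key(a)
    kb <- jx_key(b)
    ia <- seq_len(nrow(a))
    shared <- list()
    used_b <- rep(FALSE, nrow(b))
    matched_a <- rep(FALSE, nrow(a))
    for (i in ia) {
      j <- which(!used_b & kb == ka[i])
      if (length(j) > 0) {
        used_b[j[1]] <- TRUE
        matched_a[i] <- TRUE
        shared[[length(shared) + 1]] <- tibble(id_a = a$id[i],
                                               id_b = b$id[j[1]], dist = 0)
      }
    }
  } else {
    # candidate pairs under either arm correspondence
    cand <- list()
    for (i in seq_len(nrow(a))) {
      for (j in seq_len(nrow(b))) {
        d <- arm_pair_dist(a[i, ], b[j, ], tol)
        if (!is.na(d)) cand[[length(cand) + 1]] <- tibble(i = i, j = j,
                                                          dist = d)
      }
    }
    cand <- if (length(cand)) bind_rows(cand) %>% arrange(.data$dist) else
      tibble(i = integer(), j = integer(), dist = numeric())
    matched_a <- rep(FALSE, nrow(a))
    used_b <- rep(FALSE, nrow(b))
    shared <- list()
    for (r in seq_len(nrow(cand))) {
      i <- cand$i[r]; j <- cand$j[r]
      if (matched_a[i] || used_b[j]) next
      matched_a[i] <- TRUE
      used_b[j] <- TRUE
      shared[[length(shared) + 1]] <- tibble(id_a = a$id[i], id_b = b$id[j],
                                             dist = cand$dist[r])
    }
  }
  shared <- if (length(shared)) bind_rows(shared) else
    tibble(id_a = character(), id_b = character(), dist = numeric())
  lost <- a[!matched_a, , drop = FALSE]
  gained <- b[!used_b, , drop = FALSE]
  n_sh <- nrow(shared)
  counts <- tibble(n_a = nrow(a), n_b = nrow(b), shared = n_sh,
                   lost = nrow(lost), gained = nrow(gained),
                   union = nrow(a) + nrow(b) - n_sh)
  structure(list(shared = shared, lost = lost, gained = gained, tol = tol,
                 counts = counts),
            class = "junction_comparison")
}

arm_pair_dist <- function(ja, jb, tol) {
  d12 <- function(c1, p1, o1, c2, p2, o2) {
    if (c1 == c2 && o1 == o2 && abs(p1 - p2) <= tol) abs(p1 - p2) else NA_real_
  }
  # correspondence 1: a1-b1, a2-b2
  d1 <- d12(ja$chrom1, ja$pos1, ja$orient1, jb$chrom1, jb$pos1, jb$orient1)
  d2 <- d12(ja$chrom2, ja$pos2, ja$orient2, jb$chrom2, jb$pos2, jb$orient2)
  s1 <- if (!is.na(d1) && !is.na(d2)) d1 + d2 else NA_real_
  # correspondence 2: a1-b2, a2-b1
  d3 <- d12(ja$chrom1, ja$pos1, ja$orient1, jb$chrom2, jb$pos2, jb$orient2)
  d4 <- d12(ja$chrom2, ja$pos2, ja$orient2, jb$chrom1, jb$pos1, jb$orient1)
  s2 <- if (!is.na(d3) && !is.na(d4)) d3 + d4 else NA_real_
  if (is.na(s1) && is.na(s2)) NA_real_ else min(s1, s2, na.rm = TRUE)
}

#' @export
print.junction_comparison <- function(x, ...) {
  cat("Junction set comparison (tol =", x$tol, "bp)\n")
  print(x$counts)
  invisible(x)
}

#' @rdname match_junctions
#' @param x a `junction_comparison` object.
#' @param ... unused.
#' @return `tidy()`: the per-junction fate table (`id`, `set`, `fate`);
#'   `glance()`: the one-row count summary.
#' @export
tidy.junction_comparison <- function(x, ...) {
  bind_rows(
    tibble(id = x$shared$id_a, set = "a", fate = "shared"),
    tibble(id = x$shared$id_b, set = "b", fate = "shared"),
    tibble(id = x$lost$id, set = "a", fate = "lost"),
    tibble(id = x$gained$id, set = "b", fate = "gained"))
}

#' @rdname match_junctions
#' @export
glance.junction_comparison <- function(x, ...) x$counts

#' Joint cross-passage report
#'
#' Combines the junction-set comparison with per-chromosome and inter- vs
#' intra-chromosomal tallies, and (optionally) the amplified-interval
#' comparison.
#'
#' @param cmp a `junction_comparison` from [match_junctions()].
#' @param a,b the junction tibbles that were compared.
#' @param amplified_cmp optional result of
#'   [compare_amplified_segments()].
#' @return list of class `comparison_report`: `$counts`, `$by_chrom`
#'   (junction fate counts by chromosome pair), `$chrom_type` (inter- vs
#'   intra-chromosomal tallies per set), `$amplified` (per-chrom lost
#'   fractions or `NULL`).
#' @export
comparison_summary <- function(cmp, a, b, amplified_cmp = NULL) {
  a <- as_tibble(a); b <- as_tibble(b)
  fate_a <- ifelse(a$id %in% cmp$shared$id_a, "shared", "lost")
  fate_b <- ifelse(b$id %in% cmp$shared$id_b, "shared", "gained")
  tag <- function(x, fate, set) {
    tibble(set = set, id = x$id, fate = fate,
           chrom_pair = ifelse(x$chrom1 <= x$chrom2,
                               paste(x$chrom1, x$chrom2, sep = "-"),
                               paste(x$chrom2, x$chrom1, sep = "-")),
           type = ifelse(x$chrom1 == x$chrom2, "intra", "inter"))
  }
  long <- bind_rows(tag(a, fate_a, "a"), tag(b, fate_b, "b"))
  by_chrom <- long %>% dplyr::count(.data$set, .data$chrom_pair, .data$fate)
  chrom_type <- long %>% dplyr::count(.data$set, .data$type)
  structure(list(counts = cmp$counts, by_chrom = by_chrom,
                 chrom_type = chrom_type,
                 amplified = if (!is.null(amplified_cmp))
                   amplified_cmp$summary else NULL),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Cross-passage comparison\n")
  print(x$counts)
  cat("\nInter- vs intra-chromosomal junctions:\n")
  print(x$chrom_type)
  if (!is.null(x$amplified)) {
    cat("\nAmplified sequence lost:\n")
    print(x$amplified)
  }
  invisible(x)
}
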