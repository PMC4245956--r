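# Independent oracles and shared fixtures for the test suite.

# --- breakpoint-shift microhomology oracle ---------------------------------
# Counts, by direct substring equality at every shift, the number of
# alternative breakpoint placements of a junction. Flank extraction is done
# here with Biostrings subseq/reverseComplement, independently of the
# package's flank code.
oracle_flanks <- function(genome, chrom, pos, orient, side, window) {
  seq <- Biostrings::DNAString(genome[[chrom]])
  n <- length(seq)
  sub <- function(from, to) {
    from <- max(1, from); to <- min(n, to)
    if (from > to) return("")
    as.character(Biostrings::subseq(seq, from, to))
  }
  rc <- function(s) {
    if (!nzchar(s)) return(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  if (side == "first") {
    if (orient == "+") {
      list(ret = sub(pos - window + 1, pos), bey = sub(pos + 1, pos + window))
    } else {
      list(ret = rc(sub(pos, pos + window - 1)),
           bey = rc(sub(pos - window, pos - 1)))
    }
  } else {
    if (orient == "-") {
      list(ret = sub(pos, pos + window - 1), bey = sub(pos - window, pos - 1))
    } else {
      list(ret = rc(sub(pos - window + 1, pos)),
           bey = rc(sub(pos + 1, pos + window)))
    }
  }
}

oracle_mh_shift <- function(genome, chrom1, pos1, orient1,
                            chrom2, pos2, orient2, window = 50) {
  fa <- oracle_flanks(genome, chrom1, pos1, orient1, "first", window)
  fb <- oracle_flanks(genome, chrom2, pos2, orient2, "second", window)
  # right shifts: first s bases of B also readable as A's continuation
  right <- 0
  for (s in seq_len(min(nchar(fb$ret), nchar(fa$bey)))) {
    if (substr(fb$ret, 1, s) == substr(fa$bey, 1, s)) right <- s else break
  }
  # left shifts: last s bases of A also readable as the bases preceding B
  left <- 0
  la <- nchar(fa$ret); lb <- nchar(fb$bey)
  for (s in seq_len(min(la, lb))) {
    if (substr(fa$ret, la - s + 1, la) == substr(fb$bey, lb - s + 1, lb)) {
      left <- s
    } else break
  }
  left + right
}

# --- transitive-closure clustering oracle ----------------------------------
# O(n^2) union-find over the relation |pos_i - pos_j| <= max_gap on one
# chromosome; returns a canonical partition (sorted positions per group).
oracle_cluster_partition <- function(breakends, max_gap) {
  canon <- list()
  for (ch in unique(breakends$chrom)) {
    pos <- sort(breakends$pos[breakends$chrom == ch])
    n <- length(pos)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i < j && abs(pos[i] - pos[j]) <= max_gap) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    for (r in unique(roots)) {
      canon[[length(canon) + 1]] <- paste0(ch, ":",
                                           paste(pos[roots == r],
                                                 collapse = ","))
    }
  }
  sort(unlist(canon))
}

package_cluster_partition <- function(clustered) {
  b <- clustered
  key <- ifelse(is.na(b$cluster),
                paste0("s", seq_len(nrow(b))), b$cluster)
  out <- vapply(split(b, paste0(b$chrom, "|", key)), function(g) {
    paste0(g$chrom[1], ":", paste(sort(g$pos), collapse = ","))
  }, character(1))
  sort(unname(out))
}

# --- truncated-geometric convolution (analytic, per-side cap L) ------------
analytic_pmf_capped <- function(L, p = 0.25) {
  side <- c((1 - p) * p^(0:(L - 1)), p^L)  # k = 0..L, cap at L
  conv <- rep(0, 2 * L + 1)
  for (i in 0:L) for (j in 0:L) {
    conv[i + j + 1] <- conv[i + j + 1] + side[i + 1] * side[j + 1]
  }
  conv
}

# --- canonical chain comparison for contigs --------------------------------
canon_chain <- function(ids, circular) {
  if (!circular) {
    rev_ids <- rev(ids)
    if (paste(ids, collapse = ",") <= paste(rev_ids, collapse = ","))
      paste(ids, collapse = ",") else paste(rev_ids, collapse = ",")
  } else {
    best <- NULL
    n <- length(ids)
    for (dir in list(ids, rev(ids))) {
      for (r in seq_len(n)) {
        rot <- c(dir[r:n], dir[seq_len(r - 1)])
        key <- paste(rot, collapse = ",")
        if (is.null(best) || key < best) best <- key
      }
    }
    best
  }
}

# --- shared fixtures (built once per run) ----------------------------------
.fixture_cache <- new.env(parent = emptyenv())

get_fixture <- function() {
  if (is.null(.fixture_cache$fx)) {
    dir <- file.path(tempdir(), "amprearr_test_fixture")
    .fixture_cache$fx <- make_fixtures(dir, seed = 1)
  }
  .fixture_cache$fx
}

small_sim_config <- function(seed, ...) {
  defaults <- list(
    chrom_lengths = c(cA = 2e5),
    source_regions = tibble::tibble(chrom = "cA", start = 10001,
                                    end = 190000),
    n_clusters = 5, singletons_per_region = 2,
    inter_cluster_min_gap = 8000, p_fragment_drop = 0, seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
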