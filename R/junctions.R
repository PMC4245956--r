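# Junction sequence characterization: two-sided microhomology, untemplated
# insertions, insert template search, flank variant scan.

revcomp <- function(x) {
  out <- character(length(x))
  nz <- !is.na(x) & nzchar(x)
  if (any(nz)) {
    out[nz] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(x[nz])))
  }
  out[!nz] <- x[!nz]
  out
}

subseq_str <- function(genome, chrom, from, to) {
  seq <- genome[[chrom]]
  if (is.null(seq)) abort(paste0("chromosome not in reference: ", chrom))
  n <- nchar(seq)
  from <- max(1, from)
  to <- min(n, to)
  if (from > to) return("")
  substr(seq, from, to)
}

# Longest common prefix length of two strings.
common_prefix_len <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) return(0L)
  av <- utf8ToInt(a)
  bv <- utf8ToInt(b)
  m <- min(length(av), length(bv))
  neq <- which(av[seq_len(m)] != bv[seq_len(m)])
  if (length(neq) > 0) neq[1] - 1L else m
}

strrev <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

common_suffix_len <- function(a, b) common_prefix_len(strrev(a), strrev(b))

# Flank sequences of one breakend, oriented along the fused molecule.
#
# side = "first": the arm contributes the sequence *ending* at the seam;
#   `retained` ends at the breakend, `beyond` is the reference continuation
#   past it (what joining deleted), both read in junction orientation.
# side = "second": the arm contributes the sequence *starting* at the seam;
#   `retained` starts at the breakend, `beyond` is the reference immediately
#   preceding it (ending just before the seam) in junction orientation.
# orient "+": reference upstream of pos retained; "-": downstream retained.
junction_flanks <- function(genome, chrom, pos, orient, side, window) {
  if (side == "first") {
    if (orient == "+") {
      retained <- subseq_str(genome, chrom, pos - window + 1, pos)
      beyond <- subseq_str(genome, chrom, pos + 1, pos + window)
    } else {
      retained <- revcomp(subseq_str(genome, chrom, pos, pos + window - 1))
      beyond <- revcomp(subseq_str(genome, chrom, pos - window, pos - 1))
    }
  } else {
    if (orient == "-") {
      retained <- subseq_str(genome, chrom, pos, pos + window - 1)
      beyond <- subseq_str(genome, chrom, pos - window, pos - 1)
    } else {
      retained <- revcomp(subseq_str(genome, chrom, pos - window + 1, pos))
      beyond <- revcomp(subseq_str(genome, chrom, pos + 1, pos + window))
    }
  }
  truncated <- nchar(retained) < window || nchar(beyond) < window
  list(retained = retained, beyond = beyond, truncated = truncated)
}

# Two-sided microhomology between two oriented breakends.
mh_between <- function(genome, chrom1, pos1, orient1, chrom2, pos2, orient2,
                       max_window = 50) {
  fa <- junction_flanks(genome, chrom1, pos1, orient1, "first", max_window)
  fb <- junction_flanks(genome, chrom2, pos2, orient2, "second", max_window)
  mh_flank_pair(fa, fb, max_window)
}

mh_flank_pair <- function(fa, fb, max_window) {
  mh_right <- min(common_prefix_len(fb$retained, fa$beyond), max_window)
  mh_left <- min(common_suffix_len(fa$retained, fb$beyond), max_window)
  list(mh_left = mh_left, mh_right = mh_right,
       truncated = fa$truncated || fb$truncated)
}

#' Two-sided microhomology at each junction
#'
#' For every junction, computes the microhomology between the two reference
#' flanks at the fusion seam. With `A` the retained sequence ending at the
#' first arm's breakend (in junction orientation) and `B` the retained
#' sequence starting at the second arm's breakend, `mh_right` is the longest
#' `k` such that the first `k` bases of `B` equal the reference continuation
#' past `A`'s breakend, and `mh_left` the longest `k` such that the last `k`
#' bases of `A` equal the reference immediately preceding `B`'s breakend.
#' Inverted fusions are handled by reverse complementation. Breakends within
#' `max_window` of a contig edge are computed with a truncated window and
#' flagged.
#'
#' @param x a `jx_tbl` junction tibble.
#' @param genome named character vector of reference sequences.
#' @param max_window cap on each side's microhomology, bp.
#' @return `x` with columns `mh_left`, `mh_right`, `mh_len`
#'   (`= mh_left + mh_right`) and `mh_truncated` added.
#' @export
junction_microhomology <- function(x, genome, max_window = 50) {
  x <- as_tibble(x)
  res <- purrr::pmap(
    list(x$chrom1, x$pos1, x$orient1, x$chrom2, x$pos2, x$orient2),
    function(c1, p1, o1, c2, p2, o2) {
      mh_between(genome, c1, p1, o1, c2, p2, o2, max_window)
    }
  )
  x$mh_left <- purrr::map_int(res, ~ as.integer(.x$mh_left))
  x$mh_right <- purrr::map_int(res, ~ as.integer(.x$mh_right))
  x$mh_len <- x$mh_left + x$mh_right
  x$mh_truncated <- purrr::map_lgl(res, "truncated")
  x
}

#' Filter junction calls by support and amplified regions
#'
#' Keeps junctions with read support at least `min_support` and with at least
#' one arm falling inside an amplified interval. The default
#' `min_support = 3` implements a "more than two sequencing reads" rule.
#'
#' @param x a `jx_tbl` junction tibble.
#' @param amplified tibble of amplified intervals (`chrom`, `start`, `end`,
#'   1-based inclusive).
#' @param min_support minimum read support.
#' @return the filtered junction tibble.
#' @export
filter_junctions <- function(x, amplified, min_support = 3) {
  x <- as_tibble(x)
  if (nrow(x) == 0) return(x)
  in_amp <- function(chrom, pos) {
    purrr::map2_lgl(chrom, pos, function(ch, p) {
      any(amplified$chrom == ch & amplified$start <= p & amplified$end >= p)
    })
  }
  keep <- x$support >= min_support &
    (in_amp(x$chrom1, x$pos1) | in_amp(x$chrom2, x$pos2))
  x[keep, , drop = FALSE]
}

# Anchor a spanning sequence onto both reference flanks. Returns the span
# index of the last base attributable to the first arm (a_end) and the first
# base attributable to the second arm (b_start), using exact seeds of
# `seed_len` bp extended base by base across the seam.
anchor_span <- function(span, genome, chrom1, pos1, orient1,
                        chrom2, pos2, orient2, seed_len = 15, window = 100) {
  fa <- junction_flanks(genome, chrom1, pos1, orient1, "first", window)
  fb <- junction_flanks(genome, chrom2, pos2, orient2, "second", window)
  if (nchar(fa$retained) < seed_len || nchar(fb$retained) < seed_len) {
    abort("unanchored junction: flank shorter than anchor seed")
  }
  seed_a <- substr(fa$retained, nchar(fa$retained) - seed_len + 1,
                   nchar(fa$retained))
  seed_b <- substr(fb$retained, 1, seed_len)
  hit_a <- regexpr(seed_a, span, fixed = TRUE)[1]
  if (hit_a < 0) abort("unanchored junction: first flank seed not in span")
  a_end <- hit_a + seed_len - 1
  # last occurrence of the b seed
  hits_b <- gregexpr(seed_b, span, fixed = TRUE)[[1]]
  if (hits_b[1] < 0) abort("unanchored junction: second flank seed not in span")
  b_start <- hits_b[length(hits_b)]
  # extend the a anchor rightwards along the reference continuation
  ext_a <- common_prefix_len(substr(span, a_end + 1, nchar(span)), fa$beyond)
  a_end <- a_end + ext_a
  # extend the b anchor leftwards along the reference preceding b
  ext_b <- common_suffix_len(substr(span, 1, b_start - 1), fb$beyond)
  b_start <- b_start - ext_b
  list(a_end = a_end, b_start = b_start, ext_a = ext_a, ext_b = ext_b,
       fa = fa, fb = fb)
}

#' Call untemplated insertions from spanning sequences
#'
#' Anchors each junction's spanning sequence (`span_seq`) to the two
#' reference flanks with exact seeds and reports the seam bases attributable
#' to neither side as an untemplated insertion. A flush (or
#' microhomology-ambiguous) seam yields an insertion of length 0. Junctions
#' without a `span_seq` keep their declared `inserted_seq`.
#'
#' @param x a `jx_tbl` junction tibble.
#' @param genome named character vector of reference sequences.
#' @param seed_len exact anchor seed length, bp.
#' @return `x` with `inserted_seq` filled in from the span where available
#'   and an `insertion_len` column added.
#' @export
call_insertions <- function(x, genome, seed_len = 15) {
  x <- as_tibble(x)
  ins <- x[["inserted_seq"]] %||% rep("", nrow(x))
  ins[is.na(ins)] <- ""
  span <- x[["span_seq"]] %||% rep(NA_character_, nrow(x))
  for (i in seq_len(nrow(x))) {
    if (is.na(span[i]) || !nzchar(span[i])) next
    anc <- anchor_span(span[i], genome, x$chrom1[i], x$pos1[i], x$orient1[i],
                       x$chrom2[i], x$pos2[i], x$orient2[i], seed_len)
    if (anc$b_start > anc$a_end + 1) {
      ins[i] <- substr(span[i], anc$a_end + 1, anc$b_start - 1)
    } else {
      ins[i] <- ""
    }
  }
  x$inserted_seq <- toupper(ins)
  x$insertion_len <- nchar(x$inserted_seq)
  x
}

#' Characterize junctions: microhomology and insertions
#'
#' Runs the microhomology caller and the insertion caller and applies the
#' mutual-exclusion rule: a junction carrying an untemplated insertion has
#' its microhomology reported as 0 (the seam bases are attributed to the
#' insertion, not to flank homology).
#'
#' @inheritParams junction_microhomology
#' @param seed_len anchor seed length for spanning-sequence alignment.
#' @return the characterized junction tibble with `mh_left`, `mh_right`,
#'   `mh_len`, `mh_truncated`, `insertion_len` columns.
#' @export
characterize_junctions <- function(x, genome, max_window = 50, seed_len = 15) {
  x <- call_insertions(x, genome, seed_len)
  x <- junction_microhomology(x, genome, max_window)
  has_ins <- x$insertion_len > 0
  x$mh_left[has_ins] <- 0L
  x$mh_right[has_ins] <- 0L
  x$mh_len[has_ins] <- 0L
  validate_junctions(x)
}

#' Search for templates of inserted sequences in breakend flanks
#'
#' Aligns each sufficiently long insertion (both strands) locally against
#' windows around both breakends and reports matches above an identity
#' threshold. A templated insert copied from a nearby flank indicates a
#' replicative (template-switching) origin rather than untemplated synthesis.
#'
#' @param x a characterized junction tibble (with `inserted_seq`).
#' @param genome named character vector of reference sequences.
#' @param flank_window half-width of the searched window around each
#'   breakend, bp.
#' @param min_identity minimum fraction of insert bases matched.
#' @param min_len inserts shorter than this are not searched (flagged
#'   `searched = FALSE`).
#' @return tibble with one row per hit: `id`, `arm`, `strand`, `chrom`,
#'   `start`, `end`, `identity`, plus a `searched` attribute-style column on
#'   the per-junction summary. Junctions without hits contribute no rows.
#' @export
find_insert_templates <- function(x, genome, flank_window = 2000,
                                  min_identity = 0.9, min_len = 20) {
  x <- as_tibble(x)
  ins <- x[["inserted_seq"]] %||% rep("", nrow(x))
  ins[is.na(ins)] <- ""
  hits <- list()
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  for (i in seq_len(nrow(x))) {
    if (nchar(ins[i]) < min_len) next
    arms <- list(
      list(arm = "a", chrom = x$chrom1[i], pos = x$pos1[i]),
      list(arm = "b", chrom = x$chrom2[i], pos = x$pos2[i])
    )
    for (a in arms) {
      w_from <- max(1, a$pos - flank_window)
      w_to <- a$pos + flank_window
      window_seq <- subseq_str(genome, a$chrom, w_from, w_to)
      if (!nzchar(window_seq)) next
      for (strand in c("+", "-")) {
        query <- if (strand == "+") ins[i] else revcomp(ins[i])
        aln <- Biostrings::pairwiseAlignment(
          query, window_seq, type = "local", substitutionMatrix = mat,
          gapOpening = 5, gapExtension = 2)
        nm <- Biostrings::nmatch(aln)
        identity <- nm / nchar(ins[i])
        if (identity >= min_identity) {
          rng <- Biostrings::subject(aln)
          hits[[length(hits) + 1]] <- tibble(
            id = x$id[i], arm = a$arm, strand = strand, chrom = a$chrom,
            start = w_from + Biostrings::start(rng) - 1,
            end = w_from + Biostrings::end(rng) - 1,
            identity = identity)
        }
      }
    }
  }
  out <- if (length(hits) > 0) bind_rows(hits) else
    tibble(id = character(), arm = character(), strand = character(),
           chrom = character(), start = numeric(), end = numeric(),
           identity = numeric())
  searched <- tibble(id = x$id, insertion_len = nchar(ins),
                     searched = nchar(ins) >= min_len)
  attr(out, "searched") <- searched
  out
}

is_transition <- function(ref, alt) {
  (ref %in% c("A", "G") & alt %in% c("A", "G")) |
    (ref %in% c("C", "T") & alt %in% c("C", "T"))
}

#' Scan junction flanks for sequence variants
#'
#' Aligns the `window` bases of the spanning sequence on each side of the
#' seam to the corresponding reference flank and reports substitutions
#' (classed transition/transversion) and indels. Offsets are relative to the
#' seam: negative on the first-arm side, positive on the second-arm side.
#' A high local variant rate is the signature expected from low-fidelity
#' repair synthesis (break-induced replication-like mechanisms).
#'
#' @param x a `jx_tbl` junction tibble with `span_seq`.
#' @param genome named character vector of reference sequences.
#' @param window flank width scanned on each side, bp.
#' @param seed_len anchor seed length.
#' @return tibble with `id`, `side` (`"a"`/`"b"`), `offset`, `type`
#'   (`"transition"`, `"transversion"`, `"insertion"`, `"deletion"`),
#'   `ref`, `alt`, `length`.
#' @export
scan_flank_variants <- function(x, genome, window = 50, seed_len = 15) {
  x <- as_tibble(x)
  span <- x[["span_seq"]] %||% rep(NA_character_, nrow(x))
  out <- list()
  for (i in seq_len(nrow(x))) {
    if (is.na(span[i]) || !nzchar(span[i])) next
    if (grepl("[^ACGT]", span[i])) {
      abort(paste0("ambiguity codes in span of junction ", x$id[i]))
    }
    anc <- anchor_span(span[i], genome, x$chrom1[i], x$pos1[i], x$orient1[i],
                       x$chrom2[i], x$pos2[i], x$orient2[i], seed_len,
                       window = max(100, window))
    # observed flanks around the called seam; the seam may have shifted into
    # flank microhomology, so the reference follows the anchor extension
    obs_a <- substr(span[i], max(1, anc$a_end - window + 1), anc$a_end)
    obs_b <- substr(span[i], anc$b_start,
                    min(nchar(span[i]), anc$b_start + window - 1))
    ref_a_full <- paste0(anc$fa$retained,
                         substr(anc$fa$beyond, 1, anc$ext_a))
    ref_a <- substr(ref_a_full, max(1, nchar(ref_a_full) - window + 1),
                    nchar(ref_a_full))
    nb <- nchar(anc$fb$beyond)
    ref_b_full <- paste0(substr(anc$fb$beyond, nb - anc$ext_b + 1, nb),
                         anc$fb$retained)
    ref_b <- substr(ref_b_full, 1, window)
    va <- align_flank_variants(obs_a, ref_a, anchored = "right")
    if (nrow(va) > 0) {
      va$id <- x$id[i]; va$side <- "a"
      va$offset <- va$ref_pos - nchar(ref_a) - 1  # -1 .. -window
      out[[length(out) + 1]] <- va
    }
    vb <- align_flank_variants(obs_b, ref_b, anchored = "left")
    if (nrow(vb) > 0) {
      vb$id <- x$id[i]; vb$side <- "b"
      vb$offset <- vb$ref_pos  # +1 .. +window
      out[[length(out) + 1]] <- vb
    }
  }
  empty <- tibble(id = character(), side = character(), offset = numeric(),
                  type = character(), ref = character(), alt = character(),
                  length = integer())
  if (length(out) == 0) return(empty)
  bind_rows(out)[names(empty)]
}

# Global pairwise alignment of an observed flank to its reference flank;
# returns substitutions and indels with 1-based reference positions.
align_flank_variants <- function(obs, ref, anchored = c("left", "right")) {
  anchored <- match.arg(anchored)
  empty <- tibble(ref_pos = numeric(), type = character(), ref = character(),
                  alt = character(), length = integer())
  if (!nzchar(obs) || !nzchar(ref)) return(empty)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  aln <- Biostrings::pairwiseAlignment(obs, ref, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 4, gapExtension = 1)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ref_pos <- cumsum(sub != "-")
  rows <- list()
  n <- length(pat)
  idx <- 1
  while (idx <= n) {
    if (pat[idx] != "-" && sub[idx] != "-" && pat[idx] != sub[idx]) {
      type <- if (is_transition(sub[idx], pat[idx])) "transition" else "transversion"
      rows[[length(rows) + 1]] <- tibble(ref_pos = ref_pos[idx], type = type,
                                         ref = sub[idx], alt = pat[idx],
                                         length = 1L)
      idx <- idx + 1
    } else if (pat[idx] == "-") {  # deletion in observed
      j <- idx
      while (j < n && pat[j + 1] == "-") j <- j + 1
      rows[[length(rows) + 1]] <- tibble(
        ref_pos = ref_pos[idx], type = "deletion",
        ref = paste(sub[idx:j], collapse = ""), alt = "",
        length = j - idx + 1L)
      idx <- j + 1
    } else if (sub[idx] == "-") {  # insertion in observed
      j <- idx
      while (j < n && sub[j + 1] == "-") j <- j + 1
      rows[[length(rows) + 1]] <- tibble(
        ref_pos = max(ref_pos[idx], 1), type = "insertion", ref = "",
        alt = paste(pat[idx:j], collapse = ""), length = j - idx + 1L)
      idx <- j + 1
    } else {
      idx <- idx + 1
    }
  }
  if (length(rows) == 0) return(empty)
  bind_rows(rows)
}

#' Summarize characterized junctions
#'
#' Tabulates microhomology lengths and the headline fractions: blunt
#' junctions (no microhomology, no insertion), junctions with microhomology
#' among insertion-free junctions, and junctions carrying insertions. Both
#' the all-junction and the insertion-free denominators are reported because
#' published per-junction statistics use either.
#'
#' @param x a characterized junction tibble (needs `mh_len`; `insertion_len`
#'   and `samples` are used when present).
#' @return object of class `jx_summary`: list with `$by_mh` (counts per
#'   microhomology length), `$stats` (one-row tibble of fractions) and
#'   `$by_sample` (per-sample stats, `NULL` if samples are untracked).
#' @export
summarize_junctions <- function(x) {
  x <- as_tibble(x)
  if (!"mh_len" %in% names(x)) abort("junctions are not characterized (no mh_len)")
  ins_len <- x[["insertion_len"]] %||%
    nchar(ifelse(is.na(x[["inserted_seq"]] %||% ""), "", x[["inserted_seq"]] %||% ""))
  stats_of <- function(mh, ins) {
    n <- length(mh)
    insfree <- ins == 0
    tibble(
      n = n,
      n_insertion = sum(!insfree),
      frac_insertion = if (n > 0) sum(!insfree) / n else NA_real_,
      frac_blunt = if (n > 0) sum(mh == 0 & insfree) / n else NA_real_,
      frac_mh_all = if (n > 0) sum(mh >= 1) / n else NA_real_,
      frac_mh_insfree = if (any(insfree)) sum(mh[insfree] >= 1) / sum(insfree)
                        else NA_real_
    )
  }
  by_mh <- x %>%
    mutate(insertion = ins_len > 0) %>%
    dplyr::count(.data$mh_len, .data$insertion, name = "n") %>%
    arrange(.data$mh_len)
  by_sample <- NULL
  if ("samples" %in% names(x) && any(!is.na(x$samples))) {
    long <- x %>%
      mutate(.ins = ins_len) %>%
      mutate(sample = strsplit(ifelse(is.na(.data$samples), "unassigned",
                                      .data$samples), ",")) %>%
      tidyr::unnest("sample")
    by_sample <- long %>%
      group_by(.data$sample) %>%
      summarise(stats_of(.data$mh_len, .data$.ins), .groups = "drop")
  }
  structure(list(by_mh = by_mh, stats = stats_of(x$mh_len, ins_len),
                 by_sample = by_sample),
            class = "jx_summary")
}

#' @export
print.jx_summary <- function(x, ...) {
  cat("Junction characterization summary\n")
  s <- x$stats
  cat(sprintf("  junctions: %d (%.0f%% with insertions)\n",
              s$n, 100 * s$frac_insertion))
  cat(sprintf("  blunt: %.1f%%  mh>=1 (all): %.1f%%  mh>=1 (insertion-free): %.1f%%\n",
              100 * s$frac_blunt, 100 * s$frac_mh_all, 100 * s$frac_mh_insfree))
  invisible(x)
}

#' Annotate junction arms with interval classes from a BED file
#'
#' Joins a user-supplied annotation (e.g. repeat classes) onto both arms.
#'
#' @param x a `jx_tbl` junction tibble.
#' @param annotation tibble from [read_bed()] with a `name` column.
#' @return `x` with `class1` and `class2` columns (NA where unannotated).
#' @export
annotate_junction_arms <- function(x, annotation) {
  x <- as_tibble(x)
  lookup <- function(chrom, pos) {
    purrr::map2_chr(chrom, pos, function(ch, p) {
      hit <- annotation$chrom == ch & annotation$start <= p & annotation$end >= p
      if (any(hit)) annotation$name[which(hit)[1]] else NA_character_
    })
  }
  x$class1 <- lookup(x$chrom1, x$pos1)
  x$class2 <- lookup(x$chrom2, x$pos2)
  x
}
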