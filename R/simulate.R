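# Seeded amplicon rearrangement simulator.
#
# The generator emulates the architecture observed in sequenced dmin/hsr
# amplicons: amplified source regions with segment-level copy-number steps,
# breakpoints concentrated in clusters of a few hundred to a few thousand bp
# separated by tens of kb, fragments fused with a tunable microhomology bias
# or untemplated insertions, and a passage transition that loses fragments
# and junctions and creates new ones.

#' Simulator configuration
#'
#' Assembles and validates the configuration for [simulate_amplicon()].
#' Defaults describe a scaled-down two-chromosome amplicon: two source
#' regions per chromosome, 12 breakpoint clusters of 2-7 breaks spanning
#' 100-2500 bp at least 10 kb apart, joining biased toward microhomology
#' with weight `(1 + mh_bias)^mh`, 30% of joins carrying an untemplated
#' insertion (geometric length, mean 8, capped at 42), and per-molecule copy
#' numbers centred on 15-fold.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param gc_fraction GC content of the simulated reference, in (0, 1).
#' @param source_regions tibble (`chrom`, `start`, `end`) of amplified
#'   source regions; `NULL` uses two regions per chromosome.
#' @param n_clusters total number of breakpoint clusters.
#' @param breaks_per_cluster integer range (min, max) of breaks per cluster.
#' @param cluster_span_range range (bp) of cluster spans, sampled uniformly.
#' @param inter_cluster_min_gap minimum distance between cluster anchors, bp.
#' @param singletons_per_region expected unclustered breaks per region
#'   (Poisson).
#' @param mh_bias microhomology join bias `beta >= 0`; candidate partner
#'   ends are sampled with weight `(1 + beta)^mh`.
#' @param p_insertion probability that a join carries an untemplated insert
#'   (which forces called microhomology to 0).
#' @param insertion_len_mean,insertion_len_cap geometric mean and hard cap
#'   of insertion lengths, bp.
#' @param copy_number_mean mean per-molecule copy number (Poisson, floored
#'   at 1).
#' @param p_fragment_drop probability a cut fragment is left out of the
#'   amplicon (creating internal unamplified holes).
#' @param mode `"dmin"` (closed circles) or `"hsr"` (one linear chain).
#' @param min_circle_fragments smallest allowed circle, in fragments.
#' @param passage_loss_prob per-fragment loss probability at a passage
#'   transition.
#' @param passage_new_break_rate expected new breaks per surviving fragment
#'   at a passage transition.
#' @param passage_mode topology after the transition (`"hsr"` or `"dmin"`).
#' @param seed integer RNG seed; all outputs are reproducible bit-for-bit
#'   under a fixed seed.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(chrom_lengths = c(chr7 = 1e6, chr8 = 1e6),
                       gc_fraction = 0.5,
                       source_regions = NULL,
                       n_clusters = 12,
                       breaks_per_cluster = c(2, 7),
                       cluster_span_range = c(100, 2500),
                       inter_cluster_min_gap = 1e4,
                       singletons_per_region = 2,
                       mh_bias = 2,
                       p_insertion = 0.3,
                       insertion_len_mean = 8,
                       insertion_len_cap = 42,
                       copy_number_mean = 15,
                       p_fragment_drop = 0.05,
                       mode = c("dmin", "hsr"),
                       min_circle_fragments = 2,
                       passage_loss_prob = 0.4,
                       passage_new_break_rate = 0.3,
                       passage_mode = c("hsr", "dmin"),
                       seed = 1) {
  mode <- match.arg(mode)
  passage_mode <- match.arg(passage_mode)
  if (is.null(source_regions)) {
    source_regions <- tibble(
      chrom = c("chr7", "chr7", "chr8", "chr8"),
      start = c(100001, 400001, 150001, 550001),
      end = c(140000, 700000, 450000, 850000)
    )
    source_regions <- source_regions[source_regions$chrom %in%
                                       names(chrom_lengths), , drop = FALSE]
  }
  for (p in c(p_insertion, p_fragment_drop, passage_loss_prob)) {
    if (p < 0 || p > 1) abort("probabilities must lie in [0, 1]")
  }
  if (mh_bias < 0) abort("mh_bias must be >= 0")
  if (gc_fraction <= 0 || gc_fraction >= 1) {
    abort("gc_fraction must lie strictly between 0 and 1")
  }
  bad <- source_regions$end > chrom_lengths[source_regions$chrom]
  if (any(is.na(bad)) || any(bad)) {
    abort("source_regions must lie within the declared chromosomes")
  }
  structure(list(
    chrom_lengths = chrom_lengths, gc_fraction = gc_fraction,
    source_regions = as_tibble(source_regions), n_clusters = n_clusters,
    breaks_per_cluster = breaks_per_cluster,
    cluster_span_range = cluster_span_range,
    inter_cluster_min_gap = inter_cluster_min_gap,
    singletons_per_region = singletons_per_region,
    mh_bias = mh_bias, p_insertion = p_insertion,
    insertion_len_mean = insertion_len_mean,
    insertion_len_cap = insertion_len_cap,
    copy_number_mean = copy_number_mean,
    p_fragment_drop = p_fragment_drop, mode = mode,
    min_circle_fragments = min_circle_fragments,
    passage_loss_prob = passage_loss_prob,
    passage_new_break_rate = passage_new_break_rate,
    passage_mode = passage_mode, seed = seed
  ), class = "sim_config")
}

#' Simulate a reference genome
#'
#' I.i.d. bases at the requested GC content; deterministic under a fixed
#' seed.
#'
#' @param chrom_lengths named numeric vector of lengths (each >= 1000).
#' @param gc_fraction GC content, strictly between 0 and 1.
#' @param seed RNG seed.
#' @return named character vector of upper-case sequences.
#' @export
simulate_genome <- function(chrom_lengths, gc_fraction = 0.5, seed = 1) {
  if (gc_fraction <= 0 || gc_fraction >= 1) {
    abort("gc_fraction must lie strictly between 0 and 1")
  }
  if (any(chrom_lengths < 1000)) abort("chromosome lengths must be >= 1 kb")
  probs <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
             G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  withr::with_seed(seed, {
    vapply(chrom_lengths, function(len) {
      paste(sample(names(probs), len, replace = TRUE, prob = probs),
            collapse = "")
    }, character(1))
  })
}

# --- internal helpers -------------------------------------------------------

# Per-end cached flank strings for fast microhomology evaluation during join
# sampling. R1/B1 are the retained/beyond strings with the end playing the
# "first" (left-of-seam) role; the "second" role uses their reverse
# complements (precomputed, plus reversed copies for suffix matching).
end_table <- function(genome, fragments, window = 16) {
  ends <- bind_rows(
    tibble(frag_id = fragments$frag_id, side = "L",
           chrom = fragments$chrom, pos = fragments$start, orient = "-"),
    tibble(frag_id = fragments$frag_id, side = "R",
           chrom = fragments$chrom, pos = fragments$end, orient = "+")
  )
  fl <- purrr::pmap(list(ends$chrom, ends$pos, ends$orient),
                    function(ch, p, o) {
                      junction_flanks(genome, ch, p, o, "first", window)
                    })
  ends$R1 <- purrr::map_chr(fl, "retained")
  ends$B1 <- purrr::map_chr(fl, "beyond")
  ends$R2 <- revcomp(ends$R1)
  ends$B2 <- revcomp(ends$B1)
  ends$revR1 <- strrev(ends$R1)
  ends$revB2 <- strrev(ends$B2)
  ends$end_id <- paste0(ends$frag_id, ends$side)
  ends
}

# Two-sided mh between end x (first role) and each end of tbl (second role).
mh_to_candidates <- function(x, tbl) {
  right <- vapply(tbl$R2, common_prefix_len, integer(1), b = x$B1,
                  USE.NAMES = FALSE)
  left <- vapply(tbl$revB2, common_prefix_len, integer(1), b = x$revR1,
                 USE.NAMES = FALSE)
  right + left
}

draw_insert <- function(cfg, first_beyond_base, last_beyond_base) {
  len <- min(cfg$insertion_len_cap, rgeom(1, 1 / cfg$insertion_len_mean) + 1)
  bases <- c("A", "C", "G", "T")
  repeat {
    ins <- sample(bases, len, replace = TRUE)
    # canonical insert: must not be attributable to either flank continuation
    if (ins[1] != first_beyond_base && ins[len] != last_beyond_base) break
  }
  paste(ins, collapse = "")
}

end_arm <- function(e) {
  tibble(chrom = e$chrom, pos = e$pos, orient = e$orient)
}

# drop candidate ends whose junction with `cur` would exactly restore the
# reference (re-fusing the two sides of one cut) -- such a join is invisible
# to sequencing and is not a rearrangement. Kept only if it is the sole
# remaining option (forced closure).
drop_restoring <- function(cur, candidates) {
  restoring <- candidates$chrom == cur$chrom &
    ((cur$orient == "+" & candidates$orient == "-" &
        candidates$pos == cur$pos + 1) |
       (cur$orient == "-" & candidates$orient == "+" &
          candidates$pos == cur$pos - 1))
  if (all(restoring)) return(candidates)
  candidates[!restoring, , drop = FALSE]
}

# Sample joins chaining fragments into circles (dmin) or one chain (hsr).
# Returns list(junctions, membership) where membership records molecule id,
# chain position and flip per fragment.
sample_joins <- function(genome, ends, cfg, mode, molecule_offset = 0,
                         id_offset = 0) {
  beta <- cfg$mh_bias
  free <- ends
  junctions <- list()
  membership <- list()
  mol <- molecule_offset
  jid <- id_offset
  while (nrow(free) > 0) {
    mol <- mol + 1
    # start a new molecule with a random fragment, unflipped
    start_frag <- sample(unique(free$frag_id), 1)
    pos_in_chain <- 1
    membership[[length(membership) + 1]] <-
      tibble(frag_id = start_frag, molecule = mol, chain_pos = pos_in_chain,
             flipped = FALSE)
    start_end <- free[free$frag_id == start_frag & free$side == "L", ]
    cur <- free[free$frag_id == start_frag & free$side == "R", ]
    free <- free[free$frag_id != start_frag, , drop = FALSE]
    repeat {
      candidates <- free
      can_close <- mode == "dmin" && pos_in_chain >= cfg$min_circle_fragments
      if (can_close) candidates <- bind_rows(candidates, start_end)
      if (nrow(candidates) == 0) {
        if (mode == "dmin") {
          # must close the circle regardless of size
          candidates <- start_end
          can_close <- TRUE
        } else {
          break  # open chain end
        }
      }
      candidates <- drop_restoring(cur, candidates)
      with_insert <- runif(1) < cfg$p_insertion
      if (beta > 0 && !with_insert) {
        w <- (1 + beta)^mh_to_candidates(cur, candidates)
        pick <- sample.int(nrow(candidates), 1, prob = w)
      } else {
        pick <- sample.int(nrow(candidates), 1)
      }
      nxt <- candidates[pick, ]
      jid <- jid + 1
      ins <- ""
      if (with_insert) {
        ins <- draw_insert(cfg, substr(cur$B1, 1, 1),
                           substr(nxt$B2, nchar(nxt$B2), nchar(nxt$B2)))
      }
      mh <- mh_between(genome, cur$chrom, cur$pos, cur$orient,
                       nxt$chrom, nxt$pos, nxt$orient)
      junctions[[length(junctions) + 1]] <- tibble(
        id = paste0("j", jid),
        frag_a = cur$frag_id, end_a = cur$side,
        frag_b = nxt$frag_id, end_b = nxt$side,
        chrom1 = cur$chrom, pos1 = cur$pos, orient1 = cur$orient,
        chrom2 = nxt$chrom, pos2 = nxt$pos, orient2 = nxt$orient,
        mh_left = if (nzchar(ins)) 0L else as.integer(mh$mh_left),
        mh_right = if (nzchar(ins)) 0L else as.integer(mh$mh_right),
        inserted_seq = ins,
        molecule = mol
      )
      closing <- nxt$frag_id == start_end$frag_id & nxt$side == start_end$side
      if (can_close && closing) break
      pos_in_chain <- pos_in_chain + 1
      membership[[length(membership) + 1]] <-
        tibble(frag_id = nxt$frag_id, molecule = mol, chain_pos = pos_in_chain,
               flipped = nxt$side == "R")
      cur <- free[free$frag_id == nxt$frag_id & free$side != nxt$side, ]
      free <- free[free$frag_id != nxt$frag_id, , drop = FALSE]
    }
  }
  jx <- if (length(junctions) > 0) bind_rows(junctions) else NULL
  if (!is.null(jx)) jx$mh_len <- jx$mh_left + jx$mh_right
  list(junctions = jx, membership = bind_rows(membership))
}

# --- main generator ---------------------------------------------------------

#' Simulate an amplicon architecture
#'
#' Places clustered and singleton breakpoints in the configured source
#' regions, cuts the regions into fragments, drops a configurable fraction
#' of fragments (unamplified holes), and fuses the rest into closed circles
#' (dmin mode) or one linear chain (hsr mode). Partner ends are sampled with
#' probability weight `(1 + mh_bias)^mh`, where `mh` is the two-sided flank
#' microhomology of the candidate end pair; with probability `p_insertion` a
#' join instead receives an untemplated insert (called microhomology 0).
#' Every step is reproducible under the config seed.
#'
#' @param config a [sim_config()] object.
#' @param genome optional reference (named character vector); simulated from
#'   the config when `NULL`.
#' @return object of class `amplicon_sim`: list with `$genome`, `$config`,
#'   `$breakpoints`, `$fragments` (source interval, copy number, molecule,
#'   chain position, flip, dropped flag), `$junctions` (arm coordinates,
#'   realized microhomology, inserts, molecule) and `$mode`.
#' @export
simulate_amplicon <- function(config, genome = NULL) {
  cfg <- config
  if (is.null(genome)) {
    genome <- simulate_genome(cfg$chrom_lengths, cfg$gc_fraction, cfg$seed)
  }
  withr::with_seed(cfg$seed + 1L, {
    regions <- cfg$source_regions
    region_len <- regions$end - regions$start + 1
    max_span <- cfg$cluster_span_range[2]
    need <- cfg$inter_cluster_min_gap + max_span
    # allocate clusters to regions proportionally to length
    alloc <- as.vector(stats::rmultinom(1, cfg$n_clusters,
                                        region_len / sum(region_len)))
    bps <- list()
    for (r in seq_len(nrow(regions))) {
      k <- alloc[r]
      lo <- regions$start[r]
      hi <- regions$end[r] - 1
      if (k > 0) {
        if (hi - max_span - lo < need * (k - 1)) {
          abort("source region too small for the requested breakpoint clusters")
        }
        ok <- FALSE
        for (try in 1:1000) {
          anchors <- sort(round(runif(k, lo, hi - max_span)))
          if (k == 1 || min(diff(anchors)) >= need) { ok <- TRUE; break }
        }
        if (!ok) abort("could not place cluster anchors at the required spacing")
        for (a in anchors) {
          nb <- sample(seq(cfg$breaks_per_cluster[1],
                           cfg$breaks_per_cluster[2]), 1)
          span <- round(runif(1, cfg$cluster_span_range[1],
                              cfg$cluster_span_range[2]))
          offs <- if (nb > 2) {
            repeat {
              mid <- sort(round(runif(nb - 2, 1, span - 1)))
              cand <- c(0, mid, span)
              if (!anyDuplicated(cand)) break
            }
            cand
          } else if (nb == 2) c(0, span) else 0
          bps[[length(bps) + 1]] <- tibble(
            chrom = regions$chrom[r], pos = a + offs,
            cluster = paste0(regions$chrom[r], "_c", length(bps) + 1))
        }
      }
      n_single <- rpois(1, cfg$singletons_per_region)
      if (n_single > 0) {
        bps[[length(bps) + 1]] <- tibble(
          chrom = regions$chrom[r],
          pos = round(runif(n_single, lo, hi)),
          cluster = NA_character_)
      }
    }
    breakpoints <- bind_rows(bps) %>% arrange(.data$chrom, .data$pos)
    breakpoints <- breakpoints[!duplicated(breakpoints[c("chrom", "pos")]), ]

    # cut fragments between breakpoints within each source region
    frags <- list()
    for (r in seq_len(nrow(regions))) {
      ch <- regions$chrom[r]
      inside <- breakpoints$pos[breakpoints$chrom == ch &
                                  breakpoints$pos >= regions$start[r] &
                                  breakpoints$pos < regions$end[r]]
      cuts <- sort(unique(inside))
      starts <- c(regions$start[r], cuts + 1)
      ends <- c(cuts, regions$end[r])
      frags[[r]] <- tibble(chrom = ch, start = starts, end = ends)
    }
    fragments <- bind_rows(frags)
    fragments$frag_id <- paste0("f", seq_len(nrow(fragments)))
    fragments$dropped <- runif(nrow(fragments)) < cfg$p_fragment_drop
    if (all(fragments$dropped)) fragments$dropped[1] <- FALSE

    ends <- end_table(genome, fragments[!fragments$dropped, , drop = FALSE])
    sj <- sample_joins(genome, ends, cfg, cfg$mode)
    fragments <- left_join(fragments, sj$membership, by = "frag_id")

    cn <- tibble(molecule = sort(unique(sj$membership$molecule)))
    cn$copy_number <- pmax(1, rpois(nrow(cn), cfg$copy_number_mean))
    fragments <- left_join(fragments, cn, by = "molecule")
    fragments$copy_number[is.na(fragments$copy_number)] <- 0

    junctions <- sj$junctions
    junctions$fate <- "initial"
    fragments$fate <- ifelse(fragments$dropped, "dropped", "initial")

    structure(list(genome = genome, config = cfg, breakpoints = breakpoints,
                   fragments = fragments, junctions = junctions,
                   mode = cfg$mode),
              class = "amplicon_sim")
  })
}

#' @export
print.amplicon_sim <- function(x, ...) {
  cat(sprintf("Simulated amplicon (%s): %d fragments, %d junctions, %d molecule(s)\n",
              x$mode, sum(!x$fragments$dropped), nrow(x$junctions),
              length(unique(x$junctions$molecule))))
  invisible(x)
}

#' True contig chains of a simulated amplicon
#'
#' @param sim an `amplicon_sim` object.
#' @return tibble with `molecule`, `circular`, and list-columns of ordered
#'   `frag_ids` and `junction_ids`.
#' @export
truth_contigs <- function(sim) {
  frag <- sim$fragments %>% filter(!is.na(.data$molecule)) %>%
    arrange(.data$molecule, .data$chain_pos)
  jx <- sim$junctions
  frag %>%
    group_by(.data$molecule) %>%
    summarise(frag_ids = list(.data$frag_id), .groups = "drop") %>%
    mutate(junction_ids = purrr::map(.data$molecule, function(m) {
      jx$id[jx$molecule == m]
    }),
    circular = purrr::map2_lgl(.data$frag_ids, .data$junction_ids,
                               ~ length(.y) == length(.x)))
}

#' Apply a passage transition to a simulated amplicon
#'
#' Each fragment is independently lost with probability `loss_prob`; a
#' junction is lost when either of its flanking fragments is lost. New
#' breaks are added at `new_break_rate` per surviving fragment, splitting
#' fragments and creating free ends; all free ends are then re-fused (with
#' the same microhomology bias) into the `passage_mode` topology. Fates are
#' recorded per fragment and junction (`retained`, `lost`, `new`; fragments
#' may additionally be `dropped` from the start).
#'
#' @param sim an `amplicon_sim` object.
#' @param loss_prob,new_break_rate,mode,seed override the corresponding
#'   `passage_*` config entries when non-`NULL`.
#' @return a new `amplicon_sim` whose `$junctions` carries a `fate` column
#'   (`retained`/`new`, with lost junctions in `$lost_junctions`) and whose
#'   fragments record their fate; `$empty` flags an all-lost amplicon.
#' @export
simulate_passage <- function(sim, loss_prob = NULL, new_break_rate = NULL,
                             mode = NULL, seed = NULL) {
  cfg <- sim$config
  loss_prob <- loss_prob %||% cfg$passage_loss_prob
  new_break_rate <- new_break_rate %||% cfg$passage_new_break_rate
  mode <- mode %||% cfg$passage_mode
  seed <- seed %||% (cfg$seed + 2L)
  genome <- sim$genome
  withr::with_seed(seed, {
    frag <- sim$fragments %>% filter(!.data$dropped)
    jx <- sim$junctions
    lost_frag <- runif(nrow(frag)) < loss_prob
    frag$fate <- ifelse(lost_frag, "lost", "retained")
    lost_ids <- frag$frag_id[lost_frag]
    jx$fate <- ifelse(jx$frag_a %in% lost_ids | jx$frag_b %in% lost_ids,
                      "lost", "retained")
    surv <- frag[!lost_frag, , drop = FALSE]
    if (nrow(surv) == 0) {
      out <- sim
      out$fragments <- frag
      out$junctions <- jx[0, , drop = FALSE]
      out$lost_junctions <- jx
      out$empty <- TRUE
      return(out)
    }
    # new breaks split surviving fragments
    n_new <- rpois(1, new_break_rate * nrow(surv))
    new_bp <- list()
    if (n_new > 0) {
      widths <- surv$end - surv$start
      splittable <- which(widths >= 2)
      if (length(splittable) > 0) {
        tgt <- sample(splittable, min(n_new, length(splittable)),
                      replace = FALSE)
        for (i in tgt) {
          p <- round(runif(1, surv$start[i], surv$end[i] - 1))
          new_bp[[length(new_bp) + 1]] <-
            tibble(frag_id = surv$frag_id[i], pos = p)
        }
      }
    }
    pieces <- list()
    for (i in seq_len(nrow(surv))) {
      cuts <- sort(unlist(purrr::map(new_bp, function(b) {
        if (b$frag_id == surv$frag_id[i]) b$pos else NULL
      })))
      starts <- c(surv$start[i], cuts + 1)
      ends <- c(cuts, surv$end[i])
      pieces[[i]] <- tibble(
        chrom = surv$chrom[i], start = starts, end = ends,
        parent = surv$frag_id[i],
        fate = ifelse(length(cuts) > 0, "split", "retained"))
    }
    pieces <- bind_rows(pieces)
    pieces$frag_id <- ifelse(pieces$fate == "split",
                             paste0(pieces$parent, ".", seq_len(nrow(pieces))),
                             pieces$parent)

    # retained junctions glue piece ends together; find free piece ends
    kept_jx <- jx[jx$fate == "retained", , drop = FALSE]
    # a retained junction now attaches to the piece owning the original
    # fragment's outer end (splits only free the interior ends)
    owner <- function(parent, side) {
      sub <- pieces[pieces$parent == parent, , drop = FALSE]
      if (side == "L") sub$frag_id[which.min(sub$start)]
      else sub$frag_id[which.max(sub$end)]
    }
    if (nrow(kept_jx) > 0) {
      kept_jx$frag_a <- purrr::map2_chr(kept_jx$frag_a, kept_jx$end_a, owner)
      kept_jx$frag_b <- purrr::map2_chr(kept_jx$frag_b, kept_jx$end_b, owner)
    }
    occupied <- character(0)
    if (nrow(kept_jx) > 0) {
      occupied <- c(paste0(kept_jx$frag_a, ":", kept_jx$end_a),
                    paste0(kept_jx$frag_b, ":", kept_jx$end_b))
    }
    piece_ends <- bind_rows(
      tibble(frag_id = pieces$frag_id, parent = pieces$parent, side = "L",
             chrom = pieces$chrom, pos = pieces$start, orient = "-",
             outer = pieces$start == surv$start[match(pieces$parent,
                                                      surv$frag_id)]),
      tibble(frag_id = pieces$frag_id, parent = pieces$parent, side = "R",
             chrom = pieces$chrom, pos = pieces$end, orient = "+",
             outer = pieces$end == surv$end[match(pieces$parent,
                                                  surv$frag_id)])
    )
    piece_ends$used <- piece_ends$outer &
      paste0(piece_ends$frag_id, ":", piece_ends$side) %in% occupied
    free_ends <- piece_ends[!piece_ends$used, , drop = FALSE]

    # glue pieces + retained junctions into units (paths/cycles), then chain
    # the open units; each unit is represented by its free terminal ends.
    adj <- igraph_lite_components(pieces, kept_jx)
    free_ends$unit <- adj$unit[match(free_ends$frag_id, adj$frag_id)]
    closed_units <- setdiff(unique(adj$unit), unique(free_ends$unit))

    new_jx <- NULL
    if (nrow(free_ends) > 0) {
      et <- end_table2(genome, free_ends)
      sj <- sample_joins_units(genome, et, cfg, mode,
                               id_offset = max_join_id(jx))
      new_jx <- sj$junctions
      if (!is.null(new_jx)) new_jx$fate <- "new"
    }
    cn <- tibble(unit = unique(adj$unit))
    cn$copy_number <- pmax(1, rpois(nrow(cn), cfg$copy_number_mean))
    pieces$unit <- adj$unit[match(pieces$frag_id, adj$frag_id)]
    pieces$copy_number <- cn$copy_number[match(pieces$unit, cn$unit)]
    pieces$molecule <- match(pieces$unit, cn$unit)
    pieces$fate[pieces$fate == "split"] <- "new"

    all_jx <- bind_rows(kept_jx, new_jx)
    lost_tbl <- jx[jx$fate == "lost", , drop = FALSE]
    lost_frag_tbl <- frag[lost_frag, , drop = FALSE]
    dropped_tbl <- sim$fragments %>% filter(.data$dropped)

    out <- sim
    out$fragments <- bind_rows(
      pieces[, c("chrom", "start", "end", "frag_id", "molecule",
                 "copy_number", "fate")] %>%
        mutate(dropped = FALSE, chain_pos = NA_real_, flipped = NA),
      lost_frag_tbl %>% mutate(copy_number = 0),
      dropped_tbl
    )
    out$junctions <- all_jx
    out$lost_junctions <- lost_tbl
    out$mode <- mode
    out$empty <- FALSE
    out
  })
}

max_join_id <- function(jx) {
  ids <- suppressWarnings(as.integer(sub("^j", "", jx$id)))
  max(c(0L, ids[!is.na(ids)]))
}

# connected components of pieces glued by retained junctions (split
# siblings are NOT glued: a break separates them).
igraph_lite_components <- function(pieces, kept_jx) {
  ids <- pieces$frag_id
  comp <- seq_along(ids)
  find <- function(i) {
    while (comp[i] != i) i <- comp[i]
    i
  }
  if (nrow(kept_jx) > 0) {
    for (i in seq_len(nrow(kept_jx))) {
      ra <- find(match(kept_jx$frag_a[i], ids))
      rb <- find(match(kept_jx$frag_b[i], ids))
      if (ra != rb) comp[ra] <- rb
    }
  }
  roots <- vapply(seq_along(ids), find, integer(1))
  tibble(frag_id = ids, unit = paste0("u", match(roots, unique(roots))))
}

# end table for arbitrary end rows (frag_id, side, chrom, pos, orient)
end_table2 <- function(genome, ends, window = 16) {
  fl <- purrr::pmap(list(ends$chrom, ends$pos, ends$orient),
                    function(ch, p, o) {
                      junction_flanks(genome, ch, p, o, "first", window)
                    })
  ends$R1 <- purrr::map_chr(fl, "retained")
  ends$B1 <- purrr::map_chr(fl, "beyond")
  ends$R2 <- revcomp(ends$R1)
  ends$B2 <- revcomp(ends$B1)
  ends$revR1 <- strrev(ends$R1)
  ends$revB2 <- strrev(ends$B2)
  ends
}

# chain whole units by joining their free terminal ends; a unit enters the
# growing structure through one free end, its other free end (same unit)
# becomes the new open end.
sample_joins_units <- function(genome, ends, cfg, mode, id_offset = 0) {
  beta <- cfg$mh_bias
  free <- ends
  junctions <- list()
  jid <- id_offset
  while (nrow(free) > 0) {
    start_unit <- sample(unique(free$unit), 1)
    unit_ends <- free[free$unit == start_unit, , drop = FALSE]
    free <- free[free$unit != start_unit, , drop = FALSE]
    if (nrow(unit_ends) < 2) next  # a unit with one free end cannot extend
    start_end <- unit_ends[1, ]
    cur <- unit_ends[2, ]
    repeat {
      candidates <- free
      can_close <- mode == "dmin"
      if (can_close) candidates <- bind_rows(candidates, start_end)
      if (nrow(candidates) == 0) break
      candidates <- drop_restoring(cur, candidates)
      with_insert <- runif(1) < cfg$p_insertion
      if (beta > 0 && !with_insert) {
        w <- (1 + beta)^mh_to_candidates(cur, candidates)
        pick <- sample.int(nrow(candidates), 1, prob = w)
      } else {
        pick <- sample.int(nrow(candidates), 1)
      }
      nxt <- candidates[pick, ]
      jid <- jid + 1
      ins <- ""
      if (with_insert) {
        ins <- draw_insert(cfg, substr(cur$B1, 1, 1),
                           substr(nxt$B2, nchar(nxt$B2), nchar(nxt$B2)))
      }
      mh <- mh_between(genome, cur$chrom, cur$pos, cur$orient,
                       nxt$chrom, nxt$pos, nxt$orient)
      junctions[[length(junctions) + 1]] <- tibble(
        id = paste0("j", jid),
        frag_a = cur$frag_id, end_a = cur$side,
        frag_b = nxt$frag_id, end_b = nxt$side,
        chrom1 = cur$chrom, pos1 = cur$pos, orient1 = cur$orient,
        chrom2 = nxt$chrom, pos2 = nxt$pos, orient2 = nxt$orient,
        mh_left = if (nzchar(ins)) 0L else as.integer(mh$mh_left),
        mh_right = if (nzchar(ins)) 0L else as.integer(mh$mh_right),
        inserted_seq = ins,
        molecule = NA_integer_
      )
      closing <- can_close && nxt$frag_id == start_end$frag_id &&
        nxt$side == start_end$side && nxt$pos == start_end$pos
      if (closing) break
      # the partner unit's other free end becomes the open end
      partner_unit <- nxt$unit
      others <- free[free$unit == partner_unit, , drop = FALSE]
      others <- others[!(others$frag_id == nxt$frag_id &
                           others$side == nxt$side &
                           others$pos == nxt$pos), , drop = FALSE]
      free <- free[free$unit != partner_unit, , drop = FALSE]
      if (nrow(others) == 0) break  # absorbed a dead-end unit
      cur <- others[1, ]
      if (nrow(others) > 1) free <- bind_rows(free, others[-1, ])
    }
  }
  jx <- if (length(junctions) > 0) bind_rows(junctions) else NULL
  if (!is.null(jx)) jx$mh_len <- jx$mh_left + jx$mh_right
  list(junctions = jx)
}

#' Emit pipeline-facing observables from a simulated amplicon
#'
#' Converts the generative truth into the pipeline's input formats: a
#' junction table (read support Poisson with mean proportional to copy
#' number), a depth track (`baseline + copy_number * depth_per_copy`, with
#' optional per-base Poisson noise), and junction-spanning sequences built
#' from the realized flanks, inserts and microhomologies.
#'
#' @param sim an `amplicon_sim` object.
#' @param depth_per_copy depth contributed by one copy (> 0).
#' @param baseline depth of unamplified sequence.
#' @param support_per_copy mean read support contributed per copy.
#' @param noise logical; `FALSE` gives exact noiseless depth and support.
#' @param span_flank bp of retained sequence emitted on each side of the
#'   seam in `span_seq`.
#' @param sample_name value for the junction table's `samples` column.
#' @param seed RNG seed for the noise draws.
#' @return list with `$junctions` (a `jx_tbl`), `$depth` (a `depth_track`),
#'   `$amplified` (tibble of truth amplified intervals) and `$truth`
#'   (the input `sim`).
#' @export
sim_observables <- function(sim, depth_per_copy = 1.4, baseline = 3,
                            support_per_copy = 0.5, noise = TRUE,
                            span_flank = 100, sample_name = "s1",
                            seed = NULL) {
  if (depth_per_copy <= 0) abort("depth_per_copy must be > 0")
  seed <- seed %||% (sim$config$seed + 3L)
  genome <- sim$genome
  jx <- sim$junctions
  frag <- sim$fragments
  withr::with_seed(seed, {
    cn_of <- setNames(frag$copy_number, frag$frag_id)
    jx_cn <- (cn_of[jx$frag_a] + cn_of[jx$frag_b]) / 2
    mean_support <- support_per_copy * jx_cn
    support <- if (noise) rpois(nrow(jx), mean_support) else
      as.integer(round(mean_support))
    spans <- vapply(seq_len(nrow(jx)), function(i) {
      fa <- junction_flanks(genome, jx$chrom1[i], jx$pos1[i], jx$orient1[i],
                            "first", span_flank)
      fb <- junction_flanks(genome, jx$chrom2[i], jx$pos2[i], jx$orient2[i],
                            "second", span_flank)
      paste0(fa$retained, jx$inserted_seq[i], fb$retained)
    }, character(1))
    junctions <- junction_table(
      id = jx$id, chrom1 = jx$chrom1, pos1 = jx$pos1, orient1 = jx$orient1,
      chrom2 = jx$chrom2, pos2 = jx$pos2, orient2 = jx$orient2,
      support = support, inserted_seq = jx$inserted_seq, span_seq = spans,
      samples = sample_name)

    amp <- frag %>%
      filter(.data$copy_number > 0) %>%
      arrange(.data$chrom, .data$start)
    runs <- list()
    for (ch in names(genome)) {
      len <- nchar(genome[[ch]])
      sub <- amp[amp$chrom == ch, , drop = FALSE]
      bounds <- sort(unique(c(1, sub$start, sub$end + 1, len + 1)))
      starts <- bounds[-length(bounds)]
      ends <- bounds[-1] - 1
      cn <- vapply(starts, function(s) {
        hit <- sub$copy_number[sub$start <= s & sub$end >= s]
        if (length(hit) > 0) hit[1] else 0
      }, numeric(1))
      mean_depth <- baseline + cn * depth_per_copy
      if (noise) {
        # Poisson counting noise, emitted as noise_tile-bp tiles whose value
        # is the tile-mean of per-base Poisson draws (sums of Poissons), so
        # bin-level statistics match per-base emission at a fraction of the
        # track size
        noise_tile <- 100
        for (i in seq_along(starts)) {
          tile_starts <- seq(starts[i], ends[i], by = noise_tile)
          tile_ends <- pmin(tile_starts + noise_tile - 1, ends[i])
          width <- tile_ends - tile_starts + 1
          vals <- rpois(length(tile_starts), mean_depth[i] * width) / width
          runs[[length(runs) + 1]] <- tibble(
            chrom = ch, start = tile_starts, end = tile_ends, depth = vals)
        }
      } else {
        runs[[length(runs) + 1]] <- tibble(chrom = ch, start = starts,
                                           end = ends, depth = mean_depth)
      }
    }
    depth <- depth_track(bind_rows(runs))
    amp_merged <- merge_intervals(amp[, c("chrom", "start", "end")])
    list(junctions = junctions, depth = depth, amplified = amp_merged,
         truth = sim)
  })
}

# merge adjacent/overlapping intervals
merge_intervals <- function(x) {
  if (nrow(x) == 0) return(as_tibble(x))
  x %>%
    arrange(.data$chrom, .data$start) %>%
    group_by(.data$chrom) %>%
    mutate(new_run = row_number() == 1 |
             .data$start > cummax_lag(.data$end) + 1,
           run = cumsum(.data$new_run)) %>%
    group_by(.data$chrom, .data$run) %>%
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop") %>%
    select("chrom", "start", "end") %>%
    arrange(.data$chrom, .data$start)
}

cummax_lag <- function(x) {
  if (length(x) == 0) return(numeric(0))
  c(-Inf, cummax(x)[-length(x)])
}
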