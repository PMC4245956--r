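# Junction filtering and seam characterization.

test_that("support and amplified-region filters apply jointly", {
  amp <- tibble::tibble(chrom = "c1", start = 1000, end = 2000)
  jx <- junction_table(
    id = c("in2", "in3", "out9"),
    chrom1 = "c1", pos1 = c(1500, 1500, 5000), orient1 = "+",
    chrom2 = "c1", pos2 = c(9000, 9000, 9000), orient2 = "-",
    support = c(2, 3, 9))
  kept <- filter_junctions(jx, amp, min_support = 3)
  expect_equal(kept$id, "in3")  # support 2 removed, both-arms-outside removed
})

test_that("microhomology caller matches hand-constructed flanks", {
  # genome where the continuation past A starts "AC" and B starts "AC",
  # while the left-side bases disagree -> (mh_left, mh_right) = (0, 2)
  gA <- paste0(strrep("T", 50), "G", "AC", strrep("T", 47))
  gB <- paste0(strrep("A", 49), "C", "ACGG", strrep("G", 46))
  genome <- c(cA = gA, cB = gB)
  res <- junction_microhomology(
    junction_table("j1", "cA", 51, "+", "cB", 51, "-"), genome)
  expect_equal(res$mh_left, 0L)
  expect_equal(res$mh_right, 2L)
  expect_equal(res$mh_len, 2L)

  # flanks sharing nothing -> (0, 0)
  genome0 <- c(cA = paste0(strrep("A", 50), strrep("C", 50)),
               cB = paste0(strrep("G", 50), strrep("T", 50)))
  res0 <- junction_microhomology(
    junction_table("j1", "cA", 50, "+", "cB", 51, "-"), genome0)
  expect_equal(res0$mh_len, 0L)
})

test_that("caller equals the breakpoint-shift oracle on simulated junctions", {
  n_checked <- 0
  for (sd in 61:70) {
    sim <- simulate_amplicon(small_sim_config(seed = sd, p_insertion = 0))
    jx <- junction_microhomology(
      junction_table(sim$junctions$id,
                     sim$junctions$chrom1, sim$junctions$pos1,
                     sim$junctions$orient1,
                     sim$junctions$chrom2, sim$junctions$pos2,
                     sim$junctions$orient2),
      sim$genome)
    oracle <- vapply(seq_len(nrow(jx)), function(i) {
      oracle_mh_shift(sim$genome, jx$chrom1[i], jx$pos1[i], jx$orient1[i],
                      jx$chrom2[i], jx$pos2[i], jx$orient2[i])
    }, numeric(1))
    expect_equal(jx$mh_len, as.integer(oracle))
    n_checked <- n_checked + nrow(jx)
  }
  expect_gt(n_checked, 200)
})

test_that("reverse-complementing the genome leaves mh_len invariant", {
  sim <- simulate_amplicon(small_sim_config(seed = 66, p_insertion = 0))
  genome <- sim$genome
  jx <- sim$junctions
  rc_genome <- vapply(genome, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1))
  len <- nchar(genome[["cA"]])
  # mirrored breakend: position len - pos + 1, orientation flipped
  flip <- function(o) ifelse(o == "+", "-", "+")
  mirrored <- junction_table(jx$id,
                             jx$chrom1, len - jx$pos1 + 1, flip(jx$orient1),
                             jx$chrom2, len - jx$pos2 + 1, flip(jx$orient2))
  orig <- junction_microhomology(
    junction_table(jx$id, jx$chrom1, jx$pos1, jx$orient1,
                   jx$chrom2, jx$pos2, jx$orient2), genome)
  mirr <- junction_microhomology(mirrored, rc_genome)
  expect_equal(mirr$mh_len, orig$mh_len)
})

test_that("insertions are called exactly from constructed spans", {
  withr::local_seed(2)
  g <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
             collapse = "")
  genome <- c(c1 = g)
  a_flank <- substr(g, 901, 1000)     # A retained, "+" at 1000
  b_flank <- substr(g, 2001, 2100)    # B retained, "-" at 2001
  mk <- function(span) junction_table("j1", "c1", 1000, "+", "c1", 2001, "-",
                                      span_seq = span)
  # canonical insert: its boundary bases must not continue either reference
  # flank, otherwise the caller rightly attributes them to the reference
  bases <- c("A", "C", "G", "T")
  ins <- paste0(setdiff(bases, substr(g, 1001, 1001))[1], "GGT",
                setdiff(bases, substr(g, 2000, 2000))[1])
  with_ins <- call_insertions(mk(paste0(a_flank, ins, b_flank)), genome)
  expect_equal(with_ins$inserted_seq, ins)
  expect_equal(with_ins$insertion_len, 5L)

  flush <- call_insertions(mk(paste0(a_flank, b_flank)), genome)
  expect_equal(flush$insertion_len, 0L)

  expect_error(
    call_insertions(mk(paste0(strrep("A", 40), b_flank)), genome),
    "unanchored")
})

test_that("insertion calls equal simulator truth at p_insertion = 0.5", {
  for (sd in c(71, 72)) {
    sim <- simulate_amplicon(small_sim_config(seed = sd, p_insertion = 0.5))
    obs <- sim_observables(sim, noise = FALSE)
    ch <- characterize_junctions(obs$junctions, sim$genome)
    expect_equal(ch$inserted_seq, sim$junctions$inserted_seq)
    expect_equal(ch$mh_len, sim$junctions$mh_len)
    # mh and insertion are mutually exclusive on every junction
    expect_true(all(ch$mh_len == 0 | ch$insertion_len == 0))
  }
})

test_that("templated inserts are found and random inserts are not", {
  withr::local_seed(3)
  g <- paste(sample(c("A", "C", "G", "T"), 6000, replace = TRUE),
             collapse = "")
  genome <- c(c1 = g)
  # insert copied verbatim from 200 bp upstream of arm a (pos 3000)
  tmpl <- substr(g, 2771, 2800)
  jx <- junction_table("j1", "c1", 3000, "+", "c1", 5000, "-",
                       inserted_seq = tmpl)
  hits <- find_insert_templates(jx, genome, flank_window = 500)
  expect_gt(nrow(hits), 0)
  expect_true(any(hits$identity == 1 & hits$start == 2771))

  # short inserts are flagged unsearched
  short <- junction_table("j2", "c1", 3000, "+", "c1", 5000, "-",
                          inserted_seq = "ACGTACGTAC")
  h2 <- find_insert_templates(short, genome)
  expect_equal(nrow(h2), 0)
  expect_false(attr(h2, "searched")$searched[1])
})

test_that("random 30-mers almost never hit random flanks", {
  false_hits <- 0
  for (sd in 1:100) {
    withr::local_seed(900 + sd)
    g <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
               collapse = "")
    ins <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                 collapse = "")
    jx <- junction_table("j", "c1", 1200, "+", "c1", 1800, "-",
                         inserted_seq = ins)
    h <- find_insert_templates(jx, c(c1 = g), flank_window = 500,
                               min_identity = 0.9)
    false_hits <- false_hits + nrow(h)
  }
  expect_equal(false_hits, 0)
})

test_that("flank variants are detected and classified", {
  withr::local_seed(4)
  g <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
             collapse = "")
  # pin the bases at the seam so the two flanks share no boundary bases and
  # the called seam cannot drift into chance microhomology
  substr(g, 1000, 1000) <- "G"; substr(g, 2000, 2000) <- "T"
  substr(g, 1001, 1001) <- "A"; substr(g, 2001, 2001) <- "C"
  genome <- c(c1 = g)
  a_flank <- substr(g, 901, 1000)
  b_flank <- substr(g, 2001, 2100)

  # identical flanks -> no variants
  clean <- scan_flank_variants(
    junction_table("j0", "c1", 1000, "+", "c1", 2001, "-",
                   span_seq = paste0(a_flank, b_flank)), genome)
  expect_equal(nrow(clean), 0)

  # one G<->A substitution at offset -30 on the a side (a transition);
  # placed outside the 15 bp anchor seed, which requires an exact match
  mut <- a_flank
  substr(mut, 71, 71) <- if (substr(a_flank, 71, 71) == "G") "A" else "G"
  one <- scan_flank_variants(
    junction_table("j1", "c1", 1000, "+", "c1", 2001, "-",
                   span_seq = paste0(mut, b_flank)), genome)
  expect_equal(nrow(one), 1)
  expect_equal(one$offset, -30)
  expect_true(one$type %in% c("transition", "transversion"))

  # a planted 2 bp deletion in the b-side flank
  del_b <- paste0(substr(b_flank, 1, 40), substr(b_flank, 43, 100))
  two <- scan_flank_variants(
    junction_table("j2", "c1", 1000, "+", "c1", 2001, "-",
                   span_seq = paste0(a_flank, del_b)), genome)
  expect_true(any(two$type == "deletion" & two$length == 2))
})

test_that("junction summaries report both denominators", {
  all_blunt <- tibble::tibble(id = as.character(1:4), mh_len = 0L,
                              insertion_len = 0L)
  s <- summarize_junctions(all_blunt)
  expect_equal(s$stats$frac_blunt, 1)

  mixed <- tibble::tibble(id = as.character(1:10),
                          mh_len = c(0L, 0L, 1L, 2L, 1L, 0L, 0L, 0L, 3L, 0L),
                          insertion_len = c(0L, 0L, 0L, 0L, 0L, 0L, 5L, 8L,
                                            0L, 0L))
  sm <- summarize_junctions(mixed)
  expect_equal(sm$stats$frac_insertion, 0.2)
  expect_equal(sm$stats$frac_mh_all, 0.4)
  expect_equal(sm$stats$frac_mh_insfree, 0.5)
  expect_equal(sm$stats$frac_blunt, 0.4)
})
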