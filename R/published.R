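# Loaders for the published ODA14 worked-example tables shipped with the
# package (breakpoint clusters, new passage-4 breakpoints, contigs,
# amplified-region bounds).

pkg_extdata <- function(file) {
  path <- system.file("extdata", file, package = "amprearr")
  if (!nzchar(path)) abort(paste0("packaged table not found: ", file))
  path
}

read_published_tsv <- function(path) {
  as_tibble(read.table(path, header = TRUE, sep = "\t",
                       colClasses = "character", comment.char = "#",
                       stringsAsFactors = FALSE))
}

split_num <- function(x) {
  lapply(strsplit(x, ","), function(v) {
    if (length(v) == 1 && (v == "" || is.na(v))) return(numeric(0))
    suppressWarnings(as.numeric(ifelse(v == "na", NA, v)))
  })
}

#' Published chromosome-7 breakpoint clusters (passage 2)
#'
#' The breakpoint cluster layout reported for the dmin passage of the ODA14
#' oligodendroglioma xenograft: ordered member arm labels, gaps between
#' consecutive members, and the position of the first member.
#'
#' @return tibble with `cluster`, `members` (list of labels), `gaps` (list,
#'   bp), `anchor`, `printed_span`.
#' @export
published_breakpoint_clusters <- function() {
  raw <- read_published_tsv(pkg_extdata("oda14p2_chr7_clusters.tsv"))
  tibble(cluster = raw$cluster,
         members = strsplit(raw$members, " "),
         gaps = split_num(raw$gaps),
         anchor = as.numeric(raw$anchor),
         printed_span = as.numeric(raw$printed_span))
}

#' Published new chromosome-7 breakpoints (passage 4)
#'
#' @return tibble with `cluster`, `status` (`existing`/`new`), `members`
#'   (list), `gaps` (list), `anchor`.
#' @export
published_new_breakpoints <- function() {
  raw <- read_published_tsv(pkg_extdata("oda14p4_chr7_new_breakpoints.tsv"))
  tibble(cluster = raw$cluster, status = raw$status,
         members = strsplit(raw$members, " "),
         gaps = split_num(raw$gaps),
         anchor = as.numeric(raw$anchor))
}

#' Reconstruct breakpoint positions from cluster rows
#'
#' Expands anchor-plus-gaps cluster rows into one breakend per member
#' (position = anchor + cumulative gap).
#'
#' @param rows tibble with `cluster`, `members` (list), `gaps` (list) and
#'   `anchor` columns, as returned by [published_breakpoint_clusters()].
#' @param chrom chromosome to assign.
#' @return tibble with `chrom`, `pos`, `label`, `source_cluster`.
#' @export
reconstruct_breakpoints <- function(rows, chrom = "chr7") {
  out <- purrr::pmap(list(rows$cluster, rows$members, rows$gaps, rows$anchor),
                     function(cl, mem, gaps, anchor) {
                       pos <- anchor + c(0, cumsum(gaps))
                       tibble(chrom = chrom, pos = pos, label = mem,
                              source_cluster = cl)
                     })
  bind_rows(out) %>% arrange(.data$pos)
}

#' Published ODA14 contigs
#'
#' The reported contigs (ordered junction arms, per-junction microhomology,
#' fragment lengths and inter-fragment distances), transcribed as printed.
#' Suitable for replay through [contig_summary()].
#'
#' @return tibble with `passage`, `contig`, and list-columns
#'   `junction_ids`, `mh` (bp), `frag_lengths` (bp), `distances_kb`.
#' @export
published_contigs <- function() {
  raw <- read_published_tsv(pkg_extdata("oda14_contigs.tsv"))
  tibble(passage = raw$passage, contig = raw$contig,
         junction_ids = strsplit(raw$junctions, " "),
         mh = split_num(raw$mh),
         frag_lengths = split_num(raw$frag_lengths),
         distances_kb = split_num(raw$distances_kb))
}

#' Published amplified-region bounds (passage 2)
#'
#' @return tibble with `chrom`, `start`, `end` (1-based inclusive, hg19).
#' @export
published_amplified_segments <- function() {
  raw <- read_published_tsv(pkg_extdata("oda14p2_amplified_segments.tsv"))
  tibble(chrom = raw$chrom, start = as.numeric(raw$start),
         end = as.numeric(raw$end))
}
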