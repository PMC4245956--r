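#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn `%||%`
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   bind_rows left_join inner_join anti_join rename n row_number across
#'   distinct pull lag lead first last
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median rbinom rpois rgeom runif setNames binom.test
#'   ks.test rnorm complete.cases
#' @importFrom utils head tail write.table read.table
NULL

ORIENTS <- c("+", "-")

#' Build a junction table
#'
#' Constructs and validates the canonical junction tibble used throughout the
#' package. Each row is one fusion junction between two oriented breakends
#' ("arms"). Positions are 1-based; orientation `"+"` means the reference
#' upstream of (and including) `pos` is retained on that side (the fragment
#' ends at `pos`), `"-"` means the reference downstream is retained (the
#' fragment starts at `pos`).
#'
#' @param id character junction identifiers.
#' @param chrom1,pos1,orient1 first arm: chromosome, 1-based position,
#'   orientation (`"+"` or `"-"`).
#' @param chrom2,pos2,orient2 second arm.
#' @param support non-negative read support counts.
#' @param inserted_seq untemplated inserted sequence at the seam (`""` if
#'   none).
#' @param span_seq optional junction-spanning nucleotide sequence (`NA` if
#'   unavailable).
#' @param samples comma-separated sample names in which the junction was
#'   observed (`NA` if not tracked).
#' @return A tibble of class `jx_tbl` with one row per junction.
#' @export
#' @examples
#' junction_table(
#'   id = "j1",
#'   chrom1 = "chr7", pos1 = 54520243, orient1 = "+",
#'   chrom2 = "chr7", pos2 = 55123258, orient2 = "-", support = 5
#' )
junction_table <- function(id, chrom1, pos1, orient1, chrom2, pos2, orient2,
                           support = 0L, inserted_seq = "", span_seq = NA_character_,
                           samples = NA_character_) {
  out <- tibble(
    id = as.character(id),
    chrom1 = as.character(chrom1), pos1 = as.numeric(pos1),
    orient1 = as.character(orient1),
    chrom2 = as.character(chrom2), pos2 = as.numeric(pos2),
    orient2 = as.character(orient2),
    support = as.integer(support),
    inserted_seq = toupper(ifelse(is.na(inserted_seq), "", inserted_seq)),
    span_seq = toupper(as.character(span_seq)),
    samples = as.character(samples)
  )
  validate_junctions(out)
}

#' Validate a junction table
#'
#' Checks the invariants of the junction tibble: positive positions, legal
#' orientation tokens, non-negative support, and distinct arms.
#'
#' @param x a junction tibble (as from [junction_table()] or
#'   [read_junctions()]).
#' @return `x`, invisibly classed as `jx_tbl`, or an error describing the
#'   first violated invariant.
#' @export
validate_junctions <- function(x) {
  required <- c("id", "chrom1", "pos1", "orient1", "chrom2", "pos2", "orient2",
                "support")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort(paste0("junction table is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(x) > 0) {
    if (any(x$pos1 < 1) || any(x$pos2 < 1)) {
      abort("breakend positions must be >= 1 (1-based coordinates)")
    }
    bad <- !(x$orient1 %in% ORIENTS) | !(x$orient2 %in% ORIENTS)
    if (any(bad)) {
      abort(paste0("orientation tokens must be '+' or '-'; offending junction: ",
                   x$id[which(bad)[1]]))
    }
    if (any(x$support < 0)) abort("read support must be >= 0")
    same <- x$chrom1 == x$chrom2 & x$pos1 == x$pos2 & x$orient1 == x$orient2
    if (any(same)) {
      abort(paste0("the two arms of a junction must differ; offending junction: ",
                   x$id[which(same)[1]]))
    }
    if ("mh_len" %in% names(x) && "inserted_seq" %in% names(x)) {
      clash <- !is.na(x$mh_len) & x$mh_len > 0 &
        !is.na(x$inserted_seq) & nchar(x$inserted_seq) > 0
      if (any(clash)) {
        abort(paste0("microhomology and insertion are mutually exclusive; ",
                     "offending junction: ", x$id[which(clash)[1]]))
      }
    }
  }
  class(x) <- unique(c("jx_tbl", class(x)))
  x
}

JX_FILE_COLS <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                  "id", "support", "orient1", "orient2")
JX_OPT_COLS <- c("inserted_seq", "span_seq", "samples")

#' Read a junction table (BEDPE dialect)
#'
#' Reads a tab-separated junction file with a required header line:
#' `chrom1 start1 end1 chrom2 start2 end2 id support orient1 orient2`
#' plus optional `inserted_seq`, `span_seq` and `samples` columns. Breakend
#' intervals are 0-based half-open on disk (each one base wide) and are
#' converted to internal 1-based positions (`pos = end`). The `"."`
#' placeholder encodes an empty/absent optional value. Unknown columns are
#' preserved.
#'
#' @param path path to the TSV file.
#' @param samples optional character vector of declared sample names; if
#'   given, any junction annotated with a sample outside this set is an
#'   error.
#' @return A `jx_tbl` tibble (see [junction_table()]).
#' @export
read_junctions <- function(path, samples = NULL) {
  if (!file.exists(path)) abort(paste0("junction file not found: ", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, na = character())
  missing <- setdiff(JX_FILE_COLS, names(raw))
  if (length(missing) > 0) {
    abort(paste0("junction file ", path, " lacks required columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(raw) == 0) {
    return(junction_table(character(), character(), numeric(), character(),
                          character(), numeric(), character(), integer()))
  }
  num_or_die <- function(v, col) {
    out <- suppressWarnings(as.numeric(v))
    if (any(is.na(out))) {
      # +1 for the header line
      abort(paste0("malformed ", col, " at line ",
                   which(is.na(out))[1] + 1L, " of ", path))
    }
    out
  }
  start1 <- num_or_die(raw$start1, "start1")
  end1 <- num_or_die(raw$end1, "end1")
  start2 <- num_or_die(raw$start2, "start2")
  end2 <- num_or_die(raw$end2, "end2")
  bad_or <- !(raw$orient1 %in% ORIENTS) | !(raw$orient2 %in% ORIENTS)
  if (any(bad_or)) {
    abort(paste0("orientation token outside {+,-} at line ",
                 which(bad_or)[1] + 1L, " of ", path))
  }
  if (any(end1 - start1 != 1) || any(end2 - start2 != 1)) {
    bad <- which(end1 - start1 != 1 | end2 - start2 != 1)[1]
    abort(paste0("breakend interval is not one base wide at line ",
                 bad + 1L, " of ", path))
  }
  dot_na <- function(v) ifelse(v == "." | v == "", NA_character_, v)
  opt <- function(col, default) {
    if (col %in% names(raw)) dot_na(raw[[col]]) else rep(default, nrow(raw))
  }
  ins <- opt("inserted_seq", NA_character_)
  out <- junction_table(
    id = raw$id,
    chrom1 = raw$chrom1, pos1 = end1, orient1 = raw$orient1,
    chrom2 = raw$chrom2, pos2 = end2, orient2 = raw$orient2,
    support = as.integer(num_or_die(raw$support, "support")),
    inserted_seq = ifelse(is.na(ins), "", ins),
    span_seq = opt("span_seq", NA_character_),
    samples = opt("samples", NA_character_)
  )
  extra <- setdiff(names(raw), c(JX_FILE_COLS, JX_OPT_COLS))
  for (col in extra) out[[col]] <- raw[[col]]
  if (!is.null(samples)) {
    seen <- unique(unlist(strsplit(out$samples[!is.na(out$samples)], ",")))
    unknown <- setdiff(seen, samples)
    if (length(unknown) > 0) {
      abort(paste0("junction file mentions undeclared samples: ",
                   paste(unknown, collapse = ", ")))
    }
  }
  out
}

#' Write a junction table (BEDPE dialect)
#'
#' Inverse of [read_junctions()]: internal 1-based positions become 0-based
#' half-open one-base breakend intervals (`start = pos - 1`, `end = pos`).
#' Empty optional values are written as `"."`.
#'
#' @param x a `jx_tbl` junction tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_junctions <- function(x, path) {
  x <- validate_junctions(as_tibble(x))
  na_dot <- function(v) {
    v <- as.character(v)
    ifelse(is.na(v) | v == "", ".", v)
  }
  out <- tibble(
    chrom1 = x$chrom1,
    start1 = format_pos(x$pos1 - 1), end1 = format_pos(x$pos1),
    chrom2 = x$chrom2,
    start2 = format_pos(x$pos2 - 1), end2 = format_pos(x$pos2),
    id = x$id, support = x$support,
    orient1 = x$orient1, orient2 = x$orient2,
    inserted_seq = na_dot(x[["inserted_seq"]] %||% rep(NA, nrow(x))),
    span_seq = na_dot(x[["span_seq"]] %||% rep(NA, nrow(x))),
    samples = na_dot(x[["samples"]] %||% rep(NA, nrow(x)))
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

format_pos <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read a reference genome from FASTA
#'
#' @param path FASTA file.
#' @return A named character vector, one upper-cased sequence per contig.
#'   Duplicate contig names are an error.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) abort(paste0("reference FASTA not found: ", path))
  seqs <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) {
    abort(paste0("duplicate contig names in ", path, ": ",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  setNames(toupper(as.character(seqs)), nm)
}

#' Write a genome to FASTA
#'
#' @param genome named character vector of sequences.
#' @param path output FASTA path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, width = 70) {
  set <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a depth track from bedGraph
#'
#' Reads a 4-column bedGraph (`chrom start end value`, 0-based half-open,
#' whitespace separated, `track`/`#` lines skipped) into a tibble of 1-based
#' inclusive constant-depth runs. Regions absent from the file have depth 0;
#' overlapping records are an error.
#'
#' @param path bedGraph file.
#' @return A tibble with columns `chrom`, `start`, `end` (1-based inclusive)
#'   and `depth`, sorted, classed `depth_track`.
#' @export
read_depth_track <- function(path) {
  if (!file.exists(path)) abort(paste0("depth bedGraph not found: ", path))
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  if (!any(keep)) {
    return(depth_track(tibble(chrom = character(), start = numeric(),
                              end = numeric(), depth = numeric())))
  }
  df <- read.table(text = lines[keep], header = FALSE,
                   col.names = c("chrom", "start", "end", "depth"),
                   colClasses = c("character", "numeric", "numeric", "numeric"))
  depth_track(tibble(chrom = df$chrom, start = df$start + 1, end = df$end,
                     depth = df$depth))
}

#' Construct a depth track from runs
#'
#' @param runs tibble with `chrom`, `start`, `end` (1-based inclusive),
#'   `depth`.
#' @return the sorted, validated `depth_track` tibble.
#' @export
depth_track <- function(runs) {
  runs <- as_tibble(runs)[c("chrom", "start", "end", "depth")]
  if (nrow(runs) > 0) {
    if (any(runs$start < 1) || any(runs$end < runs$start)) {
      abort("depth runs must satisfy 1 <= start <= end")
    }
    runs <- arrange(runs, .data$chrom, .data$start)
    ov <- runs %>%
      group_by(.data$chrom) %>%
      mutate(overlap = .data$start <= lag(.data$end, default = -Inf)) %>%
      ungroup()
    if (any(ov$overlap)) {
      i <- which(ov$overlap)[1]
      abort(paste0("overlapping depth records on ", runs$chrom[i],
                   " near position ", format_pos(runs$start[i])))
    }
  }
  class(runs) <- unique(c("depth_track", class(runs)))
  runs
}

#' Write a depth track to bedGraph
#'
#' Zero-depth runs are omitted (absence encodes depth 0); adjacent
#' equal-depth runs are merged so the canonical representation round-trips.
#'
#' @param track a `depth_track` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_depth_track <- function(track, path) {
  track <- depth_track(track)
  track <- filter(track, .data$depth != 0)
  if (nrow(track) > 0) {
    track <- track %>%
      group_by(.data$chrom) %>%
      mutate(new_run = row_number() == 1 |
               .data$start != lag(.data$end) + 1 |
               .data$depth != lag(.data$depth),
             run = cumsum(.data$new_run)) %>%
      group_by(.data$chrom, .data$run) %>%
      summarise(start = min(.data$start), end = max(.data$end),
                depth = first(.data$depth), .groups = "drop") %>%
      arrange(.data$chrom, .data$start)
  }
  out <- data.frame(chrom = track$chrom,
                    start = format_pos(track$start - 1),
                    end = format_pos(track$end),
                    depth = track$depth)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Per-base depth lookup
#'
#' @param track a `depth_track` tibble.
#' @param chrom chromosome name (scalar).
#' @param pos vector of 1-based positions.
#' @return numeric vector of depths (0 where no run covers the position).
#' @export
depth_at <- function(track, chrom, pos) {
  runs <- filter(as_tibble(track), .data$chrom == !!chrom)
  if (nrow(runs) == 0) return(rep(0, length(pos)))
  idx <- findInterval(pos, runs$start)
  out <- rep(0, length(pos))
  hit <- idx >= 1
  hit[hit] <- pos[hit] <= runs$end[idx[hit]]
  out[hit] <- runs$depth[idx[hit]]
  out
}

#' Read genomic intervals from BED
#'
#' @param path BED file (0-based half-open); only the first three columns are
#'   used, a fourth column (name) is kept when present.
#' @return tibble with `chrom`, `start`, `end` (1-based inclusive) and
#'   optionally `name`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(paste0("BED file not found: ", path))
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  if (!any(keep)) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  df <- read.table(text = lines[keep], header = FALSE,
                   colClasses = "character")
  out <- tibble(chrom = df[[1]],
                start = as.numeric(df[[2]]) + 1,
                end = as.numeric(df[[3]]))
  if (ncol(df) >= 4) out$name <- df[[4]]
  if (any(out$start > out$end)) abort(paste0("invalid interval in ", path))
  arrange(out, .data$chrom, .data$start)
}

#' Write genomic intervals to BED
#'
#' @param x tibble with `chrom`, `start`, `end` (1-based inclusive),
#'   optional `name`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  out <- data.frame(chrom = x$chrom,
                    start = format_pos(x$start - 1),
                    end = format_pos(x$end))
  if ("name" %in% names(x)) out$name <- x$name
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Long-format breakends of a junction table
#'
#' Unnests each junction into its two oriented breakends, one row per arm.
#'
#' @param x a `jx_tbl` junction tibble.
#' @return tibble with `id`, `arm` (`"a"`/`"b"`), `chrom`, `pos`, `orient`.
#' @export
junction_breakends <- function(x) {
  x <- as_tibble(x)
  bind_rows(
    tibble(id = x$id, arm = "a", chrom = x$chrom1, pos = x$pos1,
           orient = x$orient1),
    tibble(id = x$id, arm = "b", chrom = x$chrom2, pos = x$pos2,
           orient = x$orient2)
  ) %>% arrange(.data$chrom, .data$pos)
}

#' @importFrom dplyr %>%
#' @export
dplyr::`%>%`
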