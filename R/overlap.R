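#' Read a BED3/BED6 file as a peak set
#'
#' Coordinates are kept in BED convention (0-based, half-open) in the
#' `intervals` table and converted to 1-based closed internally for the
#' interval engine. `track` and `#` comment lines are skipped; a BED3
#' line gets strand `"."` (unstranded, matches any strand).
#'
#' @param path BED file path.
#' @param name set name (defaults to the file name without extension).
#' @return A `peak_set`: list with `name`, `intervals` (data frame
#'   `chrom`, `start`, `end`, `strand`, sorted by chrom then start) and
#'   `gr` (a `GenomicRanges::GRanges` mirror).
#' @export
read_bed <- function(path, name = NULL) {
  stopifnot(file.exists(path))
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    stop("read_bed: no intervals in ", path, call. = FALSE)
  }
  fields <- strsplit(lines, "\t| +")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop("read_bed: malformed coordinates on line ", lineno[bad[1L]],
         call. = FALSE)
  }
  rev <- which(start >= end)
  if (length(rev)) {
    stop("read_bed: start >= end on line ", lineno[rev[1L]],
         call. = FALSE)
  }
  strand <- vapply(fields, function(f) {
    if (length(f) >= 6L && f[[6L]] %in% c("+", "-")) f[[6L]] else "."
  }, "")
  peak_set(data.frame(chrom = chrom, start = start, end = end,
                      strand = strand), name = name)
}

#' Construct a peak set from an interval table
#'
#' @param intervals data frame with `chrom`, `start`, `end` (0-based,
#'   half-open) and optionally `strand` (`"+"`, `"-"` or `"."`).
#' @param name set name.
#' @return A `peak_set` (see [read_bed]).
#' @export
peak_set <- function(intervals, name = "peaks") {
  stopifnot(is.data.frame(intervals),
            all(c("chrom", "start", "end") %in% names(intervals)),
            all(intervals$start >= 0),
            all(intervals$start < intervals$end))
  if (is.null(intervals$strand)) intervals$strand <- "."
  stopifnot(all(intervals$strand %in% c("+", "-", ".")))
  intervals <- intervals[order(intervals$chrom, intervals$start,
                               intervals$end), , drop = FALSE]
  rownames(intervals) <- NULL
  gr <- GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1L,
                              end = intervals$end),
    strand = ifelse(intervals$strand == ".", "*", intervals$strand))
  structure(list(name = name, intervals = intervals, gr = gr),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("Peak set '%s': %d intervals on %d sequence(s)\n",
              x$name, nrow(x$intervals), length(unique(x$intervals$chrom))))
  invisible(x)
}

#' Fraction of query peaks within a maximum gap of a subject peak
#'
#' A query interval counts as overlapping when some subject interval on
#' the same chromosome lies within `max_gap` base pairs: overlapping or
#' touching intervals have gap 0, and for disjoint intervals the gap is
#' the number of bases between the nearest ends (in 0-based half-open
#' coordinates, `gap([a,b), [c,d)) = c - b` for `c >= b`), so "within
#' 150 bp" means `gap <= 150`. With `same_strand = TRUE`, `+` only
#' matches `+`, `-` only `-`, and `"."` (unstranded) matches any strand.
#'
#' @param query,subject `peak_set` objects (see [read_bed]).
#' @param max_gap maximum separation in bp (default 150).
#' @param same_strand require matching strands (default `TRUE`).
#' @return List with `fraction` (`n_overlapping / n_query`), `n_query`
#'   and `n_overlapping`.
#' @export
overlap_fraction <- function(query, subject, max_gap = 150,
                             same_strand = TRUE) {
  stopifnot(inherits(query, "peak_set"), inherits(subject, "peak_set"),
            max_gap >= 0)
  if (nrow(query$intervals) == 0L) {
    stop("overlap_fraction: empty query set", call. = FALSE)
  }
  if (nrow(subject$intervals) == 0L) {
    stop("overlap_fraction: empty subject set", call. = FALSE)
  }
  hit <- overlapping_queries(query$gr, subject$gr, max_gap, same_strand)
  n_query <- nrow(query$intervals)
  n_overlapping <- sum(hit)
  list(fraction = n_overlapping / n_query,
       n_query = n_query,
       n_overlapping = n_overlapping)
}

# Logical vector: which query ranges have a subject within max_gap.
# Sets on entirely different chromosomes are a valid input with zero
# overlaps, so the seqlevel-mismatch warning is muffled.
overlapping_queries <- function(qgr, sgr, max_gap, same_strand) {
  hits <- withCallingHandlers(
    GenomicRanges::findOverlaps(qgr, sgr, maxgap = max_gap,
                                ignore.strand = !same_strand),
    warning = function(w) {
      if (grepl("no sequence levels in common", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  seq_along(qgr) %in% S4Vectors::queryHits(hits)
}

#' Three-way peak overlap (Venn region counts per anchor set)
#'
#' Each peak of each set receives a membership signature from the
#' pairwise [overlap_fraction] rule against the other two sets. Counts
#' are reported per anchor set: interval overlap is not a symmetric
#' partition (one anchor peak can absorb several subject peaks), so the
#' count of, say, the triple region depends on which set the peaks are
#' counted from.
#'
#' @param sets list of exactly 3 `peak_set` objects.
#' @param max_gap,same_strand as [overlap_fraction].
#' @return Data frame with one row per anchor set x signature:
#'   `anchor`, `in_<name1>`, `in_<name2>`, `in_<name3>` (logical
#'   membership), `region` (label like `"A&B&C"`), `count`.
#' @export
multiway_overlap <- function(sets, max_gap = 150, same_strand = TRUE) {
  stopifnot(is.list(sets), length(sets) == 3L,
            all(vapply(sets, inherits, logical(1), "peak_set")))
  nm <- vapply(sets, function(s) s$name, "")
  if (anyDuplicated(nm)) nm <- make.unique(nm)
  rows <- list()
  for (a in 1:3) {
    n_a <- nrow(sets[[a]]$intervals)
    if (n_a == 0L) stop("multiway_overlap: empty set ", nm[a],
                        call. = FALSE)
    member <- matrix(FALSE, nrow = n_a, ncol = 3L)
    member[, a] <- TRUE
    for (b in setdiff(1:3, a)) {
      member[, b] <- overlapping_queries(sets[[a]]$gr, sets[[b]]$gr,
                                         max_gap, same_strand)
    }
    sig <- interaction(member[, 1L], member[, 2L], member[, 3L],
                       drop = FALSE)
    combos <- expand.grid(m1 = c(FALSE, TRUE), m2 = c(FALSE, TRUE),
                          m3 = c(FALSE, TRUE))
    combos <- combos[combos[[a]], , drop = FALSE]  # anchor always member
    for (r in seq_len(nrow(combos))) {
      mr <- unlist(combos[r, ])
      cnt <- sum(member[, 1L] == mr[1L] & member[, 2L] == mr[2L] &
                   member[, 3L] == mr[3L])
      rows[[length(rows) + 1L]] <- data.frame(
        anchor = nm[a],
        m1 = mr[1L], m2 = mr[2L], m3 = mr[3L],
        region = paste(nm[mr], collapse = "&"),
        count = cnt)
    }
  }
  out <- do.call(rbind, rows)
  names(out)[2:4] <- paste0("in_", nm)
  rownames(out) <- NULL
  out
}
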