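#' Genomic interval sets on 0-based half-open coordinates
#'
#' An `interval_set` is the universal container for regulatory elements,
#' evolutionary feature sets, gene spans and blacklist regions: a data frame
#' with columns `chrom`, `start`, `end`, `name`, `strand`, kept sorted by
#' (chrom, start, end).  Coordinates follow the BED convention: `start` is
#' 0-based inclusive, `end` exclusive.  Strand is one of `"+"`, `"-"`,
#' `"*"` (unspecified).  Abutting intervals (`end == start`) do not overlap.
#'
#' @param chrom character vector of sequence names (non-empty strings).
#' @param start,end integer-like vectors; `0 <= start < end`.
#' @param name optional labels (recycled); `NA` for unnamed.
#' @param strand `"+"`, `"-"` or `"*"` (recycled).
#' @param label optional set label, stored as an attribute.
#' @return An object of class `interval_set` (a data frame).
#' @examples
#' interval_set("chr1", 0, 100)
#' @export
interval_set <- function(chrom = character(), start = integer(),
                         end = integer(), name = NA_character_,
                         strand = "*", label = NULL) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- length(start)
  if (length(end) != n) stop("start and end must have equal length")
  if (!length(chrom) %in% c(if (n > 0L) 1L else 0L, n)) {
    stop("chrom must have length 1 or length(start)")
  }
  chrom <- rep_len(as.character(chrom), n)
  x <- data.frame(chrom = as.character(chrom), start = start, end = end,
                  name = rep_len(as.character(name), max(n, 0L)),
                  strand = rep_len(as.character(strand), max(n, 0L)),
                  stringsAsFactors = FALSE)
  if (n == 0L) {
    x <- x[0L, , drop = FALSE]
  }
  validate_intervals(x)
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("interval_set", "data.frame")
  attr(x, "label") <- label
  x
}

validate_intervals <- function(x, where = NULL) {
  ctx <- if (is.null(where)) "" else paste0(" [", where, "]")
  if (any(is.na(x$chrom) | !nzchar(x$chrom))) {
    stop("empty chrom name", ctx)
  }
  if (any(is.na(x$start) | is.na(x$end))) {
    stop("missing coordinates", ctx)
  }
  if (any(x$start < 0)) {
    stop("negative start coordinate", ctx)
  }
  bad <- which(x$start >= x$end)
  if (length(bad)) {
    stop(sprintf("start >= end at record %d (%s:%g-%g)%s", bad[1],
                 x$chrom[bad[1]], x$start[bad[1]], x$end[bad[1]], ctx))
  }
  if (any(!x$strand %in% c("+", "-", "*"))) {
    stop("strand must be one of '+', '-', '*'", ctx)
  }
  invisible(x)
}

#' @export
print.interval_set <- function(x, ...) {
  lab <- attr(x, "label")
  cat(sprintf("interval_set%s with %d intervals on %d sequence(s)\n",
              if (is.null(lab)) "" else paste0(" '", lab, "'"),
              nrow(x), length(unique(x$chrom))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

# interval_set <-> GRanges (internal; GRanges is 1-based closed)
as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end),
    strand = ifelse(x$strand == "*", "*", x$strand))
}

from_granges <- function(gr, name = NA_character_, label = NULL) {
  s <- as.character(BiocGenerics::strand(gr))
  interval_set(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = BiocGenerics::start(gr) - 1,
               end = BiocGenerics::end(gr),
               name = name, strand = s, label = label)
}

#' Read and write BED files
#'
#' Reads 3- or 6-column tab-separated BED into an [interval_set].  A `"."`
#' name or strand is mapped to `NA` / `"*"`, so `read_bed(write_bed(x))`
#' round-trips both dialects.  Lines starting with `#`, `track` or
#' `browser` are skipped.
#'
#' @param path file path.
#' @param label optional set label.
#' @return An [interval_set].
#' @export
read_bed <- function(path, label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  idx <- which(keep)
  if (!length(idx)) return(interval_set(label = label))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop(sprintf("malformed BED line %d: fewer than 3 tab-separated columns",
                 idx[which(nf < 3L)[1]]))
  }
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop(sprintf("malformed BED line %d: non-numeric coordinates",
                 idx[which(is.na(start) | is.na(end))[1]]))
  }
  bad <- which(start >= end)
  if (length(bad)) {
    stop(sprintf("invalid BED line %d: start >= end", idx[bad[1]]))
  }
  nm <- ifelse(nf >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""),
               NA_character_)
  nm[nm == "."] <- NA_character_
  st <- ifelse(nf >= 6L, vapply(fields, function(f) f[min(6L, length(f))], ""),
               "*")
  st[!st %in% c("+", "-")] <- "*"
  interval_set(chrom, start, end, name = nm, strand = st, label = label)
}

#' @param x an [interval_set].
#' @rdname read_bed
#' @export
write_bed <- function(x, path) {
  six <- any(!is.na(x$name)) || any(x$strand != "*")
  if (six) {
    out <- data.frame(x$chrom, format_coord(x$start), format_coord(x$end),
                      ifelse(is.na(x$name), ".", x$name), 0L,
                      ifelse(x$strand == "*", ".", x$strand))
  } else {
    out <- data.frame(x$chrom, format_coord(x$start), format_coord(x$end))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Interval algebra: flatten, subtract, overlap counts, coverage
#'
#' `flatten()` merges intervals into a disjoint union of covered bases.
#' By default only intervals sharing at least one base are joined; abutting
#' intervals stay separate unless `gap > 0` allows up to `gap` uncovered
#' bases between merged intervals.  `subtract()` removes the bases of `b`
#' from each interval of `a` (intervals may split; names are kept).
#' `intersect_count()` reports, for each interval of `a`, how many
#' intervals of `b` overlap it by at least 1 bp.  `covered_bp()` is the
#' number of distinct covered bases.
#'
#' @param x,a,b [interval_set] objects.
#' @param gap merge intervals separated by at most this many uncovered
#'   bases (default 0: only true overlaps merge).
#' @return `flatten`/`subtract`: an [interval_set]; `intersect_count`: an
#'   integer vector along the intervals of `a`; `covered_bp`: a number.
#' @export
flatten <- function(x, gap = 0) {
  if (nrow(x) == 0L) return(x)
  mgw <- if (gap <= 0) 0L else as.integer(gap + 1L)
  gr <- GenomicRanges::reduce(as_granges(x), min.gapwidth = mgw,
                              ignore.strand = TRUE)
  from_granges(gr, label = attr(x, "label"))
}

#' @rdname flatten
#' @export
subtract <- function(a, b) {
  if (nrow(a) == 0L) return(a)
  if (nrow(b) == 0L) return(a)
  gra <- as_granges(a)
  mask <- GenomicRanges::reduce(as_granges(b), ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(gra, mask, ignore.strand = TRUE)
  untouched <- setdiff(seq_len(nrow(a)), S4Vectors::queryHits(hits))
  pieces <- list(a[untouched, , drop = FALSE])
  for (i in unique(S4Vectors::queryHits(hits))) {
    sub <- mask[S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]]
    keep <- IRanges::setdiff(IRanges::IRanges(a$start[i] + 1, a$end[i]),
                             IRanges::ranges(sub))
    if (length(keep)) {
      pieces[[length(pieces) + 1L]] <- data.frame(
        chrom = a$chrom[i], start = BiocGenerics::start(keep) - 1,
        end = BiocGenerics::end(keep), name = a$name[i],
        strand = a$strand[i], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, lapply(pieces, as.data.frame))
  interval_set(out$chrom, out$start, out$end, name = out$name,
               strand = out$strand, label = attr(a, "label"))
}

#' @rdname flatten
#' @export
intersect_count <- function(a, b) {
  if (nrow(a) == 0L) return(integer(0))
  if (nrow(b) == 0L) return(integer(nrow(a)))
  # sets over unrelated chrom universes are a legitimate zero-overlap case
  suppressWarnings(GenomicRanges::countOverlaps(as_granges(a),
                                                as_granges(b),
                                                ignore.strand = TRUE))
}

#' @rdname flatten
#' @export
covered_bp <- function(x) {
  if (nrow(x) == 0L) return(0)
  sum(as.numeric(BiocGenerics::width(
    GenomicRanges::reduce(as_granges(x), ignore.strand = TRUE))))
}

#' Flanking windows around features
#'
#' For each feature, emits the two windows `[start - width, start)` and
#' `[end, end + width)`, clamped to `[0, chrom length)`.  The feature body
#' itself is never included; windows that clamp to zero length are dropped.
#'
#' @param features an [interval_set].
#' @param width window width in bp (> 0); e.g. `5e5` or `1e6`.
#' @param chrom_lengths named numeric vector of sequence lengths.
#' @return An [interval_set] of flank windows, named `<feature>_up` /
#'   `<feature>_down`.
#' @export
flank_windows <- function(features, width, chrom_lengths) {
  stopifnot(width > 0)
  missing <- setdiff(unique(features$chrom), names(chrom_lengths))
  if (length(missing)) {
    stop("unknown chrom length for: ", paste(missing, collapse = ", "))
  }
  if (nrow(features) == 0L) return(features)
  len <- chrom_lengths[features$chrom]
  base <- ifelse(is.na(features$name), as.character(seq_len(nrow(features))),
                 features$name)
  left <- data.frame(chrom = features$chrom,
                     start = pmax(0, features$start - width),
                     end = features$start,
                     name = paste0(base, "_up"))
  right <- data.frame(chrom = features$chrom,
                      start = features$end,
                      end = pmin(len, features$end + width),
                      name = paste0(base, "_down"))
  out <- rbind(left, right)
  out <- out[out$start < out$end, , drop = FALSE]
  interval_set(out$chrom, out$start, out$end, name = out$name,
               label = attr(features, "label"))
}
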