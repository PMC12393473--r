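#' Genomes as in-memory nucleotide sequences
#'
#' A thin wrapper around a [Biostrings::DNAStringSet] keyed by chrom name.
#'
#' @param sequences named character vector or `DNAStringSet` over
#'   `{A,C,G,T,N}`.
#' @return An object of class `genome`.
#' @export
genome <- function(sequences) {
  if (is.character(sequences)) {
    sequences <- Biostrings::DNAStringSet(sequences)
  }
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("genome sequences must be named by chrom")
  }
  if (any(BiocGenerics::width(sequences) < 1L)) {
    stop("zero-length sequence in genome")
  }
  structure(list(seq = sequences), class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("genome with %d sequence(s), %s bp total\n",
              length(x$seq),
              format(sum(as.numeric(BiocGenerics::width(x$seq))),
                     big.mark = ",")))
  invisible(x)
}

#' @rdname genome
#' @param x a `genome`.
#' @return `seq_lengths`: named numeric vector of chrom lengths.
#' @export
seq_lengths <- function(x) {
  stats::setNames(as.numeric(BiocGenerics::width(x$seq)), names(x$seq))
}

#' @rdname genome
#' @param path FASTA file path.
#' @export
read_fasta <- function(path) genome(Biostrings::readDNAStringSet(path))

#' @rdname genome
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(x$seq, path, width = 70L)
  invisible(path)
}

#' Extract sequence for an interval
#'
#' Returns the nucleotide string covered by a 0-based half-open interval;
#' minus-strand requests return the reverse complement.
#'
#' @param x a [genome].
#' @param chrom,start,end interval coordinates (0-based half-open).
#' @param strand `"+"`, `"-"` or `"*"` (treated as `"+"`).
#' @return A character scalar of length `end - start`.
#' @export
fetch_sequence <- function(x, chrom, start, end, strand = "+") {
  if (!chrom %in% names(x$seq)) stop("unknown chrom: ", chrom)
  L <- as.numeric(BiocGenerics::width(x$seq[chrom]))
  if (start < 0 || end > L || start >= end) {
    stop(sprintf("interval %s:%g-%g out of bounds (length %g)",
                 chrom, start, end, L))
  }
  s <- Biostrings::subseq(x$seq[[chrom]], start + 1, end)
  if (identical(strand, "-")) s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Sparse per-position score tracks
#'
#' A `score_track` assigns a real score to runs of positions (bedGraph
#' semantics, 0-based half-open, non-overlapping).  Positions not covered
#' have no score and are reported as `NA`, never as zero.
#'
#' @param chrom,start,end,score parallel vectors defining scored runs.
#' @return An object of class `score_track` (a data frame).
#' @export
score_track <- function(chrom = character(), start = numeric(),
                        end = numeric(), score = numeric()) {
  x <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                  end = as.numeric(end), score = as.numeric(score),
                  stringsAsFactors = FALSE)
  if (nrow(x)) {
    if (any(x$start >= x$end) || any(x$start < 0)) {
      stop("invalid score-track coordinates")
    }
    x <- x[order(x$chrom, x$start), , drop = FALSE]
    same <- x$chrom[-1] == x$chrom[-nrow(x)]
    if (nrow(x) > 1 && any(same & x$start[-1] < x$end[-nrow(x)])) {
      stop("score-track intervals overlap")
    }
  }
  rownames(x) <- NULL
  class(x) <- c("score_track", "data.frame")
  x
}

#' @rdname score_track
#' @param path bedGraph file path (4 tab-separated columns).
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  tab <- tab[!grepl("^(track|browser)", tab[[1]]), , drop = FALSE]
  if (ncol(tab) < 4L) stop("bedGraph needs 4 columns: ", path)
  score_track(tab[[1]], tab[[2]], tab[[3]], tab[[4]])
}

#' @rdname score_track
#' @param x a `score_track`.
#' @export
write_bedgraph <- function(x, path) {
  out <- data.frame(x$chrom, format_coord(x$start), format_coord(x$end),
                    x$score)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Look up scores at single positions
#'
#' @param track a [score_track].
#' @param chrom sequence name.
#' @param positions 0-based positions.
#' @return Numeric vector along `positions`; `NA` where no score is
#'   defined.
#' @export
fetch_scores <- function(track, chrom, positions) {
  b <- track[track$chrom == chrom, , drop = FALSE]
  out <- rep(NA_real_, length(positions))
  if (!nrow(b)) return(out)
  idx <- findInterval(positions, b$start)
  hit <- idx >= 1L & positions < ifelse(idx >= 1L, b$end[pmax(idx, 1L)], 0)
  out[hit] <- b$score[idx[hit]]
  out
}
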