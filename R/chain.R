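#' Pairwise colinear alignment maps (chains)
#'
#' A `chain_map` holds gapped colinear alignment blocks between a source
#' and a target assembly, the structure behind coordinate liftover.  Blocks
#' are grouped into chains by `chain_id`: one chain is a single colinear
#' target run (one target chrom, one orientation, monotone coordinates).
#' Within a block source and target have equal length; blocks are pairwise
#' non-overlapping on the source across the whole map.
#'
#' Target coordinates are always stored on the forward strand of the
#' target; `t_strand == "-"` means a source position `p` inside a block
#' maps to `t_end - 1 - (p - s_start)` (and the lifted base is the reverse
#' complement).
#'
#' @param blocks data frame with columns `chain_id`, `s_chrom`, `s_start`,
#'   `s_end`, `t_chrom`, `t_start`, `t_end`, `t_strand`.
#' @param name optional assembly-pair label (e.g. `"target->sister"`).
#' @return An object of class `chain_map`.
#' @export
chain_map <- function(blocks, name = NULL) {
  need <- c("chain_id", "s_chrom", "s_start", "s_end",
            "t_chrom", "t_start", "t_end", "t_strand")
  if (!all(need %in% names(blocks))) {
    stop("chain blocks need columns: ", paste(need, collapse = ", "))
  }
  blocks <- as.data.frame(blocks)[need]
  blocks$chain_id <- as.character(blocks$chain_id)
  if (any(blocks$s_end - blocks$s_start != blocks$t_end - blocks$t_start)) {
    stop("chain block source and target lengths differ")
  }
  if (any(blocks$s_start < 0 | blocks$t_start < 0) ||
      any(blocks$s_start >= blocks$s_end)) {
    stop("invalid chain block coordinates")
  }
  if (any(!blocks$t_strand %in% c("+", "-"))) {
    stop("chain t_strand must be '+' or '-'")
  }
  blocks <- blocks[order(blocks$s_chrom, blocks$s_start), , drop = FALSE]
  rownames(blocks) <- NULL
  # non-overlap on source across the whole map
  same <- blocks$s_chrom[-1] == blocks$s_chrom[-nrow(blocks)]
  if (nrow(blocks) > 1 &&
      any(same & blocks$s_start[-1] < blocks$s_end[-nrow(blocks)])) {
    stop("chain blocks overlap on the source assembly")
  }
  # one chain = one target chrom and orientation
  per <- split(blocks, blocks$chain_id)
  ok <- vapply(per, function(b) {
    length(unique(b$t_chrom)) == 1L && length(unique(b$t_strand)) == 1L
  }, TRUE)
  if (!all(ok)) stop("a chain must map to a single target chrom and strand")
  structure(list(blocks = blocks, name = name), class = "chain_map")
}

#' @export
print.chain_map <- function(x, ...) {
  cat(sprintf("chain_map%s: %d blocks in %d chain(s)\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              nrow(x$blocks), length(unique(x$blocks$chain_id))))
  invisible(x)
}

#' Read and write chain files
#'
#' Two dialects parse to the same [chain_map]: the UCSC chain layout
#' (`chain score tName tSize tStrand tStart tEnd qName qSize qStrand
#' qStart qEnd id` headers followed by `size dt dq` alignment lines, where
#' the "t" side is the source assembly) and a simplified TSV block table
#' with the [chain_map] block columns.  Minus-strand UCSC query
#' coordinates, given on the reversed strand, are normalised to forward
#' coordinates on read.
#'
#' @param path file path; dialect is auto-detected on read.
#' @return `read_chain`: a [chain_map].
#' @export
read_chain <- function(path, name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  nonblank <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (!length(nonblank)) stop("empty chain file: ", path)
  if (grepl("^chain\\s", nonblank[1])) {
    read_chain_ucsc(nonblank, name)
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             comment.char = "#", stringsAsFactors = FALSE)
    chain_map(tab, name = name)
  }
}

read_chain_ucsc <- function(lines, name = NULL) {
  rows <- list()
  i <- 1L
  auto_id <- 0L
  while (i <= length(lines)) {
    h <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (h[1] != "chain" || length(h) < 12L) {
      stop("malformed chain header at line ", i)
    }
    s_chrom <- h[3]; s_pos <- as.numeric(h[6])
    t_chrom <- h[8]; t_size <- as.numeric(h[9]); t_strand <- h[10]
    t_pos <- as.numeric(h[11])
    auto_id <- auto_id + 1L
    id <- if (length(h) >= 13L) h[13] else as.character(auto_id)
    i <- i + 1L
    repeat {
      f <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
      size <- f[1]
      if (size > 0) {
        if (t_strand == "+") {
          ts <- t_pos; te <- t_pos + size
        } else {
          # reversed-strand coordinates -> forward coordinates
          ts <- t_size - (t_pos + size); te <- t_size - t_pos
        }
        rows[[length(rows) + 1L]] <- data.frame(
          chain_id = id, s_chrom = s_chrom, s_start = s_pos,
          s_end = s_pos + size, t_chrom = t_chrom, t_start = ts,
          t_end = te, t_strand = t_strand, stringsAsFactors = FALSE)
      }
      if (length(f) >= 3L && !anyNA(f[2:3])) {
        s_pos <- s_pos + size + f[2]
        t_pos <- t_pos + size + f[3]
        i <- i + 1L
      } else {
        i <- i + 1L
        break
      }
    }
    while (i <= length(lines) && !grepl("^chain\\s", lines[i])) i <- i + 1L
  }
  blocks <- do.call(rbind, rows)
  # within a minus-strand chain the per-block mapping above already yields
  # forward t coordinates; for '-' chains source position p maps to
  # t_end - 1 - (p - s_start) handled at lookup time
  chain_map(blocks, name = name)
}

#' @param chain a [chain_map].
#' @param dialect `"tsv"` writes the block table; `"ucsc"` writes UCSC
#'   chain records (requires `s_sizes` and `t_sizes`).
#' @param s_sizes,t_sizes named vectors of chrom lengths for the source and
#'   target assemblies (UCSC dialect only).
#' @rdname read_chain
#' @export
write_chain <- function(chain, path, dialect = c("tsv", "ucsc"),
                        s_sizes = NULL, t_sizes = NULL) {
  dialect <- match.arg(dialect)
  b <- chain$blocks
  if (dialect == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(chain$name)) writeLines(paste0("# name=", chain$name), con)
    utils::write.table(b, con, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  if (is.null(s_sizes) || is.null(t_sizes)) {
    stop("UCSC dialect needs s_sizes and t_sizes")
  }
  out <- character()
  for (id in unique(b$chain_id)) {
    cb <- b[b$chain_id == id, , drop = FALSE]
    cb <- cb[order(cb$s_start), , drop = FALSE]
    strand <- cb$t_strand[1]
    tsz <- t_sizes[[cb$t_chrom[1]]]
    # convert forward target coords back to strand-relative chain coords
    if (strand == "+") {
      tq_start <- cb$t_start; tq_end <- cb$t_end
    } else {
      tq_start <- tsz - cb$t_end; tq_end <- tsz - cb$t_start
      o <- order(tq_start)
      cb <- cb[o, , drop = FALSE]
      tq_start <- tq_start[o]; tq_end <- tq_end[o]
    }
    hdr <- sprintf("chain 1000 %s %s + %s %s %s %s %s %s %s %s",
                   cb$s_chrom[1], format_coord(s_sizes[[cb$s_chrom[1]]]),
                   format_coord(cb$s_start[1]),
                   format_coord(cb$s_end[nrow(cb)]),
                   cb$t_chrom[1], format_coord(tsz), strand,
                   format_coord(tq_start[1]),
                   format_coord(tq_end[nrow(cb)]), id)
    body <- character(nrow(cb))
    for (k in seq_len(nrow(cb))) {
      size <- cb$s_end[k] - cb$s_start[k]
      if (k < nrow(cb)) {
        dt <- cb$s_start[k + 1] - cb$s_end[k]
        dq <- tq_start[k + 1] - tq_end[k]
        body[k] <- paste(format_coord(size), format_coord(dt),
                         format_coord(dq))
      } else {
        body[k] <- format_coord(size)
      }
    }
    out <- c(out, hdr, body, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Map single positions through a chain
#'
#' Maps 0-based source positions to target coordinates through the blocks
#' of a [chain_map].  Because blocks are non-overlapping on the source,
#' each position maps through at most one block.
#'
#' @param chain a [chain_map].
#' @param chrom source sequence name.
#' @param positions 0-based source positions.
#' @return A data frame with one row per position: `t_chrom`, `t_pos`
#'   (`NA` where the position falls in a chain gap), `t_strand`,
#'   `chain_id`.
#' @export
map_positions <- function(chain, chrom, positions) {
  b <- chain$blocks[chain$blocks$s_chrom == chrom, , drop = FALSE]
  out <- data.frame(t_chrom = NA_character_, t_pos = NA_real_,
                    t_strand = NA_character_, chain_id = NA_character_,
                    stringsAsFactors = FALSE)[rep(1L, length(positions)), ,
                                              drop = FALSE]
  rownames(out) <- NULL
  if (!nrow(b)) return(out)
  idx <- findInterval(positions, b$s_start)
  hit <- idx >= 1L & positions < ifelse(idx >= 1L, b$s_end[pmax(idx, 1L)], 0)
  if (any(hit)) {
    bi <- idx[hit]
    off <- positions[hit] - b$s_start[bi]
    plus <- b$t_strand[bi] == "+"
    tp <- ifelse(plus, b$t_start[bi] + off, b$t_end[bi] - 1 - off)
    out$t_chrom[hit] <- b$t_chrom[bi]
    out$t_pos[hit] <- tp
    out$t_strand[hit] <- b$t_strand[bi]
    out$chain_id[hit] <- b$chain_id[bi]
  }
  out
}

#' Lift an interval between assemblies
#'
#' Maps a source interval through the chains of a [chain_map].  A chain is
#' a candidate when at least `min_match` of the interval's bases fall in
#' its blocks.  With `allow_multiple = FALSE` (the default, used by the
#' divergence pipeline) more than one candidate chain is an orthology
#' ambiguity and yields an empty result with reason `"multiple_hits"`;
#' cross-species element comparison uses `allow_multiple = TRUE` with
#' `min_match = 0.1`.  Minus-strand chains reverse orientation.
#'
#' @param interval a single-row [interval_set] (or a list/data frame with
#'   `chrom`, `start`, `end`).
#' @param chain a [chain_map].
#' @param allow_multiple report all candidate chains instead of rejecting.
#' @param min_match minimum fraction of bases covered by one chain's
#'   blocks (default 1: the entire length must be mappable).
#' @return A list of class `liftover_result` with `hits` (an
#'   [interval_set], one row per accepted target locus, strand set to the
#'   chain orientation) and `reason` (`NA` on success, otherwise one of
#'   `"no_coverage"`, `"below_min_match"`, `"multiple_hits"`).
#' @export
liftover_interval <- function(interval, chain, allow_multiple = FALSE,
                              min_match = 1) {
  chrom <- interval$chrom[1]; s <- interval$start[1]; e <- interval$end[1]
  width <- e - s
  b <- chain$blocks[chain$blocks$s_chrom == chrom &
                      chain$blocks$s_start < e &
                      chain$blocks$s_end > s, , drop = FALSE]
  fail <- function(reason) {
    structure(list(hits = interval_set(), reason = reason),
              class = "liftover_result")
  }
  if (!nrow(b)) return(fail("no_coverage"))
  b$ov_start <- pmax(b$s_start, s)
  b$ov_end <- pmin(b$s_end, e)
  per <- split(b, b$chain_id)
  cov <- vapply(per, function(x) sum(x$ov_end - x$ov_start), 0)
  cand <- names(cov)[cov / width >= min_match]
  if (!length(cand)) return(fail("below_min_match"))
  if (length(cand) > 1L && !allow_multiple) return(fail("multiple_hits"))
  hits <- do.call(rbind, lapply(per[cand], function(x) {
    plus <- x$t_strand[1] == "+"
    if (plus) {
      ts <- x$t_start + (x$ov_start - x$s_start)
      te <- x$t_start + (x$ov_end - x$s_start)
    } else {
      ts <- x$t_end - (x$ov_end - x$s_start)
      te <- x$t_end - (x$ov_start - x$s_start)
    }
    data.frame(chrom = x$t_chrom[1], start = min(ts), end = max(te),
               strand = x$t_strand[1], chain_id = x$chain_id[1],
               stringsAsFactors = FALSE)
  }))
  out <- interval_set(hits$chrom, hits$start, hits$end,
                      name = hits$chain_id, strand = hits$strand)
  structure(list(hits = out, reason = NA_character_),
            class = "liftover_result")
}

#' Lift every interval of a set
#'
#' Convenience wrapper around [liftover_interval()] with the defaults used
#' for cross-species element comparison (multiple matches allowed,
#' `min_match = 0.1`).
#'
#' @inheritParams liftover_interval
#' @param x an [interval_set].
#' @return An [interval_set] of mapped intervals (source interval index in
#'   `name` unless the source had names); unmappable intervals are simply
#'   absent.
#' @export
liftover_set <- function(x, chain, allow_multiple = TRUE, min_match = 0.1) {
  rows <- list()
  for (i in seq_len(nrow(x))) {
    r <- liftover_interval(x[i, , drop = FALSE], chain,
                           allow_multiple = allow_multiple,
                           min_match = min_match)
    if (nrow(r$hits)) {
      h <- as.data.frame(r$hits)
      h$name <- if (is.na(x$name[i])) as.character(i) else x$name[i]
      rows[[length(rows) + 1L]] <- h
    }
  }
  if (!length(rows)) return(interval_set(label = attr(x, "label")))
  out <- do.call(rbind, rows)
  interval_set(out$chrom, out$start, out$end, name = out$name,
               strand = out$strand, label = attr(x, "label"))
}
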