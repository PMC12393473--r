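# Brute-force oracles, kept independent of the implementation paths they
# check: coverage arrays for interval algebra, a per-base position map for
# liftover, and an exhaustive hypergeometric tail for the 2x2 exact test.

# logical coverage vector over [0, max_pos) for one chrom
oracle_coverage <- function(set, chrom, max_pos) {
  cov <- rep(FALSE, max_pos)
  s <- set[set$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(s))) {
    lo <- max(0, s$start[i]); hi <- min(max_pos, s$end[i])
    if (lo < hi) cov[(lo + 1):hi] <- TRUE
  }
  cov
}

oracle_intersect_count <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    sum(b$chrom == a$chrom[i] & b$start < a$end[i] & b$end > a$start[i])
  }, 0L)
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e4,
                             max_len = 300) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(max_pos - max_len, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  interval_set(chrom, start, start + len)
}

# per-base map of every source position through every chain independently
# of map_positions(): returns, per chain id, a vector of target positions
# (NA in gaps) and the strand
oracle_chain_map <- function(chain, chrom, L) {
  b <- chain$blocks[chain$blocks$s_chrom == chrom, , drop = FALSE]
  out <- list()
  for (id in unique(b$chain_id)) {
    cb <- b[b$chain_id == id, , drop = FALSE]
    tp <- rep(NA_real_, L)
    for (k in seq_len(nrow(cb))) {
      for (p in cb$s_start[k]:(cb$s_end[k] - 1)) {
        tp[p + 1] <- if (cb$t_strand[k] == "+") {
          cb$t_start[k] + (p - cb$s_start[k])
        } else {
          cb$t_end[k] - 1 - (p - cb$s_start[k])
        }
      }
    }
    out[[id]] <- list(t_pos = tp, t_chrom = cb$t_chrom[1],
                      strand = cb$t_strand[1])
  }
  out
}

# liftover of [s, e) via the per-base map
oracle_liftover <- function(s, e, chmap, min_match, allow_multiple) {
  width <- e - s
  cand <- list()
  for (id in names(chmap)) {
    tp <- chmap[[id]]$t_pos[(s + 1):e]
    cov <- sum(!is.na(tp))
    if (cov / width >= min_match) {
      cand[[id]] <- data.frame(chrom = chmap[[id]]$t_chrom,
                               start = min(tp, na.rm = TRUE),
                               end = max(tp, na.rm = TRUE) + 1,
                               strand = chmap[[id]]$strand,
                               chain_id = id, stringsAsFactors = FALSE)
    }
  }
  if (!length(cand)) return(NULL)
  if (length(cand) > 1L && !allow_multiple) return("multiple_hits")
  do.call(rbind, cand)
}

# random multi-chain block structure on one source chrom
random_chain <- function(L = 1000, n_chains = 2, seed_blocks = 4) {
  cuts <- sort(sample(seq(10, L - 10, by = 10),
                      n_chains * seed_blocks * 2))
  starts <- cuts[seq(1, length(cuts), by = 2)]
  ends <- cuts[seq(2, length(cuts), by = 2)]
  keep <- starts < ends
  starts <- starts[keep]; ends <- ends[keep]
  ids <- sort(rep_len(seq_len(n_chains), length(starts)))
  rows <- list()
  for (id in unique(ids)) {
    ss <- starts[ids == id]; ee <- ends[ids == id]
    strand <- sample(c("+", "-"), 1)
    tchrom <- paste0("t", id)
    offset <- sample(0:500, 1)
    w <- ee - ss
    if (strand == "+") {
      ts <- offset + cumsum(c(0, utils::head(w + 5, -1)))
      rows[[length(rows) + 1L]] <- data.frame(
        chain_id = as.character(id), s_chrom = "src", s_start = ss,
        s_end = ee, t_chrom = tchrom, t_start = ts, t_end = ts + w,
        t_strand = "+")
    } else {
      # colinear on the minus strand: later source blocks map to smaller
      # forward target coordinates
      ts <- offset + rev(cumsum(c(0, utils::head(rev(w) + 5, -1))))
      rows[[length(rows) + 1L]] <- data.frame(
        chain_id = as.character(id), s_chrom = "src", s_start = ss,
        s_end = ee, t_chrom = tchrom, t_start = ts, t_end = ts + w,
        t_strand = "-")
    }
  }
  chain_map(do.call(rbind, rows))
}

# exhaustive two-sided Fisher p for the 2x2 table [(a, bpa-a), (b, bpb-b)]
oracle_fisher_p <- function(a, bpa, b, bpb) {
  k <- a + b
  xs <- max(0, k - bpb):min(k, bpa)
  probs <- stats::dhyper(xs, bpa, bpb, k)
  p_obs <- stats::dhyper(a, bpa, bpb, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# small deterministic atlas built by hand
toy_atlas <- function(combos, conditions = autopod_conditions(),
                      element_length = 500, gap = 100, chrom = "chrA") {
  n <- length(combos)
  starts <- (seq_len(n) - 1) * (element_length + gap)
  els <- interval_set(chrom, starts, starts + element_length,
                      name = sprintf("el_%03d", seq_len(n)))
  m <- matrix(FALSE, n, length(conditions),
              dimnames = list(els$name, conditions))
  for (i in seq_len(n)) m[i, conditions %in% combos[[i]]] <- TRUE
  accessibility_atlas(els, conditions, m)
}
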