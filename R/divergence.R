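#' Configuration of the fixed-substitution survey
#'
#' @param standard_length every element is re-centred on its midpoint and
#'   resized to exactly this many bp before filtering (default 500);
#'   `NULL` disables standardisation.
#' @param maf_threshold positions polymorphic in any species with minor-
#'   allele frequency strictly above this are masked (default 0.05).
#' @param min_identity minimum sequence identity between the target
#'   fragment and its aligned counterparts (default 0.25, the expected
#'   match of random equal-length sequences, which screens out faulty
#'   alignments and indel-related mismatch while keeping orthologous
#'   bases).
#' @param identity_mode `"and"` (default) requires the identity gate
#'   against both non-target genomes; `"or"` against at least one.
#' @return A `divergence_config` list.
#' @export
divergence_config <- function(standard_length = 500, maf_threshold = 0.05,
                              min_identity = 0.25,
                              identity_mode = c("and", "or")) {
  identity_mode <- match.arg(identity_mode)
  stopifnot(is.null(standard_length) || standard_length > 0,
            maf_threshold >= 0, maf_threshold < 0.5,
            min_identity > 0, min_identity <= 1)
  structure(list(standard_length = standard_length,
                 maf_threshold = maf_threshold,
                 min_identity = min_identity,
                 identity_mode = identity_mode),
            class = "divergence_config")
}

#' Three-genome analysis context
#'
#' Bundles everything the fixed-substitution survey consumes: the target,
#' sister and outgroup genomes, the two chain maps from target
#' coordinates, the three per-species variant catalogs, the blacklist,
#' and optionally a conservation score track on target coordinates.
#'
#' @param target,sister,outgroup [genome]s.
#' @param chain_sister,chain_outgroup [chain_map]s from target
#'   coordinates to the sister and outgroup assemblies.
#' @param catalogs named list of [variant_catalog]s (`target`, `sister`,
#'   `outgroup`), all on target coordinates.
#' @param blacklist an [interval_set] (may be empty).
#' @param score_track optional [score_track] on target coordinates.
#' @return A `trio_context` list.
#' @export
trio_context <- function(target, sister, outgroup, chain_sister,
                         chain_outgroup, catalogs,
                         blacklist = interval_set(), score_track = NULL) {
  stopifnot(inherits(target, "genome"), inherits(sister, "genome"),
            inherits(outgroup, "genome"),
            inherits(chain_sister, "chain_map"),
            inherits(chain_outgroup, "chain_map"),
            all(c("target", "sister", "outgroup") %in% names(catalogs)))
  structure(list(target = target, sister = sister, outgroup = outgroup,
                 chain_sister = chain_sister,
                 chain_outgroup = chain_outgroup, catalogs = catalogs,
                 blacklist = blacklist, score_track = score_track,
                 cache = new.env(parent = emptyenv())),
            class = "trio_context")
}

#' @rdname trio_context
#' @param sim a simulated trio from [simulate_trio()].
#' @param score_track optional [score_track].
#' @export
trio_context_from_sim <- function(sim, score_track = NULL) {
  trio_context(sim$target, sim$sister, sim$outgroup, sim$chain_sister,
               sim$chain_outgroup, sim$catalogs, sim$blacklist,
               score_track)
}

#' Standardise elements to a fixed length
#'
#' Re-centres each interval on the floor of its midpoint and resizes it
#' to exactly `L` bp.  Windows that would extend past either chromosome
#' end are rejected, not clamped (clamping would break the fixed
#' length).
#'
#' @param x an [interval_set].
#' @param L standard length in bp.
#' @param chrom_lengths named vector of chrom lengths.
#' @return A list with `accepted` and `rejected` [interval_set]s.
#' @export
standardize_to_length <- function(x, L, chrom_lengths) {
  stopifnot(L > 0)
  if (nrow(x) == 0L) return(list(accepted = x, rejected = x))
  mid <- floor((x$start + x$end) / 2)
  ns <- mid - L %/% 2
  ne <- ns + L
  len <- chrom_lengths[x$chrom]
  ok <- ns >= 0 & ne <= len
  acc <- interval_set(x$chrom[ok], ns[ok], ne[ok], name = x$name[ok],
                      strand = x$strand[ok], label = attr(x, "label"))
  rej <- x[!ok, , drop = FALSE]
  rej <- interval_set(rej$chrom, rej$start, rej$end, name = rej$name,
                      strand = rej$strand, label = attr(x, "label"))
  list(accepted = acc, rejected = rej)
}

#' Mask polymorphic and blacklisted bases, fragmenting elements
#'
#' Subtracts every position polymorphic in any species at minor-allele
#' frequency strictly above `maf_threshold`, plus all blacklist bases.
#' Elements may split into several fragments; each fragment keeps its
#' parent element's name.
#'
#' @param intervals an [interval_set].
#' @param catalogs named list of [variant_catalog]s for the three
#'   species.
#' @param maf_threshold strict MAF threshold (default 0.05).
#' @param blacklist an [interval_set].
#' @return An [interval_set] of fragments.
#' @export
mask_and_fragment <- function(intervals, catalogs, maf_threshold = 0.05,
                              blacklist = interval_set()) {
  masks <- list(blacklist)
  for (cat in catalogs) {
    common <- cat[cat$maf > maf_threshold, , drop = FALSE]
    if (nrow(common)) {
      masks[[length(masks) + 1L]] <-
        interval_set(common$chrom, common$pos, common$pos + 1)
    }
  }
  masks <- masks[vapply(masks, nrow, 0L) > 0L]
  out <- intervals
  for (m in masks) out <- subtract(out, m)
  out
}

#' Align a fragment to the sister and outgroup genomes
#'
#' A fragment is surveyed only if it lifts to both non-target genomes
#' with full-length coverage at a single locus each (`min_match = 1`,
#' multiple chains rejected).  Aligned sequences are then fetched base by
#' base through the chains, reverse-complementing across minus-strand
#' chains, and the identity of the target sequence to each counterpart
#' computed (positions where either base is N are excluded from the
#' identity).
#'
#' @param fragment a single-row [interval_set].
#' @param context a [trio_context].
#' @return A list of class `surveyed_fragment`: `interval`, `target_seq`,
#'   `sister_seq`, `outgroup_seq` (per-position aligned strings),
#'   `identity_sister`, `identity_outgroup`, and `rejection` (`NA` when
#'   accepted, otherwise `"unmappable_sister"` / `"unmappable_outgroup"`).
#' @export
map_fragment_to_trio <- function(fragment, context) {
  rej <- function(reason) {
    structure(list(interval = fragment, target_seq = NULL,
                   sister_seq = NULL, outgroup_seq = NULL,
                   identity_sister = NA_real_,
                   identity_outgroup = NA_real_, rejection = reason),
              class = "surveyed_fragment")
  }
  ls <- liftover_interval(fragment, context$chain_sister,
                          allow_multiple = FALSE, min_match = 1)
  if (nrow(ls$hits) == 0L) return(rej("unmappable_sister"))
  lo <- liftover_interval(fragment, context$chain_outgroup,
                          allow_multiple = FALSE, min_match = 1)
  if (nrow(lo$hits) == 0L) return(rej("unmappable_outgroup"))

  pos <- seq(fragment$start[1], fragment$end[1] - 1)
  tseq <- strsplit(fetch_sequence(context$target, fragment$chrom[1],
                                  fragment$start[1], fragment$end[1]),
                   "")[[1]]
  sseq <- aligned_bases(context, "sister", context$chain_sister,
                        fragment$chrom[1], pos)
  oseq <- aligned_bases(context, "outgroup", context$chain_outgroup,
                        fragment$chrom[1], pos)
  structure(list(interval = fragment, target_seq = tseq,
                 sister_seq = sseq, outgroup_seq = oseq,
                 identity_sister = sequence_identity(tseq, sseq),
                 identity_outgroup = sequence_identity(tseq, oseq),
                 rejection = NA_character_),
            class = "surveyed_fragment")
}

# per-base lifted sequence; assumes full coverage (checked upstream)
aligned_bases <- function(context, role, chain, chrom, positions) {
  m <- map_positions(chain, chrom, positions)
  if (anyNA(m$t_pos)) stop("aligned_bases called on uncovered positions")
  out <- character(length(positions))
  for (tc in unique(m$t_chrom)) {
    sel <- m$t_chrom == tc
    seqchars <- genome_chars(context, role, tc)
    b <- seqchars[m$t_pos[sel] + 1]
    minus <- m$t_strand[sel] == "-"
    b[minus] <- chartr("ACGTN", "TGCAN", b[minus])
    out[sel] <- b
  }
  out
}

# memoized chromosome-as-character-vector lookup (splitting the whole
# sequence once instead of once per fragment)
genome_chars <- function(context, role, chrom) {
  key <- paste0(role, "::", chrom)
  if (!exists(key, envir = context$cache, inherits = FALSE)) {
    assign(key,
           strsplit(as.character(context[[role]]$seq[[chrom]]), "")[[1]],
           envir = context$cache)
  }
  get(key, envir = context$cache, inherits = FALSE)
}

#' Fraction of identical aligned bases
#'
#' Positions where either base is N are excluded from both numerator and
#' denominator; `NA` when no comparable position remains.
#'
#' @param a,b equal-length character vectors (or single strings) of
#'   aligned nucleotides.
#' @return A fraction in `[0, 1]`, or `NA`.
#' @export
sequence_identity <- function(a, b) {
  if (length(a) == 1L && nchar(a[1]) > 1L) a <- strsplit(a, "")[[1]]
  if (length(b) == 1L && nchar(b[1]) > 1L) b <- strsplit(b, "")[[1]]
  if (length(a) != length(b)) stop("sequence length mismatch")
  if (!length(a)) stop("empty sequences")
  ok <- a != "N" & b != "N"
  if (!any(ok)) return(NA_real_)
  mean(a[ok] == b[ok])
}

#' Call lineage-specific derived positions in a surveyed fragment
#'
#' Under two-outgroup parsimony, a position is derived on the target
#' lineage when the target base differs from the base shared by the
#' sister and outgroup (and none of the three is N); on the sister
#' lineage when the sister base differs from the base shared by target
#' and outgroup.
#'
#' @param surveyed an accepted `surveyed_fragment`.
#' @param lineage `"target"` or `"sister"`.
#' @return Sorted 0-based chromosome positions (target coordinates).
#' @export
call_derived_positions <- function(surveyed, lineage = c("target",
                                                         "sister")) {
  lineage <- match.arg(lineage)
  stopifnot(is.na(surveyed$rejection))
  t <- surveyed$target_seq; s <- surveyed$sister_seq
  o <- surveyed$outgroup_seq
  no_n <- t != "N" & s != "N" & o != "N"
  hit <- if (lineage == "target") t != s & s == o else s != t & t == o
  surveyed$interval$start[1] + which(hit & no_n) - 1
}

#' Survey element sets for lineage-specific fixed substitutions
#'
#' Runs the full procedure on each element set: standardise to a fixed
#' length, mask common polymorphisms (any species) and blacklist bases,
#' lift every surviving fragment to the sister and outgroup genomes
#' requiring full-length single-locus mappability, gate on sequence
#' identity, and call derived positions on both the target and the
#' sister lineage by two-outgroup parsimony.  Conservation scores at
#' derived positions are collected when the context carries a score
#' track.
#'
#' @param element_sets named list of [interval_set]s.
#' @param context a [trio_context].
#' @param config a [divergence_config].
#' @return An object of class `divergence_report`: `summary` (data frame
#'   with one row per set x lineage: `set`, `lineage`, `bp_surveyed`,
#'   `derived_count`, `rate_per_bp`), `derived` (per set, per lineage
#'   position vectors), `scores` (per set, per lineage score vectors with
#'   missing positions dropped and counted), `rejections` (data frame of
#'   reason tallies per set).
#' @export
run_divergence <- function(element_sets, context,
                           config = divergence_config()) {
  if (inherits(element_sets, "interval_set")) {
    element_sets <- list(elements = element_sets)
  }
  chrom_lengths <- seq_lengths(context$target)
  summary <- list(); derived <- list(); scores <- list()
  rejections <- list()
  for (set_name in names(element_sets)) {
    x <- element_sets[[set_name]]
    rejtab <- c(standardize_out_of_bounds = 0L, unmappable_sister = 0L,
                unmappable_outgroup = 0L, low_identity = 0L)
    if (!is.null(config$standard_length)) {
      std <- standardize_to_length(x, config$standard_length,
                                   chrom_lengths)
      rejtab["standardize_out_of_bounds"] <- nrow(std$rejected)
      x <- std$accepted
    }
    frags <- mask_and_fragment(x, context$catalogs, config$maf_threshold,
                               context$blacklist)
    bp <- 0
    pos_t <- numeric(0); pos_s <- numeric(0)
    for (i in seq_len(nrow(frags))) {
      sf <- map_fragment_to_trio(frags[i, , drop = FALSE], context)
      if (!is.na(sf$rejection)) {
        rejtab[sf$rejection] <- rejtab[sf$rejection] + 1L
        next
      }
      ids <- c(sf$identity_sister, sf$identity_outgroup)
      pass <- if (config$identity_mode == "and") {
        all(!is.na(ids) & ids >= config$min_identity)
      } else {
        any(!is.na(ids) & ids >= config$min_identity)
      }
      if (!pass) {
        rejtab["low_identity"] <- rejtab["low_identity"] + 1L
        next
      }
      bp <- bp + (frags$end[i] - frags$start[i])
      pos_t <- c(pos_t, call_derived_positions(sf, "target"))
      pos_s <- c(pos_s, call_derived_positions(sf, "sister"))
    }
    pos_t <- sort(unique(pos_t)); pos_s <- sort(unique(pos_s))
    chrom1 <- if (nrow(frags)) frags$chrom[1] else NA_character_
    sc <- list(target = numeric(0), sister = numeric(0),
               n_missing = c(target = 0L, sister = 0L))
    if (!is.null(context$score_track) && !is.na(chrom1)) {
      for (ln in c("target", "sister")) {
        p <- if (ln == "target") pos_t else pos_s
        v <- fetch_scores(context$score_track, chrom1, p)
        sc[[ln]] <- v[!is.na(v)]
        sc$n_missing[ln] <- sum(is.na(v))
      }
    }
    summary[[set_name]] <- data.frame(
      set = set_name, lineage = c("target", "sister"),
      bp_surveyed = bp,
      derived_count = c(length(pos_t), length(pos_s)),
      rate_per_bp = if (bp > 0) c(length(pos_t), length(pos_s)) / bp
                    else NA_real_,
      stringsAsFactors = FALSE)
    derived[[set_name]] <- list(target = pos_t, sister = pos_s)
    scores[[set_name]] <- sc
    rejections[[set_name]] <- data.frame(set = set_name,
                                         reason = names(rejtab),
                                         n = unname(rejtab),
                                         stringsAsFactors = FALSE)
  }
  structure(list(summary = do.call(rbind, c(summary,
                                            make.row.names = FALSE)),
                 derived = derived, scores = scores,
                 rejections = do.call(rbind, c(rejections,
                                               make.row.names = FALSE))),
            class = "divergence_report")
}

#' @export
print.divergence_report <- function(x, ...) {
  cat("divergence_report\n")
  print.data.frame(x$summary)
  invisible(x)
}

#' Test for a conservation-score shift between lineages
#'
#' Compares the conservation scores at target- and sister-lineage derived
#' positions with a two-sided Wilcoxon rank-sum test.  `NA` scores
#' (positions without a defined score) are excluded and counted.
#'
#' @param scores_target,scores_sister numeric score vectors.
#' @return A list: `mean_target`, `mean_sister`, `p_value`, `n_target`,
#'   `n_sister`, `n_missing`.
#' @export
conservation_shift_test <- function(scores_target, scores_sister) {
  n_missing <- sum(is.na(scores_target)) + sum(is.na(scores_sister))
  x <- scores_target[!is.na(scores_target)]
  y <- scores_sister[!is.na(scores_sister)]
  if (!length(x) || !length(y)) {
    stop("conservation_shift_test needs non-empty score lists")
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y,
                                            alternative = "two.sided"))
  list(mean_target = mean(x), mean_sister = mean(y),
       p_value = wt$p.value, n_target = length(x), n_sister = length(y),
       n_missing = n_missing)
}
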