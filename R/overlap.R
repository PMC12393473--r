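#' Feature sets carrying an evolutionary signature class
#'
#' @param feature_class one of `"HAR"`, `"hCONDEL"`, `"HAQER"`,
#'   `"inversion"`, `"SDR"`, or any custom label.
#' @param intervals an [interval_set].
#' @return An object of class `feature_set`.
#' @export
feature_set <- function(feature_class, intervals) {
  stopifnot(is.character(feature_class), length(feature_class) == 1L)
  structure(list(feature_class = feature_class, intervals = intervals),
            class = "feature_set")
}

as_intervals <- function(x) {
  if (inherits(x, "feature_set")) x$intervals else x
}

#' Count elements overlapped by a feature set
#'
#' An element counts once no matter how many features hit it; 1 bp of
#' overlap suffices.  `count_features_hit()` is the companion tally of
#' distinct features overlapping at least one element.
#'
#' @param element_set an [interval_set].
#' @param features an [interval_set] or [feature_set].
#' @return An integer count.
#' @export
count_overlapping_elements <- function(element_set, features) {
  sum(intersect_count(element_set, as_intervals(features)) > 0L)
}

#' @rdname count_overlapping_elements
#' @export
count_features_hit <- function(element_set, features) {
  sum(intersect_count(as_intervals(features), element_set) > 0L)
}

#' Overlap summary across element sets and feature classes
#'
#' Builds the summary table of regulatory-element overlaps with feature
#' classes: rows are feature classes, columns element sets, entries the
#' number of elements overlapping at least one feature (and, in the
#' companion `features_hit` matrix, the number of distinct features hit).
#'
#' @param element_sets named list of [interval_set]s.
#' @param features list of [feature_set]s.
#' @return A list with two integer matrices, `elements` and
#'   `features_hit` (feature classes x element sets).
#' @export
overlap_report <- function(element_sets, features) {
  classes <- vapply(features, function(f) f$feature_class, "")
  el <- matrix(0L, length(features), length(element_sets),
               dimnames = list(classes, names(element_sets)))
  fh <- el
  for (i in seq_along(features)) {
    for (j in seq_along(element_sets)) {
      el[i, j] <- count_overlapping_elements(element_sets[[j]], features[[i]])
      fh[i, j] <- count_features_hit(element_sets[[j]], features[[i]])
    }
  }
  list(elements = el, features_hit = fh)
}

#' Element counts in windows flanking structural features
#'
#' For each width, builds the two flank windows of every feature
#' ([flank_windows()]), removes any bases falling inside a feature body,
#' and counts the elements overlapping the remaining flank space.
#'
#' @param element_set an [interval_set].
#' @param features an [interval_set] or [feature_set] (e.g. inversions or
#'   structurally divergent regions).
#' @param widths flank widths in bp (default 500 kb and 1 Mb).
#' @param chrom_lengths named vector of chrom lengths.
#' @return Data frame with columns `width` and `n_elements`.
#' @export
flanking_feature_report <- function(element_set, features,
                                    widths = c(5e5, 1e6), chrom_lengths) {
  fx <- as_intervals(features)
  n <- vapply(widths, function(w) {
    fl <- flank_windows(fx, w, chrom_lengths)
    fl <- subtract(fl, fx)
    count_overlapping_elements(element_set, fl)
  }, 0L)
  data.frame(width = widths, n_elements = n)
}

#' Per-gene element counts within extended gene windows
#'
#' Keeps genes whose maximum normalised expression across autopod
#' tissues reaches `min_expression` (inclusive), extends each gene span
#' by `window` bp on both sides (clamped to the chromosome), and counts,
#' per gene and per element set, the elements overlapping the extended
#' span.  Genes absent from the expression table are excluded with a
#' warning.
#'
#' @param gene_spans an [interval_set] with gene ids in `name`.
#' @param element_sets named list of [interval_set]s.
#' @param window extension in bp (default 500 kb).
#' @param min_expression inclusive expression threshold (default 10).
#' @param expression_table data frame with columns `gene`, `expression`.
#' @param chrom_lengths named vector of chrom lengths.
#' @return Data frame: `gene`, then one count column per element set.
#' @export
gene_proximity_counts <- function(gene_spans, element_sets, window = 5e5,
                                  min_expression = 10, expression_table,
                                  chrom_lengths) {
  expr <- expression_table$expression[match(gene_spans$name,
                                            expression_table$gene)]
  missing <- is.na(expr)
  if (any(missing)) {
    warning(sum(missing), " gene(s) absent from expression table, excluded: ",
            paste(utils::head(gene_spans$name[missing], 5L), collapse = ", "))
  }
  keep <- !missing & expr >= min_expression
  g <- gene_spans[keep, , drop = FALSE]
  if (!nrow(g)) {
    out <- data.frame(gene = character(0))
    for (nm in names(element_sets)) out[[nm]] <- integer(0)
    return(out)
  }
  len <- chrom_lengths[g$chrom]
  ext <- interval_set(g$chrom, pmax(0, g$start - window),
                      pmin(len, g$end + window), name = g$name)
  out <- data.frame(gene = ext$name, stringsAsFactors = FALSE)
  for (nm in names(element_sets)) {
    out[[nm]] <- intersect_count(ext, element_sets[[nm]])
  }
  out
}

#' Pearson correlation between paired per-gene counts
#'
#' @param counts_a,counts_b equal-length paired count vectors (n >= 3).
#' @return A list `r`, `p` (two-sided); both `NA` with a `reason` when a
#'   vector has zero variance.
#' @export
correlate_set_counts <- function(counts_a, counts_b) {
  stopifnot(length(counts_a) == length(counts_b), length(counts_a) >= 3L)
  if (stats::sd(counts_a) == 0 || stats::sd(counts_b) == 0) {
    return(list(r = NA_real_, p = NA_real_, reason = "zero_variance"))
  }
  ct <- stats::cor.test(counts_a, counts_b, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Expected number of overlaps with differential regulatory activity
#'
#' Scales an overlap count by an empirically measured differential-
#' activity rate (e.g. one third of tested human accelerated regions, 8%
#' of tested conserved deletions), rounding to the nearest integer, half
#' away from zero.
#'
#' @param n_overlaps non-negative overlap count.
#' @param empirical_rate rate in `[0, 1]`.
#' @return An integer.
#' @examples
#' expected_differential_count(474, 1 / 3)  # 158
#' expected_differential_count(886, 0.08)   # 71
#' @export
expected_differential_count <- function(n_overlaps, empirical_rate) {
  stopifnot(n_overlaps >= 0, empirical_rate >= 0, empirical_rate <= 1)
  as.integer(floor(n_overlaps * empirical_rate + 0.5))
}
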