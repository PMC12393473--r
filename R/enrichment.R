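#' Per-base-pair feature enrichment of an element set
#'
#' The enrichment of a set for a feature class is the number of features
#' overlapping the set (each feature counted once) divided by the number
#' of bases the set covers.  The set is flattened first, so the rate is
#' invariant under splitting elements into abutting fragments.
#'
#' @param element_set an [interval_set].
#' @param features an [interval_set] or [feature_set].
#' @param label optional set label for the cell.
#' @return A list of class `enrichment_cell`: `label`, `feature_class`,
#'   `count`, `bp`, `rate` (`NA` with empty sets).
#' @export
per_bp_rate <- function(element_set, features, label = NULL) {
  fx <- as_intervals(features)
  flat <- flatten(element_set)
  bp <- covered_bp(flat)
  count <- count_features_hit(flat, fx)
  cls <- if (inherits(features, "feature_set")) features$feature_class
         else "custom"
  structure(list(label = label %||% attr(element_set, "label"),
                 feature_class = cls, count = count, bp = bp,
                 rate = if (bp > 0) count / bp else NA_real_),
            class = "enrichment_cell")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Common-variant density of an element set
#'
#' Counts catalog positions with minor-allele frequency strictly above
#' `maf_threshold` falling inside the set, per covered base pair.
#'
#' @param element_set an [interval_set].
#' @param catalog a [variant_catalog].
#' @param maf_threshold strict threshold (default 0.05).
#' @inheritParams per_bp_rate
#' @return An `enrichment_cell`.
#' @export
snp_rate <- function(element_set, catalog, maf_threshold = 0.05,
                     label = NULL) {
  flat <- flatten(element_set)
  bp <- covered_bp(flat)
  common <- catalog[catalog$maf > maf_threshold, , drop = FALSE]
  count <- 0L
  if (nrow(common) && nrow(flat)) {
    snps <- interval_set(common$chrom, common$pos, common$pos + 1)
    count <- sum(intersect_count(snps, flat) > 0L)
  }
  structure(list(label = label %||% attr(element_set, "label"),
                 feature_class = paste0("SNP_", attr(catalog, "species")),
                 count = count, bp = bp,
                 rate = if (bp > 0) count / bp else NA_real_),
            class = "enrichment_cell")
}

#' Compare per-bp enrichment between two element sets
#'
#' Default test: two-sided Fisher's exact test on the 2x2 table
#' `[(count_a, bp_a - count_a), (count_b, bp_b - count_b)]`, treating
#' each covered base as a trial.  The permutation alternative re-assigns
#' the pooled feature count uniformly over the union footprint
#' (equivalently, hypergeometric resampling of the count landing in set
#' A) and compares the observed count to that null.
#'
#' @param cell_a,cell_b `enrichment_cell`s from [per_bp_rate()] or
#'   [snp_rate()].
#' @param method `"fisher"` or `"permutation"`.
#' @param n_perm permutation draws (permutation mode).
#' @param seed RNG seed (permutation mode).
#' @return A list of class `pair_comparison`: `label_a`, `label_b`,
#'   `feature_class`, `ratio` (rate_a / rate_b; `NA` when rate_b is 0),
#'   `p_value`, `test`.
#' @export
compare_pair <- function(cell_a, cell_b, method = c("fisher", "permutation"),
                         n_perm = 10000, seed = 1) {
  method <- match.arg(method)
  a <- cell_a$count; b <- cell_b$count
  bpa <- cell_a$bp; bpb <- cell_b$bp
  stopifnot(bpa > 0, bpb > 0, a <= bpa, b <= bpb)
  ratio <- if (!is.na(cell_b$rate) && cell_b$rate > 0) {
    cell_a$rate / cell_b$rate
  } else {
    NA_real_
  }
  if (method == "fisher") {
    tab <- matrix(c(a, bpa - a, b, bpb - b), nrow = 2, byrow = TRUE)
    p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  } else {
    mu <- (a + b) * bpa / (bpa + bpb)
    sim <- with_local_seed(seed,
                           stats::rhyper(n_perm, bpa, bpb, a + b))
    p <- (sum(abs(sim - mu) >= abs(a - mu)) + 1) / (n_perm + 1)
  }
  structure(list(label_a = cell_a$label, label_b = cell_b$label,
                 feature_class = cell_a$feature_class, ratio = ratio,
                 p_value = p, test = method),
            class = "pair_comparison")
}

#' Enrichment matrix across sets and signals
#'
#' @param element_sets named list of [interval_set]s.
#' @param signals named list of [feature_set]s and/or [variant_catalog]s.
#' @param maf_threshold threshold for catalog signals.
#' @return Numeric matrix of per-bp rates (signals x sets).
#' @export
enrichment_matrix <- function(element_sets, signals, maf_threshold = 0.05) {
  out <- matrix(NA_real_, length(signals), length(element_sets),
                dimnames = list(names(signals), names(element_sets)))
  for (i in seq_along(signals)) {
    for (j in seq_along(element_sets)) {
      cell <- if (inherits(signals[[i]], "variant_catalog")) {
        snp_rate(element_sets[[j]], signals[[i]], maf_threshold)
      } else {
        per_bp_rate(element_sets[[j]], signals[[i]])
      }
      out[i, j] <- cell$rate
    }
  }
  out
}
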