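#' Element-by-condition accessibility atlas
#'
#' Couples a master element universe (one merged peak list shared by all
#' conditions) with a boolean accessibility matrix over condition labels.
#' Every element must be accessible in at least one condition.
#'
#' @param elements an [interval_set] of regulatory elements (names used
#'   as row ids).
#' @param conditions character vector of condition labels; autopod labels
#'   follow `limb.digit.region.timepoint`.
#' @param matrix logical matrix, `nrow(elements)` x `length(conditions)`.
#' @return An object of class `accessibility_atlas`.
#' @export
accessibility_atlas <- function(elements, conditions, matrix) {
  matrix <- as.matrix(matrix)
  mode(matrix) <- "logical"
  if (nrow(matrix) != nrow(elements) || ncol(matrix) != length(conditions)) {
    stop("matrix dimensions must match elements x conditions")
  }
  if (nrow(matrix) && any(rowSums(matrix) == 0L)) {
    stop("every element must be accessible in at least one condition")
  }
  dimnames(matrix) <- list(elements$name, conditions)
  structure(list(elements = elements, conditions = conditions,
                 matrix = matrix),
            class = "accessibility_atlas")
}

#' @export
print.accessibility_atlas <- function(x, ...) {
  cat(sprintf("accessibility_atlas: %d elements x %d conditions\n",
              nrow(x$elements), length(x$conditions)))
  invisible(x)
}

#' @rdname accessibility_atlas
#' @param atlas an `accessibility_atlas`.
#' @param keep logical or integer index of elements to retain.
#' @export
subset_atlas <- function(atlas, keep) {
  els <- atlas$elements[keep, , drop = FALSE]
  els <- interval_set(els$chrom, els$start, els$end, name = els$name,
                      strand = els$strand,
                      label = attr(atlas$elements, "label"))
  accessibility_atlas(els, atlas$conditions,
                      atlas$matrix[keep, , drop = FALSE])
}

#' Serialise an atlas as BED plus a TSV accessibility matrix
#'
#' @param atlas an [accessibility_atlas].
#' @param bed_path,matrix_path output paths.
#' @export
write_atlas <- function(atlas, bed_path, matrix_path) {
  write_bed(atlas$elements, bed_path)
  tab <- data.frame(element = rownames(atlas$matrix),
                    atlas$matrix * 1L, check.names = FALSE)
  utils::write.table(tab, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(bed_path, matrix_path) {
  els <- read_bed(bed_path)
  tab <- utils::read.table(matrix_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE]) == 1
  if (!identical(els$name, tab$element)) {
    # align on names
    m <- m[match(els$name, tab$element), , drop = FALSE]
  }
  accessibility_atlas(els, colnames(m), m)
}

#' Remove elements also accessible in embryonic brain
#'
#' Drops every element overlapping a brain peak by at least 1 bp — whole
#' elements, not just the overlapping bases — to exclude regulatory
#' regions likely tied to general housekeeping activity.
#'
#' @param atlas an [accessibility_atlas].
#' @param brain_set an [interval_set] of brain-accessible peaks.
#' @return The filtered atlas.
#' @export
brain_filter <- function(atlas, brain_set) {
  if (nrow(brain_set) == 0L || nrow(atlas$elements) == 0L) return(atlas)
  hit <- intersect_count(atlas$elements, brain_set) > 0L
  subset_atlas(atlas, !hit)
}

#' Classify elements by accessibility specificity
#'
#' Two independent classifications per element: `autopod_specific` — no
#' overlap with any other developing-skeleton peak set (long-bone ends,
#' scapula, pelvis, vertebrae); and `tissue_and_timepoint_specific` —
#' accessible in exactly one tissue, where a tissue is a
#' (limb, digit, region) combination and accessibility at one or both
#' timepoints of that tissue counts once.  `shared_with_skeleton` is the
#' complement of `autopod_specific`.
#'
#' @param atlas an [accessibility_atlas] with parseable autopod condition
#'   labels.
#' @param other_skeleton_sets list of [interval_set]s from other skeletal
#'   tissues (possibly empty).
#' @return Data frame with columns `element`, `autopod_specific`,
#'   `shared_with_skeleton`, `tissue_and_timepoint_specific`.
#' @export
classify_specificity <- function(atlas, other_skeleton_sets = list()) {
  n <- nrow(atlas$elements)
  shared <- rep(FALSE, n)
  for (s in other_skeleton_sets) {
    if (nrow(s)) shared <- shared | intersect_count(atlas$elements, s) > 0L
  }
  meta <- condition_meta(atlas$conditions)
  tiss <- meta$tissue
  n_tissues <- apply(atlas$matrix, 1L, function(row) {
    length(unique(tiss[row]))
  })
  data.frame(element = atlas$elements$name,
             autopod_specific = !shared,
             shared_with_skeleton = shared,
             tissue_and_timepoint_specific = n_tissues == 1L,
             stringsAsFactors = FALSE)
}

#' Partition elements along an anatomical axis
#'
#' Splits an atlas (normally restricted to autopod-specific elements)
#' into three disjoint subsets along one axis: for `axis = "limb"`,
#' hand-only (accessible in at least one hand condition and no foot
#' condition), foot-only, and shared; analogously for
#' `axis = "region"` (phalanges vs metapodial) and `axis = "timepoint"`
#' (early vs late).
#'
#' @param atlas an [accessibility_atlas].
#' @param axis one of `"limb"`, `"region"`, `"timepoint"`.
#' @return A list of class `partition_result`: `axis`, `levels`, and
#'   `subsets` — three [interval_set]s named `<A>_only`, `<B>_only`,
#'   `shared`, a disjoint cover of the input elements.
#' @export
partition_by_axis <- function(atlas, axis) {
  levels <- switch(axis,
                   limb = c("hand", "foot"),
                   region = c("phalanges", "metapodial"),
                   timepoint = c("early", "late"),
                   stop("unknown axis: ", axis))
  meta <- condition_meta(atlas$conditions)
  fac <- meta[[axis]]
  in_a <- atlas$matrix[, fac == levels[1], drop = FALSE]
  in_b <- atlas$matrix[, fac == levels[2], drop = FALSE]
  has_a <- rowSums(in_a) > 0L
  has_b <- rowSums(in_b) > 0L
  pick <- function(keep) {
    els <- atlas$elements[keep, , drop = FALSE]
    interval_set(els$chrom, els$start, els$end, name = els$name,
                 strand = els$strand)
  }
  subsets <- list(pick(has_a & !has_b), pick(!has_a & has_b),
                  pick(has_a & has_b))
  names(subsets) <- c(paste0(levels[1], "_only"),
                      paste0(levels[2], "_only"), "shared")
  stopifnot(sum(vapply(subsets, nrow, 0L)) == nrow(atlas$elements))
  structure(list(axis = axis, levels = levels, subsets = subsets),
            class = "partition_result")
}

#' Timepoint sharing profile of condition combinations
#'
#' Groups elements by their exact condition combination, drops
#' combinations carried by fewer than `min_combination_size` elements
#' (default 5), and tallies the remaining elements by the number of
#' distinct tissues accessible at the early and at the late timepoint.
#'
#' @param atlas an [accessibility_atlas].
#' @param min_combination_size minimum elements per combination (>= 1).
#' @return Data frame with columns `n_early`, `n_late`, `n_elements`,
#'   one row per occupied cell.
#' @export
sharing_profile <- function(atlas, min_combination_size = 5) {
  stopifnot(min_combination_size >= 1)
  meta <- condition_meta(atlas$conditions)
  key <- apply(atlas$matrix, 1L, function(row) {
    paste(atlas$conditions[row], collapse = ";")
  })
  sizes <- table(key)
  keep <- key %in% names(sizes)[sizes >= min_combination_size]
  if (!any(keep)) {
    return(data.frame(n_early = integer(0), n_late = integer(0),
                      n_elements = integer(0)))
  }
  m <- atlas$matrix[keep, , drop = FALSE]
  n_early <- apply(m, 1L, function(row) {
    length(unique(meta$tissue[row & meta$timepoint == "early"]))
  })
  n_late <- apply(m, 1L, function(row) {
    length(unique(meta$tissue[row & meta$timepoint == "late"]))
  })
  agg <- stats::aggregate(list(n_elements = rep(1L, sum(keep))),
                          by = list(n_early = n_early, n_late = n_late),
                          FUN = sum)
  agg[order(agg$n_early, agg$n_late), , drop = FALSE]
}

#' Elements shared with another species
#'
#' Counts atlas elements overlapped (>= 1 bp) by a set of intervals
#' lifted from another species.  The lifted set is expected to come from
#' [liftover_set()] with multiple matches allowed and `min_match = 0.1`.
#'
#' @param atlas an [accessibility_atlas].
#' @param lifted_set an [interval_set] on the atlas assembly.
#' @param autopod_specific optional logical vector (e.g. from
#'   [classify_specificity()]) restricting a second tally.
#' @return A list: `n_shared`, `fraction`, and when `autopod_specific`
#'   is given, `n_shared_specific`, `fraction_specific`.
#' @export
cross_species_shared <- function(atlas, lifted_set,
                                 autopod_specific = NULL) {
  hit <- intersect_count(atlas$elements, lifted_set) > 0L
  out <- list(n_shared = sum(hit),
              fraction = if (length(hit)) mean(hit) else NA_real_)
  if (!is.null(autopod_specific)) {
    sel <- hit[autopod_specific]
    out$n_shared_specific <- sum(sel)
    out$fraction_specific <- if (length(sel)) mean(sel) else NA_real_
  }
  out
}
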