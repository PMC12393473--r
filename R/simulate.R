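#' @keywords internal
with_local_seed <- function(seed, code) {
  force(seed) # before saving state: the caller may draw the seed itself
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

BASES <- c("A", "C", "G", "T")

#' Per-species catalog of polymorphic sites
#'
#' Records common and rare single-nucleotide polymorphisms with their
#' minor-allele frequencies (MAF, in `[0, 0.5]`), on the coordinates of
#' the pipeline's target assembly.
#'
#' @param species species label.
#' @param chrom,pos,maf parallel vectors: sequence name, 0-based position,
#'   minor-allele frequency.
#' @return An object of class `variant_catalog` (a data frame).
#' @export
variant_catalog <- function(species, chrom = character(),
                            pos = numeric(), maf = numeric()) {
  x <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                  maf = as.numeric(maf), stringsAsFactors = FALSE)
  if (any(x$maf < 0 | x$maf > 0.5)) stop("MAF must lie in [0, 0.5]")
  if (anyDuplicated(x[c("chrom", "pos")])) {
    stop("duplicate positions in variant catalog")
  }
  x <- x[order(x$chrom, x$pos), , drop = FALSE]
  rownames(x) <- NULL
  attr(x, "species") <- species
  class(x) <- c("variant_catalog", "data.frame")
  x
}

#' @rdname variant_catalog
#' @param path tab-separated file with columns `species`, `chrom`, `pos`,
#'   `maf`.
#' @export
read_variant_catalog <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  variant_catalog(tab$species[1], tab$chrom, tab$pos, tab$maf)
}

#' @rdname variant_catalog
#' @param x a `variant_catalog`.
#' @export
write_variant_catalog <- function(x, path) {
  out <- data.frame(species = attr(x, "species"), chrom = x$chrom,
                    pos = format_coord(x$pos), maf = x$maf)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Parameters for a three-species genome simulation
#'
#' Describes the stated world of a target/sister/outgroup trio: a single
#' ancestral chromosome, lineage-specific fixed substitutions planted on
#' the target and sister branches, per-species polymorphic sites with
#' minor-allele frequencies, and deletion blocks in the sister and
#' outgroup that create liftover gaps.
#'
#' @param chrom_length chromosome length in bp.
#' @param n_target_fixed,n_sister_fixed counts of fixed substitutions
#'   planted on the target and sister lineages (placed at distinct
#'   positions, disjoint between lineages so the planted truth is
#'   identifiable).
#' @param n_polymorphic polymorphic sites per species; MAF drawn
#'   uniformly on (0, 0.5), so roughly 90% are common (MAF > 0.05).
#'   Polymorphic sites may coincide with planted fixed substitutions;
#'   masking has to resolve the collision.
#' @param indel_blocks list of `c(position, length)` deletions applied to
#'   both sister and outgroup, excluded from the chains.
#' @param blacklist optional [interval_set] of blacklist regions (target
#'   coordinates); default empty.
#' @param chrom chromosome name shared by the three assemblies.
#' @param seed RNG seed; identical seeds give byte-identical output.
#' @return A `trio_sim_params` list.
#' @export
trio_sim_params <- function(chrom_length = 1e6, n_target_fixed = 200,
                            n_sister_fixed = 150, n_polymorphic = 100,
                            indel_blocks = list(), blacklist = NULL,
                            chrom = "chrS", seed = 1) {
  if (n_target_fixed + n_sister_fixed > chrom_length) {
    stop("more planted substitutions than positions")
  }
  if (length(indel_blocks)) {
    for (blk in indel_blocks) {
      if (blk[1] < 0 || blk[1] + blk[2] > chrom_length) {
        stop("indel block outside chromosome")
      }
    }
  }
  structure(list(chrom_length = chrom_length,
                 n_target_fixed = n_target_fixed,
                 n_sister_fixed = n_sister_fixed,
                 n_polymorphic = n_polymorphic,
                 indel_blocks = indel_blocks,
                 blacklist = if (is.null(blacklist)) interval_set()
                             else blacklist,
                 chrom = chrom, seed = seed),
            class = "trio_sim_params")
}

#' Simulate a target/sister/outgroup genome trio with planted truth
#'
#' Draws a uniform-ACGT ancestor and derives three genomes from it: each
#' planted target-lineage substitution changes the target base to a
#' different nucleotide while sister and outgroup keep the ancestral
#' state, and symmetrically for the sister lineage.  Deletion blocks are
#' removed from the sister and outgroup sequences and excluded from the
#' chains, creating unmappable gaps.  Polymorphic sites are recorded per
#' species with their drawn frequencies (all reported on target
#' coordinates, as after lifting real catalogs to the target assembly);
#' sister/outgroup sites are only placed at positions surviving deletion.
#'
#' @param params a [trio_sim_params].
#' @return A list with `target`, `sister`, `outgroup` ([genome]s),
#'   `chain_sister`, `chain_outgroup` ([chain_map]s from target
#'   coordinates), `catalogs` (named list of [variant_catalog]s),
#'   `blacklist`, and `truth` — the truth table with
#'   `target_fixed`/`sister_fixed` positions, per-species polymorphism
#'   tables and `unmappable` deletion blocks.
#' @export
simulate_trio <- function(params) {
  stopifnot(inherits(params, "trio_sim_params"))
  with_local_seed(params$seed, {
    L <- params$chrom_length
    chrom <- params$chrom
    anc <- sample(BASES, L, replace = TRUE)
    n_fix <- params$n_target_fixed + params$n_sister_fixed
    fixed_pos <- if (n_fix > 0) sort(sample.int(L, n_fix) - 1L) else integer(0)
    pick <- if (n_fix > 0) sample(n_fix) else integer(0)
    target_pos <- sort(fixed_pos[pick[seq_len(params$n_target_fixed)]])
    sister_pos <- sort(setdiff(fixed_pos, target_pos))

    mutate <- function(seq, pos) {
      for (p in pos) {
        seq[p + 1] <- sample(setdiff(BASES, seq[p + 1]), 1L)
      }
      seq
    }
    target_seq <- mutate(anc, target_pos)
    sister_full <- mutate(anc, sister_pos)
    outgroup_full <- anc

    # deletions in sister/outgroup -> chain gaps
    del <- interval_set()
    if (length(params$indel_blocks)) {
      del <- flatten(interval_set(
        chrom = chrom,
        start = vapply(params$indel_blocks, `[`, 0, 1L),
        end = vapply(params$indel_blocks, function(b) b[1] + b[2], 0)))
    }
    keep_mask <- rep(TRUE, L)
    if (nrow(del)) {
      for (i in seq_len(nrow(del))) {
        keep_mask[(del$start[i] + 1):del$end[i]] <- FALSE
      }
    }
    sister_seq <- sister_full[keep_mask]
    outgroup_seq <- outgroup_full[keep_mask]

    # chain: complement of deletions, target offsets shifted by cumulative
    # deleted bases; one colinear run per assembly pair
    kept <- interval_set(chrom, 0, L)
    if (nrow(del)) kept <- subtract(kept, del)
    shift <- cumsum(c(0, (kept$end - kept$start)))[seq_len(nrow(kept))]
    blocks <- data.frame(chain_id = "1", s_chrom = chrom,
                         s_start = kept$start, s_end = kept$end,
                         t_chrom = chrom, t_start = shift,
                         t_end = shift + (kept$end - kept$start),
                         t_strand = "+", stringsAsFactors = FALSE)
    chain_sister <- chain_map(blocks, name = "target->sister")
    chain_outgroup <- chain_map(blocks, name = "target->outgroup")

    draw_catalog <- function(species, surviving_only) {
      n <- params$n_polymorphic
      if (n == 0L) {
        return(variant_catalog(species))
      }
      pool <- if (surviving_only) which(keep_mask) - 1L else seq_len(L) - 1L
      pos <- sort(sample(pool, min(n, length(pool))))
      variant_catalog(species, chrom = chrom, pos = pos,
                      maf = round(stats::runif(length(pos), 0, 0.5), 4))
    }
    catalogs <- list(target = draw_catalog("target", FALSE),
                     sister = draw_catalog("sister", TRUE),
                     outgroup = draw_catalog("outgroup", TRUE))

    truth <- list(
      target_fixed = target_pos, sister_fixed = sister_pos,
      polymorphic = lapply(catalogs, function(cat) {
        data.frame(pos = cat$pos, maf = cat$maf)
      }),
      unmappable = del)

    list(target = genome(stats::setNames(paste(target_seq, collapse = ""),
                                         chrom)),
         sister = genome(stats::setNames(paste(sister_seq, collapse = ""),
                                         chrom)),
         outgroup = genome(stats::setNames(paste(outgroup_seq,
                                                 collapse = ""), chrom)),
         chain_sister = chain_sister, chain_outgroup = chain_outgroup,
         catalogs = catalogs, blacklist = params$blacklist, truth = truth)
  })
}

#' Write a simulated trio to standard formats
#'
#' Emits FASTA for the three genomes, the chains in both the UCSC and TSV
#' dialects, TSV variant catalogs, a BED blacklist and a JSON truth table.
#'
#' @param sim result of [simulate_trio()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
write_trio <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_fasta(sim$target, p("target.fa"))
  write_fasta(sim$sister, p("sister.fa"))
  write_fasta(sim$outgroup, p("outgroup.fa"))
  write_chain(sim$chain_sister, p("target_sister.tsv"), dialect = "tsv")
  write_chain(sim$chain_outgroup, p("target_outgroup.tsv"), dialect = "tsv")
  write_chain(sim$chain_sister, p("target_sister.chain"), dialect = "ucsc",
              s_sizes = seq_lengths(sim$target),
              t_sizes = seq_lengths(sim$sister))
  write_chain(sim$chain_outgroup, p("target_outgroup.chain"),
              dialect = "ucsc", s_sizes = seq_lengths(sim$target),
              t_sizes = seq_lengths(sim$outgroup))
  for (sp in names(sim$catalogs)) {
    write_variant_catalog(sim$catalogs[[sp]], p(paste0("snps_", sp, ".tsv")))
  }
  write_bed(sim$blacklist, p("blacklist.bed"))
  jsonlite::write_json(sim$truth[c("target_fixed", "sister_fixed")],
                       p("truth.json"))
  invisible(vapply(list.files(dir, full.names = TRUE), identity, ""))
}

#' The autopod condition grid
#'
#' The full design is 2 limbs (hand, foot) x 5 digits (I..V) x 2
#' proximal-distal regions (phalanges, metapodial) = 20 tissues, each at
#' an early and a late developmental timepoint: 40 conditions, labelled
#' `limb.digit.region.timepoint`.
#'
#' @return Character vector of 40 condition labels.
#' @export
autopod_conditions <- function() {
  g <- expand.grid(limb = c("hand", "foot"),
                   digit = c("I", "II", "III", "IV", "V"),
                   region = c("phalanges", "metapodial"),
                   timepoint = c("early", "late"),
                   stringsAsFactors = FALSE)
  paste(g$limb, g$digit, g$region, g$timepoint, sep = ".")
}

#' Parse condition labels into their anatomical factors
#'
#' @param labels condition labels of the form `limb.digit.region.timepoint`.
#' @return Data frame with columns `limb`, `digit`, `region`, `timepoint`,
#'   `tissue` (limb.digit.region, collapsing timepoint).
#' @export
condition_meta <- function(labels) {
  parts <- strsplit(labels, ".", fixed = TRUE)
  if (any(lengths(parts) != 4L)) {
    stop("condition labels must be limb.digit.region.timepoint")
  }
  m <- do.call(rbind, parts)
  data.frame(label = labels, limb = m[, 1], digit = m[, 2], region = m[, 3],
             timepoint = m[, 4],
             tissue = paste(m[, 1], m[, 2], m[, 3], sep = "."),
             stringsAsFactors = FALSE)
}

#' Default accessibility sharing structure
#'
#' A mixture over condition combinations emulating the qualitative
#' structure of developing-skeleton accessibility atlases: a broadly
#' accessible core, limb-, region- and timepoint-restricted blocks, and a
#' tail of single-tissue-specific elements.
#'
#' @param conditions condition labels (default [autopod_conditions()]).
#' @return A list of `list(combination = <labels>, prob = <weight>)`
#'   entries with weights summing to 1.
#' @export
default_sharing_spec <- function(conditions = autopod_conditions()) {
  meta <- condition_meta(conditions)
  pickc <- function(sel) conditions[sel]
  list(
    list(combination = conditions, prob = 0.30),
    list(combination = pickc(meta$limb == "hand"), prob = 0.10),
    list(combination = pickc(meta$limb == "foot"), prob = 0.10),
    list(combination = pickc(meta$region == "phalanges"), prob = 0.10),
    list(combination = pickc(meta$region == "metapodial"), prob = 0.05),
    list(combination = pickc(meta$timepoint == "early"), prob = 0.10),
    list(combination = pickc(meta$timepoint == "late"), prob = 0.05),
    list(combination = pickc(meta$tissue == "hand.I.phalanges"),
         prob = 0.10),
    list(combination = pickc(meta$tissue == "foot.V.metapodial"),
         prob = 0.10))
}

#' Simulate an element-by-condition accessibility atlas
#'
#' Places `n_elements` non-overlapping elements (default 500 bp, so
#' length standardisation is the identity in clean tests) on one
#' chromosome and draws each element's condition combination from
#' `sharing_spec`.
#'
#' @param n_elements number of regulatory elements.
#' @param conditions condition labels (default the 40-condition autopod
#'   grid).
#' @param sharing_spec list of `list(combination, prob)`; probabilities
#'   must sum to 1 and every combination must be a non-empty subset of
#'   `conditions`.
#' @param seed RNG seed.
#' @param element_length,gap element size and spacing in bp.
#' @param chrom chromosome name.
#' @return A list with `atlas` (an [accessibility_atlas]) and
#'   `combo_index` — the index into `sharing_spec` drawn for each element
#'   (the planted truth).
#' @export
simulate_atlas <- function(n_elements, conditions = autopod_conditions(),
                           sharing_spec = default_sharing_spec(conditions),
                           seed = 1, element_length = 500, gap = 100,
                           chrom = "chrA") {
  probs <- vapply(sharing_spec, function(s) s$prob, 0)
  if (abs(sum(probs) - 1) > 1e-8) stop("sharing_spec weights must sum to 1")
  for (s in sharing_spec) {
    if (!length(s$combination) || !all(s$combination %in% conditions)) {
      stop("sharing_spec combination not a subset of conditions")
    }
  }
  with_local_seed(seed, {
    starts <- (seq_len(n_elements) - 1L) * (element_length + gap)
    els <- interval_set(chrom, starts, starts + element_length,
                        name = sprintf("el_%05d", seq_len(n_elements)),
                        label = "elements")
    combo <- sample.int(length(sharing_spec), n_elements, replace = TRUE,
                        prob = probs)
    mat <- matrix(FALSE, n_elements, length(conditions),
                  dimnames = list(els$name, conditions))
    for (k in seq_along(sharing_spec)) {
      mat[combo == k, conditions %in% sharing_spec[[k]]$combination] <- TRUE
    }
    list(atlas = accessibility_atlas(els, conditions, mat),
         combo_index = combo)
  })
}

#' Simulate a conservation score track with a planted shift
#'
#' Background positions score `N(baseline, noise_sd)`; constrained
#' positions score `N(baseline + shift, noise_sd)`.
#'
#' @param positions_constrained 0-based positions carrying the shift.
#' @param shift mean shift at constrained positions.
#' @param noise_sd score standard deviation (> 0).
#' @param seed RNG seed.
#' @param chrom chromosome name.
#' @param background_positions 0-based background positions; default all
#'   positions from 0 to `max(positions_constrained, 999)` not in the
#'   constrained set.
#' @param baseline background mean (default 0).
#' @return A [score_track] with one 1-bp run per scored position.
#' @export
simulate_score_track <- function(positions_constrained, shift, noise_sd,
                                 seed = 1, chrom = "chrS",
                                 background_positions = NULL,
                                 baseline = 0) {
  stopifnot(noise_sd > 0)
  if (is.null(background_positions)) {
    hi <- max(c(positions_constrained, 999))
    background_positions <- setdiff(0:hi, positions_constrained)
  }
  with_local_seed(seed, {
    pos <- c(background_positions, positions_constrained)
    mu <- c(rep(baseline, length(background_positions)),
            rep(baseline + shift, length(positions_constrained)))
    sc <- stats::rnorm(length(pos), mu, noise_sd)
    o <- order(pos)
    score_track(chrom = rep(chrom, length(pos)), start = pos[o],
                end = pos[o] + 1, score = sc[o])
  })
}

#' Simulate a skeletal measurement table with planted proportions
#'
#' Draws per-individual bone measurements for three species with
#' species-specific stratum means, so interspecific percent changes are
#' known by construction: relative to the reference species, the
#' numerator species' mean in each stratum is scaled by the planted
#' factor.
#'
#' @param n_per_species individuals per species (default 10).
#' @param species species labels; the first is the reference.
#' @param scale named list per non-reference species: either a single
#'   factor applied to all strata or a function(limb, digit, element,
#'   dimension) returning the factor.
#' @param cv coefficient of variation of individual measurements.
#' @param seed RNG seed.
#' @return A [measurement_table].
#' @export
simulate_measurements <- function(n_per_species = 10,
                                  species = c("chimpanzee", "human",
                                              "gorilla"),
                                  scale = list(human = 0.85,
                                               gorilla = 1.1),
                                  cv = 0.05, seed = 1) {
  strata <- expand.grid(limb = c("hand", "foot"),
                        digit = c("I", "II", "III", "IV", "V"),
                        element = c("metapodial", "proximal_phalanx",
                                    "middle_phalanx"),
                        dimension = c("length", "width"),
                        stringsAsFactors = FALSE)
  strata <- strata[!(strata$digit == "I" &
                       strata$element == "middle_phalanx"), , drop = FALSE]
  base <- ifelse(strata$dimension == "length", 40, 10)
  with_local_seed(seed, {
    rows <- list()
    for (sp in species) {
      fac <- if (sp == species[1]) 1 else scale[[sp]]
      for (k in seq_len(nrow(strata))) {
        f <- if (is.function(fac)) {
          fac(strata$limb[k], strata$digit[k], strata$element[k],
              strata$dimension[k])
        } else {
          fac
        }
        mu <- base[k] * f
        rows[[length(rows) + 1L]] <- data.frame(
          species = sp,
          individual = paste0(sp, "_", seq_len(n_per_species)),
          element = strata$element[k], digit = strata$digit[k],
          limb = strata$limb[k], dimension = strata$dimension[k],
          value = pmax(0.1, stats::rnorm(n_per_species, mu, cv * mu)),
          stringsAsFactors = FALSE)
      }
    }
    tab <- do.call(rbind, rows)
    measurement_table(tab$species, tab$individual, tab$element, tab$digit,
                      tab$limb, tab$dimension, tab$value)
  })
}
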