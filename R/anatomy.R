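#' Skeletal measurement tables
#'
#' One row per measured bone dimension: species, individual, skeletal
#' element (`metapodial`, `proximal_phalanx`, `middle_phalanx` — or
#' `phalanges` once pooled), digit I-V, limb, dimension (`length` or
#' `width`) and the value in mm (> 0).
#'
#' @param species,individual,element,digit,limb,dimension,value parallel
#'   vectors; see Details.
#' @return An object of class `measurement_table` (a data frame).
#' @export
measurement_table <- function(species, individual, element, digit, limb,
                              dimension, value) {
  x <- data.frame(species = as.character(species),
                  individual = as.character(individual),
                  element = as.character(element),
                  digit = as.character(digit),
                  limb = as.character(limb),
                  dimension = as.character(dimension),
                  value = as.numeric(value), stringsAsFactors = FALSE)
  if (any(!is.finite(x$value) | x$value <= 0)) {
    stop("measurement values must be positive")
  }
  if (any(!x$limb %in% c("hand", "foot"))) stop("limb must be hand or foot")
  if (any(!x$digit %in% c("I", "II", "III", "IV", "V"))) {
    stop("digit must be I..V")
  }
  class(x) <- c("measurement_table", "data.frame")
  x
}

#' @rdname measurement_table
#' @param path CSV file with the `measurement_table` columns.
#' @export
read_measurements <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  measurement_table(tab$species, tab$individual, tab$element, tab$digit,
                    tab$limb, tab$dimension, tab$value)
}

#' Pool proximal and middle phalanx measurements per digit
#'
#' Raw proximal- and middle-phalanx records of a digit are pooled into a
#' single `phalanges` stratum before averaging (digit I, which has no
#' middle phalanx, passes through with its proximal records only).
#'
#' @param table a [measurement_table].
#' @return A `measurement_table` with `proximal_phalanx` /
#'   `middle_phalanx` rows relabelled `phalanges`.
#' @export
combine_phalanges <- function(table) {
  phal <- table$element %in% c("proximal_phalanx", "middle_phalanx")
  table$element[phal] <- "phalanges"
  table
}

#' Interspecific percent change in skeletal proportions
#'
#' For every (limb, digit, element, dimension) stratum, the percent
#' change is `mean(values of species_num) / mean(values of species_den)
#' * 100`; 100 means identical mean size, values below 100 a smaller
#' numerator species.
#'
#' @param table a [measurement_table] (normally after
#'   [combine_phalanges()]).
#' @param species_num,species_den numerator and denominator species
#'   labels.
#' @return Data frame with columns `limb`, `digit`, `element`,
#'   `dimension`, `mean_num`, `mean_den`, `percent` (`NA` where either
#'   species has no records in the stratum).
#' @export
percent_change <- function(table, species_num, species_den) {
  strata <- unique(table[c("limb", "digit", "element", "dimension")])
  strata <- strata[order(strata$limb, strata$digit, strata$element,
                         strata$dimension), , drop = FALSE]
  rownames(strata) <- NULL
  res <- strata
  res$mean_num <- NA_real_
  res$mean_den <- NA_real_
  res$percent <- NA_real_
  for (i in seq_len(nrow(strata))) {
    sel <- table$limb == strata$limb[i] & table$digit == strata$digit[i] &
      table$element == strata$element[i] &
      table$dimension == strata$dimension[i]
    vn <- table$value[sel & table$species == species_num]
    vd <- table$value[sel & table$species == species_den]
    if (length(vn) && length(vd)) {
      res$mean_num[i] <- mean(vn)
      res$mean_den[i] <- mean(vd)
      res$percent[i] <- res$mean_num[i] / res$mean_den[i] * 100
    }
  }
  res
}
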