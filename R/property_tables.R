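#' Construct a physicochemical property grouping
#'
#' A grouping partitions the 20 canonical amino acids into three classes for
#' one physicochemical property (the basis of the CTD encoding). All 20 amino
#' acids must be mapped and every class index in 1..3 must be used.
#'
#' @param property_name name of the property.
#' @param class_of named integer vector: amino acid -> class index in 1..3.
#' @return A list of class `property_grouping`.
#' @export
#' @examples
#' g <- property_grouping("toy",
#'   setNames(c(rep(1L, 10), rep(2L, 5), rep(3L, 5)),
#'            c("A","C","D","E","F","G","H","I","K","L",
#'              "M","N","P","Q","R","S","T","V","W","Y")))
property_grouping <- function(property_name, class_of) {
  class_of <- setNames(as.integer(class_of), names(class_of))
  missing <- setdiff(AA_ALPHABET, names(class_of))
  if (length(missing) > 0L)
    stopf("grouping '%s' does not map amino acid(s): %s",
          property_name, paste(missing, collapse = " "))
  class_of <- class_of[AA_ALPHABET]
  if (!all(class_of %in% 1:3))
    stopf("grouping '%s' has class indices outside 1..3", property_name)
  if (!all(1:3 %in% class_of))
    stopf("grouping '%s' leaves a class in 1..3 unused", property_name)
  structure(list(property_name = property_name, class_of = class_of),
            class = "property_grouping")
}

#' Construct an amino-acid index (property scale)
#'
#' A scale assigns a real value to each of the 20 canonical amino acids; it is
#' the input of the Moreau-Broto autocorrelation and pseudo-amino-acid
#' composition blocks. [normalize_scale()] centres the 20 values to mean 0 and
#' scales them to unit (population) standard deviation.
#'
#' @param property_name name of the index.
#' @param value_of named numeric vector: amino acid -> value; all finite.
#' @return A list of class `property_scale`.
#' @export
property_scale <- function(property_name, value_of) {
  value_of <- setNames(as.numeric(value_of), names(value_of))
  missing <- setdiff(AA_ALPHABET, names(value_of))
  if (length(missing) > 0L)
    stopf("scale '%s' does not cover amino acid(s): %s",
          property_name, paste(missing, collapse = " "))
  value_of <- value_of[AA_ALPHABET]
  if (!all(is.finite(value_of)))
    stopf("scale '%s' has non-finite values", property_name)
  structure(list(property_name = property_name, value_of = value_of),
            class = "property_scale")
}

#' @rdname property_scale
#' @param scale a `property_scale`.
#' @export
normalize_scale <- function(scale) {
  v <- scale$value_of
  mu <- mean(v)
  s <- sqrt(mean((v - mu)^2))  # population sd over the 20 values
  if (s == 0) {
    scale$value_of[] <- 0
  } else {
    scale$value_of <- (v - mu) / s
  }
  scale
}

read_grouping_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  split_tab <- split(tab, tab$property_name)
  out <- lapply(names(split_tab), function(p) {
    rows <- split_tab[[p]]
    property_grouping(p, setNames(rows$class_index, rows$amino_acid))
  })
  setNames(out, names(split_tab))
}

read_scale_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  split_tab <- split(tab, tab$property_name)
  out <- lapply(names(split_tab), function(p) {
    rows <- split_tab[[p]]
    property_scale(p, setNames(rows$value, rows$amino_acid))
  })
  setNames(out, names(split_tab))
}

# fixed display order of the 12 grouped properties
GROUPED_PROPERTY_ORDER <- c(
  "polarity", "hydrophobicity", "surface_tension", "charge",
  "normalized_vdw_volume", "polarizability", "secondary_structure",
  "solvent_accessibility", "molecular_weight", "solubility",
  "hbond_donor", "hbond_acceptor")

#' Packaged physicochemical property tables
#'
#' `default_groupings()` returns the 12 shipped three-class groupings
#' (polarity, hydrophobicity, surface tension, charge, normalized van der
#' Waals volume, polarizability, secondary-structure propensity, solvent
#' accessibility, molecular weight, solubility, and side-chain hydrogen-bond
#' donor/acceptor counts). `default_scales()` returns the shipped amino-acid
#' indices (Kyte-Doolittle hydrophobicity, Hopp-Woods hydrophilicity, residue
#' molecular weight). Both are loaded from editable TSV files under
#' `inst/extdata`, so alternative class assignments can be supplied by pointing
#' [descriptor_config()] at a different table.
#'
#' @return A named list of [property_grouping] / [property_scale] objects.
#' @export
default_groupings <- function() {
  path <- system.file("extdata", "property_groupings.tsv", package = "profam",
                      mustWork = TRUE)
  g <- read_grouping_table(path)
  g[GROUPED_PROPERTY_ORDER]
}

#' @rdname default_groupings
#' @export
default_scales <- function() {
  path <- system.file("extdata", "property_scales.tsv", package = "profam",
                      mustWork = TRUE)
  read_scale_table(path)
}
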