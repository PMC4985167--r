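# Descriptor blocks: amino-acid composition, CTD over three-class property
# groupings, Moreau-Broto autocorrelation, pseudo-amino-acid composition.

as_residues <- function(x) {
  if (inherits(x, "protein_set")) {
    if (nrow(x) != 1L) stopf("expected a single sequence, got %d", nrow(x))
    return(x$residues)
  }
  as.character(x)
}

residue_indices <- function(res) {
  idx <- match(strsplit(res, "", fixed = TRUE)[[1]], AA_ALPHABET)
  if (anyNA(idx))
    stopf("sequence contains non-canonical residues; run validate_sequence() first")
  idx
}

#' Amino-acid composition
#'
#' Fraction of each of the 20 canonical amino acids in the sequence, in fixed
#' alphabetical order (ACDEFGHIKLMNPQRSTVWY). Sums to 1.
#'
#' @param seq a validated residue string or single-row [protein_set].
#' @return Named numeric vector of length 20.
#' @export
#' @examples
#' aa_composition("AAAA")["A"]  # 1
aa_composition <- function(seq) {
  idx <- residue_indices(as_residues(seq))
  setNames(tabulate(idx, nbins = 20L) / length(idx), AA_ALPHABET)
}

#' CTD descriptors for one property grouping
#'
#' The composition/transition/distribution encoding of a sequence under a
#' three-class partition of the amino acids by a physicochemical property:
#'
#' * Composition `C`: fraction of residues in each class (3 values, sum 1).
#' * Transition `T`: for each unordered class pair (1,2), (1,3), (2,3), the
#'   number of adjacent positions whose classes are that pair in either order,
#'   divided by L-1 (3 values). A length-1 sequence has all-zero transitions.
#' * Distribution `D`: for each class, the fractional positions (1-based
#'   position / L) of the first, 25%, 50%, 75% and last occurrence of the
#'   class (15 values, class-major). For a class with n occurrences the
#'   quantile occurrence indices are `(1, max(1, floor(0.25 n)),
#'   max(1, floor(0.5 n)), max(1, floor(0.75 n)), n)`; an absent class yields
#'   five zeros.
#'
#' `ctd_descriptor()` concatenates the three into the 21-element per-property
#' block (3 C + 3 T + 15 D).
#'
#' @param seq a validated residue string or single-row [protein_set].
#' @param grouping a [property_grouping].
#' @return `ctd_composition`/`ctd_transition`: numeric length 3;
#'   `ctd_distribution`: numeric length 15; `ctd_descriptor`: numeric length 21.
#' @export
ctd_composition <- function(seq, grouping) {
  cls <- grouping$class_of[residue_indices(as_residues(seq))]
  setNames(tabulate(cls, nbins = 3L) / length(cls), paste0("C", 1:3))
}

#' @rdname ctd_composition
#' @export
ctd_transition <- function(seq, grouping) {
  cls <- grouping$class_of[residue_indices(as_residues(seq))]
  out <- setNames(numeric(3), c("T12", "T13", "T23"))
  L <- length(cls)
  if (L < 2L) return(out)
  a <- cls[-L]; b <- cls[-1L]
  lo <- pmin(a, b); hi <- pmax(a, b)
  out["T12"] <- sum(lo == 1L & hi == 2L) / (L - 1L)
  out["T13"] <- sum(lo == 1L & hi == 3L) / (L - 1L)
  out["T23"] <- sum(lo == 2L & hi == 3L) / (L - 1L)
  out
}

#' @rdname ctd_composition
#' @export
ctd_distribution <- function(seq, grouping) {
  cls <- grouping$class_of[residue_indices(as_residues(seq))]
  L <- length(cls)
  out <- numeric(15)
  names(out) <- paste0("D", rep(1:3, each = 5), ".",
                       rep(c("first", "q25", "q50", "q75", "last"), 3))
  for (j in 1:3) {
    pos <- which(cls == j)
    n <- length(pos)
    if (n == 0L) next
    idx <- c(1L, max(1L, floor(0.25 * n)), max(1L, floor(0.50 * n)),
             max(1L, floor(0.75 * n)), n)
    out[(j - 1L) * 5L + 1:5] <- pos[idx] / L
  }
  out
}

#' @rdname ctd_composition
#' @export
ctd_descriptor <- function(seq, grouping) {
  res <- as_residues(seq)
  c(ctd_composition(res, grouping),
    ctd_transition(res, grouping),
    ctd_distribution(res, grouping))
}

#' Moreau-Broto autocorrelation of an amino-acid index
#'
#' For lag d in `1..max_lag`,
#' `AC(d) = (1/(L-d)) * sum_{i=1..L-d} p(i) * p(i+d)`, where `p(i)` is the
#' zero-mean unit-variance normalized index value of residue i.
#'
#' @param seq a validated residue string or single-row [protein_set].
#' @param scale a [property_scale] (normalized internally).
#' @param max_lag maximum lag; must be smaller than the sequence length.
#' @return Numeric vector of length `max_lag`.
#' @export
moreau_broto <- function(seq, scale, max_lag = 30L) {
  idx <- residue_indices(as_residues(seq))
  L <- length(idx)
  max_lag <- as.integer(max_lag)
  if (max_lag < 1L) stopf("max_lag must be >= 1")
  if (max_lag >= L)
    stopf("max_lag (%d) must be smaller than the sequence length (%d); use a smaller lag or a longer sequence",
          max_lag, L)
  p <- normalize_scale(scale)$value_of[idx]
  vapply(seq_len(max_lag), function(d)
    sum(p[1:(L - d)] * p[(1 + d):L]) / (L - d), numeric(1))
}

#' Pseudo-amino-acid composition
#'
#' Chou's classic form: the first 20 components are
#' `f_a / (1 + w * sum(theta))` with `f_a` the amino-acid frequencies; the
#' next `lam` components are `w * theta_k / (1 + w * sum(theta))`.
#' `theta_k` is the mean over positions i of the averaged squared
#' normalized-scale differences between residues i and i+k across the supplied
#' scales. All components sum to 1; `lam = 0` reduces to [aa_composition()].
#'
#' @param seq a validated residue string or single-row [protein_set].
#' @param scales list of [property_scale] objects (normalized internally).
#' @param lam number of sequence-order correlation tiers; `lam < L`.
#' @param w weight of the correlation terms, in `[0, 1]`.
#' @return Numeric vector of length `20 + lam`.
#' @export
pseaac <- function(seq, scales = default_scales(), lam = 10L, w = 0.05) {
  idx <- residue_indices(as_residues(seq))
  L <- length(idx)
  lam <- as.integer(lam)
  if (lam < 0L) stopf("lam must be non-negative")
  if (lam >= L) stopf("lam (%d) must be smaller than the sequence length (%d)",
                      lam, L)
  if (w < 0 || w > 1) stopf("w must be in [0, 1]")
  f <- tabulate(idx, nbins = 20L) / L
  theta <- numeric(0)
  if (lam > 0L) {
    P <- vapply(scales, function(s) normalize_scale(s)$value_of[idx],
                numeric(L))  # L x n_scales
    P <- as.matrix(P)
    theta <- vapply(seq_len(lam), function(k) {
      d2 <- (P[(1 + k):L, , drop = FALSE] - P[1:(L - k), , drop = FALSE])^2
      mean(rowMeans(d2))
    }, numeric(1))
  }
  denom <- 1 + w * sum(theta)
  out <- c(f, w * theta) / denom
  names(out) <- c(AA_ALPHABET, if (lam > 0L) paste0("theta", seq_len(lam)))
  out
}

#' Descriptor configuration
#'
#' Declares which feature blocks [featurize()] computes and with which
#' parameter values, and carries the property tables themselves so that the
#' resulting feature layout is a pure function of the configuration. The
#' configuration is fingerprinted (`digest`); trained models refuse queries
#' featurized under a different configuration.
#'
#' Default: amino-acid composition (20) plus one 21-element CTD block for each
#' of the 12 grouped properties (total 272); autocorrelation and
#' pseudo-amino-acid composition are off by default.
#'
#' @param aac include the 20-dim amino-acid composition block.
#' @param ctd_properties character vector of grouped property names (subset of
#'   `names(groupings)`); one 21-dim CTD block each.
#' @param groupings named list of [property_grouping] objects.
#' @param autocorrelation_scales character vector of scale names for
#'   Moreau-Broto blocks (`max_lag` values each), or `NULL` to disable.
#' @param max_lag Moreau-Broto maximum lag.
#' @param pseaac include the pseudo-amino-acid composition block
#'   (`20 + lambda` values).
#' @param pseaac_scales scale names used for the PseAAC correlation terms.
#' @param lambda PseAAC correlation tier count.
#' @param w PseAAC correlation weight.
#' @param scales named list of [property_scale] objects.
#' @return A list of class `descriptor_config` with a `digest` field.
#' @export
descriptor_config <- function(aac = TRUE,
                              ctd_properties = names(default_groupings()),
                              groupings = default_groupings(),
                              autocorrelation_scales = NULL,
                              max_lag = 30L,
                              pseaac = FALSE,
                              pseaac_scales = c("hydrophobicity",
                                                "hydrophilicity",
                                                "molecular_weight"),
                              lambda = 10L,
                              w = 0.05,
                              scales = default_scales()) {
  ctd_properties <- as.character(ctd_properties)
  bad <- setdiff(ctd_properties, names(groupings))
  if (length(bad) > 0L)
    stopf("unknown grouped property: %s", paste(bad, collapse = ", "))
  if (!is.null(autocorrelation_scales)) {
    bad <- setdiff(autocorrelation_scales, names(scales))
    if (length(bad) > 0L)
      stopf("unknown scale: %s", paste(bad, collapse = ", "))
  }
  if (isTRUE(pseaac)) {
    bad <- setdiff(pseaac_scales, names(scales))
    if (length(bad) > 0L)
      stopf("unknown PseAAC scale: %s", paste(bad, collapse = ", "))
  }
  cfg <- structure(list(aac = isTRUE(aac),
                        ctd_properties = ctd_properties,
                        groupings = groupings[ctd_properties],
                        autocorrelation_scales = autocorrelation_scales,
                        max_lag = as.integer(max_lag),
                        pseaac = isTRUE(pseaac),
                        pseaac_scales = if (isTRUE(pseaac)) pseaac_scales else character(0),
                        lambda = as.integer(lambda),
                        w = as.numeric(w),
                        scales = scales),
                   class = "descriptor_config")
  cfg$digest <- config_digest(cfg)
  cfg
}

config_digest <- function(cfg) {
  parts <- c("v1", cfg$aac,
             vapply(cfg$groupings, function(g)
               paste(g$property_name, paste(g$class_of, collapse = ","),
                     sep = ":"), character(1)),
             "mb", cfg$autocorrelation_scales %||% "none", cfg$max_lag,
             "pse", cfg$pseaac, cfg$pseaac_scales, cfg$lambda,
             sprintf("%.10g", cfg$w),
             vapply(cfg$scales[unique(c(cfg$autocorrelation_scales,
                                        cfg$pseaac_scales))],
                    function(s) paste(s$property_name,
                                      paste(sprintf("%.10g", s$value_of),
                                            collapse = ","), sep = ":"),
                    character(1)))
  content_digest(parts)
}

config_blocks <- function(cfg) {
  blocks <- list()
  if (cfg$aac) blocks[["aac"]] <- 20L
  for (p in cfg$ctd_properties) blocks[[paste0("ctd.", p)]] <- 21L
  for (s in cfg$autocorrelation_scales %||% character(0))
    blocks[[paste0("mb.", s)]] <- cfg$max_lag
  if (cfg$pseaac) blocks[["pseaac"]] <- 20L + cfg$lambda
  lens <- unlist(blocks)
  data.frame(block_name = names(blocks),
             start = cumsum(c(1L, unname(lens)))[seq_along(lens)],
             length = unname(lens),
             stringsAsFactors = FALSE)
}

#' Number of features produced by a descriptor configuration
#' @param config a [descriptor_config].
#' @return Integer feature-vector dimension.
#' @export
config_dimension <- function(config) sum(config_blocks(config)$length)

# minimum sequence length required by each enabled block
config_min_lengths <- function(cfg) {
  req <- c(if (cfg$aac) c(aac = 1L),
           if (length(cfg$ctd_properties)) setNames(
             rep(1L, length(cfg$ctd_properties)),
             paste0("ctd.", cfg$ctd_properties)),
           if (length(cfg$autocorrelation_scales %||% character(0)))
             setNames(rep(cfg$max_lag + 1L,
                          length(cfg$autocorrelation_scales)),
                      paste0("mb.", cfg$autocorrelation_scales)),
           if (cfg$pseaac) c(pseaac = cfg$lambda + 1L))
  req
}

#' Compute the full feature vector of a sequence
#'
#' Concatenates, in fixed order, the blocks enabled in `config`: amino-acid
#' composition, one CTD block per grouped property, Moreau-Broto
#' autocorrelation per scale, and pseudo-amino-acid composition. The result
#' carries a `blocks` attribute (name/start/length, tiling the vector exactly)
#' and a `config_digest` attribute. Deterministic and pure.
#'
#' @param seq a validated residue string or single-row [protein_set].
#' @param config a [descriptor_config].
#' @return Named numeric vector with attributes `blocks` and `config_digest`.
#' @export
featurize <- function(seq, config = descriptor_config()) {
  res <- as_residues(seq)
  L <- nchar(res)
  req <- config_min_lengths(config)
  short <- req[req > L]
  if (length(short) > 0L)
    stopf("sequence of length %d is too short for block '%s' (minimum length %d)",
          L, names(short)[1L], short[[1L]])
  parts <- list()
  if (config$aac)
    parts[["aac"]] <- setNames(aa_composition(res), paste0("aac.", AA_ALPHABET))
  for (p in config$ctd_properties) {
    v <- ctd_descriptor(res, config$groupings[[p]])
    names(v) <- paste0("ctd.", p, ".", names(v))
    parts[[paste0("ctd.", p)]] <- v
  }
  for (s in config$autocorrelation_scales %||% character(0)) {
    v <- moreau_broto(res, config$scales[[s]], config$max_lag)
    names(v) <- paste0("mb.", s, ".lag", seq_along(v))
    parts[[paste0("mb.", s)]] <- v
  }
  if (config$pseaac) {
    v <- pseaac(res, config$scales[config$pseaac_scales], config$lambda,
                config$w)
    names(v) <- paste0("pseaac.", names(v))
    parts[["pseaac"]] <- v
  }
  out <- unlist(unname(parts), use.names = TRUE)
  attr(out, "blocks") <- config_blocks(config)
  attr(out, "config_digest") <- config$digest
  out
}

#' Featurize a protein collection into a matrix
#'
#' @param proteins a [protein_set].
#' @param config a [descriptor_config].
#' @return Numeric matrix, one row per sequence (rownames = ids), with a
#'   `config_digest` attribute.
#' @export
featurize_matrix <- function(proteins, config = descriptor_config()) {
  rows <- lapply(proteins$residues, featurize, config = config)
  X <- do.call(rbind, rows)
  rownames(X) <- proteins$id
  attr(X, "config_digest") <- config$digest
  X
}
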