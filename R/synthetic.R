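# Synthetic protein families with controllable physicochemical separation,
# class imbalance and noise. The generator emulates the premise that members
# of a functional family share residue-composition bias under one
# physicochemical property, which is enough to make every downstream stage
# (descriptors, dataset construction, training, evaluation) testable without
# any external download. It is not a protein evolution simulator.

#' Define a synthetic family profile
#'
#' Residues of a family member are drawn by first sampling a property class
#' from `class_bias` for the anchor property (or, with probability `noise`,
#' uniformly over the 20 amino acids), then sampling uniformly among the
#' amino acids of that class. Other properties inherit whatever correlation
#' the amino-acid choice induces.
#'
#' @param family_id family label.
#' @param class_bias probability triple over the anchor property's classes
#'   1..3; must sum to 1.
#' @param anchor_property name of the grouped property the bias acts on.
#' @param length_range integer pair (min, max) of residue counts; min >= 30
#'   so the default descriptor blocks are always computable.
#' @param noise probability in `[0, 1]` of drawing a residue uniformly
#'   instead of from the bias.
#' @return A list of class `family_profile`.
#' @export
family_profile <- function(family_id, class_bias,
                           anchor_property = "hydrophobicity",
                           length_range = c(60L, 120L), noise = 0.1) {
  class_bias <- as.numeric(class_bias)
  if (length(class_bias) != 3L || any(class_bias < 0) ||
      abs(sum(class_bias) - 1) > 1e-9)
    stopf("class_bias must be a probability triple summing to 1")
  length_range <- as.integer(length_range)
  if (length(length_range) != 2L || length_range[1] > length_range[2])
    stopf("length_range must be an increasing (min, max) pair")
  if (length_range[1] < 30L)
    stopf("minimum length must be >= 30 (descriptor block requirement)")
  if (noise < 0 || noise > 1) stopf("noise must be in [0, 1]")
  groupings <- default_groupings()
  if (!anchor_property %in% names(groupings))
    stopf("unknown anchor property '%s'", anchor_property)
  structure(list(family_id = family_id, class_bias = class_bias,
                 anchor_property = anchor_property,
                 length_range = length_range, noise = noise),
            class = "family_profile")
}

#' Generate synthetic family members
#'
#' Fully reproducible by seed; lengths are uniform on the profile's
#' `length_range`.
#'
#' @param profile a [family_profile].
#' @param n number of sequences (>= 1).
#' @param seed integer seed.
#' @param id_prefix prefix for generated ids.
#' @return A [protein_set] of `n` sequences.
#' @export
generate_family <- function(profile, n, seed = 1L,
                            id_prefix = profile$family_id) {
  if (!inherits(profile, "family_profile")) stopf("invalid family profile")
  n <- as.integer(n)
  if (n < 1L) stopf("n must be >= 1")
  grouping <- default_groupings()[[profile$anchor_property]]
  class_members <- split(names(grouping$class_of), grouping$class_of)
  with_seed(seed, {
    lens <- sample(profile$length_range[1]:profile$length_range[2], n,
                   replace = TRUE)
    residues <- vapply(lens, function(L) {
      uniform <- runif(L) < profile$noise
      cls <- sample.int(3L, L, replace = TRUE, prob = profile$class_bias)
      aa <- character(L)
      for (j in 1:3) {
        sel <- !uniform & cls == j
        if (any(sel))
          aa[sel] <- sample(class_members[[j]], sum(sel), replace = TRUE)
      }
      if (any(uniform))
        aa[uniform] <- sample(AA_ALPHABET, sum(uniform), replace = TRUE)
      paste(aa, collapse = "")
    }, character(1))
  })
  protein_set(id = sprintf("%s_%04d", id_prefix, seq_len(n)),
              residues = residues,
              description = sprintf("synthetic member of %s",
                                    profile$family_id))
}

#' Default synthetic benchmark profiles
#'
#' One member family biased toward anchor-property class 1 and four
#' background families biased toward classes 2/3, all at noise 0.1 — a toy
#' mirror of the imbalanced member/non-member structure of real functional
#' family datasets, with disjoint dominant classes so the member family is
#' learnable from CTD features.
#'
#' @return A list of five [family_profile] objects (member first).
#' @export
default_benchmark_profiles <- function() {
  list(family_profile("FAM_MEMBER", c(0.80, 0.10, 0.10)),
       family_profile("BG_ALPHA",   c(0.10, 0.80, 0.10)),
       family_profile("BG_BETA",    c(0.10, 0.10, 0.80)),
       family_profile("BG_GAMMA",   c(0.15, 0.70, 0.15)),
       family_profile("BG_DELTA",   c(0.15, 0.15, 0.70)))
}

#' Generate a labelled synthetic benchmark
#'
#' `n_pos` members are drawn from the first profile and `n_neg` background
#' proteins from the remaining profiles (dealt round-robin). Synthetic
#' domain-family annotations are attached — the member family's proteins
#' share one domain family, and each background family is chopped into
#' domain families of `domain_family_size` consecutive proteins — so
#' [build_dataset_split()] runs unchanged on the output.
#'
#' @param profiles list of [family_profile]s: member family first, then at
#'   least one background family.
#' @param n_pos number of member proteins.
#' @param n_neg number of background proteins.
#' @param seed integer seed.
#' @param domain_family_size synthetic domain-family size for backgrounds.
#' @return A list: `sequences` ([protein_set]), `annotations`
#'   (functional-family table for the members), `domain_map` (domain-family
#'   table for all proteins), `family_id`, `seed`.
#' @export
generate_benchmark <- function(profiles = default_benchmark_profiles(),
                               n_pos = 60L, n_neg = 300L, seed = 1L,
                               domain_family_size = 3L) {
  if (length(profiles) < 2L)
    stopf("need a member profile and at least one background profile")
  member <- profiles[[1L]]
  backgrounds <- profiles[-1L]
  pos <- generate_family(member, n_pos, seed = derive_seed(seed, "pos"))
  counts <- rep(floor(n_neg / length(backgrounds)), length(backgrounds))
  extra <- n_neg - sum(counts)
  if (extra > 0L) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  negs <- lapply(seq_along(backgrounds), function(i) {
    if (counts[i] == 0L) return(NULL)
    generate_family(backgrounds[[i]], counts[i],
                    seed = derive_seed(seed, paste0("neg", i)))
  })
  negs <- negs[!vapply(negs, is.null, logical(1))]
  all_seqs <- do.call(rbind, c(list(pos), negs))
  class(all_seqs) <- c("protein_set", "data.frame")
  annotations <- data.frame(protein_id = pos$id,
                            family_id = member$family_id,
                            stringsAsFactors = FALSE)
  dom_rows <- list(data.frame(protein_id = pos$id,
                              family_id = paste0("DOM_", member$family_id),
                              stringsAsFactors = FALSE))
  for (i in seq_along(negs)) {
    ids <- negs[[i]]$id
    chunk <- ceiling(seq_along(ids) / domain_family_size)
    dom_rows[[i + 1L]] <- data.frame(
      protein_id = ids,
      family_id = sprintf("DOM_%s_%03d", backgrounds[[i]]$family_id, chunk),
      stringsAsFactors = FALSE)
  }
  list(sequences = all_seqs,
       annotations = annotations,
       domain_map = do.call(rbind, dom_rows),
       family_id = member$family_id,
       seed = seed)
}
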