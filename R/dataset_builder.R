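# Per-family dataset construction: grouped positive splitting, domain-family
# based negative sampling, cross-partition deduplication.

PARTITIONS <- c("train", "test", "independent")

new_dataset_split <- function(family_id, partitions, provenance) {
  structure(list(family_id = family_id, partitions = partitions,
                 negative_provenance = provenance),
            class = "dataset_split")
}

#' Group positive proteins by name
#'
#' Protein members of the same name but different species origin are grouped
#' together before partitioning, so that close orthologs are spread across
#' the partitions. Groups are ordered lexicographically by name; a missing
#' name falls back to the protein id.
#'
#' @param positives a [protein_set] of family members.
#' @return A named list of id character vectors, one per name group.
#' @export
group_members <- function(positives) {
  keys <- ifelse(is.na(positives$name) | !nzchar(positives$name),
                 positives$id, positives$name)
  groups <- split(positives$id, keys)
  groups[order(names(groups))]
}

#' Assign positive members to train/test/independent partitions
#'
#' Members within each group are shuffled with the seed and dealt round-robin
#' to the three partitions in the cycle train -> test -> independent. The
#' cycle pointer starts at train and is carried across groups so that
#' collections dominated by singleton groups still populate all partitions;
#' within any one group the partition sizes differ by at most 1.
#'
#' @param groups output of [group_members()].
#' @param seed integer seed.
#' @return Named list of id vectors: `train`, `test`, `independent`.
#' @export
assign_positive_splits <- function(groups, seed = 1L) {
  total <- sum(lengths(groups))
  if (total < 3L)
    stopf("need at least 3 positive members to populate three partitions, got %d",
          total)
  parts <- setNames(vector("list", 3L), PARTITIONS)
  for (p in PARTITIONS) parts[[p]] <- character(0)
  pointer <- 0L
  with_seed(seed, {
    for (g in groups) {
      members <- if (length(g) > 1L) sample(g) else g
      for (id in members) {
        p <- PARTITIONS[pointer %% 3L + 1L]
        parts[[p]] <- c(parts[[p]], id)
        pointer <- pointer + 1L
      }
    }
  })
  parts
}

#' Sample negatives from domain families free of positives
#'
#' Domain (e.g. Pfam) families containing at least one member of the
#' functional family are "positive families" and are excluded entirely; from
#' each remaining "negative family", up to `per_family` representative
#' proteins are sampled uniformly without replacement and dealt one per
#' partition in the cycle train -> test -> independent. A protein mapped to
#' several domain families is used at most once.
#'
#' @param positive_ids character vector of positive protein ids.
#' @param domain_map data frame (`protein_id`, `family_id`) mapping proteins
#'   to domain families.
#' @param all_proteins a [protein_set]; sampling is restricted to its ids.
#' @param per_family representatives per negative family (default 3, one per
#'   partition).
#' @param seed integer seed.
#' @return List with `partitions` (named list of id vectors) and `provenance`
#'   (named character: negative id -> source domain family).
#' @export
sample_negatives <- function(positive_ids, domain_map, all_proteins,
                             per_family = 3L, seed = 1L) {
  fams <- split(domain_map$protein_id, domain_map$family_id)
  fams <- lapply(fams, intersect, all_proteins$id)
  positive_fams <- vapply(fams, function(ids)
    any(ids %in% positive_ids), logical(1))
  neg_fams <- fams[!positive_fams & lengths(fams) > 0L]
  if (length(neg_fams) == 0L)
    stopf("no negative domain families available (all contain positives)")
  neg_fams <- neg_fams[order(names(neg_fams))]
  parts <- setNames(lapply(PARTITIONS, function(p) character(0)), PARTITIONS)
  provenance <- character(0)
  used <- character(0)
  with_seed(seed, {
    for (fam in names(neg_fams)) {
      pool <- setdiff(neg_fams[[fam]], c(positive_ids, used))
      if (length(pool) == 0L) next
      take <- min(per_family, length(pool))
      picked <- if (length(pool) > 1L) sample(pool, take) else pool
      for (i in seq_along(picked)) {
        p <- PARTITIONS[(i - 1L) %% 3L + 1L]
        parts[[p]] <- c(parts[[p]], picked[i])
      }
      provenance[picked] <- fam
      used <- c(used, picked)
    }
  })
  list(partitions = parts, provenance = provenance)
}

#' Remove duplicated proteins within and across partitions
#'
#' Two proteins are duplicates when their residue strings are identical.
#' Within the split, one representative is kept per distinct residue string:
#' the copy in the highest-priority partition (train > test > independent;
#' first occurrence within a partition). Removal counts are reported via a
#' message. This prevents evaluation-set leakage of training sequences.
#'
#' @param split a `dataset_split`.
#' @param sequences a [protein_set] covering every id in the split.
#' @return The deduplicated `dataset_split`.
#' @export
deduplicate <- function(split, sequences) {
  res_of <- setNames(sequences$residues, sequences$id)
  seen <- character(0)
  removed <- 0L
  for (p in PARTITIONS) {
    for (lab in c("pos", "neg")) {
      ids <- split$partitions[[p]][[lab]]
      if (length(ids) == 0L) next
      res <- res_of[ids]
      if (anyNA(res))
        stopf("split references id(s) absent from the sequence collection: %s",
              paste(ids[is.na(res)], collapse = ", "))
      keep <- !(res %in% seen) & !duplicated(res)
      removed <- removed + sum(!keep)
      split$partitions[[p]][[lab]] <- ids[keep]
      seen <- c(seen, res[keep])
    }
  }
  if (removed > 0L)
    message(sprintf("deduplicate: removed %d duplicated protein(s)", removed))
  split$negative_provenance <-
    split$negative_provenance[names(split$negative_provenance) %in%
                                unlist(lapply(split$partitions, `[[`, "neg"))]
  split
}

#' Build a complete per-family dataset split
#'
#' Runs the full construction procedure: select the family's positives,
#' group them by name, deal groups round-robin into train/test/independent,
#' sample negatives from positive-free domain families, and deduplicate by
#' residue identity across partitions.
#'
#' @param sequences a validated [protein_set] of all candidate proteins.
#' @param annotations data frame (`protein_id`, `family_id`) of functional
#'   family membership.
#' @param domain_map data frame (`protein_id`, `family_id`) of domain-family
#'   membership, used only for negative sampling.
#' @param family_id the functional family to build a split for.
#' @param per_family negatives sampled per negative domain family.
#' @param seed integer seed controlling the shuffles and sampling.
#' @return A `dataset_split`.
#' @export
build_dataset_split <- function(sequences, annotations, domain_map, family_id,
                                per_family = 3L, seed = 1L) {
  pos_ids <- intersect(
    annotations$protein_id[annotations$family_id == family_id],
    sequences$id)
  if (length(pos_ids) < 3L)
    stopf("family '%s' has %d annotated member(s) in the collection; need >= 3",
          family_id, length(pos_ids))
  positives <- sequences[match(pos_ids, sequences$id), , drop = FALSE]
  class(positives) <- c("protein_set", "data.frame")
  pos_parts <- assign_positive_splits(group_members(positives),
                                      seed = derive_seed(seed, "positives"))
  neg <- sample_negatives(pos_ids, domain_map, sequences,
                          per_family = per_family,
                          seed = derive_seed(seed, "negatives"))
  partitions <- setNames(lapply(PARTITIONS, function(p)
    list(pos = pos_parts[[p]], neg = neg$partitions[[p]])), PARTITIONS)
  split <- new_dataset_split(family_id, partitions, neg$provenance)
  deduplicate(split, sequences)
}

#' Write a split manifest as TSV
#'
#' Columns: `protein_id`, `partition`, `label` (pos/neg),
#' `provenance_family` (source domain family for negatives, `NA` for
#' positives).
#'
#' @param split a `dataset_split`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_split_manifest <- function(split, path) {
  rows <- do.call(rbind, lapply(PARTITIONS, function(p) {
    pos <- split$partitions[[p]]$pos
    neg <- split$partitions[[p]]$neg
    data.frame(protein_id = c(pos, neg),
               partition = p,
               label = c(rep("pos", length(pos)), rep("neg", length(neg))),
               provenance_family = c(rep(NA_character_, length(pos)),
                                     unname(split$negative_provenance[neg])),
               stringsAsFactors = FALSE)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("dataset_split for family '%s'\n", x$family_id))
  for (p in PARTITIONS)
    cat(sprintf("  %-12s %4d pos / %4d neg\n", p,
                length(x$partitions[[p]]$pos),
                length(x$partitions[[p]]$neg)))
  invisible(x)
}
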