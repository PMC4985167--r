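make_named_set <- function(names) {
  n <- length(names)
  ps <- rand_protein_set(n)
  ps$name <- names
  ps
}

test_that("group_members groups by name and conserves members", {
  set.seed(61)
  ps <- make_named_set(c("kinaseA", "kinaseA", "kinaseB"))
  g <- group_members(ps)
  expect_equal(names(g), c("kinaseA", "kinaseB"))
  expect_equal(lengths(g), c(kinaseA = 2L, kinaseB = 1L))

  ps2 <- rand_protein_set(10)  # all-distinct names fall back to ids
  expect_equal(lengths(group_members(ps2)), setNames(rep(1L, 10), ps2$id))

  ps3 <- make_named_set(sample(LETTERS[1:7], 100, replace = TRUE))
  expect_equal(sum(lengths(group_members(ps3))), 100L)
})

test_that("positive split assignment is round-robin, conserving and seeded", {
  set.seed(62)
  g9 <- list(grp = sprintf("m%d", 1:9))
  parts <- assign_positive_splits(g9, seed = 3)
  expect_equal(lengths(parts),
               c(train = 3L, test = 3L, independent = 3L))

  g4 <- list(grp = sprintf("m%d", 1:4))
  parts4 <- assign_positive_splits(g4, seed = 3)
  expect_equal(lengths(parts4), c(train = 2L, test = 1L, independent = 1L))

  expect_error(assign_positive_splits(list(a = "x", b = "y"), seed = 1),
               "at least 3")

  # conservation and disjointness on random groups; determinism by seed
  ps <- make_named_set(sample(letters[1:9], 60, replace = TRUE))
  groups <- group_members(ps)
  a <- assign_positive_splits(groups, seed = 11)
  b <- assign_positive_splits(groups, seed = 11)
  expect_identical(a, b)
  all_ids <- unlist(a)
  expect_setequal(all_ids, ps$id)
  expect_equal(anyDuplicated(all_ids), 0L)
})

test_that("negative sampling excludes positive families and is reproducible", {
  set.seed(63)
  ps <- rand_protein_set(40, prefix = "N")
  # 8 domain families of 5; families DF1 and DF2 contain a positive each
  dom <- data.frame(protein_id = ps$id,
                    family_id = rep(sprintf("DF%d", 1:8), each = 5),
                    stringsAsFactors = FALSE)
  positives <- c(ps$id[1], ps$id[6])
  neg <- sample_negatives(positives, dom, ps, per_family = 3, seed = 5)
  # 6 negative families contribute one id per partition
  expect_equal(lengths(neg$partitions),
               c(train = 6L, test = 6L, independent = 6L))
  sampled <- unlist(neg$partitions)
  expect_length(intersect(sampled, positives), 0L)
  expect_false(any(neg$provenance[sampled] %in% c("DF1", "DF2")))
  expect_setequal(names(neg$provenance), sampled)

  neg2 <- sample_negatives(positives, dom, ps, per_family = 3, seed = 5)
  expect_identical(neg, neg2)
  neg3 <- sample_negatives(positives, dom, ps, per_family = 3, seed = 6)
  expect_false(identical(neg, neg3))

  expect_error(sample_negatives(ps$id, dom, ps), "no negative")
})

test_that("deduplicate keeps the highest-priority copy and removes leakage", {
  set.seed(64)
  ps <- rand_protein_set(12)
  ps$residues[7] <- ps$residues[1]   # duplicate across partitions
  ps$residues[10] <- ps$residues[2]  # duplicate within a partition
  ps$residues[11] <- ps$residues[2]
  split <- profam:::new_dataset_split(
    "FAM",
    list(train = list(pos = ps$id[1:2], neg = ps$id[3:4]),
         test = list(pos = ps$id[5], neg = ps$id[c(6, 7)]),
         independent = list(pos = ps$id[c(8, 10)], neg = ps$id[c(9, 11, 12)])),
    setNames(rep("DF", 7), ps$id[c(3, 4, 6, 7, 9, 11, 12)]))
  expect_message(out <- deduplicate(split, ps), "removed 3")
  expect_false(ps$id[7] %in% unlist(out$partitions))   # train copy wins
  expect_true(ps$id[1] %in% out$partitions$train$pos)
  # leakage-freedom: no residue string in more than one partition
  res_by_part <- lapply(out$partitions, function(p)
    ps$residues[match(unlist(p), ps$id)])
  expect_equal(anyDuplicated(unlist(res_by_part)), 0L)
  # provenance only for surviving negatives
  expect_setequal(names(out$negative_provenance),
                  unlist(lapply(out$partitions, `[[`, "neg")))

  # no duplicates -> identity
  ps2 <- rand_protein_set(6, prefix = "Q")
  split2 <- profam:::new_dataset_split(
    "FAM", list(train = list(pos = ps2$id[1:2], neg = ps2$id[3]),
                test = list(pos = ps2$id[4], neg = ps2$id[5]),
                independent = list(pos = ps2$id[6], neg = character(0))),
    setNames(rep("DF", 2), ps2$id[c(3, 5)]))
  expect_identical(deduplicate(split2, ps2), split2)
})

test_that("build_dataset_split is deterministic and conserves labels", {
  bench <- generate_benchmark(n_pos = 15, n_neg = 60, seed = 9)
  s1 <- build_dataset_split(bench$sequences, bench$annotations,
                            bench$domain_map, bench$family_id, seed = 4)
  s2 <- build_dataset_split(bench$sequences, bench$annotations,
                            bench$domain_map, bench$family_id, seed = 4)
  expect_identical(s1, s2)
  pos_ids <- bench$annotations$protein_id
  split_pos <- unlist(lapply(s1$partitions, `[[`, "pos"))
  split_neg <- unlist(lapply(s1$partitions, `[[`, "neg"))
  expect_true(all(split_pos %in% pos_ids))
  expect_length(intersect(split_neg, pos_ids), 0L)
  expect_equal(anyDuplicated(c(split_pos, split_neg)), 0L)

  path <- tempfile(fileext = ".tsv")
  write_split_manifest(s1, path)
  manifest <- read.delim(path, stringsAsFactors = FALSE)
  expect_setequal(manifest$protein_id, c(split_pos, split_neg))
  expect_true(all(!is.na(manifest$provenance_family[manifest$label == "neg"])))
})
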