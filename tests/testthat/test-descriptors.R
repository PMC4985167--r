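# The worked-example constants asserted here are the published values for the
# 30-residue two-letter sequence (16 A, 14 E); see also test-acceptance.R.

test_that("amino-acid composition matches counting on fixed and random input", {
  v <- aa_composition("AAAA")
  expect_equal(unname(v[c("A", "E")]), c(1, 0))
  expect_equal(sum(v), 1)

  w <- aa_composition(WORKED_SEQ)
  expect_equal(unname(w["A"]), 16 / 30)
  expect_equal(unname(w["E"]), 14 / 30)
  expect_equal(sum(w[!names(w) %in% c("A", "E")]), 0)

  set.seed(11)
  res <- rand_residues(200)
  chars <- strsplit(res, "")[[1]]
  counted <- vapply(AAS, function(a) sum(chars == a), numeric(1)) / 200
  expect_equal(aa_composition(res), counted)
})

test_that("CTD reproduces the worked example under the charge grouping", {
  g <- default_groupings()$charge  # A -> class 2, E -> class 3
  expect_equal(round(ctd_composition(WORKED_SEQ, g), 2),
               c(C1 = 0, C2 = 0.53, C3 = 0.47))
  expect_equal(round(unname(ctd_transition(WORKED_SEQ, g)[["T23"]]), 2), 0.52)
  expect_equal(ctd_transition(WORKED_SEQ, g)[["T23"]], 15 / 29)
  D <- round(ctd_distribution(WORKED_SEQ, g), 2)
  expect_equal(unname(D[6:10]), c(0.03, 0.17, 0.40, 0.67, 0.97))   # class of A
  expect_equal(unname(D[11:15]), c(0.07, 0.27, 0.60, 0.77, 1.00))  # class of E
})

test_that("CTD degenerate cases", {
  g <- default_groupings()$hydrophobicity
  expect_equal(unname(ctd_composition("LLLL", g)), c(0, 0, 1))  # all class 3
  expect_equal(unname(ctd_transition("AAAA", g)), c(0, 0, 0))
  expect_equal(unname(ctd_transition("A", g)), c(0, 0, 0))      # length-1 rule
  # homopolymer distribution forced by the quantile-index rule
  D <- ctd_distribution("AAAA", g)
  expect_equal(unname(D[6:10]), c(0.25, 0.25, 0.50, 0.75, 1.00))
  expect_equal(unname(D[1:5]), rep(0, 5))                        # absent class
})

test_that("CTD matches brute-force oracles and invariants on random input", {
  set.seed(21)
  for (i in 1:150) {
    g <- rand_grouping()
    res <- rand_residues(sample(2:80, 1))
    C <- ctd_composition(res, g)
    Tv <- ctd_transition(res, g)
    D <- ctd_distribution(res, g)
    expect_equal(unname(C), oracle_composition(res, g))
    expect_equal(unname(Tv), oracle_transition(res, g))
    expect_equal(unname(D), oracle_distribution(res, g))
    # invariants
    expect_equal(sum(C), 1, tolerance = 1e-9)
    expect_lte(sum(Tv), 1)
    for (j in 1:3) {
      quint <- D[(j - 1) * 5 + 1:5]
      expect_true(all(diff(quint) >= 0))
    }
  }
})

test_that("Moreau-Broto autocorrelation matches the summation oracle", {
  scales <- default_scales()
  # constant index normalizes to zero -> all-zero autocorrelation
  const <- property_scale("const", setNames(rep(3.7, 20), AAS))
  expect_equal(moreau_broto("AEAAAEAE", const, 4), rep(0, 4))
  # two-residue sequence, lag 1: the single product term
  hp <- normalize_scale(scales$hydrophobicity)$value_of
  expect_equal(moreau_broto("AE", scales$hydrophobicity, 1),
               unname(hp["A"] * hp["E"]))
  expect_error(moreau_broto("AEA", scales$hydrophobicity, 5), "smaller")

  set.seed(31)
  for (i in 1:40) {
    res <- rand_residues(100)
    expect_equal(moreau_broto(res, scales$hydrophobicity, 30),
                 oracle_moreau_broto(res, scales$hydrophobicity, 30))
  }
})

test_that("PseAAC collapses correctly and matches the summation oracle", {
  scales <- default_scales()
  set.seed(41)
  res <- rand_residues(80)
  # lam = 0 -> plain composition
  expect_equal(unname(pseaac(res, scales, lam = 0)),
               unname(aa_composition(res)))
  # w = 0 -> composition plus zero tail
  v <- pseaac(res, scales, lam = 5, w = 0)
  expect_equal(unname(v[1:20]), unname(aa_composition(res)))
  expect_equal(unname(v[21:25]), rep(0, 5))
  expect_error(pseaac("AEA", scales, lam = 3), "smaller")

  for (i in 1:40) {
    res <- rand_residues(sample(40:90, 1))
    v <- pseaac(res, scales, lam = 5, w = 0.05)
    expect_equal(unname(v), oracle_pseaac(res, scales, 5, 0.05))
    expect_equal(sum(v), 1, tolerance = 1e-9)
  }
})

test_that("featurize assembles the documented layout deterministically", {
  cfg <- descriptor_config()
  expect_equal(config_dimension(cfg), 20 + 12 * 21)  # 272
  set.seed(51)
  res <- rand_residues(60)
  v1 <- featurize(res, cfg)
  v2 <- featurize(res, cfg)
  expect_identical(v1, v2)  # bitwise-identical repeated calls
  blocks <- attr(v1, "blocks")
  expect_true(all(blocks$length[startsWith(blocks$block_name, "ctd.")] == 21))
  # blocks tile the vector with no gaps or overlaps
  expect_equal(blocks$start, cumsum(c(1, head(blocks$length, -1))))
  expect_equal(sum(blocks$length), length(v1))
  expect_true(all(is.finite(v1)))

  # full configuration dimension: 272 + 2*30 + (20+10)
  cfg_full <- descriptor_config(
    autocorrelation_scales = c("hydrophobicity", "molecular_weight"),
    pseaac = TRUE)
  expect_equal(config_dimension(cfg_full), 272 + 60 + 30)
  expect_false(cfg_full$digest == cfg$digest)

  # permutation: composition-type blocks unchanged, order-dependent ones not
  perm <- paste(sample(strsplit(res, "")[[1]]), collapse = "")
  vp <- featurize(perm, cfg_full)
  vf <- featurize(res, cfg_full)
  expect_equal(vp[1:20], vf[1:20])
  cidx <- which(grepl("\\.C[123]$", names(vf)))
  expect_equal(vp[cidx], vf[cidx])
  expect_false(isTRUE(all.equal(unname(vp), unname(vf))))
})

test_that("featurize names the block when the sequence is too short", {
  cfg <- descriptor_config(autocorrelation_scales = "hydrophobicity",
                           max_lag = 30)
  expect_error(featurize(rand_residues(20), cfg), "mb.hydrophobicity")
  cfg2 <- descriptor_config(pseaac = TRUE, lambda = 40)
  expect_error(featurize(rand_residues(30), cfg2), "pseaac")
})

test_that("grouping and scale constructors enforce their invariants", {
  expect_error(property_grouping("bad", setNames(rep(1L, 20), AAS)), "unused")
  expect_error(property_grouping("bad", setNames(c(rep(1L, 19)), AAS[1:19])),
               "does not map")
  expect_error(property_scale("bad", setNames(c(rep(1, 19), NA), AAS)),
               "non-finite")
  g <- default_groupings()
  expect_length(g, 12L)
  for (p in names(g)) expect_s3_class(g[[p]], "property_grouping")
  ns <- normalize_scale(default_scales()$molecular_weight)$value_of
  expect_equal(mean(ns), 0, tolerance = 1e-12)
  expect_equal(mean(ns^2), 1, tolerance = 1e-12)
})
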