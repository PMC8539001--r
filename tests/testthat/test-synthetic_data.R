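demo_cross <- data.frame(hybrid_id = "H1", parent1_id = "P1",
                         parent2_id = "P2", stringsAsFactors = FALSE)
demo_parents <- data.frame(genotype_id = c("P1", "P2"),
                           TNF = c(40, 80), YP = c(1.0, 3.0),
                           TSSC = c(5.0, 6.0), TA = c(0.35, 0.45),
                           stringsAsFactors = FALSE)

test_that("generators are pure functions of spec and seed", {
  het <- data.frame(hybrid_id = "H1", YP = 50)
  t1 <- gen_trait_table(demo_parents, demo_cross, het, sd = 0.2,
                        n_reps = 3, seed = 41)
  t2 <- gen_trait_table(demo_parents, demo_cross, het, sd = 0.2,
                        n_reps = 3, seed = 41)
  expect_identical(t1, t2)
  g1 <- gen_genotype_matrix(4, 200, seed = 41)
  g2 <- gen_genotype_matrix(4, 200, seed = 41)
  expect_identical(g1$calls, g2$calls)
  expect_identical(g1$loci, g2$loci)
  m1 <- gen_marker_templates(marker_fixture_spec("Sw-5"), seed = 41)
  m2 <- gen_marker_templates(marker_fixture_spec("Sw-5"), seed = 41)
  expect_identical(m1$R_template, m2$R_template)
  g3 <- gen_genotype_matrix(4, 200, seed = 42)
  expect_false(identical(g1$calls, g3$calls))
})

test_that("zero-noise crosses return the planted heterosis exactly", {
  het <- data.frame(hybrid_id = "H1", TNF = -10, YP = 192.65, TSSC = 5,
                    TA = 0)
  tt <- gen_trait_table(demo_parents, demo_cross, het, sd = 0,
                        n_reps = 3, seed = 43)
  rec <- heterosis_table(tt, demo_cross, c("TNF", "YP", "TSSC", "TA"))
  expect_equal(rec$YP, 192.65)
  expect_equal(rec$TNF, -10)
  expect_equal(rec$TSSC, 5)
  expect_equal(rec$TA, 0)
  # e = 0 means F1 equals the mid-parent exactly
  expect_equal(mean(tt$TA[tt$genotype_id == "H1"]), 0.40)
})

test_that("noisy crosses recover the planted effect within 3 sd / sqrt(n)", {
  sigma <- 0.1; n <- 30L; e <- 50
  het <- data.frame(hybrid_id = "H1", YP = e)
  tt <- gen_trait_table(demo_parents, demo_cross, het, sd = sigma,
                        n_reps = n, seed = 44)
  rec <- heterosis_table(tt, demo_cross, "YP")
  pm <- 2.0
  tol_pct <- 100 * (3 * sigma / sqrt(n)) / pm * 2  # parents are noisy too
  expect_lt(abs(rec$YP - e), tol_pct)
})

test_that("trait generation respects bounds and rejects bad specs", {
  het <- data.frame(hybrid_id = "H1", YP = 0)
  bad <- demo_parents; bad$YP[1] <- -1
  expect_error(gen_trait_table(bad, demo_cross, het, seed = 1),
               "non-negative")
  tt <- gen_trait_table(
    data.frame(genotype_id = c("P1", "P2"), FS = c(98, 99), YP = c(0.01, 0.02)),
    demo_cross, het, sd = 5, n_reps = 50, seed = 45)
  expect_true(all(tt$FS <= 100 & tt$FS >= 0))
  expect_true(all(tt$YP >= 0))
})

test_that("a unit-similarity pair is generated identical", {
  gm <- gen_genotype_matrix(2, 300, target_similarity = 1.0, seed = 46)
  expect_identical(gm$calls[1, ], gm$calls[2, ])
  expect_equal(ibs_matrix(gm)[1, 2], 1.0)
})

test_that("the 0.54 similarity regime is realised within 0.02", {
  gm <- gen_genotype_matrix(2, 5000, target_similarity = 0.54, seed = 47)
  expect_lt(abs(ibs_matrix(gm)[1, 2] - 0.54), 0.02)
})

test_that("infeasible similarity matrices are rejected with the pair named", {
  tgt <- matrix(c(1, 0.9, 0.1,
                  0.9, 1, 0.9,
                  0.1, 0.9, 1), 3, 3)
  # f2 = .1, f3 = .9 implies s(2,3) = .9*.1 + .1*.9 = 0.18, not 0.9
  expect_error(gen_genotype_matrix(3, 100, target_similarity = tgt,
                                   seed = 48),
               "pair \\(2, 3\\)")
  # consistent triple: f2 = 0.1, f3 = 0.18 imply s(2,3) = 0.756
  ok <- matrix(c(1, 0.9, 0.82,
                 0.9, 1, 0.756,
                 0.82, 0.756, 1), 3, 3)
  gm <- gen_genotype_matrix(3, 4000, target_similarity = ok, seed = 48)
  ib <- ibs_matrix(gm)
  expect_lt(abs(ib[2, 3] - 0.756), 0.03)
})

test_that("missingness and depth are planted as requested", {
  gm <- gen_genotype_matrix(4, 2000, target_similarity = 0.9,
                            missing_rate = 0.2, depth_mean = 12, seed = 49)
  expect_lt(abs(mean(is.na(gm$calls)) - 0.2), 0.03)
  expect_lt(abs(mean(gm$depth) - 12), 1)
  gm2 <- gen_genotype_matrix(3, 100, depth_mean = NULL, seed = 49)
  expect_null(gm2$depth)
})

test_that("heterozygote rate knob produces heterozygous calls", {
  gm <- gen_genotype_matrix(4, 2000, het_rate = 0.1, seed = 50)
  expect_lt(abs(mean(gm$calls == 1L) - 0.1), 0.03)
})

test_that("marker templates reproduce their specified digest geometry", {
  for (s in c(3, 101)) {
    sw <- gen_marker_templates(marker_fixture_spec("Sw-5"), seed = s)
    expect_true(same_bands(sw$assay$S, c(133, 225)))
    expect_true(same_bands(sw$assay$R, c(43, 133, 182)))
    ve <- gen_marker_templates(marker_fixture_spec("Ve-1"), seed = s)
    expect_true(same_bands(ve$assay$R, c(156, 105)))
    expect_true(same_bands(ve$assay$S, c(130, 105, 26)))
  }
})

test_that("backgrounds are scrubbed of unplanted recognition sites", {
  sw <- gen_marker_templates(marker_fixture_spec("Sw-5"), seed = 51)
  enz <- sw$assay$enzyme
  # exhaustive scan: every site present must be a planted one
  sites_r <- find_restriction_sites(sw$R_template, enz)
  sites_s <- find_restriction_sites(sw$S_template, enz)
  expect_equal(nrow(sites_r), 2L)   # shared + resistant-specific
  expect_equal(nrow(sites_s), 1L)   # shared only
})

test_that("a zero-site spec digests to a single fragment", {
  spec <- list(marker = "toy", type = "caps", enzyme = "DdeI",
               amplicon_length = 180L, primer_length = 20L, flank = 30L)
  fx <- gen_marker_templates(spec, seed = 52)
  expect_equal(fx$assay$R$fragment_lengths, 180L)
  expect_equal(fx$assay$S$fragment_lengths, 180L)
})

test_that("site placements overlapping a primer region are spec errors", {
  spec <- marker_fixture_spec("Sw-5")
  spec$shared_site_starts <- 10L          # inside the forward primer
  expect_error(gen_marker_templates(spec, seed = 53), "primer region")
})

test_that("FASTA export writes a synthetic-labelled template pair", {
  dir <- withr::local_tempdir()
  gen_marker_templates(marker_fixture_spec("Sw-5"), seed = 54,
                       fasta_dir = dir)
  fa <- Biostrings::readDNAStringSet(file.path(dir, "Sw-5_R.fa"))
  expect_match(names(fa), "synthetic")
  expect_equal(length(fa[[1]]), 458L)     # 358 bp amplicon + 2 x 50 flanks
})
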