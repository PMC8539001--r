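test_that("trait bin scores follow the ten-wide half-open scale", {
  expect_equal(si_trait_score(0), 0L)
  expect_equal(si_trait_score(c(15, 30)), c(1L, 2L))   # published mapping
  expect_equal(si_trait_score(31.5), 3L)
  expect_equal(si_trait_score(c(10, 10.01, 20, 20.5)), c(0L, 1L, 1L, 2L))
  expect_error(si_trait_score(-1), "non-negative")
  # agrees with direct enumeration on a dense grid
  v <- seq(0, 250, by = 0.25)
  expect_equal(si_trait_score(v), bf_bin_score(v))
})

test_that("bin scores and the selection index are non-decreasing", {
  v <- sort(runif(200, 0, 300))
  expect_true(all(diff(si_trait_score(v)) >= 0))
  fs <- sort(runif(50, 0, 100))
  expect_true(all(diff(selection_index(fs, 50, 2)) >= 0))
  tnf <- sort(runif(50, 0, 300))
  expect_true(all(diff(selection_index(50, tnf, 2)) >= 0))
  yp <- sort(runif(50, 0, 8))
  expect_true(all(diff(selection_index(50, 50, yp)) >= 0))
})

test_that("selection index sums the three trait scores", {
  expect_equal(selection_index(0, 0, 0), 0L)
  expect_equal(selection_index(55, 145, 3.15), 22L)    # 5 + 14 + 3
  expect_equal(selection_index(100, 10, 0.5), 9L)      # 9 + 0 + 0
  expect_true(is.na(selection_index(55, NA, 3.15)))    # explicit missing
  expect_equal(selection_index(55, 145, 3.15, yp_mode = "direct"),
               5 + 14 + 31.5)
})

test_that("selection indices are computed per environment, never pooled", {
  tt <- data.frame(
    genotype_id = rep("G1", 4), environment = rep(c("A", "B"), each = 2),
    year = 2019, replicate = c(1, 2, 1, 2),
    FS = c(50, 60, 20, 30), TNF = c(100, 110, 40, 50),
    YP = c(3, 3.2, 1, 1.2))
  si <- selection_index_table(tt)
  expect_equal(nrow(si), 2L)
  expect_equal(si$SI[si$environment == "A"],
               selection_index(55, 105, 3.1))
  expect_equal(si$SI[si$environment == "B"],
               selection_index(25, 45, 1.1))
})

test_that("mid-parent heterosis arithmetic and symmetry", {
  expect_equal(heterosis_pct(2, 1, 3), 0)
  expect_equal(heterosis_pct(3, 1, 3), 50)
  expect_equal(heterosis_pct(4.5, 2, 1), 200)
  expect_equal(heterosis_pct(3, 1, 3), heterosis_pct(3, 3, 1))
  expect_equal(heterosis_pct(1.5, 1, 1), 100 * (1.5 - 1) / 1)
  expect_warning(out <- heterosis_pct(1, 0, 0), "undefined")
  expect_true(is.na(out))
})

test_that("heat tolerance and quality scores match hand arithmetic", {
  expect_equal(hts(0, 0), 0)
  expect_equal(hts(100, 4), 50)
  expect_equal(hts(230, 6), 83)
  expect_error(hts(-1, 1), "non-negative")
  expect_equal(qs(5.5, 0.3), 1 + 1 + 22 / 15)
  expect_equal(qs(6.6, 0.44), 6.6 / 5.5 + 0.44 / 0.3 + 6.6 / (0.44 * 12.5))
  expect_equal(qs(0, 0.6), 0.6 / 0.3)     # zero-sugar degenerate case
  expect_error(qs(5, 0), "positive")
  # strictly increasing in TSSC at fixed TA
  tssc <- sort(runif(30, 0, 12))
  expect_true(all(diff(qs(tssc, 0.4)) > 0))
})

test_that("resistance-gene score counting modes", {
  mk <- function(calls) data.frame(genotype_id = "H", gene = ASSAYED_GENES,
                                   call = calls, stringsAsFactors = FALSE)
  expect_equal(rgs(mk(rep("SS", 6)), "H"), 0)
  expect_equal(rgs(mk(c("RR", "RS", "RS", "SS", "SS", "SS")), "H"), 0.5)
  expect_equal(rgs(mk(rep("RR", 6)), "H"), 1)
  expect_equal(rgs(mk(c("RR", "RS", "RS", "SS", "SS", "SS")), "H",
                   mode = "allele"), 4 / 6)
  expect_error(rgs(mk(c("RR", "NULL", rep("SS", 4))), "H"), "NULL")
  expect_equal(rgs(mk(c("RR", "NULL", rep("SS", 4))), "H",
                   on_null = "skip"), 1 / 5)
  expect_error(rgs(mk(rep("SS", 6))[-1, ], "H"), "Mi-1.2")
})

test_that("adding a resistant call never decreases the score", {
  set.seed(42)
  for (i in 1:20) {
    calls <- sample(c("RR", "RS", "SS"), 6, replace = TRUE)
    tab <- data.frame(genotype_id = "H", gene = ASSAYED_GENES, call = calls)
    base <- rgs(tab, "H")
    ss <- which(calls == "SS")
    if (!length(ss)) next
    calls2 <- calls
    calls2[ss[1]] <- "RS"
    tab2 <- data.frame(genotype_id = "H", gene = ASSAYED_GENES,
                       call = calls2)
    expect_gte(rgs(tab2, "H"), base)
  }
})

test_that("hybrid index thresholds are recomputable means", {
  sc <- data.frame(hybrid_id = c("A", "B", "C"),
                   HTS = c(10, 20, 30), QS = c(3, 3, 3), RGS = c(.5, .5, .5))
  hi <- hybrid_index(sc)
  expect_equal(unname(hi$thresholds["HTS"]), 20)
  expect_equal(hi$scores$elite, c(FALSE, FALSE, FALSE))  # QS/RGS tied
  hi2 <- hybrid_index(sc, rule = "hts_qs")
  expect_equal(hi2$scores$elite, c(FALSE, FALSE, FALSE)) # QS tied
  sc$QS <- c(2.9, 3.0, 3.1)
  hi3 <- hybrid_index(sc, rule = "hts_qs")
  expect_equal(hi3$scores$elite, c(FALSE, FALSE, TRUE))
})

test_that("degenerate equality yields no elites under the default rule", {
  sc <- data.frame(hybrid_id = c("A", "B"), HTS = c(5, 5), QS = c(3, 3),
                   RGS = c(.5, .5))
  hi <- hybrid_index(sc)
  expect_equal(unname(hi$thresholds), c(5, 3, .5))
  expect_false(any(hi$scores$elite))
})

test_that("a planted elite subset is recovered exactly", {
  set.seed(7)
  n <- 13
  elite_idx <- sample(n, 7)
  sc <- data.frame(hybrid_id = sprintf("H%02d", 1:n),
                   HTS = 40, QS = 3.4, RGS = 0.4)
  sc$HTS[elite_idx] <- 80; sc$QS[elite_idx] <- 4; sc$RGS[elite_idx] <- 0.7
  hi <- hybrid_index(sc)
  expect_setequal(which(hi$scores$elite), elite_idx)
})

test_that("hybrids with missing scores are excluded with a warning", {
  sc <- data.frame(hybrid_id = c("A", "B", "C"),
                   HTS = c(10, 20, NA), QS = c(3, 4, 5), RGS = c(.4, .6, .9))
  expect_warning(hi <- hybrid_index(sc), "C")
  expect_equal(unname(hi$thresholds["HTS"]), 15)
  expect_false(hi$scores$elite[3])
  expect_error(hybrid_index(sc[c(1, 3), ]), "at least 2")
})

test_that("titratable acidity follows the titration formula", {
  expect_equal(titratable_acidity(0.1, 0, 2.5), 0)
  expect_equal(titratable_acidity(0.1, 10, 2.5), 2.8)  # G1 = 40
  expect_equal(titratable_acidity(0.1, 20, 2.5),
               2 * titratable_acidity(0.1, 10, 2.5))   # linear in volume
  expect_equal(titratable_acidity(0.1, 10, 5),
               titratable_acidity(0.1, 10, 2.5) / 2)   # inverse in mass
  expect_error(titratable_acidity(0.1, 10, 0), "positive")
})

test_that("heterosis is recovered from the recorded trait table", {
  cr <- data.frame(hybrid_id = "H1", parent1_id = "P1", parent2_id = "P2")
  tt <- data.frame(genotype_id = rep(c("P1", "P2", "H1"), each = 2),
                   environment = "E", year = 2019, replicate = c(1, 2),
                   YP = c(1.0, 1.0, 3.0, 3.0, 4.5, 4.5),
                   TNF = c(10, 10, 20, 20, 15, 15))
  het <- heterosis_table(tt, cr, c("YP", "TNF"))
  expect_equal(het$YP, 125)                 # (4.5 - 2) / 2
  expect_equal(het$TNF, 0)
  expect_error(heterosis_table(tt, data.frame(hybrid_id = "H1",
                                              parent1_id = "P1",
                                              parent2_id = "P9")), "P9")
})
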