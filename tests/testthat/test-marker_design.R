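catalog <- enzyme_catalog()

test_that("diagnostic SNP discovery matches a per-column scan", {
  snps <- find_diagnostic_snps("ACGT", "ACAT")
  expect_equal(snps$column, 3L)
  expect_equal(snps$resistant_base, "G")
  expect_equal(snps$susceptible_base, "A")
  expect_equal(nrow(find_diagnostic_snps("ACGT", "ACGT")), 0L)
  # class-internal polymorphism excludes the column
  snps2 <- find_diagnostic_snps(c("ACGT", "ACTT"), c("ACAT", "ACAT"))
  expect_equal(nrow(snps2), 0L)
  # gap columns are excluded
  snps3 <- find_diagnostic_snps("AC-T", "ACAT")
  expect_equal(nrow(snps3), 0L)
  expect_error(find_diagnostic_snps("ACGT", "ACGTA"), "length")

  set.seed(11)
  for (i in 1:10) {
    base <- random_dna(60)
    res <- c(base, base)
    sus_chars <- strsplit(base, "")[[1]]
    flip <- sample(60, 5)
    for (p in flip) {
      sus_chars[p] <- setdiff(c("A", "C", "G", "T"), sus_chars[p])[1]
    }
    sus <- paste(sus_chars, collapse = "")
    got <- find_diagnostic_snps(res, c(sus, sus))
    expect_equal(got$column, bf_diagnostic_columns(res, c(sus, sus)))
  }
})

test_that("dCAPS design engineers a discriminating site", {
  # planted toy: SNP destroys/creates a DdeI site one substitution away
  set.seed(12)
  left <- random_dna(40)
  right <- random_dna(40)
  # context: ...[40 bases] A T A A [SNP] [40 bases]...
  # window CTNAG needs C at the first position -> one engineered A->C
  context_core <- paste0(left, "ATAA", "G", right)  # susceptible allele
  snp <- list(position = 45L, resistant_base = "C", susceptible_base = "G")
  des <- design_dcaps(context_core, snp, catalog["DdeI"],
                      primer_length = 25L)
  expect_s3_class(des, "dcaps_design")
  expect_lte(sum(!is.null(des$engineered)), 1L)
  expect_false(same_bands(des$patterns$R, des$patterns$S))
})

test_that("a natural site difference needs no engineered mismatch", {
  set.seed(13)
  left <- random_dna(40)
  right <- random_dna(40)
  context <- paste0(left, "CTAA", "G", right)  # CTAAG complete for S
  snp <- list(position = 45L, resistant_base = "C", susceptible_base = "G")
  des <- design_dcaps(context, snp, catalog["DdeI"], primer_length = 25L)
  expect_s3_class(des, "dcaps_design")
  expect_null(des$engineered)
  expect_false(same_bands(des$patterns$R, des$patterns$S))
})

test_that("design failure reports near misses", {
  context <- paste0(strrep("A", 60), "G", strrep("A", 60))
  snp <- list(position = 61L, resistant_base = "C", susceptible_base = "G")
  des <- design_dcaps(context, snp, catalog["EcoRI"], primer_length = 20L)
  expect_s3_class(des, "dcaps_design_failure")
})

test_that("the Ve-1 fixture design reproduces the published assay", {
  ve <- gen_marker_templates(marker_fixture_spec("Ve-1"), seed = 17)
  inner <- ve$inner_region
  ctx <- substr(ve$R_template, inner["start"], inner["end"])
  des <- design_dcaps(ctx,
                      list(position = 30L, resistant_base = "C",
                           susceptible_base = "G"),
                      catalog[c("Hpy188I", "DdeI")],
                      primer_length = 29L, amplicon_end = 261L)
  expect_s3_class(des, "dcaps_design")
  expect_equal(des$enzyme$name, "DdeI")
  expect_equal(nrow(des$engineered), 1L)
  expect_equal(des$engineered$original, "A")
  expect_equal(des$engineered$introduced, "C")
  expect_true(same_bands(des$patterns$R, c(156, 105)))
  expect_true(same_bands(des$patterns$S, c(130, 105, 26)))
})

test_that("every successful design discriminates when re-simulated", {
  # closure property over seeded synthetic contexts
  set.seed(14)
  n_ok <- 0L
  for (i in 1:25) {
    context <- random_dna(120)
    pos <- 60L
    chars <- strsplit(context, "")[[1]]
    bases <- sample(c("A", "C", "G", "T"), 2)
    snp <- list(position = pos, resistant_base = bases[1],
                susceptible_base = bases[2])
    des <- design_dcaps(context, snp, catalog, primer_length = 25L)
    if (inherits(des, "dcaps_design_failure")) next
    n_ok <- n_ok + 1L
    expect_false(same_bands(des$patterns$R, des$patterns$S))
    expect_equal(sum(des$patterns$R$fragment_lengths),
                 sum(des$patterns$S$fragment_lengths))
  }
  expect_gt(n_ok, 5L)   # the panel should succeed reasonably often
})

test_that("SCAR design puts the diagnostic base at the 3' terminus", {
  set.seed(15)
  base <- random_dna(300)
  r <- base
  s_chars <- strsplit(base, "")[[1]]
  s_chars[100] <- setdiff(c("A", "C", "G", "T"), s_chars[100])[1]
  s <- paste(s_chars, collapse = "")
  des <- design_allele_specific_scar(r, s, 150L, primer_length = 20L)
  expect_s3_class(des, "scar_design")
  expect_equal(substr(des$R$forward, 20, 20), substr(r, 100, 100))
  expect_equal(substr(des$S$forward, 20, 20), substr(s, 100, 100))
  expect_equal(des$amplicon_length, 150L)
  # each pair amplifies only its own allele
  expect_equal(in_silico_pcr(r, des$R)$length, 150L)
  expect_true(is_pcr_failure(in_silico_pcr(s, des$R)))
  expect_true(is_pcr_failure(in_silico_pcr(r, des$S)))
  expect_equal(in_silico_pcr(s, des$S)$length, 150L)
  # identical alleles cannot be discriminated
  expect_s3_class(design_allele_specific_scar(r, r, 150L),
                  "scar_design_failure")
})

test_that("the Tm-2 fixture yields equal-length allele amplicons", {
  tm <- gen_marker_templates(marker_fixture_spec("Tm-2"), seed = 19)
  expect_equal(tm$assay$amplicon_length, 206L)
  ar <- in_silico_pcr(tm$R_template, tm$assay$R)
  as_ <- in_silico_pcr(tm$S_template, tm$assay$S)
  expect_equal(ar$length, 206L)
  expect_equal(as_$length, 206L)
})

test_that("low-identity windows rank divergent regions first", {
  set.seed(16)
  gene <- random_dna(400)
  par_chars <- strsplit(gene, "")[[1]]
  block <- 201:220
  for (p in block) {
    par_chars[p] <- setdiff(c("A", "C", "G", "T"), par_chars[p])[1]
  }
  paralog <- paste(par_chars, collapse = "")
  win <- find_specific_windows(gene, paralog, 20L, 100)
  expect_equal(win$identity[1], 0)
  expect_true(win$start[1] %in% block)
  # identical sequences: nothing below any threshold < 100
  expect_equal(nrow(find_specific_windows(gene, gene, 20L, 99.9)), 0L)
  # vacuous threshold returns every imperfect window
  expect_equal(nrow(win),
               sum(vapply(1:(400 - 19), function(s) {
                 any(block %in% s:(s + 19))
               }, logical(1))))
  expect_error(find_specific_windows("ACGT", gene, 10L), "longer")
})

test_that("the nested assay separates gene from paralog", {
  ve <- gen_marker_templates(marker_fixture_spec("Ve-1"), seed = 23)
  # dCAPS primers alone amplify from the paralog too often; the outer
  # pair is paralog-specific, so the nested assay only works on the gene
  amp <- nested_pcr(ve$R_template, ve$assay$outer, ve$assay$primers)
  expect_equal(amp$length, 261L)
  expect_equal(attr(amp, "outer")$length, 1016L)
  expect_error(nested_pcr(ve$paralog, ve$assay$outer, ve$assay$primers))
  # the paralog's divergence shows up as low-identity windows
  win <- find_specific_windows(ve$R_template, ve$paralog, 22L, 80)
  expect_gt(nrow(win), 0L)
})

test_that("genotype calls follow the band and amplification rules", {
  sw <- gen_marker_templates(marker_fixture_spec("Sw-5"), seed = 29)
  expect_equal(call_genotype(c(43, 133, 182), sw$assay), "RR")
  expect_equal(call_genotype(c(133, 225), sw$assay), "SS")
  expect_equal(call_genotype(c(43, 133, 182, 225), sw$assay), "RS")
  out <- call_genotype(c(99, 259), sw$assay)
  expect_equal(unclass(out)[1], "NULL")
  expect_match(attr(out, "mismatch"), "matches no expected pattern")
  scar <- list(type = "scar")
  expect_equal(call_genotype(list(R = TRUE, S = FALSE), scar), "RR")
  expect_equal(call_genotype(list(R = FALSE, S = TRUE), scar), "SS")
  expect_equal(call_genotype(list(R = TRUE, S = TRUE), scar), "RS")
  expect_equal(call_genotype(list(R = FALSE, S = FALSE), scar), "NULL")
})
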