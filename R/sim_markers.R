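.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.concretize_site <- function(code_chars) {
  vapply(code_chars, function(cc) IUPAC_CODES[[cc]][1], character(1))
}

# Remove every unplanted recognition site (both strands) from a set of
# synchronized template variants, mutating the same position in every
# variant so the alleles stay aligned outside the planted geometry.
# `protect` is an integer set of positions that must never be touched; a
# site lying entirely inside protected positions is considered planted
# and kept.
.scrub_set <- function(seqs, enzymes, protect, max_iter = 500L) {
  for (iter in seq_len(max_iter)) {
    dirty <- FALSE
    for (enz in enzymes) {
      code <- strsplit(enz$recognition, "")[[1]]
      code_minus <- strsplit(as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(enz$recognition))), "")[[1]]
      for (chars in seqs) {
        sites <- find_restriction_sites(paste(chars, collapse = ""), enz)
        for (k in seq_len(nrow(sites))) {
          span <- sites$start[k]:sites$end[k]
          if (all(span %in% protect)) next       # planted site
          free <- setdiff(span, protect)
          mutated <- FALSE
          for (p in free) {
            off <- p - sites$start[k] + 1L
            cc <- if (sites$strand[k] == "+") code[off] else code_minus[off]
            breakers <- setdiff(c("A", "C", "G", "T"), IUPAC_CODES[[cc]])
            if (!length(breakers)) next          # N position, unbreakable
            for (nm in names(seqs)) seqs[[nm]][p] <- breakers[1]
            mutated <- TRUE
            break
          }
          if (!mutated && length(free)) {
            # fall back: change a free base arbitrarily and rescan
            p <- free[1]
            nb <- setdiff(c("A", "C", "G", "T"), seqs[[1]][p])[1]
            for (nm in names(seqs)) seqs[[nm]][p] <- nb
            mutated <- TRUE
          }
          if (mutated) dirty <- TRUE
        }
        if (dirty) break
      }
      if (dirty) break
    }
    if (!dirty) return(seqs)
  }
  stop("could not scrub accidental restriction sites in ", max_iter,
       " iterations")
}

.assert_pattern <- function(observed, expected, what) {
  if (!same_bands(observed, expected)) {
    stop("generated ", what, " digest {",
         paste(observed$fragment_lengths, collapse = ","),
         "} does not match the specified {",
         paste(sort(expected), collapse = ","), "}")
  }
}

#' Built-in marker fixture specifications
#'
#' Returns the generation spec for one of the three assays the package's
#' synthetic templates reproduce:
#'
#' * `"Sw-5"`: CAPS; 358 bp amplicon, Hpy188I; susceptible allele cut once
#'   (fragments 133 + 225), resistant twice (43 + 133 + 182); diagnostic
#'   SNP C (resistant) / T (susceptible).
#' * `"Ve-1"`: nested PCR (1016 bp outer, 261 bp inner) followed by a
#'   DdeI dCAPS with an engineered A->C in the forward primer; resistant
#'   fragments 156 + 105, susceptible 130 + 105 + 26; diagnostic SNP C
#'   (resistant) / G (susceptible). A paralogous sequence is generated
#'   alongside to exercise paralog-specific outer-primer placement.
#' * `"Tm-2"`: allele-specific SCAR pair, both amplicons 206 bp.
#'
#' All template sequences are synthetic constructions reproducing the
#' assays' published fragment geometry, not database downloads.
#'
#' @param marker `"Sw-5"`, `"Ve-1"` or `"Tm-2"`.
#' @return A spec list consumed by [gen_marker_templates()].
#' @export
marker_fixture_spec <- function(marker = c("Sw-5", "Ve-1", "Tm-2")) {
  marker <- match.arg(marker)
  switch(marker,
    "Sw-5" = list(
      marker = "Sw-5", type = "caps", enzyme = "Hpy188I",
      amplicon_length = 358L, primer_length = 20L, flank = 50L,
      shared_site_starts = 131L, allele_site_starts = 174L,
      snp = list(amplicon_pos = 175L, resistant = "C", susceptible = "T"),
      expected = list(R = c(43L, 133L, 182L), S = c(133L, 225L))),
    "Ve-1" = list(
      marker = "Ve-1", type = "dcaps", enzyme = "DdeI",
      outer_amplicon = 1016L, inner_amplicon = 261L,
      inner_start_in_outer = 300L, outer_primer_length = 22L,
      inner_primer_length = 29L, flank = 60L,
      snp = list(inner_pos = 30L, resistant = "C", susceptible = "G"),
      fixed_inner = c("26" = "A", "27" = "T", "28" = "G", "29" = "A",
                      "31" = "C"),
      shared_site_start = 156L,
      engineered = list(position = 26L, original = "A", introduced = "C"),
      paralog_divergence = 0.09,
      expected = list(R = c(156L, 105L), S = c(26L, 105L, 130L))),
    "Tm-2" = list(
      marker = "Tm-2", type = "scar", amplicon_length = 206L,
      primer_length = 20L, flank = 50L,
      diagnostic = data.frame(
        column = c(70L, 90L, 95L, 100L),
        resistant_base = c("A", "C", "G", "T"),
        susceptible_base = c("G", "T", "A", "C"),
        stringsAsFactors = FALSE)))
}

#' Generate allele template sequences for a marker assay
#'
#' Builds a resistant/susceptible template pair from random background
#' sequence with the assay's restriction sites planted at the specified
#' offsets and the background scrubbed of accidental sites for the
#' assay's enzyme (both strands). Primer landing regions are embedded,
#' and the construction is closed: amplifying and digesting the returned
#' templates with the returned assay reproduces the specified fragment
#' multisets exactly (verified at generation time).
#'
#' @param spec A spec from [marker_fixture_spec()] or a custom list of
#'   the same shape.
#' @param seed Random seed; templates are a pure function of
#'   `(spec, seed)`.
#' @param fasta_dir Optional directory; when given, the template pair is
#'   also written as `<marker>_R.fa` / `<marker>_S.fa` (and
#'   `<marker>_paralog.fa` where applicable).
#' @return List of class `marker_fixture`: `marker`, `type`,
#'   `R_template`, `S_template`, optional `paralog`, and `assay` (primer
#'   pairs, enzyme, expected per-allele patterns or SCAR definition).
#' @export
gen_marker_templates <- function(spec, seed, fasta_dir = NULL) {
  fix <- .with_seed(seed, switch(spec$type,
    caps = .build_caps_fixture(spec),
    dcaps = .build_dcaps_fixture(spec),
    scar = .build_scar_fixture(spec),
    stop("unknown fixture type: ", spec$type)))
  fix$seed <- seed
  class(fix) <- "marker_fixture"
  if (!is.null(fasta_dir)) {
    dir.create(fasta_dir, showWarnings = FALSE, recursive = TRUE)
    seqs <- c(R = fix$R_template, S = fix$S_template)
    if (!is.null(fix$paralog)) seqs <- c(seqs, paralog = fix$paralog)
    for (nm in names(seqs)) {
      ss <- Biostrings::DNAStringSet(seqs[[nm]])
      names(ss) <- paste0(fix$marker, "_", nm, "_synthetic")
      Biostrings::writeXStringSet(
        ss, file.path(fasta_dir, paste0(fix$marker, "_", nm, ".fa")))
    }
  }
  fix
}

.build_caps_fixture <- function(spec) {
  enz <- enzyme_catalog()[[spec$enzyme]]
  if (is.null(enz)) stop("enzyme not in catalog: ", spec$enzyme)
  code <- strsplit(enz$recognition, "")[[1]]
  L <- length(code)
  alen <- spec$amplicon_length
  flank <- spec$flank
  total <- alen + 2L * flank
  amp0 <- flank  # template offset of amplicon position 0

  prim_f <- (amp0 + 1L):(amp0 + spec$primer_length)
  prim_r <- (amp0 + alen - spec$primer_length + 1L):(amp0 + alen)
  site_starts <- c(spec$shared_site_starts, spec$allele_site_starts)
  site_pos <- unlist(lapply(site_starts, function(s) {
    if (any((s:(s + L - 1L)) %in% c(seq_len(spec$primer_length),
                                    (alen - spec$primer_length + 1L):alen))) {
      stop("site placement overlaps a primer region (start ", s, ")")
    }
    amp0 + (s:(s + L - 1L))
  }))
  snp_pos <- if (!is.null(spec$snp)) amp0 + spec$snp$amplicon_pos else NULL

  chars <- strsplit(.random_dna(total), "")[[1]]
  for (s in site_starts) {
    chars[amp0 + (s:(s + L - 1L))] <- .concretize_site(code)
  }
  r_chars <- chars; s_chars <- chars
  if (!is.null(spec$snp)) {
    r_chars[snp_pos] <- spec$snp$resistant
    s_chars[snp_pos] <- spec$snp$susceptible
    # the susceptible base must break every allele-specific site it sits in
    for (s in spec$allele_site_starts) {
      span <- s:(s + L - 1L)
      if (!spec$snp$amplicon_pos %in% span) {
        stop("allele-specific site at ", s, " does not contain the SNP")
      }
      off <- spec$snp$amplicon_pos - s + 1L
      if (.iupac_match(spec$snp$susceptible, code[off])) {
        stop("susceptible base does not break the site at ", s)
      }
    }
  }
  protect <- unique(c(site_pos, snp_pos))
  scr <- .scrub_set(list(r = r_chars, s = s_chars), list(enz), protect)
  r_seq <- paste(scr$r, collapse = ""); s_seq <- paste(scr$s, collapse = "")

  fwd <- substr(r_seq, prim_f[1], prim_f[length(prim_f)])
  rev_p <- .revcomp(substr(r_seq, prim_r[1], prim_r[length(prim_r)]))
  pp <- primer_pair(fwd, rev_p, target_gene = spec$marker)
  pat <- lapply(c(R = r_seq, S = s_seq), function(tmpl) {
    amp <- in_silico_pcr(tmpl, pp)
    if (!inherits(amp, "amplicon")) stop("fixture primers failed to amplify")
    if (amp$length != alen) stop("fixture amplicon length mismatch")
    digest(amp, enz)
  })
  if (!is.null(spec$expected)) {
    .assert_pattern(pat$R, spec$expected$R, paste(spec$marker, "R"))
    .assert_pattern(pat$S, spec$expected$S, paste(spec$marker, "S"))
  }
  pat$R$allele_label <- "R"; pat$S$allele_label <- "S"
  list(marker = spec$marker, type = "caps",
       R_template = r_seq, S_template = s_seq,
       assay = list(type = "caps", primers = pp, enzyme = enz,
                    R = pat$R, S = pat$S),
       amplicon_length = alen)
}

.build_dcaps_fixture <- function(spec) {
  enz <- enzyme_catalog()[[spec$enzyme]]
  code <- strsplit(enz$recognition, "")[[1]]
  L <- length(code)
  flank <- spec$flank
  o_len <- spec$outer_amplicon
  i_len <- spec$inner_amplicon
  i0 <- spec$inner_start_in_outer          # inner position 1 == outer i0
  total <- o_len + 2L * flank
  out0 <- flank                             # template offset of outer pos 0
  inner_tpl <- function(ip) out0 + i0 - 1L + ip   # inner pos -> template pos

  outer_f <- (out0 + 1L):(out0 + spec$outer_primer_length)
  outer_r <- (out0 + o_len - spec$outer_primer_length + 1L):(out0 + o_len)
  inner_f <- inner_tpl(1L:spec$inner_primer_length)
  inner_r <- inner_tpl((i_len - spec$inner_primer_length + 1L):i_len)
  shared_span <- inner_tpl(spec$shared_site_start:(spec$shared_site_start +
                                                     L - 1L))
  fixed_pos <- inner_tpl(as.integer(names(spec$fixed_inner)))
  snp_tpl <- inner_tpl(spec$snp$inner_pos)

  chars <- strsplit(.random_dna(total), "")[[1]]
  chars[shared_span] <- .concretize_site(code)
  chars[fixed_pos] <- unname(spec$fixed_inner)
  r_chars <- chars; s_chars <- chars
  r_chars[snp_tpl] <- spec$snp$resistant
  s_chars[snp_tpl] <- spec$snp$susceptible
  protect <- unique(c(shared_span, fixed_pos, snp_tpl))
  # the dCAPS product carries the engineered base, so accidental sites are
  # removed from engineered variants of both alleles as well
  eng_pos <- inner_tpl(spec$engineered$position)
  r_eng <- r_chars; s_eng <- s_chars
  r_eng[eng_pos] <- spec$engineered$introduced
  s_eng[eng_pos] <- spec$engineered$introduced
  scr <- .scrub_set(list(r = r_chars, s = s_chars, re = r_eng, se = s_eng),
                    list(enz), protect)
  r_seq <- paste(scr$r, collapse = ""); s_seq <- paste(scr$s, collapse = "")

  sub <- function(seqn, span) substr(seqn, span[1], span[length(span)])
  outer_pp <- primer_pair(sub(r_seq, outer_f),
                          .revcomp(sub(r_seq, outer_r)),
                          target_gene = spec$marker)
  inner_fwd <- sub(r_seq, inner_f)
  em <- spec$engineered
  substr(inner_fwd, em$position, em$position) <- em$introduced
  inner_pp <- primer_pair(
    inner_fwd, .revcomp(sub(r_seq, inner_r)),
    engineered_mismatch = list(primer = "forward", position = em$position,
                               original = em$original,
                               introduced = em$introduced),
    target_gene = spec$marker)

  pat <- lapply(c(R = r_seq, S = s_seq), function(tmpl) {
    amp <- nested_pcr(tmpl, outer_pp, inner_pp)
    if (amp$length != i_len) stop("inner amplicon length mismatch")
    if (attr(amp, "outer")$length != o_len) {
      stop("outer amplicon length mismatch")
    }
    digest(amp, enz)
  })
  .assert_pattern(pat$R, spec$expected$R, paste(spec$marker, "R"))
  .assert_pattern(pat$S, spec$expected$S, paste(spec$marker, "S"))
  pat$R$allele_label <- "R"; pat$S$allele_label <- "S"

  # paralog: same backbone diverged everywhere except the inner (dCAPS)
  # primer landing sites, with the outer primer regions heavily diverged
  # so only the true gene supports the first PCR
  par_chars <- scr$s
  divergeable <- setdiff(seq_len(total), c(inner_f, inner_r))
  mut <- divergeable[stats::runif(length(divergeable)) <
                       spec$paralog_divergence]
  heavy <- c(outer_f, outer_r)
  mut <- unique(c(mut, heavy[stats::runif(length(heavy)) < 0.5]))
  for (p in mut) {
    par_chars[p] <- sample(setdiff(c("A", "C", "G", "T"), par_chars[p]), 1)
  }
  paralog <- paste(par_chars, collapse = "")

  list(marker = spec$marker, type = "dcaps",
       R_template = r_seq, S_template = s_seq, paralog = paralog,
       assay = list(type = "dcaps", outer = outer_pp, primers = inner_pp,
                    enzyme = enz, R = pat$R, S = pat$S),
       inner_region = c(start = inner_tpl(1L), end = inner_tpl(i_len)),
       amplicon_length = i_len, outer_amplicon_length = o_len)
}

.build_scar_fixture <- function(spec) {
  total <- spec$amplicon_length + 2L * spec$flank
  r_chars <- strsplit(.random_dna(total), "")[[1]]
  s_chars <- r_chars
  for (i in seq_len(nrow(spec$diagnostic))) {
    cl <- spec$diagnostic$column[i]
    r_chars[cl] <- spec$diagnostic$resistant_base[i]
    s_chars[cl] <- spec$diagnostic$susceptible_base[i]
  }
  r_seq <- paste(r_chars, collapse = ""); s_seq <- paste(s_chars, collapse = "")
  design <- design_allele_specific_scar(r_seq, s_seq,
                                        spec$amplicon_length,
                                        spec$primer_length)
  if (!inherits(design, "scar_design")) {
    stop("SCAR design failed on generated templates")
  }
  # closure: each allele-specific pair amplifies its own allele only
  for (al in c("R", "S")) {
    own <- if (al == "R") r_seq else s_seq
    other <- if (al == "R") s_seq else r_seq
    amp <- in_silico_pcr(own, design[[al]])
    if (!inherits(amp, "amplicon") || amp$length != spec$amplicon_length) {
      stop("SCAR ", al, " pair failed on its own allele")
    }
    if (!is_pcr_failure(suppressWarnings(in_silico_pcr(other,
                                                       design[[al]])))) {
      stop("SCAR ", al, " pair amplified the other allele")
    }
  }
  list(marker = spec$marker, type = "scar",
       R_template = r_seq, S_template = s_seq,
       assay = list(type = "scar", R = design$R, S = design$S,
                    amplicon_length = design$amplicon_length,
                    diagnostic_column = design$diagnostic_column),
       amplicon_length = spec$amplicon_length)
}

#' @export
print.marker_fixture <- function(x, ...) {
  cat("marker_fixture", x$marker, "(", x$type, "):",
      x$amplicon_length, "bp amplicon\n")
  invisible(x)
}
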