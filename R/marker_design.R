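.seq_chars <- function(x) {
  if (inherits(x, "XStringSet")) x <- as.character(x)
  x <- toupper(x)
  lens <- nchar(x)
  if (length(unique(lens)) != 1L) {
    stop("sequences are not aligned: lengths ", paste(lens, collapse = ", "))
  }
  do.call(rbind, strsplit(x, ""))
}

#' Find diagnostic SNP columns between two allele classes
#'
#' Scans an alignment of resistant and susceptible sequences and reports
#' every column at which each class is internally monomorphic and the two
#' classes differ. Columns containing gaps are excluded.
#'
#' @param resistant_seqs,susceptible_seqs Aligned sequences (character
#'   vectors or `DNAStringSet`), all of one aligned length.
#' @return `data.frame` with columns `column`, `resistant_base`,
#'   `susceptible_base`.
#' @export
find_diagnostic_snps <- function(resistant_seqs, susceptible_seqs) {
  r <- .seq_chars(resistant_seqs)
  s <- .seq_chars(susceptible_seqs)
  if (ncol(r) != ncol(s)) {
    stop("resistant and susceptible alignments have different lengths")
  }
  hits <- lapply(seq_len(ncol(r)), function(j) {
    rb <- unique(r[, j]); sb <- unique(s[, j])
    if (length(rb) == 1L && length(sb) == 1L && rb != sb &&
        rb %in% c("A", "C", "G", "T") && sb %in% c("A", "C", "G", "T")) {
      data.frame(column = j, resistant_base = rb, susceptible_base = sb,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(column = integer(0), resistant_base = character(0),
                      susceptible_base = character(0))
  }
  out
}

#' Design a dCAPS (or degenerate CAPS) assay around a diagnostic SNP
#'
#' Searches every recognition window of every candidate enzyme that
#' overlaps the SNP for a placement in which: the SNP base completes the
#' site for exactly one allele, and every other mismatching window
#' position can be repaired by at most `max_engineered_mismatches`
#' substitutions inside the forward primer, excluding the SNP column and
#' the three 3'-terminal primer bases. Zero required substitutions is the
#' degenerate CAPS case. If no placement works on the given strand the
#' search is repeated on the reverse complement.
#'
#' The returned design is closed under re-simulation: the engineered
#' primer is amplified against both allele templates and digested, and
#' the two patterns are verified to differ.
#'
#' @param context Template sequence around the SNP (one strand; the two
#'   alleles differ only at the SNP).
#' @param snp List with `position` (1-based in `context`),
#'   `resistant_base`, `susceptible_base`.
#' @param enzymes List of [enzyme()] objects (e.g. [enzyme_catalog()]).
#' @param primer_length Forward-primer length (3' end abuts the SNP).
#' @param max_engineered_mismatches Engineering budget (default 1).
#' @param amplicon_end Template position at which the amplicon ends
#'   (reverse primer is the reverse complement of the final
#'   `primer_length` bases up to it); defaults to the end of `context`.
#' @return Object of class `dcaps_design` (primer pair, enzyme, per-allele
#'   [digest_pattern()]s), or `dcaps_design_failure` listing near misses.
#' @export
design_dcaps <- function(context, snp, enzymes,
                         primer_length = 25L,
                         max_engineered_mismatches = 1L,
                         amplicon_end = nchar(context)) {
  context <- toupper(context)
  if (inherits(enzymes, "enzyme")) enzymes <- list(enzymes)
  res <- .design_dcaps_strand(context, snp, enzymes, primer_length,
                              max_engineered_mismatches, amplicon_end,
                              strand = "+")
  if (inherits(res, "dcaps_design")) return(res)
  rc_context <- .revcomp(context)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc_snp <- list(position = nchar(context) - snp$position + 1L,
                 resistant_base = comp[[snp$resistant_base]],
                 susceptible_base = comp[[snp$susceptible_base]])
  res2 <- .design_dcaps_strand(rc_context, rc_snp, enzymes, primer_length,
                               max_engineered_mismatches,
                               nchar(context), strand = "-")
  if (inherits(res2, "dcaps_design")) return(res2)
  structure(list(near_misses = rbind(res$near_misses, res2$near_misses)),
            class = "dcaps_design_failure")
}

.design_dcaps_strand <- function(context, snp, enzymes, primer_length,
                                 max_eng, amplicon_end, strand) {
  pos <- snp$position
  chars <- strsplit(context, "")[[1]]
  if (pos <= primer_length || amplicon_end - pos < primer_length) {
    stop("SNP needs at least primer_length context on both sides")
  }
  p_start <- pos - primer_length
  near <- list()
  candidates <- list()
  for (enz in enzymes) {
    code <- strsplit(enz$recognition, "")[[1]]
    L <- length(code)
    for (w in (pos - L + 1L):pos) {
      if (w < 1L || w + L - 1L > nchar(context)) next
      cols <- w:(w + L - 1L)
      snp_col <- pos - w + 1L
      match_r <- .iupac_match(snp$resistant_base, code[snp_col])
      match_s <- .iupac_match(snp$susceptible_base, code[snp_col])
      if (match_r == match_s) next            # not discriminating here
      others <- cols[cols != pos]
      mism <- others[!mapply(.iupac_match, chars[others],
                             code[others - w + 1L])]
      downstream <- mism[mism > pos]
      in_tail <- mism[mism < pos & mism > pos - 1L - 3L]
      before_primer <- mism[mism < p_start]
      reason <- NULL
      if (length(downstream)) reason <- "mismatch downstream of primer"
      else if (length(in_tail)) reason <- "mismatch within 3 bases of 3' end"
      else if (length(before_primer)) reason <- "mismatch upstream of primer"
      else if (length(mism) > max_eng) reason <- "engineering budget exceeded"
      if (!is.null(reason)) {
        near[[length(near) + 1L]] <- data.frame(
          enzyme = enz$name, window_start = w,
          n_mismatches = length(mism), reason = reason,
          stringsAsFactors = FALSE)
        next
      }
      candidates[[length(candidates) + 1L]] <- list(
        enz = enz, w = w, mism = mism, code = code,
        site_allele = if (match_r) "R" else "S")
    }
  }
  if (!length(candidates)) {
    return(structure(
      list(near_misses = if (length(near)) do.call(rbind, near) else
        data.frame(enzyme = character(0), window_start = integer(0),
                   n_mismatches = integer(0), reason = character(0))),
      class = "dcaps_design_failure"))
  }
  n_mm <- vapply(candidates, function(c) length(c$mism), integer(1))
  cand <- candidates[[order(n_mm, vapply(candidates, `[[`, 1L, "w"))[1]]]

  fwd <- chars[p_start:(pos - 1L)]
  engineered <- NULL
  for (p in cand$mism) {
    opts <- IUPAC_CODES[[cand$code[p - cand$w + 1L]]]
    intro <- opts[opts != chars[p]][1]
    engineered <- rbind(engineered, data.frame(
      position = p - p_start + 1L, original = chars[p],
      introduced = intro, stringsAsFactors = FALSE))
    fwd[p - p_start + 1L] <- intro
  }
  rev_primer <- .revcomp(paste(
    chars[(amplicon_end - primer_length + 1L):amplicon_end],
    collapse = ""))
  em <- if (!is.null(engineered) && nrow(engineered) == 1L) {
    list(primer = "forward", position = engineered$position[1],
         original = engineered$original[1],
         introduced = engineered$introduced[1])
  } else NULL
  pp <- primer_pair(paste(fwd, collapse = ""), rev_primer,
                    engineered_mismatch = em)

  allele_template <- function(base) {
    ch <- chars; ch[pos] <- base; paste(ch, collapse = "")
  }
  patterns <- lapply(c(R = snp$resistant_base, S = snp$susceptible_base),
                     function(b) {
    amp <- in_silico_pcr(allele_template(b), pp)
    if (!inherits(amp, "amplicon")) {
      stop("internal design error: engineered primer failed to amplify")
    }
    digest(amp, cand$enz)
  })
  patterns$R$allele_label <- "R"; patterns$S$allele_label <- "S"
  if (same_bands(patterns$R, patterns$S)) {
    stop("design does not discriminate the alleles after re-simulation")
  }
  structure(list(primer_pair = pp, enzyme = cand$enz, strand = strand,
                 window = c(start = cand$w,
                            end = cand$w + length(cand$code) - 1L),
                 engineered = engineered,
                 site_allele = cand$site_allele,
                 patterns = patterns,
                 amplicon_length = amplicon_end - p_start + 1L),
            class = "dcaps_design")
}

#' @export
print.dcaps_design <- function(x, ...) {
  cat("dCAPS design:", x$enzyme$name, "site for allele", x$site_allele,
      "; amplicon", x$amplicon_length, "bp\n")
  if (!is.null(x$engineered) && nrow(x$engineered)) {
    cat("engineered:", paste0(x$engineered$original, "->",
                              x$engineered$introduced, " at primer position ",
                              x$engineered$position, collapse = "; "), "\n")
  } else cat("no engineered mismatch (natural CAPS)\n")
  cat("R: {", paste(x$patterns$R$fragment_lengths, collapse = ", "),
      "}  S: {", paste(x$patterns$S$fragment_lengths, collapse = ", "),
      "} bp\n")
  invisible(x)
}

#' Design allele-specific SCAR primer pairs
#'
#' Chooses a discriminating polymorphism whose flanks allow a forward
#' primer ending exactly on the diagnostic base (3' terminus) and a
#' common reverse primer in a region identical between the alleles, so
#' that both allele-specific amplicons have equal length.
#'
#' @param resistant_seq,susceptible_seq Aligned allele sequences (equal
#'   length, A/C/G/T).
#' @param amplicon_target_length Desired amplicon length.
#' @param primer_length Primer length for both primers.
#' @return List of class `scar_design` with elements `R` and `S`
#'   ([primer_pair()]s), `amplicon_length` and `diagnostic_column`; or an
#'   object of class `scar_design_failure`.
#' @export
design_allele_specific_scar <- function(resistant_seq, susceptible_seq,
                                        amplicon_target_length,
                                        primer_length = 20L) {
  snps <- find_diagnostic_snps(resistant_seq, susceptible_seq)
  if (!nrow(snps)) {
    return(structure(list(reason = "no discriminating polymorphism"),
                     class = "scar_design_failure"))
  }
  r <- toupper(as.character(resistant_seq))
  s <- toupper(as.character(susceptible_seq))
  n <- nchar(r)
  for (i in seq_len(nrow(snps))) {
    c0 <- snps$column[i]
    a_start <- c0 - primer_length + 1L
    a_end <- a_start + amplicon_target_length - 1L
    if (a_start < 1L || a_end > n) next
    rev_region <- (a_end - primer_length + 1L):a_end
    # common reverse primer: region must be monomorphic between alleles
    if (any(snps$column %in% rev_region)) next
    # allele-specific forward: no other polymorphism inside the primer
    fwd_region <- a_start:c0
    if (any(snps$column %in% setdiff(fwd_region, c0))) next
    fwd_r <- substr(r, a_start, c0)
    fwd_s <- substr(s, a_start, c0)
    rev_p <- .revcomp(substr(r, a_end - primer_length + 1L, a_end))
    return(structure(list(
      R = primer_pair(fwd_r, rev_p, target_gene = "R-specific"),
      S = primer_pair(fwd_s, rev_p, target_gene = "S-specific"),
      amplicon_length = amplicon_target_length,
      diagnostic_column = c0), class = "scar_design"))
  }
  structure(list(reason = paste("no diagnostic column with enough",
                                "monomorphic context")),
            class = "scar_design_failure")
}

#' Rank low-identity windows between a gene and its paralog
#'
#' Slides a fixed-length window along the (aligned) pair and reports the
#' percent identity per window; windows below the threshold are returned
#' ranked by ascending identity, as candidate zones for paralog-specific
#' primer placement. Unequal-length inputs are globally aligned first and
#' identity is computed over alignment columns (gap = mismatch), with
#' window coordinates reported on the gene sequence.
#'
#' @param gene_seq,paralog_seq DNA sequences.
#' @param window_len Window length in alignment columns.
#' @param identity_threshold Keep windows with identity strictly below
#'   this percentage.
#' @return `data.frame` with `start`, `end` (gene coordinates) and
#'   `identity` (percent), ordered by ascending identity.
#' @export
find_specific_windows <- function(gene_seq, paralog_seq, window_len,
                                  identity_threshold = 100) {
  g <- toupper(as.character(gene_seq))
  p <- toupper(as.character(paralog_seq))
  if (!nzchar(g) || !nzchar(p)) stop("sequences must be non-empty")
  if (window_len > nchar(g) || window_len > nchar(p)) {
    stop("window longer than a sequence")
  }
  if (nchar(g) == nchar(p)) {
    ga <- g; pa <- p
  } else {
    aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(g),
                                         Biostrings::DNAString(p),
                                         type = "global")
    ga <- as.character(Biostrings::alignedPattern(aln))
    pa <- as.character(Biostrings::alignedSubject(aln))
  }
  gc <- strsplit(ga, "")[[1]]
  pc <- strsplit(pa, "")[[1]]
  match_col <- gc == pc & gc != "-"
  gene_pos <- cumsum(gc != "-")
  n <- length(gc)
  if (window_len > n) stop("window longer than the alignment")
  starts <- seq_len(n - window_len + 1L)
  cm <- cumsum(c(0L, match_col))
  ident <- 100 * (cm[starts + window_len] - cm[starts]) / window_len
  out <- data.frame(start = gene_pos[starts],
                    end = gene_pos[starts + window_len - 1L],
                    identity = ident)
  out <- out[out$identity < identity_threshold, , drop = FALSE]
  out <- out[order(out$identity, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call a genotype from an observed assay result
#'
#' CAPS/dCAPS assays compare the observed band set with the expected
#' resistant pattern (call RR), susceptible pattern (SS), or their union
#' with shared fragments collapsed (RS, co-migration on a gel). SCAR
#' assays call from the amplification pair: product in the R-specific
#' reaction only (RR), S only (SS), both (RS), neither (NULL).
#'
#' @param observed For CAPS: a [digest_pattern()] or integer fragment
#'   lengths. For SCAR: a logical vector/list with elements `R` and `S`
#'   (amplification observed).
#' @param assay For CAPS: list with elements `R` and `S`, the expected
#'   [digest_pattern()]s. For SCAR: `list(type = "scar")`.
#' @return One of `"RR"`, `"RS"`, `"SS"`, `"NULL"`; an unmatched CAPS
#'   pattern returns `"NULL"` with a `mismatch` attribute.
#' @export
call_genotype <- function(observed, assay) {
  if (!is.null(assay$type) && assay$type == "scar") {
    r_amp <- isTRUE(observed[["R"]]); s_amp <- isTRUE(observed[["S"]])
    return(if (r_amp && s_amp) "RS" else if (r_amp) "RR"
           else if (s_amp) "SS" else "NULL")
  }
  bands <- function(x) {
    unique(if (inherits(x, "digest_pattern")) x$fragment_lengths else
      as.integer(x))
  }
  obs <- bands(observed)
  r_bands <- bands(assay$R); s_bands <- bands(assay$S)
  het <- union(r_bands, s_bands)
  if (setequal(obs, r_bands) && setequal(obs, s_bands)) {
    # non-discriminating assay observed; cannot separate RR from SS
    return(structure("NULL", mismatch = "R and S patterns identical"))
  }
  if (setequal(obs, r_bands)) return("RR")
  if (setequal(obs, s_bands)) return("SS")
  if (setequal(obs, het)) return("RS")
  structure("NULL",
            mismatch = paste0("observed {",
                              paste(sort(obs), collapse = ","),
                              "} matches no expected pattern"))
}
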