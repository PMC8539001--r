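# Independent brute-force oracles used to cross-check the implementation.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# bin score by direct enumeration: smallest k with value <= 10 * (k + 1)
bf_bin_score <- function(value) {
  vapply(value, function(v) {
    k <- 0L
    while (v > 10 * (k + 1)) k <- k + 1L
    k
  }, integer(1))
}

# IBS by an explicit double loop over pairs and loci
bf_ibs <- function(calls) {
  n <- nrow(calls)
  out <- diag(1, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      num <- 0; den <- 0
      for (l in seq_len(ncol(calls))) {
        gi <- calls[i, l]; gj <- calls[j, l]
        if (is.na(gi) || is.na(gj)) next
        num <- num + (2 - abs(gi - gj)) / 2
        den <- den + 1
      }
      out[i, j] <- if (den > 0) num / den else NA_real_
    }
  }
  out
}

iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

revcomp_chr <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# digest fragments by scanning every position on both strands directly
bf_digest_fragments <- function(seqn, recognition, cut_offset) {
  chars <- strsplit(seqn, "")[[1]]
  code <- strsplit(recognition, "")[[1]]
  rc_code <- strsplit(gsub("U", "N", revcomp_iupac(recognition)), "")[[1]]
  L <- length(code)
  n <- length(chars)
  matches_at <- function(start, cd) {
    all(vapply(seq_len(L), function(o) {
      chars[start + o - 1L] %in% iupac_sets[[cd[o]]]
    }, logical(1)))
  }
  cuts <- integer(0)
  for (s in seq_len(n - L + 1L)) {
    plus <- matches_at(s, code)
    minus <- matches_at(s, rc_code)
    if (plus) cuts <- c(cuts, s - 1L + cut_offset)
    if (minus && !plus) cuts <- c(cuts, s + L - 1L - cut_offset)
  }
  cuts <- sort(unique(cuts[cuts > 0L & cuts < n]))
  diff(c(0L, cuts, n))
}

revcomp_iupac <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# exact-match PCR by a direct O(n * m) scan
bf_pcr_products <- function(template, fwd, rev) {
  n <- nchar(template)
  find_all <- function(pat) {
    hits <- integer(0)
    lp <- nchar(pat)
    for (s in seq_len(n - lp + 1L)) {
      if (substr(template, s, s + lp - 1L) == pat) hits <- c(hits, s)
    }
    hits
  }
  f_hits <- find_all(fwd)
  rc <- revcomp_chr(rev)
  r_hits <- find_all(rc)
  out <- list()
  for (f in f_hits) {
    for (rs in r_hits) {
      re <- rs + nchar(rc) - 1L
      if (rs > f + nchar(fwd) - 1L) {
        out[[length(out) + 1L]] <- c(start = f, end = re)
      }
    }
  }
  out
}

# column-wise class-consistency scan for diagnostic SNPs
bf_diagnostic_columns <- function(res, sus) {
  rm <- do.call(rbind, strsplit(res, ""))
  sm <- do.call(rbind, strsplit(sus, ""))
  which(vapply(seq_len(ncol(rm)), function(j) {
    rb <- unique(rm[, j]); sb <- unique(sm[, j])
    length(rb) == 1 && length(sb) == 1 && rb != sb &&
      all(c(rb, sb) %in% c("A", "C", "G", "T"))
  }, logical(1)))
}

# small trait fixture used by several io tests
write_demo_trait_file <- function(path, fs = c(55, 60, 70)) {
  df <- data.frame(genotype_id = paste0("G", seq_along(fs)),
                   environment = "E1", year = 2019,
                   replicate = seq_along(fs),
                   FS = fs, TNF = c(100, 120, 90), FW = c(80, 85, 75),
                   YP = c(2.5, 3.1, 2.2), TSSC = c(5.0, 5.5, 6.0),
                   TA = c(0.35, 0.40, 0.45))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}

# minimal hand-written VCF for reader tests
write_demo_vcf <- function(path, with_multiallelic = FALSE) {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", sep = "\t"),
    paste("ch01", 101, ".", "A", "G", ".", "PASS", ".", "GT:DP",
          "0/0:10", "1/1:12", sep = "\t"),
    paste("ch01", 205, ".", "C", "T", ".", "PASS", ".", "GT:DP",
          "0/1:9", "0/0:11", sep = "\t"),
    paste("ch01", 310, ".", "G", "A", ".", "PASS", ".", "GT:DP",
          "./.:0", "0/1:8", sep = "\t"),
    paste("ch02", 55, ".", "T", "C", ".", "PASS", ".", "GT:DP",
          "1/1:20", "1/1:18", sep = "\t"),
    paste("ch02", 90, ".", "A", "T", ".", "PASS", ".", "GT:DP",
          "0/0:15", "0/1:14", sep = "\t"))
  if (with_multiallelic) {
    lines <- c(lines,
               paste("ch02", 140, ".", "G", "A,T", ".", "PASS", ".",
                     "GT:DP", "1/2:10", "0/1:10", sep = "\t"))
  }
  writeLines(lines, path)
  path
}
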