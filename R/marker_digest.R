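.as_dna_string <- function(x) {
  if (inherits(x, "amplicon")) x <- x$sequence
  if (is.character(x)) x <- Biostrings::DNAString(toupper(x))
  x
}

#' Find restriction-site occurrences on both strands
#'
#' Returns one row per double-stranded site: matches of the recognition
#' sequence on the plus strand, plus matches of its reverse complement
#' (sites read on the minus strand). A minus-strand match occupying the
#' same interval as a plus-strand match (palindromic sites) is reported
#' once. The `cut` column is the number of bases left of the cut, in
#' top-strand coordinates.
#'
#' @param seq DNA sequence (character, `DNAString` or `amplicon`).
#' @param enz An [enzyme()].
#' @return `data.frame` with columns `start`, `end`, `strand`, `cut`.
#' @export
find_restriction_sites <- function(seq, enz) {
  subject <- .as_dna_string(seq)
  pat <- Biostrings::DNAString(enz$recognition)
  plus <- Biostrings::matchPattern(pat, subject, fixed = FALSE)
  minus <- Biostrings::matchPattern(Biostrings::reverseComplement(pat),
                                    subject, fixed = FALSE)
  res <- data.frame(start = BiocGenerics::start(plus),
                    end = BiocGenerics::end(plus),
                    strand = rep("+", length(plus)),
                    stringsAsFactors = FALSE)
  if (length(minus)) {
    mn <- data.frame(start = BiocGenerics::start(minus),
                     end = BiocGenerics::end(minus),
                     strand = "-", stringsAsFactors = FALSE)
    dup <- paste(mn$start, mn$end) %in% paste(res$start, res$end)
    res <- rbind(res, mn[!dup, ])
  }
  if (nrow(res)) {
    res$cut <- ifelse(res$strand == "+",
                      res$start - 1L + enz$cut_offset,
                      res$end - enz$cut_offset)
    res <- res[order(res$start), ]
    rownames(res) <- NULL
  } else {
    res$cut <- integer(0)
  }
  res
}

#' Construct a digest pattern
#'
#' @param fragment_lengths Positive integer fragment lengths.
#' @param allele_label Optional `"R"`, `"S"` or `"H"`.
#' @param cuts Optional cut coordinates retained for inspection.
#' @return Object of class `digest_pattern`.
#' @export
digest_pattern <- function(fragment_lengths, allele_label = NA_character_,
                           cuts = NULL) {
  fragment_lengths <- sort(as.integer(fragment_lengths))
  if (any(fragment_lengths <= 0L)) stop("fragment lengths must be positive")
  structure(list(fragment_lengths = fragment_lengths,
                 allele_label = allele_label, cuts = cuts),
            class = "digest_pattern")
}

#' @export
print.digest_pattern <- function(x, ...) {
  cat("digest_pattern",
      if (!is.na(x$allele_label)) paste0("(", x$allele_label, ")") else "",
      ": {", paste(x$fragment_lengths, collapse = ", "), "} bp\n")
  invisible(x)
}

#' Simulate a restriction digest
#'
#' Scans both strands for IUPAC-expanded recognition matches, deduplicates
#' cut positions, and returns the fragment-length multiset. Fragment
#' lengths always sum to the amplicon length.
#'
#' @param amplicon DNA sequence (character, `DNAString` or [in_silico_pcr()]
#'   amplicon); alphabet must be A/C/G/T.
#' @param enz An [enzyme()].
#' @param allele_label Optional label carried on the pattern.
#' @return A [digest_pattern()].
#' @export
digest <- function(amplicon, enz, allele_label = NA_character_) {
  subject <- .as_dna_string(amplicon)
  n <- length(subject)
  if (n == 0L) stop("cannot digest an empty sequence")
  if (!all(strsplit(as.character(subject), "")[[1]] %in%
           c("A", "C", "G", "T"))) {
    stop("amplicon must contain only A/C/G/T")
  }
  sites <- find_restriction_sites(subject, enz)
  cuts <- sort(unique(sites$cut[sites$cut > 0L & sites$cut < n]))
  digest_pattern(diff(c(0L, cuts, n)), allele_label = allele_label,
                 cuts = cuts)
}

#' Compare two digest patterns as band sets
#'
#' Gel bands co-migrate, so comparison is on the set of distinct fragment
#' lengths.
#'
#' @param a,b [digest_pattern()] objects or integer vectors.
#' @return Logical.
#' @export
same_bands <- function(a, b) {
  fl <- function(x) if (inherits(x, "digest_pattern")) x$fragment_lengths else x
  setequal(fl(a), fl(b))
}
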