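#' Filter a genotype matrix on missingness, depth and polymorphism
#'
#' Site-level filtering with the conventions of the standard VCF filtering
#' tool: `max_missing = 0.5` keeps sites where at least half the samples
#' have data (the flag's inverted semantics), `min_mean_dp` drops sites
#' with mean depth below the threshold, and monomorphic sites (fewer than
#' two observed genotype states) are removed. Sites without depth
#' annotation pass the depth filter with a warning (array-derived matrices
#' carry no depth). Locus order is preserved and the operation is
#' idempotent.
#'
#' @param gm A [genotype_matrix()].
#' @param max_missing Minimum fraction of non-missing calls per site, in
#'   \[0, 1\].
#' @param min_mean_dp Minimum per-site mean depth, >= 0.
#' @return The filtered [genotype_matrix()]; attribute `n_dropped` records
#'   how many sites each rule removed.
#' @export
filter_variants <- function(gm, max_missing = 0.5, min_mean_dp = 5) {
  if (!inherits(gm, "genotype_matrix")) stop("gm must be a genotype_matrix")
  if (max_missing < 0 || max_missing > 1) {
    stop("max_missing must lie in [0, 1]")
  }
  if (min_mean_dp < 0) stop("min_mean_dp must be non-negative")
  if (ncol(gm$calls) == 0L) stop("genotype matrix has no loci")
  called <- colMeans(!is.na(gm$calls))
  keep_miss <- called >= max_missing
  if (is.null(gm$depth)) {
    warning("no depth annotation; all sites pass the depth filter")
    keep_dp <- rep(TRUE, ncol(gm$calls))
  } else {
    keep_dp <- !is.na(gm$depth) & gm$depth >= min_mean_dp
  }
  n_states <- apply(gm$calls, 2, function(g) length(unique(g[!is.na(g)])))
  keep_poly <- n_states >= 2L
  keep <- keep_miss & keep_dp & keep_poly
  out <- genotype_matrix(gm$calls[, keep, drop = FALSE],
                         gm$loci[keep, , drop = FALSE],
                         if (is.null(gm$depth)) NULL else gm$depth[keep])
  attr(out, "n_dropped") <- c(missingness = sum(!keep_miss),
                              depth = sum(!keep_dp),
                              monomorphic = sum(!keep_poly))
  out
}

#' Pairwise identity-by-state allele-sharing matrix
#'
#' For each sample pair, IBS is the mean over jointly non-missing loci of
#' `(2 - |g_i - g_j|) / 2` with dosage coding 0/1/2 (the allele-sharing
#' convention of standard distance tools). The alternative
#' `"exact_identity"` method counts the fraction of loci with identical
#' genotype states. Pairs sharing no locus get `NA` with a warning.
#'
#' @param gm A [genotype_matrix()] with at least two samples.
#' @param method `"dosage_sharing"` (default) or `"exact_identity"`.
#' @return A symmetric matrix of class `ibs_matrix` with unit diagonal;
#'   attribute `n_shared` holds the per-pair count of jointly non-missing
#'   loci.
#' @export
ibs_matrix <- function(gm, method = c("dosage_sharing", "exact_identity")) {
  method <- match.arg(method)
  calls <- gm$calls
  n <- nrow(calls)
  if (n < 2L) stop("need at least two samples")
  ibs <- diag(1, n)
  shared <- matrix(NA_integer_, n, n)
  dimnames(ibs) <- dimnames(shared) <- list(rownames(calls), rownames(calls))
  diag(shared) <- as.integer(rowSums(!is.na(calls)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(calls[i, ]) & !is.na(calls[j, ])
      shared[i, j] <- shared[j, i] <- sum(ok)
      if (!any(ok)) {
        warning("samples ", rownames(calls)[i], " and ", rownames(calls)[j],
                " share no non-missing locus; IBS undefined")
        ibs[i, j] <- ibs[j, i] <- NA_real_
        next
      }
      v <- switch(method,
        dosage_sharing = mean((2 - abs(calls[i, ok] - calls[j, ok])) / 2),
        exact_identity = mean(calls[i, ok] == calls[j, ok]))
      ibs[i, j] <- ibs[j, i] <- v
    }
  }
  attr(ibs, "n_shared") <- shared
  attr(ibs, "method") <- method
  class(ibs) <- c("ibs_matrix", class(ibs))
  ibs
}

#' @export
print.ibs_matrix <- function(x, ...) {
  y <- unclass(x)
  attr(y, "n_shared") <- NULL
  attr(y, "method") <- NULL
  print(round(y, 3))
  off <- y[upper.tri(y)]
  cat("IBS range (off-diagonal):", round(min(off, na.rm = TRUE), 3), "-",
      round(max(off, na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' Scan a genotype matrix against a resistance-gene catalog
#'
#' A genotype is polymorphic at a locus when it carries at least one
#' alternate allele (dosage >= 1). For each genotype the scan reports the
#' catalog genes containing such loci, the count of such SNPs, and the
#' percentage of all catalog SNPs (loci inside catalog genes carrying an
#' alternate allele in at least one genotype) that the genotype accounts
#' for. Loci whose chromosome matches no catalog chromosome trigger a
#' coordinate-system warning with a count.
#'
#' @param gm A [genotype_matrix()].
#' @param catalog A [gene_catalog()] with interval coordinates.
#' @return `data.frame` with `genotype_id`, `n_snps`, `n_genes`,
#'   `pct_of_total_snps` and a list-column `genes`.
#' @export
prg_scan <- function(gm, catalog) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(catalog, "gene_catalog"))
  if (any(is.na(catalog$start)) || any(is.na(catalog$end))) {
    stop("catalog has no interval coordinates; use prg_scan_fixture() ",
         "for multiplicity-based catalogs")
  }
  loci <- gm$loci
  off_chrom <- !loci$chrom %in% unique(catalog$chromosome)
  if (any(off_chrom)) {
    warning(sum(off_chrom), " locus/loci on chromosomes absent from the ",
            "catalog (coordinate-system mismatch?)")
  }
  gene_of <- rep(NA_character_, nrow(loci))
  for (k in seq_len(nrow(catalog))) {
    hit <- loci$chrom == catalog$chromosome[k] &
      loci$pos >= catalog$start[k] & loci$pos <= catalog$end[k]
    gene_of[hit] <- catalog$gene_id[k]
  }
  in_gene <- !is.na(gene_of)
  any_alt <- colSums(gm$calls >= 1L, na.rm = TRUE) > 0L
  total_snps <- sum(in_gene & any_alt)
  ids <- rownames(gm$calls)
  res <- lapply(ids, function(s) {
    alt <- !is.na(gm$calls[s, ]) & gm$calls[s, ] >= 1L & in_gene
    genes <- unique(gene_of[alt])
    data.frame(genotype_id = s, n_snps = sum(alt),
               n_genes = length(genes),
               pct_of_total_snps = if (total_snps > 0)
                 100 * sum(alt) / total_snps else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$genes <- lapply(ids, function(s) {
    alt <- !is.na(gm$calls[s, ]) & gm$calls[s, ] >= 1L & in_gene
    sort(unique(gene_of[alt]))
  })
  attr(out, "total_snps") <- total_snps
  out
}

#' Resistance-gene scan of a multiplicity-based catalog
#'
#' Runs the per-genotype variability bookkeeping directly on a catalog
#' whose per-gene SNP content is given as genotype multiplicities (e.g.
#' the packaged transcription of the study's variant table): a genotype's
#' SNP count is the sum of its multiplicities over genes, the per-gene
#' distinct-SNP count is the maximum multiplicity across genotypes, and
#' percentages are taken over the catalog-wide SNP total.
#'
#' @param catalog A [gene_catalog()] carrying a `snp_multiplicity`
#'   attribute.
#' @param genotype_ids Genotypes to report; defaults to all mentioned.
#' @return `data.frame` with `genotype_id`, `n_snps`, `n_genes`,
#'   `pct_of_total_snps`, `pct_of_genes`; attributes `total_snps` and
#'   `total_genes`.
#' @export
prg_scan_fixture <- function(catalog, genotype_ids = NULL) {
  mult <- attr(catalog, "snp_multiplicity")
  if (is.null(mult)) stop("catalog carries no snp_multiplicity attribute")
  total_snps <- sum(vapply(mult, max, integer(1)))
  total_genes <- length(mult)
  if (is.null(genotype_ids)) {
    genotype_ids <- sort(unique(unlist(lapply(mult, names))))
  }
  out <- do.call(rbind, lapply(genotype_ids, function(g) {
    per_gene <- vapply(mult, function(x) {
      if (g %in% names(x)) x[[g]] else 0L
    }, integer(1))
    data.frame(genotype_id = g,
               n_snps = sum(per_gene),
               n_genes = sum(per_gene > 0L),
               pct_of_total_snps = 100 * sum(per_gene) / total_snps,
               pct_of_genes = 100 * sum(per_gene > 0L) / total_genes,
               stringsAsFactors = FALSE)
  }))
  attr(out, "total_snps") <- total_snps
  attr(out, "total_genes") <- total_genes
  out
}

IMPACT_CLASSES <- c("HIGH", "MODERATE", "LOW", "MODIFIER")

.round_half_up <- function(x, digits) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Tally variant-impact classes
#'
#' Counts annotations per impact class and derives percentages of the
#' total. Printed percentages use half-up rounding to two decimals below
#' 1% and one decimal otherwise (the convention of the summary this
#' reproduces).
#'
#' @param classes Character vector of impact classes (subset of HIGH,
#'   MODERATE, LOW, MODIFIER), one element per annotated SNP.
#' @return `data.frame` of class `impact_tally` with `class`, `count`,
#'   `percent` (full precision) and `percent_printed`.
#' @export
impact_tally <- function(classes) {
  classes <- toupper(classes)
  bad <- setdiff(unique(classes), IMPACT_CLASSES)
  if (length(bad)) {
    stop("unknown impact class(es): ", paste(bad, collapse = ", "))
  }
  total <- length(classes)
  if (total == 0L) stop("no annotations supplied")
  counts <- vapply(IMPACT_CLASSES, function(cl) sum(classes == cl),
                   integer(1))
  keep <- counts > 0L
  pct <- 100 * counts / total
  printed <- ifelse(pct < 1, .round_half_up(pct, 2), .round_half_up(pct, 1))
  out <- data.frame(class = IMPACT_CLASSES, count = counts, percent = pct,
                    percent_printed = printed, stringsAsFactors = FALSE,
                    row.names = NULL)[keep, ]
  rownames(out) <- NULL
  class(out) <- c("impact_tally", "data.frame")
  out
}
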