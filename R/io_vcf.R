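#' Construct a genotype matrix container
#'
#' Samples x biallelic loci with dosage-coded calls (0 = homozygous
#' reference, 1 = heterozygous, 2 = homozygous alternate, `NA` = missing)
#' plus per-site mean depth where available.
#'
#' @param calls Integer matrix (samples in rows, loci in columns) with
#'   values in `{0, 1, 2, NA}`; rownames are sample ids.
#' @param loci `data.frame` with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, one row per matrix column.
#' @param depth Optional numeric vector of per-site mean depth.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, loci, depth = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(loci) != ncol(calls)) {
    stop("loci table has ", nrow(loci), " rows but calls has ",
         ncol(calls), " columns")
  }
  if (!all(calls %in% c(0L, 1L, 2L, NA))) {
    stop("calls must be coded 0/1/2/NA")
  }
  if (!is.null(depth)) {
    if (length(depth) != ncol(calls)) stop("depth length must equal n loci")
    if (any(depth < 0, na.rm = TRUE)) stop("depth must be non-negative")
  }
  if (is.null(rownames(calls))) {
    rownames(calls) <- paste0("S", seq_len(nrow(calls)))
  }
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  structure(list(calls = calls, loci = loci, depth = depth),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "samples x", ncol(x$calls),
      "loci;", if (is.null(x$depth)) "no depth" else "with depth", "\n")
  cat("missing fraction:",
      round(mean(is.na(x$calls)), 3), "\n")
  invisible(x)
}

#' Per-site fraction of missing calls
#' @param gm A [genotype_matrix()].
#' @return Numeric vector, one value per locus.
#' @export
missing_fraction <- function(gm) {
  colMeans(is.na(gm$calls))
}

.gt_to_dosage <- function(gt) {
  # half-calls and anything containing '.' are treated as missing
  out <- rep(NA_integer_, length(gt))
  ok <- !is.na(gt) & grepl("^[0-9]+[/|][0-9]+$", gt)
  if (any(ok)) {
    alleles <- strsplit(gt[ok], "[/|]")
    out[ok] <- vapply(alleles, function(a) sum(a != "0"), integer(1))
  }
  out
}

#' Read genotypes from a VCF file
#'
#' Retains biallelic SNP sites only; multi-allelic records are dropped
#' (default) or split into one pseudo-site per alternate allele. Calls are
#' dosage-coded 0/1/2; any genotype containing `.` (including half-calls)
#' is missing. Per-site mean depth is carried when the FORMAT DP field is
#' present.
#'
#' @param path Path to a VCF 4.x file (plain or bgzipped).
#' @param multiallelic `"drop"` or `"split"`.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, multiallelic = c("drop", "split")) {
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (is.null(v@gt) || ncol(v@gt) < 2L) stop("VCF has no sample columns: ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  has_dp <- any(grepl("DP", v@gt[, "FORMAT"]))
  dp <- if (has_dp) {
    suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  } else NULL

  multi <- grepl(",", fix$ALT)
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    if (length(alts) > 1L && multiallelic == "drop") next
    for (k in seq_along(alts)) {
      g <- gt[i, ]
      if (length(alts) == 1L) {
        dos <- .gt_to_dosage(g)
      } else {
        # split: dosage of alternate allele k, '.' anywhere -> missing
        dos <- rep(NA_integer_, length(g))
        ok <- !is.na(g) & grepl("^[0-9]+[/|][0-9]+$", g)
        if (any(ok)) {
          al <- strsplit(g[ok], "[/|]")
          dos[ok] <- vapply(al, function(a) sum(a == as.character(k)),
                            integer(1))
        }
      }
      rows[[length(rows) + 1L]] <- list(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[k], dosage = dos,
        depth = if (is.null(dp)) NA_real_ else mean(dp[i, ], na.rm = TRUE))
    }
  }
  if (!length(rows)) stop("no biallelic sites retained from ", path)
  calls <- vapply(rows, function(r) r$dosage, integer(ncol(gt)))
  if (is.null(dim(calls))) calls <- matrix(calls, nrow = ncol(gt))
  rownames(calls) <- colnames(gt)  # samples x loci
  loci <- data.frame(
    chrom = vapply(rows, `[[`, "", "chrom"),
    pos = vapply(rows, `[[`, 1L, "pos"),
    ref = vapply(rows, `[[`, "", "ref"),
    alt = vapply(rows, `[[`, "", "alt"),
    stringsAsFactors = FALSE)
  depth <- vapply(rows, `[[`, 1, "depth")
  if (all(is.na(depth))) depth <- NULL
  genotype_matrix(calls, loci, depth)
}

#' Write a genotype matrix as a plain-text VCF 4.2 file
#'
#' Emits GT (and DP when depth is present) so that `read_vcf()` on the
#' output reproduces the retained fields exactly.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(gm, path) {
  calls <- gm$calls
  loci <- gm$loci
  has_dp <- !is.null(gm$depth)
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=heatcross_", utils::packageVersion("heatcross")),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (has_dp) {
    hdr <- c(hdr,
      '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">')
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", rownames(calls)),
                      collapse = "\t"))
  gt_code <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(ncol(calls)), function(j) {
    g <- calls[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    if (has_dp) {
      dp <- as.integer(round(gm$depth[j]))
      gt <- paste(gt, dp, sep = ":")
    }
    paste(c(loci$chrom[j], loci$pos[j], ".", loci$ref[j], loci$alt[j],
            ".", "PASS", ".", if (has_dp) "GT:DP" else "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}
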