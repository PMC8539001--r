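#' Construct a resistance-gene catalog
#'
#' Genomic intervals are 1-based inclusive throughout the package (BED
#' input is converted on read). An optional per-gene, per-genotype SNP
#' multiplicity map supports scans of transcribed variant tables that
#' report counts rather than coordinates.
#'
#' @param gene_id Character vector of unique gene ids.
#' @param chromosome Chromosome name per gene.
#' @param start,end 1-based inclusive bounds (`NA` allowed when unknown).
#' @param gene_function Free-text functional annotation.
#' @param snp_multiplicity Optional named list: per gene, a named integer
#'   vector of genotype -> number of distinct SNPs in that gene.
#' @return A `data.frame` of class `gene_catalog`.
#' @export
gene_catalog <- function(gene_id, chromosome, start = NA_integer_,
                         end = NA_integer_, gene_function = NA_character_,
                         snp_multiplicity = NULL) {
  if (anyDuplicated(gene_id)) stop("gene_id values must be unique")
  df <- data.frame(gene_id = gene_id, chromosome = chromosome,
                   start = as.integer(start), end = as.integer(end),
                   gene_function = gene_function, stringsAsFactors = FALSE)
  bad <- which(!is.na(df$start) & !is.na(df$end) & df$start > df$end)
  if (length(bad)) {
    stop("start > end for gene(s): ", paste(df$gene_id[bad], collapse = ", "))
  }
  if (!is.null(snp_multiplicity)) {
    stopifnot(all(names(snp_multiplicity) %in% gene_id))
    ok <- vapply(snp_multiplicity,
                 function(x) all(x >= 1L) && all(x == as.integer(x)),
                 logical(1))
    if (!all(ok)) stop("SNP multiplicities must be positive integers")
    attr(df, "snp_multiplicity") <- snp_multiplicity
  }
  class(df) <- c("gene_catalog", "data.frame")
  df
}

#' Read gene intervals from BED or GFF
#'
#' Uses the standard tracklayer importer, so BED half-open coordinates are
#' converted to the package's 1-based inclusive convention automatically.
#'
#' @param path A BED 3+ or GFF3 file.
#' @param id_field Metadata column holding the gene id (`"name"` for BED,
#'   `"ID"` or `"gene_id"` for GFF); the first one found is used.
#' @return A [gene_catalog()].
#' @export
read_gene_intervals <- function(path, id_field = c("name", "ID", "gene_id")) {
  if (!file.exists(path)) stop("interval file not found: ", path)
  gr <- rtracklayer::import(path)
  meta <- as.data.frame(gr)
  id_col <- intersect(id_field, names(meta))
  ids <- if (length(id_col)) as.character(meta[[id_col[1]]]) else
    paste0("gene", seq_along(gr))
  ids[is.na(ids)] <- paste0("gene", which(is.na(ids)))
  gene_catalog(gene_id = ids,
               chromosome = as.character(meta$seqnames),
               start = meta$start, end = meta$end)
}
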