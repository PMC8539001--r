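#' The six resistance genes assayed by the packaged marker-call fixtures
#' @export
ASSAYED_GENES <- c("Mi-1.2", "Ph-3", "Sw-5", "Tm-2", "Ty-3", "Ve-1")

.fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "heatcross")
  if (!nzchar(p)) stop("packaged fixture missing: ", file)
  p
}

.parse_multiplicity <- function(s) {
  # "E11 (2), E42, PDVIT (3)" -> c(E11 = 2, E42 = 1, PDVIT = 3)
  parts <- trimws(strsplit(s, ",", fixed = TRUE)[[1]])
  m <- regmatches(parts, regexec("^([A-Za-z0-9]+)(?: \\((\\d+)\\))?$", parts))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) stop("unparseable genotype cell: ", paste(parts[bad], collapse = "; "))
  counts <- vapply(m, function(x) {
    if (is.na(x[3]) || x[3] == "") 1L else as.integer(x[3])
  }, integer(1))
  stats::setNames(counts, vapply(m, `[`, "", 2))
}

.solyc_chromosome <- function(gene_id) {
  m <- regmatches(gene_id, regexec("^Solyc(\\d{2})g", gene_id))
  vapply(m, function(x) {
    if (length(x) < 2) NA_character_ else paste0("ch", x[2])
  }, character(1))
}

.read_call_table <- function(path) {
  wide <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  genes <- setdiff(names(wide), "genotype_id")
  long <- data.frame(
    genotype_id = rep(wide$genotype_id, times = length(genes)),
    gene = rep(genes, each = nrow(wide)),
    call = unlist(wide[genes], use.names = FALSE),
    stringsAsFactors = FALSE)
  bad <- !long$call %in% c("RR", "RS", "SS", "NULL")
  if (any(bad)) stop("invalid marker call(s): ",
                     paste(unique(long$call[bad]), collapse = ", "))
  if (anyDuplicated(long[c("genotype_id", "gene")])) {
    stop("duplicate (genotype, gene) call")
  }
  class(long) <- c("marker_call_table", "data.frame")
  long
}

#' Load a packaged fixture transcribed from the source study's tables
#'
#' * `"table1"` - catalog of 57 resistance genes carrying 71 high/moderate
#'   impact SNPs, with per-genotype SNP multiplicities (bracketed counts;
#'   a plain genotype id means one SNP).
#' * `"table2"` - marker calls (RR/RS/SS) for 15 parental genotypes at the
#'   six assayed resistance genes.
#' * `"table3"` - mid-parent heterosis percentages for 13 F1 hybrids at
#'   six traits.
#' * `"hybrid_calls"` - marker calls for the 13 F1 hybrids.
#' * `"crosses"` - cross-design table (partially synthetic: only two
#'   parentages are printed in the source; the rest are plausible
#'   assignments consistent with the hybrids' marker calls).
#'
#' Loads are pure: repeated calls return identical objects.
#'
#' @param name One of `"table1"`, `"table2"`, `"table3"`,
#'   `"hybrid_calls"`, `"crosses"`.
#' @return See above; `table1` returns a [gene_catalog()], `table2` and
#'   `hybrid_calls` a `marker_call_table`, `table3` and `crosses` plain
#'   data.frames.
#' @export
load_fixture <- function(name = c("table1", "table2", "table3",
                                  "hybrid_calls", "crosses")) {
  name <- match.arg(name)
  switch(name,
    table1 = {
      raw <- utils::read.delim(.fixture_path("table1_rgene_snps.tsv"),
                               stringsAsFactors = FALSE)
      mult <- lapply(raw$mutated_genotypes, .parse_multiplicity)
      names(mult) <- raw$gene
      cat1 <- gene_catalog(gene_id = raw$gene,
                           chromosome = .solyc_chromosome(raw$gene),
                           gene_function = raw$protein_function,
                           snp_multiplicity = mult)
      cat1$high_impact <- raw$high_impact == "yes"
      cat1$predicted_effect <- raw$predicted_effect
      cat1
    },
    table2 = .read_call_table(.fixture_path("table2_marker_calls.tsv")),
    hybrid_calls = .read_call_table(.fixture_path("hybrid_marker_calls.tsv")),
    table3 = {
      df <- utils::read.delim(.fixture_path("table3_heterosis.tsv"),
                              stringsAsFactors = FALSE)
      df
    },
    crosses = read_cross_table(.fixture_path("crosses_fig2_synthetic.tsv"))
  )
}
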