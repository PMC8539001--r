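#' Arbitrary-scale bin score for a single trait value
#'
#' The scale bins trait values in widths of ten: values in \[0, 10\] score
#' 0, (10, 20\] score 1, (20, 30\] score 2, and so on. Intervals are
#' half-open above so the mapping is total on the non-negative reals while
#' preserving the integer ranges of the published scale.
#'
#' @param value Numeric vector of non-negative trait values.
#' @return Integer bin scores; `NA` values propagate.
#' @export
si_trait_score <- function(value) {
  if (any(value < 0, na.rm = TRUE)) stop("trait value must be non-negative")
  as.integer(pmax(0, ceiling(value / 10) - 1))
}

#' Selection index from fruit set, fruit number and yield
#'
#' Sum of the arbitrary-scale bin scores for fruit set (FS, %), fruit
#' number per plant (TNF) and yield per plant (YP, kg). Yield enters the
#' scale after multiplication by ten (so 3.15 kg/plant scores as 31.5,
#' bin 3). The alternative reading, adding `10 * YP` directly to the two
#' binned scores, is exposed as `yp_mode = "direct"`.
#'
#' Any missing trait yields an explicit `NA` score, never a silent zero.
#'
#' @param FS,TNF,YP Numeric vectors (recycled to a common length).
#' @param yp_mode `"binned"` (default) or `"direct"`.
#' @return Numeric vector of selection indices (integer under `"binned"`).
#' @export
selection_index <- function(FS, TNF, YP, yp_mode = c("binned", "direct")) {
  yp_mode <- match.arg(yp_mode)
  n <- max(length(FS), length(TNF), length(YP))
  FS <- rep_len(FS, n); TNF <- rep_len(TNF, n); YP <- rep_len(YP, n)
  yp_term <- switch(yp_mode,
                    binned = si_trait_score(10 * YP),
                    direct = 10 * YP)
  out <- si_trait_score(FS) + si_trait_score(TNF) + yp_term
  out[is.na(FS) | is.na(TNF) | is.na(YP)] <- NA
  out
}

#' Per-environment selection indices from a trait table
#'
#' Trait values are averaged per genotype within each environment (across
#' years and replicates) before scoring; environments are never pooled
#' into a single index.
#'
#' @param traits A `trait_table` (see [read_trait_table()]).
#' @param yp_mode Passed to [selection_index()].
#' @return `data.frame` with `genotype_id`, `environment`, trait means and
#'   `SI`.
#' @export
selection_index_table <- function(traits, yp_mode = c("binned", "direct")) {
  yp_mode <- match.arg(yp_mode)
  env <- if (all(is.na(traits$environment))) "all" else traits$environment
  agg <- stats::aggregate(
    traits[c("FS", "TNF", "YP")],
    by = list(genotype_id = traits$genotype_id, environment = env),
    FUN = function(x) mean(x, na.rm = TRUE))
  agg$SI <- selection_index(agg$FS, agg$TNF, agg$YP, yp_mode = yp_mode)
  agg
}

#' Mid-parent heterosis percentage
#'
#' `100 * (F1 - PM) / PM`, with `PM = (p1 + p2) / 2` the mid-parent value.
#' When the mid-parent value is zero the result is undefined and returned
#' as `NA` with a warning (never coerced to zero).
#'
#' @param f1_value Hybrid trait value(s).
#' @param p1_value,p2_value Parent trait values.
#' @return Numeric vector of heterosis percentages.
#' @export
heterosis_pct <- function(f1_value, p1_value, p2_value) {
  pm <- (p1_value + p2_value) / 2
  undef <- !is.na(pm) & pm == 0
  if (any(undef)) {
    warning("mid-parent value is zero for ", sum(undef),
            " case(s); heterosis undefined (NA)")
  }
  out <- 100 * (f1_value - pm) / pm
  out[undef] <- NA_real_
  out
}

#' Mid-parent heterosis for every hybrid and trait in a cross design
#'
#' Trait values are averaged per genotype across replicates before the
#' heterosis formula is applied.
#'
#' @param traits A `trait_table` containing hybrid and parent records.
#' @param crosses A `cross_design` table.
#' @param trait_cols Trait columns to evaluate.
#' @return `data.frame`: one row per hybrid, one column per trait, values
#'   in percent.
#' @export
heterosis_table <- function(traits, crosses, trait_cols = TRAIT_COLUMNS) {
  trait_cols <- intersect(trait_cols, names(traits))
  means <- stats::aggregate(traits[trait_cols],
                            by = list(genotype_id = traits$genotype_id),
                            FUN = function(x) mean(x, na.rm = TRUE))
  rownames(means) <- means$genotype_id
  unknown <- setdiff(unlist(crosses[c("hybrid_id", "parent1_id",
                                      "parent2_id")]),
                     means$genotype_id)
  if (length(unknown)) {
    stop("genotype(s) absent from trait table: ",
         paste(unknown, collapse = ", "))
  }
  out <- data.frame(hybrid_id = crosses$hybrid_id, stringsAsFactors = FALSE)
  for (tr in trait_cols) {
    out[[tr]] <- heterosis_pct(means[crosses$hybrid_id, tr],
                               means[crosses$parent1_id, tr],
                               means[crosses$parent2_id, tr])
  }
  out
}

#' Heat tolerance score
#'
#' `HTS = TNF / 10 + YP * 10`: fruit number per plant scaled down, yield
#' per plant (kg) scaled up, so both yield components weigh comparably.
#'
#' @param TNF,YP Numeric vectors.
#' @return Numeric vector; `NA` inputs propagate.
#' @export
hts <- function(TNF, YP) {
  if (any(TNF < 0, na.rm = TRUE) || any(YP < 0, na.rm = TRUE)) {
    stop("TNF and YP must be non-negative")
  }
  TNF / 10 + YP * 10
}

#' Fruit quality score
#'
#' `QS = TA / 0.3 + TSSC / 5.5 + TSSC / (TA * 12.5)`: each quality trait
#' is divided by its bibliographic optimum (0.3 g/100 g acidity, 5.5 Brix
#' solids, 12.5 solids/acidity ratio).
#'
#' @param TSSC Total soluble solids (degrees Brix).
#' @param TA Titratable acidity (g citric acid / 100 g); must be > 0.
#' @return Numeric vector; `NA` inputs propagate.
#' @export
qs <- function(TSSC, TA) {
  bad <- which(!is.na(TA) & TA <= 0)
  if (length(bad)) {
    stop("TA must be positive (division by zero) at position(s): ",
         paste(bad, collapse = ", "))
  }
  TA / 0.3 + TSSC / 5.5 + TSSC / (TA * 12.5)
}

#' Resistance-gene score from marker calls
#'
#' Default counting (`"locus"`): the fraction of assayed genes at which
#' the genotype carries at least one resistant allele (call RR or RS).
#' `"allele"` counts resistant alleles (RR = 2, RS = 1) divided by the
#' number of assayed genes (range \[0, 2\]). `"segregating"` applies locus
#' counting after excluding genes whose calls are identical across all
#' genotypes in `calls` (uninformative, fixed loci).
#'
#' @param calls A `marker_call_table` (long format: `genotype_id`, `gene`,
#'   `call`).
#' @param genotype_id Genotype to score.
#' @param assayed_genes Genes forming the denominator.
#' @param mode Counting convention, see above.
#' @param on_null `"error"` (default) or `"skip"`: how to treat NULL
#'   (failed-assay) calls in the assayed set; `"skip"` drops the gene from
#'   numerator and denominator.
#' @return A single numeric score.
#' @export
rgs <- function(calls, genotype_id, assayed_genes = ASSAYED_GENES,
                mode = c("locus", "allele", "segregating"),
                on_null = c("error", "skip")) {
  mode <- match.arg(mode)
  on_null <- match.arg(on_null)
  if (mode == "segregating") {
    fixed <- vapply(assayed_genes, function(g) {
      length(unique(calls$call[calls$gene == g])) == 1L
    }, logical(1))
    assayed_genes <- assayed_genes[!fixed]
  }
  sub <- calls[calls$genotype_id == genotype_id &
                 calls$gene %in% assayed_genes, ]
  absent <- setdiff(assayed_genes, sub$gene)
  if (length(absent)) {
    stop("no call for gene(s) ", paste(absent, collapse = ", "),
         " in genotype ", genotype_id)
  }
  is_null <- sub$call == "NULL"
  if (any(is_null)) {
    if (on_null == "error") {
      stop("NULL call(s) for ", genotype_id, " at ",
           paste(sub$gene[is_null], collapse = ", "),
           "; set on_null = \"skip\" to drop them")
    }
    sub <- sub[!is_null, ]
  }
  denom <- nrow(sub)
  if (denom == 0L) return(NA_real_)
  num <- switch(mode,
    locus = ,
    segregating = sum(sub$call %in% c("RR", "RS")),
    allele = sum(c(RR = 2, RS = 1, SS = 0)[sub$call]))
  num / denom
}

#' Resistance-gene scores for every genotype in a call table
#'
#' @inheritParams rgs
#' @return `data.frame` with `genotype_id` and `RGS`.
#' @export
rgs_table <- function(calls, assayed_genes = ASSAYED_GENES,
                      mode = c("locus", "allele", "segregating"),
                      on_null = c("error", "skip")) {
  ids <- unique(calls$genotype_id)
  data.frame(
    genotype_id = ids,
    RGS = vapply(ids, function(g) {
      rgs(calls, g, assayed_genes, mode = mode, on_null = on_null)
    }, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Hybrid index: mean thresholds and elite classification
#'
#' Computes per-score mean thresholds over the evaluated hybrid set and
#' flags elite hybrids. The default rule requires a hybrid to exceed the
#' mean threshold strictly on all three scores; `"two_of_three"` and
#' `"hts_qs"` (heat tolerance and quality only) are alternatives.
#' Hybrids missing any score are excluded from the threshold means with a
#' warning and are never flagged elite.
#'
#' @param scores `data.frame` with columns `hybrid_id`, `HTS`, `QS`, `RGS`.
#' @param rule Elite rule, see above.
#' @return An object of class `hybrid_index`: list with `scores` (input
#'   plus logical `elite`) and `thresholds` (named means).
#' @export
hybrid_index <- function(scores, rule = c("all", "two_of_three", "hts_qs")) {
  rule <- match.arg(rule)
  need <- c("hybrid_id", "HTS", "QS", "RGS")
  stopifnot(all(need %in% names(scores)))
  complete <- stats::complete.cases(scores[c("HTS", "QS", "RGS")])
  if (sum(complete) < 2L) stop("need at least 2 hybrids with all three scores")
  if (any(!complete)) {
    warning(sum(!complete), " hybrid(s) with missing scores excluded ",
            "from thresholds: ",
            paste(scores$hybrid_id[!complete], collapse = ", "))
  }
  thresholds <- colMeans(scores[complete, c("HTS", "QS", "RGS")])
  above <- cbind(HTS = scores$HTS > thresholds["HTS"],
                 QS = scores$QS > thresholds["QS"],
                 RGS = scores$RGS > thresholds["RGS"])
  elite <- switch(rule,
    all = rowSums(above) == 3L,
    two_of_three = rowSums(above) >= 2L,
    hts_qs = above[, "HTS"] & above[, "QS"])
  elite[!complete] <- FALSE
  elite[is.na(elite)] <- FALSE
  out <- scores
  out$elite <- elite
  structure(list(scores = out, thresholds = thresholds, rule = rule),
            class = "hybrid_index")
}

#' @export
print.hybrid_index <- function(x, ...) {
  cat("hybrid_index (rule:", x$rule, ")\n")
  cat("thresholds: HTS =", round(x$thresholds["HTS"], 2),
      "QS =", round(x$thresholds["QS"], 2),
      "RGS =", round(x$thresholds["RGS"], 2), "\n")
  cat("elite:", paste(x$scores$hybrid_id[x$scores$elite], collapse = ", "),
      "\n")
  invisible(x)
}

#' Titratable acidity from an NaOH titration
#'
#' `G1 = [NaOH] (N) x vol_NaOH (mL) / m_sample (g) x 1000 / 10`; the
#' citric-acid content is `G1` multiplied by the fixed conversion factor
#' 0.070.
#'
#' @param naoh_normality Titrant concentration in Normality.
#' @param vol_naoh Titrant volume added, mL.
#' @param m_sample Sample mass, g; must be positive.
#' @param ca_factor Citric-acid conversion factor (fixed, 0.070).
#' @return Titratable acidity in g citric acid / 100 g.
#' @export
titratable_acidity <- function(naoh_normality, vol_naoh, m_sample,
                               ca_factor = 0.070) {
  if (any(m_sample <= 0)) stop("m_sample must be positive")
  if (any(vol_naoh < 0)) stop("vol_naoh must be non-negative")
  g1 <- naoh_normality * vol_naoh / m_sample * 1000 / 10
  g1 * ca_factor
}
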