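.config_defaults <- function() {
  list(
    out_dir = "heatcross_run",
    seed = 1L,
    n_loci = 2000L,
    n_reps = 3L,
    trait_sd = 0,
    filter = list(max_missing = 0.5, min_mean_dp = 5),
    si = list(yp_mode = "binned"),
    rgs = list(counting = "locus"),
    elite = list(rule = "all"),
    verbosity = 1L)
}

.merge_config <- function(config) {
  defaults <- .config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  for (nm in names(config)) {
    if (is.list(defaults[[nm]]) && is.list(config[[nm]])) {
      bad <- setdiff(names(config[[nm]]), names(defaults[[nm]]))
      if (length(bad)) {
        stop("unknown config key(s): ",
             paste(paste0(nm, ".", bad), collapse = ", "))
      }
      defaults[[nm]][names(config[[nm]])] <- config[[nm]]
    } else {
      defaults[[nm]] <- config[[nm]]
    }
  }
  defaults
}

.config_hash <- function(config) {
  flat <- paste(deparse(config), collapse = "")
  # small stable rolling hash; avoids external digest dependencies
  h <- 0
  for (ch in utf8ToInt(flat)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.stamp_write <- function(df, path, config_hash, seed) {
  hdr <- sprintf("# heatcross %s; config=%s; seed=%d",
                 as.character(utils::packageVersion("heatcross")),
                 config_hash, seed)
  con <- file(path, "w")
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
}

# Demo parent trait means derived from the packaged parental summary
# classes (fruit-set and yield tolerance classes HH/H/M/L and fruit
# quality H/M/L), mapped to representative values: FS 75/60/40%, YP
# 3.5/2.5/1.5 kg/plant (TNF proportional), TSSC 6.0/5.5/5.0 Brix and TA
# 0.45/0.40/0.35 g/100 g for high/medium/low quality.
.demo_parent_means <- function() {
  cls <- data.frame(
    genotype_id = c("E7", "E11", "E20", "E36", "E42", "E45", "E48", "E55",
                    "E103", "E109", "E111", "LA2662", "LA3120", "PDLUC",
                    "PDVIT"),
    fs = c("HH", "M", "M", "H", "M", "M", "M", "H", "HH", "M", "M", "H",
           "H", "-", "H"),
    yp = c("M", "M", "M", "H", "M", "M", "M", "M", "L", "M", "L", "H",
           "H", "-", "M"),
    quality = c("M", "M", "M", "M", "M", "H", "M", "L", "H", "M", "H",
                "L", "L", "H", "H"),
    stringsAsFactors = FALSE)
  fs_val <- c(HH = 75, H = 60, M = 40, L = 25, "-" = 50)
  yp_val <- c(H = 3.5, M = 2.5, L = 1.5, "-" = 2.5)
  tssc_val <- c(H = 6.0, M = 5.5, L = 5.0, "-" = 5.5)
  ta_val <- c(H = 0.45, M = 0.40, L = 0.35, "-" = 0.40)
  data.frame(
    genotype_id = cls$genotype_id,
    FS = unname(fs_val[cls$fs]),
    TNF = unname(30 * yp_val[cls$yp]),
    FW = 80,
    YP = unname(yp_val[cls$yp]),
    TSSC = unname(tssc_val[cls$quality]),
    TA = unname(ta_val[cls$quality]),
    stringsAsFactors = FALSE)
}

#' Run the full breeding-evaluation pipeline on packaged and synthetic data
#'
#' Executes the stages of the hybrid-selection workflow end to end:
#' genotype-matrix filtering and identity-by-state distances (on a seeded
#' synthetic matrix), resistance-gene scan and impact tally (on the
#' packaged variant catalog), synthetic trait generation with the
#' packaged heterosis values planted as effects, selection indices and
#' recovered heterosis, marker-template simulation with virtual
#' PCR/digest genotype calls, resistance-gene scores, and the final
#' hybrid index with elite classification. Stages communicate via files
#' in `out_dir`; every output carries the tool version, a config hash and
#' the seed, so a rerun with the same config is byte-identical.
#'
#' @param config Named list overriding the defaults (`out_dir`, `seed`,
#'   `n_loci`, `n_reps`, `trait_sd`, `filter$max_missing`,
#'   `filter$min_mean_dp`, `si$yp_mode`, `rgs$counting`, `elite$rule`,
#'   `verbosity`). Unknown keys are rejected.
#' @return Invisibly, a list with the principal in-memory results
#'   (`ibs`, `prg`, `impact`, `si`, `heterosis`, `marker_calls`,
#'   `hybrid_index`) and `out_dir`.
#' @export
run_full_pipeline <- function(config = list()) {
  cfg <- .merge_config(config)
  seed <- as.integer(cfg$seed)
  # hash over the scientific configuration only, so identical analyses in
  # different output directories stamp identical headers
  hash <- .config_hash(cfg[setdiff(names(cfg), c("out_dir", "verbosity"))])
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (cfg$verbosity > 0) message("[heatcross] ", ...)
  writeLines(paste(deparse(cfg), collapse = "\n"),
             file.path(cfg$out_dir, "config_echo.txt"))

  stage <- "genotype filtering"
  result <- tryCatch({
    say("stage: simulate + filter genotype matrix (", cfg$n_loci, " loci)")
    targets <- c(0.95, 0.92, 0.54, 0.90)
    gm <- gen_genotype_matrix(n_samples = 5L, n_loci = cfg$n_loci,
                              target_similarity = targets,
                              missing_rate = 0.1, depth_mean = 20,
                              seed = seed)
    gmf <- filter_variants(gm, cfg$filter$max_missing, cfg$filter$min_mean_dp)
    say("  loci in: ", ncol(gm$calls), "; surviving: ", ncol(gmf$calls))

    stage <- "IBS"
    say("stage: identity-by-state matrix")
    ibs <- ibs_matrix(gmf)
    .stamp_write(as.data.frame(unclass(ibs)[, ]),
                 file.path(cfg$out_dir, "ibs_matrix.tsv"), hash, seed)

    stage <- "resistance-gene scan"
    say("stage: resistance-gene catalog scan + impact tally")
    catalog <- load_fixture("table1")
    prg <- prg_scan_fixture(catalog)
    .stamp_write(prg, file.path(cfg$out_dir, "prg_scan.tsv"), hash, seed)
    # one HIGH SNP per flagged gene; remaining catalog SNPs are MODERATE
    n_high <- sum(catalog$high_impact %in% TRUE)
    total <- attr(prg, "total_snps")
    classes <- c(rep("HIGH", n_high), rep("MODERATE", total - n_high))
    impact <- impact_tally(classes)
    .stamp_write(impact, file.path(cfg$out_dir, "impact_tally.tsv"),
                 hash, seed)

    stage <- "trait simulation"
    say("stage: synthetic traits with planted heterosis")
    crosses <- load_fixture("crosses")
    het_planted <- load_fixture("table3")
    het_planted$TSSC_TA <- NULL
    parent_means <- .demo_parent_means()
    parent_means <- parent_means[parent_means$genotype_id %in%
                                   unique(c(crosses$parent1_id,
                                            crosses$parent2_id)), ]
    traits <- gen_trait_table(parent_means, crosses,
                              het_planted[c("hybrid_id", "TNF", "FW", "YP",
                                            "TSSC", "TA")],
                              sd = cfg$trait_sd, n_reps = cfg$n_reps,
                              seed = seed)
    si_tab <- selection_index_table(traits, yp_mode = cfg$si$yp_mode)
    .stamp_write(si_tab, file.path(cfg$out_dir, "selection_index.tsv"),
                 hash, seed)
    het_rec <- heterosis_table(traits, crosses,
                               c("TNF", "FW", "YP", "TSSC", "TA"))
    .stamp_write(het_rec, file.path(cfg$out_dir, "heterosis.tsv"),
                 hash, seed)

    stage <- "marker assays"
    say("stage: marker template simulation + genotype calling")
    fixtures <- lapply(c("Sw-5", "Ve-1"), function(m) {
      gen_marker_templates(marker_fixture_spec(m), seed = seed)
    })
    call_rows <- do.call(rbind, lapply(fixtures, function(fx) {
      obs_r <- fx$assay$R; obs_s <- fx$assay$S
      data.frame(marker = fx$marker,
                 R_template_call = call_genotype(obs_r, fx$assay),
                 S_template_call = call_genotype(obs_s, fx$assay),
                 het_call = call_genotype(
                   union(obs_r$fragment_lengths, obs_s$fragment_lengths),
                   fx$assay),
                 stringsAsFactors = FALSE)
    }))
    .stamp_write(call_rows, file.path(cfg$out_dir, "marker_calls.tsv"),
                 hash, seed)

    stage <- "hybrid index"
    say("stage: resistance scores + hybrid index")
    hyb_calls <- load_fixture("hybrid_calls")
    rgs_tab <- rgs_table(hyb_calls, mode = cfg$rgs$counting)
    means <- stats::aggregate(
      traits[c("TNF", "YP", "TSSC", "TA")],
      by = list(hybrid_id = traits$genotype_id), FUN = mean)
    means <- means[means$hybrid_id %in% crosses$hybrid_id, ]
    scores <- data.frame(
      hybrid_id = means$hybrid_id,
      HTS = hts(means$TNF, means$YP),
      QS = qs(means$TSSC, means$TA),
      stringsAsFactors = FALSE)
    scores <- merge(scores,
                    stats::setNames(rgs_tab, c("hybrid_id", "RGS")),
                    by = "hybrid_id")
    if (nrow(scores) < 2L) {
      warning("fewer than two hybrids with complete scores; ",
              "hybrid-index stage skipped")
      hi <- NULL
    } else {
      hi <- hybrid_index(scores, rule = cfg$elite$rule)
      .stamp_write(hi$scores, file.path(cfg$out_dir, "hybrid_index.tsv"),
                   hash, seed)
      .stamp_write(
        data.frame(score = names(hi$thresholds),
                   threshold = unname(hi$thresholds)),
        file.path(cfg$out_dir, "thresholds.tsv"), hash, seed)
      say("  elite hybrids: ",
          paste(hi$scores$hybrid_id[hi$scores$elite], collapse = ", "))
    }

    list(ibs = ibs, prg = prg, impact = impact, si = si_tab,
         heterosis = het_rec, marker_calls = call_rows,
         hybrid_index = hi, out_dir = cfg$out_dir)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
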