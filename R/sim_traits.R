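.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a trait table with planted mid-parent heterosis
#'
#' For each cross and trait, the F1 expectation is
#' `midparent * (1 + e/100)` where `e` is the planted heterosis percent;
#' replicate noise is additive Gaussian truncated at zero (traits are
#' non-negative; fruit set is additionally capped at 100). With zero
#' noise, [heterosis_pct()] on the generated table recovers the planted
#' effects exactly.
#'
#' Defaults mirror the field design the package models: three replicates
#' per genotype in one environment.
#'
#' @param parent_means `data.frame` with `genotype_id` and trait columns
#'   (any subset of [TRAIT_COLUMNS]); one row per parent.
#' @param crosses A `cross_design` table (or data.frame with `hybrid_id`,
#'   `parent1_id`, `parent2_id`).
#' @param heterosis `data.frame` with `hybrid_id` and planted heterosis
#'   percentages per trait column (traits absent default to 0).
#' @param sd Replicate noise standard deviation: scalar or named per
#'   trait.
#' @param n_reps Replicates per genotype (>= 1).
#' @param environment Environment label stamped on all rows.
#' @param year Year stamped on all rows.
#' @param seed Random seed (required; generation is pure in `(spec, seed)`).
#' @return A `trait_table` with parent and hybrid replicate rows; the
#'   `truth` attribute holds the planted per-hybrid expectations and
#'   heterosis.
#' @export
gen_trait_table <- function(parent_means, crosses, heterosis, sd = 0,
                            n_reps = 3L, environment = "SYN", year = 2019L,
                            seed) {
  stopifnot(n_reps >= 1L, all(sd >= 0))
  trait_cols <- intersect(TRAIT_COLUMNS, names(parent_means))
  if (!length(trait_cols)) stop("parent_means has no trait columns")
  if (any(unlist(parent_means[trait_cols]) < 0, na.rm = TRUE)) {
    stop("parent trait means must be non-negative")
  }
  sd_of <- function(tr) {
    if (length(sd) == 1L && is.null(names(sd))) sd else
      if (tr %in% names(sd)) sd[[tr]] else 0
  }
  rownames(parent_means) <- parent_means$genotype_id
  unknown <- setdiff(c(crosses$parent1_id, crosses$parent2_id),
                     parent_means$genotype_id)
  if (length(unknown)) stop("parents without means: ",
                            paste(unknown, collapse = ", "))

  expectations <- rbind(
    data.frame(genotype_id = parent_means$genotype_id,
               parent_means[trait_cols], stringsAsFactors = FALSE,
               row.names = NULL),
    do.call(rbind, lapply(seq_len(nrow(crosses)), function(i) {
      h <- crosses$hybrid_id[i]
      pm <- (parent_means[crosses$parent1_id[i], trait_cols] +
               parent_means[crosses$parent2_id[i], trait_cols]) / 2
      e <- vapply(trait_cols, function(tr) {
        row <- heterosis[heterosis$hybrid_id == h, , drop = FALSE]
        if (nrow(row) && tr %in% names(row)) row[[tr]][1] else 0
      }, numeric(1))
      out <- data.frame(genotype_id = h, stringsAsFactors = FALSE)
      for (tr in trait_cols) out[[tr]] <- pm[[tr]] * (1 + e[[tr]] / 100)
      out
    })))

  rows <- .with_seed(seed, {
    do.call(rbind, lapply(seq_len(nrow(expectations)), function(i) {
      reps <- do.call(rbind, lapply(seq_len(n_reps), function(r) {
        row <- data.frame(genotype_id = expectations$genotype_id[i],
                          environment = environment, year = year,
                          replicate = r, stringsAsFactors = FALSE)
        for (tr in trait_cols) {
          v <- expectations[[tr]][i] + stats::rnorm(1, 0, sd_of(tr))
          v <- max(0, v)
          if (tr == "FS") v <- min(100, v)
          row[[tr]] <- v
        }
        row
      }))
      reps
    }))
  })
  validate_trait_table(rows)
  class(rows) <- c("trait_table", "data.frame")
  attr(rows, "truth") <- list(expectations = expectations,
                              heterosis = heterosis, sd = sd,
                              n_reps = n_reps, seed = seed)
  rows
}
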