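#' Generate a genotype matrix with controlled pairwise similarity
#'
#' The first sample is a base (near-)homozygous haplotype with dosages in
#' `{0, 2}`; every other sample is derived from it by independent
#' per-locus dosage flips (0 <-> 2) with probability `1 - target`, so the
#' expected dosage-sharing IBS against the base equals the target. Under
#' independent flips the implied similarity between two derived samples
#' `i, j` is `(1 - f_i)(1 - f_j) + f_i f_j`; when a full target matrix is
#' supplied, entries incompatible with that relation (beyond
#' `infeasible_tol`) raise a generation error naming the pair.
#' Heterozygous calls, missingness and per-site depth are planted on top.
#'
#' Generation is a pure function of its arguments and `seed`.
#'
#' @param n_samples,n_loci Dimensions.
#' @param target_similarity Scalar (all samples vs the base), vector of
#'   length `n_samples - 1`, or full symmetric matrix of targets in
#'   \[0, 1\].
#' @param missing_rate Per-call missingness probability.
#' @param het_rate Probability a call is recoded heterozygous (inbred
#'   lines are near-homozygous, so the default is 0).
#' @param depth_mean Mean per-site depth (Poisson); `NULL` for no depth.
#' @param infeasible_tol Tolerance for the target-matrix feasibility check.
#' @param seed Random seed.
#' @return A [genotype_matrix()]; the `truth` attribute records the flip
#'   fractions and targets.
#' @export
gen_genotype_matrix <- function(n_samples, n_loci, target_similarity = 0.95,
                                missing_rate = 0, het_rate = 0,
                                depth_mean = 20, infeasible_tol = 0.05,
                                seed) {
  stopifnot(n_samples >= 2L, n_loci >= 1L,
            missing_rate >= 0, missing_rate < 1, het_rate >= 0, het_rate <= 1)
  ts <- target_similarity
  if (is.matrix(ts)) {
    stopifnot(nrow(ts) == n_samples, ncol(ts) == n_samples)
    if (any(ts < 0 | ts > 1)) stop("target similarities must lie in [0, 1]")
    f <- 1 - ts[1, ]
    for (i in 2:n_samples) {
      for (j in seq_len(n_samples)[-seq_len(i)]) {
        implied <- (1 - f[i]) * (1 - f[j]) + f[i] * f[j]
        if (abs(implied - ts[i, j]) > infeasible_tol) {
          stop("infeasible similarity for pair (", i, ", ", j, "): target ",
               ts[i, j], " vs implied ", round(implied, 4))
        }
      }
    }
  } else {
    if (any(ts < 0 | ts > 1)) stop("target similarities must lie in [0, 1]")
    f <- c(0, rep_len(1 - ts, n_samples - 1L))
  }
  out <- .with_seed(seed, {
    base <- sample(c(0L, 2L), n_loci, replace = TRUE)
    calls <- matrix(NA_integer_, n_samples, n_loci)
    calls[1, ] <- base
    for (i in 2:n_samples) {
      flip <- stats::runif(n_loci) < f[i]
      calls[i, ] <- ifelse(flip, 2L - base, base)
    }
    if (het_rate > 0) {
      het <- matrix(stats::runif(length(calls)) < het_rate,
                    n_samples, n_loci)
      calls[het] <- 1L
    }
    if (missing_rate > 0) {
      calls[matrix(stats::runif(length(calls)) < missing_rate,
                   n_samples, n_loci)] <- NA_integer_
    }
    rownames(calls) <- paste0("S", seq_len(n_samples))
    pos <- sort(sample.int(n_loci * 100L, n_loci))
    ref <- sample(c("A", "C", "G", "T"), n_loci, replace = TRUE)
    alt <- vapply(ref, function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
    loci <- data.frame(chrom = "ch01", pos = pos, ref = ref, alt = alt,
                       stringsAsFactors = FALSE)
    depth <- if (is.null(depth_mean)) NULL else
      stats::rpois(n_loci, depth_mean)
    genotype_matrix(calls, loci, depth)
  })
  attr(out, "truth") <- list(flip_fraction = f,
                             target_similarity = target_similarity,
                             missing_rate = missing_rate,
                             het_rate = het_rate, seed = seed)
  out
}
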