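#' Define a PCR primer pair
#'
#' Primers are plain A/C/G/T strings, written 5' to 3'. A dCAPS-style
#' engineered mismatch is recorded as metadata so that virtual PCR can
#' bind the primer at its genomic site (the template base at the
#' engineered position is allowed to disagree) while the product carries
#' the engineered base.
#'
#' @param forward,reverse Primer sequences, 5'->3', length >= 15.
#' @param engineered_mismatch Optional list with elements `primer`
#'   (`"forward"` or `"reverse"`), `position` (1-based from the primer's
#'   5' end), `original` and `introduced` (single bases).
#' @param target_gene Optional gene name.
#' @return Object of class `primer_pair`.
#' @export
primer_pair <- function(forward, reverse, engineered_mismatch = NULL,
                        target_gene = NA_character_) {
  forward <- toupper(forward); reverse <- toupper(reverse)
  for (p in c(forward, reverse)) {
    if (!grepl("^[ACGT]+$", p)) stop("primers must contain only A/C/G/T")
    if (nchar(p) < 15L) stop("primers must be at least 15 nt long")
  }
  if (!is.null(engineered_mismatch)) {
    em <- engineered_mismatch
    stopifnot(all(c("primer", "position", "original", "introduced")
                  %in% names(em)))
    em$primer <- match.arg(em$primer, c("forward", "reverse"))
    plen <- nchar(if (em$primer == "forward") forward else reverse)
    if (em$position < 1L || em$position > plen) {
      stop("engineered mismatch position outside primer")
    }
    target <- if (em$primer == "forward") forward else reverse
    if (substr(target, em$position, em$position) != em$introduced) {
      stop("primer base at engineered position does not equal the ",
           "introduced base")
    }
    engineered_mismatch <- em
  }
  structure(list(forward = forward, reverse = reverse,
                 engineered_mismatch = engineered_mismatch,
                 target_gene = target_gene),
            class = "primer_pair")
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

.binding_probe <- function(primers, which) {
  # the probe used to locate the binding site: engineered base reverted
  p <- if (which == "forward") primers$forward else primers$reverse
  em <- primers$engineered_mismatch
  if (!is.null(em) && em$primer == which) {
    substr(p, em$position, em$position) <- em$original
  }
  p
}

.amplicon <- function(sequence, template_start, template_end) {
  stopifnot(nchar(sequence) == template_end - template_start + 1L)
  structure(list(sequence = sequence, template_start = template_start,
                 template_end = template_end, length = nchar(sequence)),
            class = "amplicon")
}

#' @export
print.amplicon <- function(x, ...) {
  cat("amplicon:", x$length, "bp, template", x$template_start, "-",
      x$template_end, "\n")
  invisible(x)
}

#' A no-product PCR result carrying diagnostic detail
#'
#' @param diagnostic Character vector explaining why no product formed.
#' @return Object of class `pcr_failure`.
#' @export
pcr_failure <- function(diagnostic) {
  structure(list(diagnostic = diagnostic), class = "pcr_failure")
}

#' @rdname pcr_failure
#' @param x Object to test.
#' @export
is_pcr_failure <- function(x) inherits(x, "pcr_failure")

#' @export
print.pcr_failure <- function(x, ...) {
  cat("no PCR product:", paste(x$diagnostic, collapse = "; "), "\n")
  invisible(x)
}

#' Virtual PCR on a template sequence
#'
#' The forward primer is matched on the plus strand and the reverse primer
#' on the minus strand (its reverse complement on the plus strand),
#' allowing up to `max_binding_mismatches` mismatches. An engineered dCAPS
#' mismatch recorded on the primer pair is tolerated by construction: the
#' site is located with the original base, and the product carries the
#' engineered one. The product is the forward primer, the intervening
#' template, and the reverse complement of the reverse primer.
#'
#' With no binding site for either primer the result is a [pcr_failure()]
#' naming the primer(s) that failed. A primer pair whose only placements
#' overlap or are inverted is an error. Multiple products are all
#' returned, with a warning.
#'
#' @param template DNA sequence (character or `DNAString`).
#' @param primers A [primer_pair()].
#' @param max_binding_mismatches Mismatch budget per primer (default 0,
#'   exact binding).
#' @return An `amplicon`, a list of amplicons (multi-product), or a
#'   [pcr_failure()].
#' @export
in_silico_pcr <- function(template, primers, max_binding_mismatches = 0L) {
  subject <- .as_dna_string(template)
  if (length(subject) == 0L) stop("template must be non-empty")
  fwd <- .binding_probe(primers, "forward")
  rev_rc <- .revcomp(.binding_probe(primers, "reverse"))
  fm <- Biostrings::matchPattern(Biostrings::DNAString(fwd), subject,
                                 max.mismatch = max_binding_mismatches)
  rm_ <- Biostrings::matchPattern(Biostrings::DNAString(rev_rc), subject,
                                  max.mismatch = max_binding_mismatches)
  f_starts <- BiocGenerics::start(fm)
  r_ends <- BiocGenerics::end(rm_)
  r_starts <- BiocGenerics::start(rm_)
  if (!length(f_starts) || !length(r_starts)) {
    diag <- c(if (!length(f_starts)) "forward primer has no binding site",
              if (!length(r_starts)) "reverse primer has no binding site")
    return(pcr_failure(diag))
  }
  tmpl <- as.character(subject)
  lf <- nchar(primers$forward)
  products <- list()
  n_overlapping <- 0L
  for (f in f_starts) {
    for (j in seq_along(r_starts)) {
      rs <- r_starts[j]; re <- r_ends[j]
      if (rs <= f + lf - 1L) {              # overlapping or inverted
        n_overlapping <- n_overlapping + 1L
        next
      }
      mid <- substr(tmpl, f + lf, rs - 1L)
      seqn <- paste0(primers$forward, mid, .revcomp(primers$reverse))
      products[[length(products) + 1L]] <- .amplicon(seqn, f, re)
    }
  }
  if (!length(products)) {
    if (n_overlapping > 0L) {
      stop("primer placements overlap or are inverted; no valid product")
    }
    return(pcr_failure("no compatible primer placement"))
  }
  if (length(products) > 1L) {
    warning("multiple PCR products (", length(products), ")")
    return(products)
  }
  products[[1L]]
}

#' Nested PCR: an outer amplification followed by an inner one
#'
#' The inner pair must bind within the outer amplicon; inner products
#' located on the template outside the outer amplicon raise a specificity
#' error. Inner amplicon coordinates are reported both relative to the
#' outer amplicon and to the original template.
#'
#' @param template DNA sequence.
#' @param outer,inner [primer_pair()] objects.
#' @param max_binding_mismatches Passed to both amplifications.
#' @return The inner `amplicon`; attributes `outer` (the outer amplicon)
#'   and `template_coords` (inner start/end on the original template).
#' @export
nested_pcr <- function(template, outer, inner, max_binding_mismatches = 0L) {
  a1 <- in_silico_pcr(template, outer, max_binding_mismatches)
  if (is_pcr_failure(a1)) stop("outer pair produced no amplicon: ",
                               paste(a1$diagnostic, collapse = "; "))
  if (!inherits(a1, "amplicon")) stop("outer pair produced multiple products")
  direct <- suppressWarnings(in_silico_pcr(template, inner,
                                           max_binding_mismatches))
  direct_list <- if (is_pcr_failure(direct)) list() else
    if (inherits(direct, "amplicon")) list(direct) else direct
  for (d in direct_list) {
    if (d$template_start < a1$template_start ||
        d$template_end > a1$template_end) {
      stop("inner pair binds the template outside the outer amplicon ",
           "(specificity failure)")
    }
  }
  a2 <- suppressWarnings(in_silico_pcr(a1$sequence, inner,
                                       max_binding_mismatches))
  if (is_pcr_failure(a2)) stop("inner pair does not bind within the outer ",
                               "amplicon")
  if (!inherits(a2, "amplicon")) stop("inner pair produced multiple ",
                                      "products within the outer amplicon")
  attr(a2, "outer") <- a1
  attr(a2, "template_coords") <- c(
    start = a1$template_start + a2$template_start - 1L,
    end = a1$template_start + a2$template_end - 1L)
  a2
}
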