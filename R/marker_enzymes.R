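IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

.iupac_match <- function(base, code) {
  base %in% IUPAC_CODES[[code]]
}

#' Define a restriction enzyme
#'
#' @param name Enzyme name.
#' @param recognition Recognition site as an IUPAC string (e.g. `"CTNAG"`).
#' @param cut_offset Number of bases after the recognition start, on the
#'   scanned strand, at which the enzyme cuts (`"C/TNAG"` has offset 1).
#' @return An object of class `enzyme`.
#' @export
enzyme <- function(name, recognition, cut_offset) {
  recognition <- toupper(recognition)
  if (!all(strsplit(recognition, "")[[1]] %in% names(IUPAC_CODES))) {
    stop("recognition site must contain IUPAC codes only: ", recognition)
  }
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0L || cut_offset > nchar(recognition)) {
    stop("cut_offset must lie within [0, ", nchar(recognition), "]")
  }
  structure(list(name = name, recognition = recognition,
                 cut_offset = cut_offset),
            class = "enzyme")
}

#' @export
print.enzyme <- function(x, ...) {
  site <- paste0(substr(x$recognition, 1, x$cut_offset), "^",
                 substr(x$recognition, x$cut_offset + 1,
                        nchar(x$recognition)))
  cat("enzyme", x$name, ":", site, "\n")
  invisible(x)
}

#' Load a restriction-enzyme catalog
#'
#' The packaged catalog ships Hpy188I (`TCN^GA`) and DdeI (`C^TNAG`) used
#' by the CAPS/dCAPS assays, plus a small panel of common cutters for
#' design searches. A custom catalog may be supplied as a delimited file
#' with columns `name`, `recognition`, `cut_offset`.
#'
#' @param path Optional path to a custom catalog file.
#' @return Named list of [enzyme()] objects.
#' @export
enzyme_catalog <- function(path = NULL) {
  if (is.null(path)) path <- .fixture_path("enzymes.tsv")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "recognition", "cut_offset") %in% names(df)))
  stats::setNames(
    lapply(seq_len(nrow(df)), function(i) {
      enzyme(df$name[i], df$recognition[i], df$cut_offset[i])
    }),
    df$name)
}
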