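#' Tags-per-million normalization with zero revision
#'
#' TPM = count / N * 10^6 where N is the library's total clean-read count
#' (whole-library, not the miRNA-mapped total). Cells whose normalized value
#' is zero are revised to 0.01 so that log ratios stay finite.
#'
#' @param expr a `mir_expr` (from [quantify_known_mirnas()] or [mir_expr()]).
#' @return the same object with the `tpm` layer populated.
#' @export
tpm_normalize <- function(expr) {
  stopifnot(inherits(expr, "mir_expr"))
  meta <- expr$meta
  missing <- setdiff(colnames(expr$counts), meta$library_id)
  if (length(missing)) {
    stop("no metadata for library: ", paste(missing, collapse = ", "))
  }
  N <- stats::setNames(meta$total_reads, meta$library_id)[colnames(expr$counts)]
  if (any(N <= 0)) stop("library total clean reads must be positive")
  tpm <- sweep(expr$counts, 2, N, "/") * 1e6
  tpm[tpm == 0] <- 0.01
  expr$tpm <- tpm
  expr
}

#' High-expression filter defining the analysis universe
#'
#' Retains exactly the miRNAs whose TPM strictly exceeds `threshold` in at
#' least one library (the printed inequality is strict, so a miRNA peaking at
#' exactly the threshold is removed). Row order is preserved.
#'
#' @param expr a TPM-normalized `mir_expr`.
#' @param threshold TPM cutoff (default 28).
#' @return filtered `mir_expr`, with a `filter` attribute recording the
#'   threshold and the number of rows removed.
#' @export
high_expression_filter <- function(expr, threshold = 28) {
  stopifnot(inherits(expr, "mir_expr"))
  if (is.null(expr$tpm)) stop("TPM layer not populated; run tpm_normalize()")
  if (threshold < 0) stop("threshold must be non-negative")
  keep <- apply(expr$tpm, 1, max) > threshold
  out <- expr
  out$counts <- expr$counts[keep, , drop = FALSE]
  out$tpm <- expr$tpm[keep, , drop = FALSE]
  attr(out, "filter") <- list(threshold = threshold,
                              removed = sum(!keep), kept = sum(keep))
  out
}

#' Construct an expression container from a count matrix and metadata
#'
#' @param counts miRNA x library integer matrix.
#' @param meta data.frame with library_id, breed, stage, total_reads.
#' @return a `mir_expr` object.
#' @export
mir_expr <- function(counts, meta) {
  stopifnot(is.matrix(counts), all(counts >= 0),
            all(c("library_id", "breed", "stage", "total_reads") %in%
                  names(meta)))
  if (anyDuplicated(paste(meta$breed, meta$stage))) {
    stop("(breed, stage) must be unique across libraries")
  }
  structure(list(counts = counts, tpm = NULL, meta = meta),
            class = "mir_expr")
}

#' @export
print.mir_expr <- function(x, ...) {
  cat("mir_expr:", nrow(x$counts), "miRNAs x", ncol(x$counts), "libraries;",
      if (is.null(x$tpm)) "raw counts only" else "TPM layer present", "\n")
  invisible(x)
}

# per-breed stage-trajectory TPM matrix (miRNA x stage), columns ordered by
# stage; shared by the time-series and network stages.
stage_matrix <- function(expr, breed) {
  meta <- expr$meta[expr$meta$breed == breed, , drop = FALSE]
  meta <- meta[order(meta$stage), , drop = FALSE]
  m <- expr$tpm[, meta$library_id, drop = FALSE]
  colnames(m) <- as.character(meta$stage)
  m
}
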