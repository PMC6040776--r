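#' Reverse complement of DNA character strings
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences (A/C/G/T).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Write a collapsed tag library as FASTA
#'
#' Headers follow the `tag<serial>_x<count>` dialect used for deduplicated
#' small RNA reads, e.g. `>tag000001_x532`.
#'
#' @param tags named integer vector: names are tag sequences, values counts.
#' @param path output file.
#' @export
write_tag_fasta <- function(tags, path) {
  stopifnot(is.numeric(tags), !is.null(names(tags)))
  ids <- sprintf("tag%06d_x%d", seq_along(tags), as.integer(tags))
  seqs <- Biostrings::DNAStringSet(names(tags))
  names(seqs) <- ids
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Read a collapsed tag library FASTA
#'
#' Parses the `<id>_x<count>` header dialect back into a named count vector.
#'
#' @param path FASTA file written by [write_tag_fasta()] or any collapsed-read
#'   FASTA whose headers end in `_x<count>`.
#' @return named integer vector (names = tag sequences, values = counts).
#' @export
read_tag_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  m <- regmatches(names(seqs), regexpr("_x([0-9]+)$", names(seqs)))
  if (length(m) != length(seqs)) {
    stop("every FASTA header must end in the collapsed-count suffix '_x<count>'")
  }
  counts <- as.integer(sub("_x", "", m))
  stats::setNames(counts, as.character(seqs))
}

#' Write feature intervals as BED
#'
#' Coordinates are 0-based half-open throughout the package, so intervals are
#' written verbatim. The feature category goes in the BED name column.
#'
#' @param features data.frame with columns chrom, start, end, category, strand
#'   (and optionally name).
#' @param path output file.
#' @export
write_features_bed <- function(features, path) {
  name <- if ("name" %in% names(features)) {
    paste(features$category, features$name, sep = "|")
  } else {
    features$category
  }
  bed <- data.frame(chrom = features$chrom, start = features$start,
                    end = features$end, name = name, score = 0L,
                    strand = features$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read feature intervals from BED
#'
#' @param path BED file written by [write_features_bed()].
#' @return data.frame with chrom, start, end, category, name, strand
#'   (0-based half-open).
#' @export
read_features_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand"))
  parts <- strsplit(bed$name, "|", fixed = TRUE)
  data.frame(chrom = bed$chrom, start = bed$start, end = bed$end,
             category = vapply(parts, `[`, "", 1L),
             name = vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, ""),
             strand = bed$strand, stringsAsFactors = FALSE)
}

#' Write a numeric expression matrix as TSV
#'
#' Row names in the first column (`id`), library ids as the header row.
#'
#' @param mat numeric matrix with row and column names.
#' @param path output file.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix TSV written by [write_matrix_tsv()]
#'
#' @param path TSV file.
#' @return numeric matrix with row and column names.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}

# extract a genome subsequence, 0-based half-open; '-' strand returns the
# reverse complement (the tag-sense sequence).
extract_seq <- function(annotation, chrom, start, end, strand = "+") {
  s <- substr(annotation$chromosomes[[chrom]], start + 1L, end)
  if (strand == "-") revcomp(s) else s
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}
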