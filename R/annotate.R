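#' Preprocess collapsed tags
#'
#' Applies the clean-read rules to an adaptor-trimmed collapsed tag set: tags
#' shorter than 18 nt are eliminated, as are tags containing characters
#' outside A/C/G/T; counts of the survivors are preserved.
#'
#' @param raw named integer vector (names = tag sequences, values = counts).
#' @return named integer vector of surviving tags, with a `length_histogram`
#'   attribute (per-length total counts).
#' @export
preprocess_tags <- function(raw) {
  if (length(raw) == 0) {
    warning("empty tag set")
    out <- integer(0)
    attr(out, "length_histogram") <- integer(0)
    return(out)
  }
  stopifnot(!is.null(names(raw)))
  seqs <- toupper(names(raw))
  ok <- nchar(seqs) >= 18L & !grepl("[^ACGT]", seqs)
  out <- stats::setNames(as.integer(raw[ok]), seqs[ok])
  len <- nchar(names(out))
  hist <- tapply(out, len, sum)
  attr(out, "length_histogram") <- stats::setNames(as.integer(hist),
                                                   names(hist))
  out
}

#' Map tags to the genome by exact full-length match
#'
#' Every exact occurrence of each tag on either strand is reported; a
#' minus-strand hit means the tag equals the reverse complement of the genome
#' interval. Matching is exact (no mismatches, no gaps). Coordinates are
#' 0-based half-open.
#'
#' @param tags character vector of unique tag sequences (or a named count
#'   vector, in which case names are used).
#' @param annotation a `genome_annotation`.
#' @return list with `hits` (data.frame: tag, chrom, start, end, strand) and
#'   `unmapped` (character vector of tags without any hit).
#' @export
map_tags <- function(tags, annotation) {
  if (!is.character(tags)) tags <- names(tags)
  tags <- unique(tags)
  chrom_set <- Biostrings::DNAStringSet(unlist(annotation$chromosomes))
  hit_list <- list()
  by_len <- split(tags, nchar(tags))
  for (grp in by_len) {
    fwd <- Biostrings::PDict(Biostrings::DNAStringSet(grp))
    rev <- Biostrings::PDict(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(grp)))
    for (chrom in names(annotation$chromosomes)) {
      subject <- chrom_set[[chrom]]
      for (strand in c("+", "-")) {
        pd <- if (strand == "+") fwd else rev
        m <- Biostrings::matchPDict(pd, subject)
        n_per <- S4Vectors::elementNROWS(m)
        if (sum(n_per) == 0) next
        ir <- unlist(m)
        hit_list[[length(hit_list) + 1L]] <- data.frame(
          tag = rep(grp, n_per),
          chrom = chrom,
          start = IRanges::start(ir) - 1L,
          end = IRanges::end(ir),
          strand = strand,
          stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (length(hit_list)) do.call(rbind, hit_list) else
    data.frame(tag = character(0), chrom = character(0), start = integer(0),
               end = integer(0), strand = character(0))
  rownames(hits) <- NULL
  list(hits = hits, unmapped = setdiff(tags, hits$tag))
}

#' Assign each mapped tag a single annotation category
#'
#' Applies the priority rule rRNAetc(GenBank) > rRNAetc(Rfam) > known miRNA >
#' repeat > exon > intron across all of a tag's hits: the tag receives the
#' highest-priority category among the features any hit overlaps. miRNA
#' assignment is strand-specific; all other categories match on either strand
#' (repeat and rRNA-class annotations are commonly unstranded). Mapped tags
#' overlapping nothing are labelled `"unann"`.
#'
#' @param hits hit table from [map_tags()].
#' @param annotation a `genome_annotation`.
#' @return data.frame with columns tag, category (one row per mapped tag).
#' @export
annotate_tags <- function(hits, annotation) {
  feats <- annotation$features
  bad <- setdiff(unique(feats$category), PRIORITY_CATEGORIES)
  if (length(bad)) {
    stop("unknown annotation category: ", paste(bad, collapse = ", "))
  }
  tags <- unique(hits$tag)
  prio <- stats::setNames(rep(length(PRIORITY_CATEGORIES) + 1L, length(tags)),
                          tags)
  for (chrom in unique(hits$chrom)) {
    h <- hits[hits$chrom == chrom, , drop = FALSE]
    f <- feats[feats$chrom == chrom, , drop = FALSE]
    if (nrow(h) == 0 || nrow(f) == 0) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(h$start + 1L, h$end),
      IRanges::IRanges(f$start + 1L, f$end))
    if (length(ov) == 0) next
    qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
    cat <- f$category[si]
    strand_ok <- cat != "known_miRNA" | f$strand[si] == h$strand[qi]
    keep <- which(strand_ok)
    for (j in keep) {
      tg <- h$tag[qi[j]]
      p <- match(cat[j], PRIORITY_CATEGORIES)
      if (p < prio[tg]) prio[tg] <- p
    }
  }
  data.frame(tag = tags,
             category = c(PRIORITY_CATEGORIES, "unann")[prio],
             stringsAsFactors = FALSE)
}

#' Per-library annotation category count table
#'
#' Distributes each library's tag counts over the annotation categories
#' (plus `"unann"` for mapped-but-unannotated and `"unmapped"` tags), the
#' composition summary usually drawn as a small RNA annotation pie.
#'
#' @param annot annotation table from [annotate_tags()].
#' @param mapping result of [map_tags()] (for the unmapped set).
#' @param libraries named list of `list(meta, tags)`.
#' @return data.frame: library_id, category, tags (unique), reads (counts).
#' @export
annotation_summary <- function(annot, mapping, libraries) {
  cat_of <- stats::setNames(annot$category, annot$tag)
  rows <- list()
  cats <- c(PRIORITY_CATEGORIES, "unann", "unmapped")
  for (lib in names(libraries)) {
    tags <- libraries[[lib]]$tags
    cc <- cat_of[names(tags)]
    cc[is.na(cc)] <- "unmapped"
    reads <- tapply(tags, factor(cc, levels = cats), sum)
    ntags <- tapply(rep(1L, length(tags)), factor(cc, levels = cats), sum)
    rows[[lib]] <- data.frame(library_id = lib, category = cats,
                              tags = as.integer(ifelse(is.na(ntags), 0, ntags)),
                              reads = as.integer(ifelse(is.na(reads), 0, reads)),
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Quantify known miRNAs from annotated tag alignments
#'
#' A tag's count accrues to a mature miRNA when one of its hits lies on the
#' mature locus strand with both start and end within `tolerance` nt of the
#' mature locus (absorbing isomiR end variation). Each tag accrues to at most
#' one miRNA: ties across mature loci are broken by the smallest total
#' start+end offset, then by lexicographic miRNA id.
#'
#' @param hits hit table from [map_tags()].
#' @param annot annotation table from [annotate_tags()]; only tags annotated
#'   `known_miRNA` are counted.
#' @param annotation a `genome_annotation` (for the mature catalog).
#' @param libraries named list of `list(meta, tags)`; metadata must be present
#'   for every library.
#' @param tolerance maximum start/end offset in nt (default 2).
#' @return a `mir_expr` object: list with `counts` (miRNA x library matrix),
#'   `meta` (library metadata data.frame) and `tpm = NULL`.
#' @export
quantify_known_mirnas <- function(hits, annot, annotation, libraries,
                                  tolerance = 2L) {
  for (lib in libraries) {
    if (is.null(lib$meta) || is.null(lib$meta$total_reads)) {
      stop("library metadata missing for a tag set")
    }
  }
  catalog <- annotation$catalog
  mir_tags <- annot$tag[annot$category == "known_miRNA"]
  h <- hits[hits$tag %in% mir_tags, , drop = FALSE]
  assign <- character(0)
  if (nrow(h) > 0) {
    # candidate (hit, mature locus) matches within tolerance, same strand
    per_tag <- split(seq_len(nrow(h)), h$tag)
    assign <- vapply(per_tag, function(idx) {
      best_id <- NA_character_; best_off <- Inf
      for (i in idx) {
        same <- catalog$chrom == h$chrom[i] & catalog$strand == h$strand[i]
        ds <- abs(catalog$mat_start - h$start[i])
        de <- abs(catalog$mat_end - h$end[i])
        cand <- which(same & ds <= tolerance & de <= tolerance)
        for (ci in cand) {
          off <- ds[ci] + de[ci]
          if (off < best_off ||
              (off == best_off && catalog$mirna_id[ci] < best_id)) {
            best_off <- off
            best_id <- catalog$mirna_id[ci]
          }
        }
      }
      best_id
    }, "")
  }
  assign <- assign[!is.na(assign)]
  lib_ids <- names(libraries)
  counts <- matrix(0L, nrow(catalog), length(lib_ids),
                   dimnames = list(catalog$mirna_id, lib_ids))
  for (lib in lib_ids) {
    tags <- libraries[[lib]]$tags
    common <- intersect(names(assign), names(tags))
    if (length(common)) {
      agg <- tapply(tags[common], assign[common], sum)
      counts[names(agg), lib] <- as.integer(agg)
    }
  }
  meta <- do.call(rbind, lapply(libraries, function(l)
    data.frame(library_id = l$meta$library_id, breed = l$meta$breed,
               stage = l$meta$stage, total_reads = l$meta$total_reads,
               stringsAsFactors = FALSE)))
  rownames(meta) <- NULL
  structure(list(counts = counts, tpm = NULL, meta = meta),
            class = "mir_expr")
}
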