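#' Maximum base-pairing fold of a sequence
#'
#' Dynamic-programming base-pair maximization (Nussinov) over the canonical
#' pairs A:U, G:C and G:U with a minimum hairpin loop of `min_loop` unpaired
#' bases. DNA input is read as its transcript (T as U). Returns one optimal
#' structure via traceback.
#'
#' @param seq a single DNA/RNA sequence.
#' @param min_loop minimum number of unpaired bases in a hairpin loop
#'   (default 3).
#' @return list with `max_pairs` (the optimum) and `pairs` (2-column matrix of
#'   1-based paired positions, i < j).
#' @export
nussinov_fold <- function(seq, min_loop = 3L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  .nussinov_fold(toupper(seq), as.integer(min_loop))
}

# decompose a secondary structure (pair list) into stem-loops: each hairpin
# (innermost pair) plus the chain of enclosing pairs that branch nowhere else.
stem_loops <- function(pairs) {
  if (nrow(pairs) == 0) return(list())
  n <- nrow(pairs)
  # parent = immediately enclosing pair (max start among enclosing)
  parent <- integer(n)
  for (r in seq_len(n)) {
    enc <- which(pairs[, 1] < pairs[r, 1] & pairs[, 2] > pairs[r, 2])
    parent[r] <- if (length(enc)) enc[which.max(pairs[enc, 1])] else 0L
  }
  children <- tabulate(parent, nbins = n)
  # chains start at hairpin-closing pairs (no children) or multiloop-closing
  # pairs (>= 2 children) and extend outward through single-child parents
  starts <- which(children != 1L)
  lapply(starts, function(h) {
    chain <- h
    p <- parent[h]
    while (p > 0L && children[p] == 1L) {
      chain <- c(chain, p)
      p <- parent[p]
    }
    outer <- chain[length(chain)]
    list(pairs = pairs[chain, , drop = FALSE],
         n_pairs = length(chain),
         loop_start = pairs[h, 1], loop_end = pairs[h, 2],
         loop_len = pairs[h, 2] - pairs[h, 1] - 1L,
         arm5 = c(pairs[outer, 1], pairs[h, 1]),
         arm3 = c(pairs[h, 2], pairs[outer, 2]))
  })
}

# evaluate one folded window: fold, decompose into stem-loops, find the
# stem-loop whose duplex pairs the most tag bases, and apply the acceptance
# criteria. loop_len is the unpaired span between the tag's paired segment
# and its partner segment (the hairpin loop, for a clean duplex).
evaluate_hairpin_window <- function(win, t0, t1, min_paired, max_loop,
                                    max_bulge = 2L) {
  fold <- nussinov_fold(win)
  pairs <- fold$pairs
  tag_pos <- (t0 + 1L):t1                    # 1-based
  stems <- stem_loops(pairs)
  np5 <- vapply(stems, function(s) sum(tag_pos %in% s$pairs[, 1]), 0L)
  np3 <- vapply(stems, function(s) sum(tag_pos %in% s$pairs[, 2]), 0L)
  arm <- NA_character_; loop_len <- NA_integer_; stem_pairs <- 0L
  paired_tag <- 0L
  on_arm <- FALSE
  if (length(stems) && max(np5 + np3) > 0L) {
    k <- which.max(np5 + np3)
    best <- stems[[k]]
    stem_pairs <- best$n_pairs
    in5 <- best$pairs[, 1] %in% tag_pos
    in3 <- best$pairs[, 2] %in% tag_pos
    compact <- FALSE
    if (np5[k] > 0L && np3[k] == 0L && t1 < best$arm3[1]) {
      arm <- "5p"; on_arm <- TRUE; paired_tag <- np5[k]
      loop_len <- min(best$pairs[in5, 2]) - max(best$pairs[in5, 1]) - 1L
      tag_span <- diff(range(best$pairs[in5, 1])) + 1L
      partner_span <- diff(range(best$pairs[in5, 2])) + 1L
      compact <- max(tag_span, partner_span) <= paired_tag + max_bulge
    } else if (np3[k] > 0L && np5[k] == 0L && t0 + 1L > best$arm5[2]) {
      arm <- "3p"; on_arm <- TRUE; paired_tag <- np3[k]
      loop_len <- min(best$pairs[in3, 2]) - max(best$pairs[in3, 1]) - 1L
      tag_span <- diff(range(best$pairs[in3, 2])) + 1L
      partner_span <- diff(range(best$pairs[in3, 1])) + 1L
      compact <- max(tag_span, partner_span) <= paired_tag + max_bulge
    }
  }
  list(arm = arm, paired_tag = paired_tag, stem_pairs = stem_pairs,
       loop_len = loop_len,
       accepted = on_arm && compact && paired_tag >= min_paired &&
         !is.na(loop_len) && loop_len <= max_loop)
}

#' Call novel miRNA hairpin candidates from unannotated mapped tags
#'
#' For each genomic hit of each unannotated tag, the flanking window
#' (tag +/- `flank` nt, truncated at chromosome ends, minus-strand windows
#' reverse-complemented to tag sense) is folded by base-pair maximization.
#' The candidate stem-loop of a window is the one whose duplex pairs the most
#' tag bases. The locus is accepted when (a) the tag lies on one arm of that
#' stem-loop: all its paired bases sit on the same side of the duplex and the
#' tag does not reach into the opposite arm (unpaired dangling tag ends are
#' allowed, as in real precursors), (b) at least `min_paired` of the tag's
#' bases are paired within the stem-loop's duplex in a compact duplex (the
#' paired segment on either arm may exceed the pair count by at most
#' `max_bulge` nt, the bulge tolerance that mirrors the arm-complementarity
#' requirement), and (c) the unpaired span
#' between the tag's paired segment and its partner segment — the hairpin
#' loop, for a clean duplex — is at most `max_loop` nt. When the symmetric
#' window yields no acceptable stem-loop, the two tag-anchored subwindows
#' (5 nt outer dangle) are folded as well, which removes co-optimal flanking
#' structure that can fragment the duplex in the traceback.
#'
#' @param hits hit table from [map_tags()].
#' @param annot annotation table from [annotate_tags()]; only `"unann"` tags
#'   are considered.
#' @param annotation a `genome_annotation`.
#' @param flank flanking window half-width in nt (default 100).
#' @param min_paired minimum paired tag bases (default 16).
#' @param max_loop maximum loop length in nt (default 50).
#' @param max_bulge duplex bulge tolerance in nt (default 2).
#' @return data.frame of candidates: tag, chrom, start, end (window, 0-based
#'   half-open), strand, arm (5p/3p), paired_tag_bases, stem_pairs, loop_len,
#'   accepted.
#' @export
detect_novel_hairpins <- function(hits, annot, annotation, flank = 100L,
                                  min_paired = 16L, max_loop = 50L,
                                  max_bulge = 2L) {
  unann <- annot$tag[annot$category == "unann"]
  h <- hits[hits$tag %in% unann, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(h))) {
    chrom_len <- nchar(annotation$chromosomes[[h$chrom[i]]])
    # symmetric window first; if it fails, tag-anchored windows (5 nt outer
    # dangle) remove co-optimal flank structure that can shred the duplex
    # in the traceback
    windows <- list(c(flank, flank), c(5L, flank), c(flank, 5L))
    res <- NULL
    for (wdef in windows) {
      ws <- max(0L, h$start[i] - wdef[1])
      we <- min(chrom_len, h$end[i] + wdef[2])
      win <- extract_seq(annotation, h$chrom[i], ws, we, h$strand[i])
      # tag position within the window, in window (tag-sense) coordinates
      if (h$strand[i] == "+") {
        t0 <- h$start[i] - ws
      } else {
        t0 <- we - h$end[i]
      }
      t1 <- t0 + (h$end[i] - h$start[i])     # 0-based half-open in window
      ev <- evaluate_hairpin_window(win, t0, t1, min_paired, max_loop,
                                    max_bulge)
      if (is.null(res) || ev$accepted) {
        res <- c(list(ws = ws, we = we), ev)
      }
      if (ev$accepted) break
    }
    rows[[length(rows) + 1L]] <- data.frame(
      tag = h$tag[i], chrom = h$chrom[i], start = res$ws, end = res$we,
      strand = h$strand[i], arm = res$arm,
      paired_tag_bases = res$paired_tag, stem_pairs = res$stem_pairs,
      loop_len = res$loop_len, accepted = res$accepted,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tag = character(0), chrom = character(0), start = integer(0),
               end = integer(0), strand = character(0), arm = character(0),
               paired_tag_bases = integer(0), stem_pairs = integer(0),
               loop_len = integer(0), accepted = logical(0))
  rownames(out) <- NULL
  out
}
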