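#' Seed-match target prediction
#'
#' A miRNA is predicted to target an mRNA when the reverse complement of its
#' seed (positions 2-8, a 7-mer) occurs in the 3'UTR. This is the canonical
#' 7-mer site rule, used as a transparent stand-in when an external predicted
#' target table is not supplied.
#'
#' @param mirna_seqs named character vector of mature miRNA sequences
#'   (RNA or DNA alphabet; at least 8 nt).
#' @param utr_seqs named character vector of 3'UTR sequences.
#' @return data.frame: mirna_id, mrna_id, n_sites, positions (1-based match
#'   starts, comma separated). Only predicted pairs appear.
#' @export
seed_match_targets <- function(mirna_seqs, utr_seqs) {
  stopifnot(!is.null(names(mirna_seqs)), !is.null(names(utr_seqs)))
  mirna_dna <- toupper(chartr("u", "t", chartr("U", "T", mirna_seqs)))
  if (any(nchar(mirna_dna) < 8)) stop("miRNA sequences must be >= 8 nt")
  utr_dna <- toupper(chartr("u", "t", chartr("U", "T", utr_seqs)))
  rows <- list()
  for (m in names(mirna_dna)) {
    site <- revcomp(substr(mirna_dna[[m]], 2L, 8L))
    for (g in names(utr_dna)) {
      pos <- gregexpr(site, utr_dna[[g]], fixed = TRUE)[[1]]
      if (pos[1] == -1) next
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = m, mrna_id = g, n_sites = length(pos),
        positions = paste(pos, collapse = ","), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna_id = character(0), mrna_id = character(0),
               n_sites = integer(0), positions = character(0))
  rownames(out) <- NULL
  out
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (ties receive their mean
#' rank). Returns `NA` when either vector is constant (undefined ranks);
#' callers exclude such pairs.
#'
#' @param a,b numeric vectors of equal length >= 3.
#' @return correlation in \[-1, 1\], or `NA`.
#' @export
spearman_rho <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  if (length(a) < 3) stop("need at least 3 observations")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(rank(a, ties.method = "average"),
             rank(b, ties.method = "average"))
}

#' Pair breed-DE miRNAs with predicted targets by negative correlation
#'
#' First pairing step of the network construction: a predicted (miRNA, mRNA)
#' pair passes when the miRNA is breed-DE at at least one stage and the
#' Spearman correlation of the two 5-stage expression trajectories is below
#' `rho_threshold` in TC and/or YK. The printed pairing threshold is read as
#' rho < -0.5 (a negative-correlation criterion); both the threshold and its
#' sign are arguments, so the positive-magnitude reading is also runnable.
#'
#' @param breed_de_mirnas character vector of breed-DE miRNA ids (or the
#'   data.frame from `screen_de(mode = "breed")`, from which DE ids are taken).
#' @param predicted data.frame with columns mirna_id, mrna_id.
#' @param expr a TPM-normalized `mir_expr` (miRNA trajectories).
#' @param mrna_expr mRNA x library matrix over the same libraries.
#' @param rho_threshold correlation cutoff (default -0.5).
#' @return data.frame: mirna_id, mrna_id, rho per breed, passes_pairing.
#' @export
pair_breed_de <- function(breed_de_mirnas, predicted, expr, mrna_expr,
                          rho_threshold = -0.5) {
  if (is.data.frame(breed_de_mirnas)) {
    breed_de_mirnas <- unique(
      breed_de_mirnas$mirna_id[breed_de_mirnas$is_de])
  }
  breeds <- sort(unique(expr$meta$breed))
  mir_traj <- lapply(breeds, function(b) stage_matrix(expr, b))
  names(mir_traj) <- breeds
  mrna_traj <- lapply(breeds, function(b) {
    meta <- expr$meta[expr$meta$breed == b, , drop = FALSE]
    meta <- meta[order(meta$stage), , drop = FALSE]
    mrna_expr[, meta$library_id, drop = FALSE]
  })
  names(mrna_traj) <- breeds
  rows <- list()
  for (i in seq_len(nrow(predicted))) {
    m <- predicted$mirna_id[i]; g <- predicted$mrna_id[i]
    if (!m %in% breed_de_mirnas) next
    if (!m %in% rownames(mir_traj[[1]]) || !g %in% rownames(mrna_traj[[1]])) {
      warning("missing trajectory for pair ", m, " / ", g, "; skipped")
      next
    }
    rho <- vapply(breeds, function(b)
      spearman_rho(mir_traj[[b]][m, ], mrna_traj[[b]][g, ]), 0)
    passes <- any(!is.na(rho) & rho < rho_threshold)
    row <- data.frame(mirna_id = m, mrna_id = g, stringsAsFactors = FALSE)
    for (b in breeds) row[[paste0("rho_", b)]] <- rho[[b]]
    row$passes_pairing <- passes
    rows[[length(rows) + 1L]] <- row
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    df <- data.frame(mirna_id = character(0), mrna_id = character(0))
    for (b in breeds) df[[paste0("rho_", b)]] <- numeric(0)
    df$passes_pairing <- logical(0)
    df
  }
  rownames(out) <- NULL
  out
}

#' Intersect pairs with the breed-DE mRNA set
#'
#' Final filtering step: keeps exactly the passing pairs whose mRNA is itself
#' breed-DE at some stage.
#'
#' @param pairs data.frame from [pair_breed_de()] (only rows with
#'   `passes_pairing` are considered, if the column is present).
#' @param breed_de_mrnas character vector of breed-DE mRNA ids.
#' @return the filtered pair data.frame.
#' @export
intersect_breed_de_mrna <- function(pairs, breed_de_mrnas) {
  if ("passes_pairing" %in% names(pairs)) {
    pairs <- pairs[pairs$passes_pairing, , drop = FALSE]
  }
  out <- pairs[pairs$mrna_id %in% breed_de_mrnas, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the bipartite miRNA-mRNA interaction network
#'
#' Nodes are the miRNAs and mRNAs of the final pairs; edges the pairs
#' themselves (deduplicated). Hubs are nodes with degree >= `hub_degree`
#' (inclusive).
#'
#' @param pairs final pair data.frame (columns mirna_id, mrna_id).
#' @param hub_degree hub cutoff (default 5).
#' @return list with `graph` (igraph), `nodes` (name, type, degree, hub,
#'   degree-ranked) and `edges`.
#' @export
build_network <- function(pairs, hub_degree = 5L) {
  edges <- unique(pairs[, c("mirna_id", "mrna_id")])
  mirnas <- unique(edges$mirna_id)
  mrnas <- unique(edges$mrna_id)
  vertices <- data.frame(name = c(mirnas, mrnas),
                         type = c(rep("miRNA", length(mirnas)),
                                  rep("mRNA", length(mrnas))),
                         stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = vertices)
  deg <- igraph::degree(g)
  nodes <- data.frame(name = vertices$name, type = vertices$type,
                      degree = as.integer(deg[vertices$name]),
                      stringsAsFactors = FALSE)
  nodes$hub <- nodes$degree >= hub_degree
  nodes <- nodes[order(-nodes$degree, nodes$name), , drop = FALSE]
  rownames(nodes) <- NULL
  igraph::V(g)$degree <- as.integer(deg)
  igraph::V(g)$hub <- deg >= hub_degree
  list(graph = g, nodes = nodes, edges = edges, hub_degree = hub_degree)
}

#' Export the interaction network as SIF and GraphML
#'
#' SIF lines read `miRNA targets mRNA` (tab separated, one per edge);
#' GraphML carries the node type, degree and hub attributes and round-trips
#' through standard graph readers.
#'
#' @param network output of [build_network()].
#' @param sif_path,graphml_path output files (either may be `NULL` to skip).
#' @return invisibly, the written paths.
#' @export
export_network <- function(network, sif_path = NULL, graphml_path = NULL) {
  written <- character(0)
  if (!is.null(sif_path)) {
    lines <- sprintf("%s\ttargets\t%s", network$edges$mirna_id,
                     network$edges$mrna_id)
    writeLines(lines, sif_path)
    written <- c(written, sif_path)
  }
  if (!is.null(graphml_path)) {
    igraph::write_graph(network$graph, graphml_path, format = "graphml")
    written <- c(written, graphml_path)
  }
  invisible(written)
}

#' Binomial-test term overrepresentation
#'
#' For a target gene set of size n and a term annotating a fraction q of the
#' gene universe, the enrichment p-value is the one-sided binomial tail
#' P(X >= k | n, q) where k is the number of targets annotated to the term.
#' Terms with p below `alpha` are flagged enriched.
#'
#' @param genes character vector of target gene ids (must lie in the universe).
#' @param annotation data.frame with columns term, gene.
#' @param universe background gene ids; defaults to all genes in `annotation`.
#' @param alpha significance level (default 0.05).
#' @return data.frame: term, k, n, q, p_value, enriched, ordered by p.
#' @export
binomial_overrepresentation <- function(genes, annotation, universe = NULL,
                                        alpha = 0.05) {
  if (is.null(universe)) universe <- unique(annotation$gene)
  if (length(universe) == 0) stop("empty gene universe")
  if (!all(genes %in% universe)) {
    stop("target genes must be a subset of the universe")
  }
  ann <- annotation[annotation$gene %in% universe, , drop = FALSE]
  n <- length(unique(genes))
  terms <- unique(ann$term)
  rows <- lapply(terms, function(tm) {
    tg <- unique(ann$gene[ann$term == tm])
    k <- length(intersect(genes, tg))
    q <- length(tg) / length(universe)
    p <- stats::pbinom(k - 1L, n, q, lower.tail = FALSE)
    data.frame(term = tm, k = k, n = n, q = q, p_value = p,
               enriched = p < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
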