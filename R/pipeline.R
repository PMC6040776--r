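#' Run the full comparative miRNAome pipeline
#'
#' Executes every stage on a (synthetic or user-assembled) study: tag
#' preprocessing, exact mapping, priority-rule annotation, known-miRNA
#' quantification, TPM normalization and high-expression filtering, stage-
#' and breed-DE screening, library ordination (PCA/HCA), model-profile
#' time-series clustering per breed, novel hairpin calling, and the
#' three-step miRNA-mRNA pairing with network construction and hub
#' extraction.
#'
#' @param study a `mir_sim` from [generate_study()], or any list with the
#'   same `annotation`, `libraries` and `mrna` components.
#' @param breed_de_mrnas character vector of breed-DE mRNA ids used in the
#'   intersection step; defaults to the study's ground truth when present
#'   (the synthetic stand-in for the external mRNA screen).
#' @param tpm_threshold high-expression filter (default 28).
#' @param fold_threshold,p_threshold DE gates (defaults 2 and 0.05).
#' @param rho_threshold pairing correlation gate (default -0.5).
#' @param hub_degree hub cutoff (default 5).
#' @param stem_m,unit_change model-profile parameters (defaults 20 and 1).
#' @return list with all intermediate and final results (see element names).
#' @export
run_pipeline <- function(study,
                         breed_de_mrnas = NULL,
                         tpm_threshold = 28,
                         fold_threshold = 2,
                         p_threshold = 0.05,
                         rho_threshold = -0.5,
                         hub_degree = 5L,
                         stem_m = 20L,
                         unit_change = 1) {
  libraries <- lapply(study$libraries, function(l) {
    l$tags <- preprocess_tags(l$tags)
    l
  })
  all_tags <- unique(unlist(lapply(libraries, function(l) names(l$tags))))
  mapping <- map_tags(all_tags, study$annotation)
  annot <- annotate_tags(mapping$hits, study$annotation)
  composition <- annotation_summary(annot, mapping, libraries)
  expr <- quantify_known_mirnas(mapping$hits, annot, study$annotation,
                                libraries)
  expr <- tpm_normalize(expr)
  filtered <- high_expression_filter(expr, tpm_threshold)

  breed_de <- screen_de(filtered, "breed", fold_threshold, p_threshold)
  stage_de <- screen_de(filtered, "stage", fold_threshold, p_threshold)
  stage_summary <- de_set_algebra(stage_de)

  z <- zscore(filtered$tpm)
  pca <- pca_libraries(z)
  hca <- hcluster_libraries(z)
  breeds <- sort(unique(filtered$meta$breed))
  stem <- lapply(breeds, function(b)
    stem_cluster(filtered, b, m = stem_m, unit_change = unit_change,
                 alpha = p_threshold))
  names(stem) <- breeds

  hairpins <- detect_novel_hairpins(mapping$hits, annot, study$annotation)

  if (is.null(breed_de_mrnas)) {
    breed_de_mrnas <- study$truth$breed_de_mrnas
  }
  pairs <- pair_breed_de(breed_de, study$mrna$targets, filtered,
                         study$mrna$expr, rho_threshold)
  final_pairs <- intersect_breed_de_mrna(pairs, breed_de_mrnas)
  network <- build_network(final_pairs, hub_degree)

  list(mapping = mapping, annotation_table = annot,
       composition = composition,
       expr = expr, filtered = filtered,
       breed_de = breed_de, stage_de = stage_de,
       stage_summary = stage_summary,
       pca = pca, hca = hca, stem = stem,
       hairpins = hairpins,
       pairs = pairs, final_pairs = final_pairs, network = network)
}
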