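# reduced-scale study shared across test files (memoized); the full-scale
# default configuration is exercised in the end-to-end acceptance test
small_config <- function(seed = 101L, ...) {
  args <- list(seed = seed,
               n_chromosomes = 1L,
               chromosome_length = 40000L,
               n_known_mirnas = 40L,
               n_novel_hairpins = 4L,
               n_contaminant_features = 6L,
               library_depth = 20000L,
               n_breed_de = 2L,
               n_decline = 8L,
               n_mrnas = 60L,
               n_true_targets = 6L)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

.sim_cache <- new.env(parent = emptyenv())

small_study <- function() {
  if (is.null(.sim_cache$study)) {
    .sim_cache$study <- generate_study(small_config())
  }
  .sim_cache$study
}

small_pipeline <- function() {
  if (is.null(.sim_cache$res)) {
    .sim_cache$res <- run_pipeline(small_study())
  }
  .sim_cache$res
}

# hand-built miniature annotation for targeted annotate/quantify tests
toy_annotation <- function(chrom_seq, features, catalog = NULL) {
  if (is.null(catalog)) {
    catalog <- data.frame(mirna_id = character(0), mature_seq = character(0),
                          chrom = character(0), mat_start = integer(0),
                          mat_end = integer(0), strand = character(0),
                          pre_start = integer(0), pre_end = integer(0))
  }
  structure(list(chromosomes = list(chr1 = chrom_seq),
                 features = features, catalog = catalog),
            class = "genome_annotation")
}

toy_features <- function(...) {
  rows <- list(...)
  if (!length(rows)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      category = character(0), name = character(0)))
  }
  do.call(rbind, lapply(rows, function(r)
    data.frame(chrom = "chr1", start = r[[1]], end = r[[2]],
               strand = r[[3]], category = r[[4]],
               name = "f", stringsAsFactors = FALSE)))
}
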