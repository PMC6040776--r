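#' Configuration for a synthetic comparative miRNAome study
#'
#' Defines the study design emulated by the generator: two breeds (TC, YK)
#' sampled at five prenatal stages (40, 55, 63, 70, 90 dpc), one pooled tag
#' library per breed-stage cell, a miniature genome carrying known miRNA
#' precursors, planted novel hairpins and contaminant (non-miRNA) features,
#' and an accompanying mRNA expression matrix with planted regulatory targets.
#'
#' @param seed integer seed; the same configuration (including seed) yields
#'   byte-identical outputs.
#' @param n_chromosomes,chromosome_length genome size (nucleotides per chromosome).
#' @param n_known_mirnas number of catalog (known) miRNAs.
#' @param n_novel_hairpins planted novel hairpin loci (inverted repeats with a
#'   mature tag on the 5' arm).
#' @param n_contaminant_features features per non-miRNA category
#'   (rRNAetc_genbank, rRNAetc_rfam, repeat, exon, intron).
#' @param library_depth expected total tag count per library.
#' @param breeds,stages design labels; stages must be strictly increasing.
#' @param n_breed_de planted breed-differential miRNAs per stage.
#' @param breed_de_fold multiplicative breed effect; must exceed 2 so planted
#'   effects clear the fold-change gate.
#' @param n_decline miRNAs with a strictly declining temporal trend (both breeds).
#' @param decline_decay per-stage multiplicative decay of declining miRNAs.
#' @param noise_model list with `type` in `"none"` (counts = rounded means),
#'   `"poisson"`, or `"nb"` (negative binomial; supply `dispersion`, the
#'   var = mu + dispersion * mu^2 parameterization).
#' @param n_mrnas,n_true_targets mRNA panel size and planted miRNA->mRNA pairs.
#' @param target_qualifying_fraction fraction of planted pairs whose mRNA is
#'   additionally flagged breed-DE (and hence survives the network intersection).
#' @param mirna_fraction expected fraction of library counts from known miRNAs;
#'   contaminant/novel/unmappable fractions are scaled against it.
#' @param n_unmapped_tags tags absent from the genome (library noise).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chromosome_length = 100000L,
                       n_known_mirnas = 150L,
                       n_novel_hairpins = 10L,
                       n_contaminant_features = 20L,
                       library_depth = 50000L,
                       breeds = c("TC", "YK"),
                       stages = c(40L, 55L, 63L, 70L, 90L),
                       n_breed_de = 6L,
                       breed_de_fold = 4,
                       n_decline = 30L,
                       decline_decay = 0.45,
                       noise_model = list(type = "none", dispersion = 0),
                       n_mrnas = 200L,
                       n_true_targets = 20L,
                       target_qualifying_fraction = 0.6,
                       mirna_fraction = 0.70,
                       n_unmapped_tags = 25L) {
  stopifnot(length(breeds) == 2L, length(stages) >= 2L)
  if (any(diff(stages) <= 0)) stop("stages must be strictly increasing")
  if (breed_de_fold <= 2) stop("breed_de_fold must exceed 2")
  counts <- c(n_chromosomes, chromosome_length, n_known_mirnas,
              n_novel_hairpins, n_contaminant_features, library_depth,
              n_breed_de, n_decline, n_mrnas, n_true_targets, n_unmapped_tags)
  if (any(counts < 0)) stop("all size parameters must be non-negative")
  if (library_depth <= 0) stop("library_depth must be positive")
  if (!noise_model$type %in% c("none", "poisson", "nb")) {
    stop("noise_model$type must be one of 'none', 'poisson', 'nb'")
  }
  if (n_decline + length(stages) * n_breed_de > n_known_mirnas) {
    stop("planted decline and breed-DE sets exceed the miRNA catalog size")
  }
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# non-overlapping interval allocator: places feature lengths on chromosomes
# with random gaps; errors naming the category that no longer fits.
allocate_intervals <- function(chrom_names, chrom_len, lengths, categories) {
  ord <- sample(seq_along(lengths))
  res <- data.frame(chrom = character(length(lengths)),
                    start = integer(length(lengths)),
                    end = integer(length(lengths)))
  ci <- 1L
  cursor <- 100L
  for (k in ord) {
    len <- lengths[k]
    gap <- sample(30:120, 1L)
    while (cursor + gap + len > chrom_len - 100L) {
      ci <- ci + 1L
      if (ci > length(chrom_names)) {
        stop("genome capacity exceeded while placing category '",
             categories[k], "'; enlarge the genome or reduce feature counts")
      }
      cursor <- 100L
      gap <- sample(30:120, 1L)
    }
    start <- cursor + gap
    res$chrom[k] <- chrom_names[ci]
    res$start[k] <- start
    res$end[k] <- start + len
    cursor <- start + len
  }
  res
}

#' Generate the synthetic reference genome and annotation
#'
#' Builds random chromosome sequences and plants, at non-overlapping loci:
#' known miRNA precursors embedding their mature sequences, novel hairpin loci
#' constructed as inverted repeats (30 nt arms, >= 90 percent arm
#' complementarity, 12 nt loop, a 22 nt mature tag on the 5' arm), and
#' contaminant features for each non-miRNA annotation category.
#'
#' @param config a [sim_config()].
#' @return list with `annotation` (a `genome_annotation`: chromosomes, feature
#'   table, miRNA catalog) and `hairpins` (planted novel hairpin ground truth).
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chrom_names <- sprintf("chr%d", seq_len(config$n_chromosomes))
  chroms <- stats::setNames(
    lapply(chrom_names, function(x) random_dna(config$chromosome_length)),
    chrom_names)

  n_mir <- config$n_known_mirnas
  n_hp <- config$n_novel_hairpins
  cat_names <- c("rRNAetc_genbank", "rRNAetc_rfam", "repeat", "exon", "intron")
  n_cont <- config$n_contaminant_features

  mat_len <- sample(21:23, n_mir, replace = TRUE)
  pre_len <- mat_len + 50L
  arm <- 30L; loop <- 12L; hp_mat_len <- 22L
  hp_len <- 2L * arm + loop
  cont_len <- rep(200L, 5L * n_cont)

  lengths <- c(pre_len, rep(hp_len, n_hp), cont_len)
  categories <- c(rep("known_miRNA", n_mir), rep("novel_hairpin", n_hp),
                  rep(cat_names, each = n_cont))
  loci <- allocate_intervals(chrom_names, config$chromosome_length,
                             lengths, categories)

  paste_seq <- function(chrom, start, end, seq) {
    substr(chroms[[chrom]], start + 1L, end) <<- seq
  }

  # known miRNA precursors: mature sequence embedded 15 nt into a random
  # precursor; half the loci on the minus strand.
  catalog <- data.frame(mirna_id = sprintf("sim-miR-%03d", seq_len(n_mir)),
                        mature_seq = character(n_mir), chrom = character(n_mir),
                        mat_start = integer(n_mir), mat_end = integer(n_mir),
                        strand = character(n_mir), pre_start = integer(n_mir),
                        pre_end = integer(n_mir), stringsAsFactors = FALSE)
  features <- list()
  for (i in seq_len(n_mir)) {
    ml <- mat_len[i]; pl <- pre_len[i]
    mature <- random_dna(ml)
    pre <- random_dna(pl)
    off <- 15L
    substr(pre, off + 1L, off + ml) <- mature
    strand <- sample(c("+", "-"), 1L)
    locus <- loci[i, ]
    ins <- if (strand == "+") pre else revcomp(pre)
    paste_seq(locus$chrom, locus$start, locus$end, ins)
    if (strand == "+") {
      ms <- locus$start + off
    } else {
      ms <- locus$start + pl - off - ml
    }
    catalog[i, c("mature_seq", "chrom", "strand")] <-
      list(mature, locus$chrom, strand)
    catalog$mat_start[i] <- ms
    catalog$mat_end[i] <- ms + ml
    catalog$pre_start[i] <- locus$start
    catalog$pre_end[i] <- locus$end
    features[[length(features) + 1L]] <-
      data.frame(chrom = locus$chrom, start = locus$start, end = locus$end,
                 strand = strand, category = "known_miRNA",
                 name = catalog$mirna_id[i])
  }

  # novel hairpins: arm3 = revcomp(arm5) with 2/30 mismatches (93% identity);
  # mature tag at arm5 positions 3..24 (0-based offset 2).
  hairpins <- data.frame(hairpin_id = sprintf("hairpin-%02d", seq_len(n_hp)),
                         chrom = character(n_hp), start = integer(n_hp),
                         end = integer(n_hp), strand = character(n_hp),
                         mature_seq = character(n_hp),
                         mature_start = integer(n_hp),
                         mature_end = integer(n_hp),
                         arm = rep("5p", n_hp), stringsAsFactors = FALSE)
  if (n_hp > 0) for (i in seq_len(n_hp)) {
    arm5 <- random_dna(arm)
    arm3 <- revcomp(arm5)
    mut <- sample(arm, 2L)
    for (m in mut) {
      substr(arm3, m, m) <- sample(setdiff(DNA_BASES, substr(arm3, m, m)), 1L)
    }
    hp <- paste0(arm5, random_dna(loop), arm3)
    strand <- sample(c("+", "-"), 1L)
    locus <- loci[n_mir + i, ]
    paste_seq(locus$chrom, locus$start, locus$end,
              if (strand == "+") hp else revcomp(hp))
    off <- 2L
    mature <- substr(arm5, off + 1L, off + hp_mat_len)
    if (strand == "+") {
      ms <- locus$start + off
    } else {
      ms <- locus$start + hp_len - off - hp_mat_len
    }
    hairpins[i, c("chrom", "strand", "mature_seq")] <-
      list(locus$chrom, strand, mature)
    hairpins$start[i] <- locus$start
    hairpins$end[i] <- locus$end
    hairpins$mature_start[i] <- ms
    hairpins$mature_end[i] <- ms + hp_mat_len
  }

  # contaminant features keep the underlying random sequence; only intervals
  # are recorded (their tags are sampled from the genome at library time).
  for (j in seq_along(cat_names)) {
    idx <- n_mir + n_hp + ((j - 1L) * n_cont + 1L):(j * n_cont)
    if (n_cont > 0) {
      features[[length(features) + 1L]] <-
        data.frame(chrom = loci$chrom[idx], start = loci$start[idx],
                   end = loci$end[idx], strand = "+",
                   category = cat_names[j],
                   name = sprintf("%s-%02d", cat_names[j], seq_len(n_cont)))
    }
  }

  annotation <- structure(
    list(chromosomes = chroms,
         features = do.call(rbind, features),
         catalog = catalog),
    class = "genome_annotation")
  list(annotation = annotation, hairpins = hairpins)
}

# count draw under the configured noise model; mu may be a vector.
draw_counts <- function(mu, noise_model) {
  switch(noise_model$type,
         none = as.integer(round(mu)),
         poisson = stats::rpois(length(mu), mu),
         nb = {
           disp <- noise_model$dispersion
           if (disp <= 0) stats::rpois(length(mu), mu)
           else stats::rnbinom(length(mu), mu = mu, size = 1 / disp)
         })
}

#' Generate the ten synthetic tag libraries
#'
#' Draws per-tag counts around per-miRNA means. Declining miRNAs decay by
#' `decline_decay` per stage in both breeds; each planted breed-DE miRNA
#' carries a `breed_de_fold` effect at its designated stage (direction
#' alternating between the breeds); remaining miRNAs are null (log-normal
#' constant means). Each known miRNA is emitted as its canonical mature tag
#' plus four isomiR length variants within +/- 2 nt. Contaminant tags are
#' sampled from the non-miRNA features, novel-hairpin mature tags from the
#' planted hairpins, and a small pool of unmappable tags is added.
#'
#' @param config a [sim_config()].
#' @param reference output of [generate_reference()].
#' @return list with `libraries` (named list of `list(meta, tags)` per
#'   breed-stage cell; `meta` holds library_id, breed, stage and the total
#'   clean-read count N), `truth` (planted breed-DE table, declining and null
#'   miRNA ids) and `mirna_counts` (the generator's own per-miRNA count
#'   bookkeeping, miRNA x library).
#' @export
generate_libraries <- function(config, reference) {
  stopifnot(inherits(config, "sim_config"))
  if (config$library_depth <= 0) stop("library_depth must be positive")
  set.seed(config$seed + 1L)
  ann <- reference$annotation
  catalog <- ann$catalog
  stages <- config$stages
  nS <- length(stages)
  ids <- catalog$mirna_id
  n_mir <- length(ids)

  decline_ids <- ids[seq_len(config$n_decline)]
  nb <- config$n_breed_de
  de_rows <- list()
  de_ids <- character(0)
  if (nb > 0) {
    for (k in seq_len(nS)) {
      block <- ids[config$n_decline + ((k - 1L) * nb + 1L):(k * nb)]
      dirs <- rep(c("up_TC", "up_YK"), length.out = nb)
      de_rows[[k]] <- data.frame(mirna_id = block, stage = stages[k],
                                 direction = dirs, fold = config$breed_de_fold,
                                 stringsAsFactors = FALSE)
      de_ids <- c(de_ids, block)
    }
  }
  breed_de <- if (length(de_rows)) do.call(rbind, de_rows) else
    data.frame(mirna_id = character(0), stage = integer(0),
               direction = character(0), fold = numeric(0))
  null_ids <- setdiff(ids, c(decline_ids, de_ids))

  # per-miRNA baseline means, scaled so the catalog-wide expectation matches
  # library_depth * mirna_fraction at the first stage.
  base <- stats::setNames(numeric(n_mir), ids)
  base[decline_ids] <- 500
  base[de_ids] <- 150
  base[null_ids] <- stats::rlnorm(length(null_ids), log(80), 1)
  scale0 <- config$library_depth * config$mirna_fraction / sum(base)
  base <- base * scale0

  lib_ids <- as.vector(vapply(config$breeds,
                              function(b) paste0(b, stages),
                              character(nS)))
  mu <- matrix(0, n_mir, length(lib_ids), dimnames = list(ids, lib_ids))
  for (b in config$breeds) for (k in seq_len(nS)) {
    lib <- paste0(b, stages[k])
    m <- base
    m[decline_ids] <- m[decline_ids] * config$decline_decay^(k - 1L)
    up <- breed_de$mirna_id[breed_de$stage == stages[k]]
    if (length(up)) {
      dirs <- breed_de$direction[breed_de$stage == stages[k]]
      boost <- up[(dirs == "up_TC" & b == "TC") | (dirs == "up_YK" & b == "YK")]
      m[boost] <- m[boost] * config$breed_de_fold
    }
    mu[, lib] <- m
  }

  # isomiR tags: canonical mature plus four length variants (genomic start/end
  # offsets within the +/- 2 nt matching tolerance); weights fixed.
  offsets <- list(c(0L, 0L), c(-1L, 0L), c(0L, 1L), c(1L, -1L), c(-2L, 2L))
  weights <- c(0.6, 0.1, 0.1, 0.1, 0.1)
  iso_seq <- matrix("", n_mir, length(offsets))
  for (i in seq_len(n_mir)) {
    for (v in seq_along(offsets)) {
      d <- offsets[[v]]
      s <- catalog$mat_start[i] + d[1]; e <- catalog$mat_end[i] + d[2]
      iso_seq[i, v] <- extract_seq(ann, catalog$chrom[i], s, e,
                                   catalog$strand[i])
    }
  }

  # contaminant tag pools, fixed across libraries; per-library counts drawn
  # around means scaled relative to the miRNA fraction.
  cat_frac <- c(rRNAetc_genbank = 0.08, rRNAetc_rfam = 0.04, `repeat` = 0.05,
                exon = 0.04, intron = 0.04)
  pools <- lapply(names(cat_frac), function(cat) {
    feats <- ann$features[ann$features$category == cat, , drop = FALSE]
    if (nrow(feats) == 0) return(character(0))
    unique(unlist(lapply(seq_len(nrow(feats)), function(r) {
      vapply(1:3, function(z) {
        len <- sample(19:24, 1L)
        s <- feats$start[r] + sample.int(feats$end[r] - feats$start[r] - len, 1L)
        extract_seq(ann, feats$chrom[r], s, s + len, "+")
      }, "")
    })))
  })
  names(pools) <- names(cat_frac)
  novel_tags <- reference$hairpins$mature_seq
  unmapped_tags <- if (config$n_unmapped_tags > 0)
    vapply(seq_len(config$n_unmapped_tags), function(i) random_dna(22L), "")
    else character(0)

  libraries <- list()
  mirna_counts <- matrix(0L, n_mir, length(lib_ids),
                         dimnames = list(ids, lib_ids))
  for (b in config$breeds) for (k in seq_len(nS)) {
    lib <- paste0(b, stages[k])
    mu_l <- mu[, lib]
    iso_mu <- outer(mu_l, weights)          # miRNA x variant means
    iso_counts <- draw_counts(as.vector(iso_mu), config$noise_model)
    tag_seqs <- as.vector(iso_seq)
    depth <- config$library_depth
    aux_seqs <- character(0); aux_mu <- numeric(0)
    for (cat in names(pools)) {
      pool <- pools[[cat]]
      if (length(pool)) {
        aux_seqs <- c(aux_seqs, pool)
        aux_mu <- c(aux_mu, rep(depth * cat_frac[[cat]] / length(pool),
                                length(pool)))
      }
    }
    if (length(novel_tags)) {
      aux_seqs <- c(aux_seqs, novel_tags)
      aux_mu <- c(aux_mu, rep(depth * 0.03 / length(novel_tags),
                              length(novel_tags)))
    }
    if (length(unmapped_tags)) {
      aux_seqs <- c(aux_seqs, unmapped_tags)
      aux_mu <- c(aux_mu, rep(depth * 0.02 / length(unmapped_tags),
                              length(unmapped_tags)))
    }
    aux_counts <- draw_counts(aux_mu, config$noise_model)
    all_seqs <- c(tag_seqs, aux_seqs)
    all_counts <- c(iso_counts, aux_counts)
    keep <- all_counts > 0
    tags <- tapply(all_counts[keep], all_seqs[keep], sum)
    tags <- stats::setNames(as.integer(tags), names(tags))
    mir_tab <- matrix(iso_counts, n_mir)
    mirna_counts[, lib] <- as.integer(rowSums(mir_tab))
    libraries[[lib]] <- list(
      meta = list(library_id = lib, breed = b, stage = stages[k],
                  total_reads = sum(tags)),
      tags = tags)
  }

  list(libraries = libraries,
       truth = list(breed_de = breed_de, decline = decline_ids,
                    null_mirnas = null_ids),
       mirna_counts = mirna_counts)
}

#' Generate the synthetic mRNA expression matrix and predicted-target table
#'
#' Planted target pairs take an mRNA whose per-breed stage trend is the exact
#' mirror of its miRNA's realized TPM trajectory (so Spearman rho = -1 on the
#' emitted data whenever the miRNA trend is non-constant in that breed). Decoy
#' predicted pairs combine either a non-DE miRNA with a random-trend mRNA, or
#' a breed-DE miRNA with an mRNA excluded from the breed-DE mRNA set, so they
#' cannot pass the full pairing conjunction. A `target_qualifying_fraction` of
#' planted pairs have their mRNA flagged breed-DE.
#'
#' @param config a [sim_config()].
#' @param libs output of [generate_libraries()].
#' @return list with `expr` (mRNA x library matrix), `targets` (predicted-pair
#'   table) and `truth` (planted pairs with qualifying flags, breed-DE mRNA ids).
#' @export
generate_mrna_profiles <- function(config, libs) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  stages <- config$stages
  lib_ids <- colnames(libs$mirna_counts)
  N <- vapply(libs$libraries, function(l) l$meta$total_reads, 0)[lib_ids]
  tpm <- sweep(libs$mirna_counts, 2, N, "/") * 1e6
  tpm[tpm == 0] <- 0.01

  genes <- sprintf("gene-%03d", seq_len(config$n_mrnas))
  expr <- matrix(0, config$n_mrnas, length(lib_ids),
                 dimnames = list(genes, lib_ids))
  for (b in config$breeds) {
    cols <- paste0(b, stages)
    expr[, cols] <- matrix(stats::rlnorm(config$n_mrnas * length(stages),
                                         log(50), 0.8),
                           config$n_mrnas)
  }

  nt <- config$n_true_targets
  de_pool <- unique(libs$truth$breed_de$mirna_id)
  if (nt > 0 && length(de_pool) == 0) {
    stop("planted target pairs require planted breed-DE miRNAs")
  }
  planted <- if (nt > 0) {
    # concentrate planted pairs (up to 6 mRNAs per miRNA) so the canonical
    # study exercises hub extraction at the degree >= 5 cutoff
    data.frame(mirna_id = de_pool[(seq_len(nt) - 1L) %/% 6L %%
                                    length(de_pool) + 1L],
               mrna_id = genes[seq_len(nt)], stringsAsFactors = FALSE)
  } else {
    data.frame(mirna_id = character(0), mrna_id = character(0))
  }
  if (nt > 0) for (p in seq_len(nt)) {
    m <- planted$mirna_id[p]
    for (b in config$breeds) {
      cols <- paste0(b, stages)
      traj <- tpm[m, cols]
      expr[planted$mrna_id[p], cols] <- (max(traj) + min(traj)) - traj
    }
  }

  n_qual <- floor(config$target_qualifying_fraction * nt)
  qualifying <- rep(FALSE, nt)
  qualifying[seq_len(n_qual)] <- TRUE

  # decoys: half on null miRNAs, half on breed-DE miRNAs whose mRNA is kept
  # out of the breed-DE mRNA set
  decoy_genes <- setdiff(genes, planted$mrna_id)
  n_dec <- min(max(nt, 10L), length(decoy_genes) - 10L)
  n_dec <- max(n_dec, 0L)
  decoys <- if (n_dec > 0) {
    null_pool <- libs$truth$null_mirnas
    half <- if (length(de_pool)) n_dec %/% 2L else n_dec
    data.frame(
      mirna_id = c(rep(null_pool, length.out = half),
                   rep(de_pool, length.out = n_dec - half)),
      mrna_id = decoy_genes[seq_len(n_dec)], stringsAsFactors = FALSE)
  } else {
    data.frame(mirna_id = character(0), mrna_id = character(0))
  }
  targets <- unique(rbind(planted, decoys))

  extra_de_genes <- setdiff(decoy_genes, decoys$mrna_id)
  extra_de_genes <- utils::head(extra_de_genes, 10L)
  breed_de_mrnas <- c(planted$mrna_id[qualifying], extra_de_genes)

  truth_pairs <- planted
  truth_pairs$qualifying <- qualifying
  list(expr = expr, targets = targets,
       truth = list(target_pairs = truth_pairs,
                    breed_de_mrnas = breed_de_mrnas))
}

#' Generate a complete synthetic study
#'
#' Runs [generate_reference()], [generate_libraries()] and
#' [generate_mrna_profiles()] and merges their ground truth.
#'
#' @param config a [sim_config()].
#' @return object of class `mir_sim`: config, annotation, libraries, mRNA data
#'   and the combined `truth` (breed-DE miRNAs, declining set, novel hairpins,
#'   target pairs, breed-DE mRNAs).
#' @export
generate_study <- function(config = sim_config()) {
  ref <- generate_reference(config)
  libs <- generate_libraries(config, ref)
  mrna <- generate_mrna_profiles(config, libs)
  structure(
    list(config = config,
         annotation = ref$annotation,
         libraries = libs$libraries,
         mirna_counts = libs$mirna_counts,
         mrna = list(expr = mrna$expr, targets = mrna$targets),
         truth = c(list(novel_hairpins = ref$hairpins), libs$truth,
                   mrna$truth)),
    class = "mir_sim")
}

#' Write a synthetic study to disk as plain-text files
#'
#' Emits genome FASTA, features BED (0-based half-open, category in the name
#' column), catalog FASTA (mature and precursor records), one collapsed tag
#' FASTA per library (`tag<serial>_x<count>` headers), the mRNA matrix and
#' target table as TSV, and ground truth plus configuration as JSON, so every
#' planted signal is re-derivable from the emitted files alone.
#'
#' @param study a `mir_sim` from [generate_study()].
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
write_simulation <- function(study, dir) {
  stopifnot(inherits(study, "mir_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- study$annotation
  genome <- Biostrings::DNAStringSet(unlist(ann$chromosomes))
  Biostrings::writeXStringSet(genome, file.path(dir, "genome.fa"), width = 80L)
  write_features_bed(ann$features, file.path(dir, "features.bed"))
  cat_fa <- Biostrings::DNAStringSet(c(
    stats::setNames(ann$catalog$mature_seq, ann$catalog$mirna_id),
    stats::setNames(
      vapply(seq_len(nrow(ann$catalog)), function(i)
        extract_seq(ann, ann$catalog$chrom[i], ann$catalog$pre_start[i],
                    ann$catalog$pre_end[i], ann$catalog$strand[i]), ""),
      paste0(ann$catalog$mirna_id, "_pre"))))
  Biostrings::writeXStringSet(cat_fa, file.path(dir, "known_mirnas.fa"),
                              width = 80L)
  for (lib in names(study$libraries)) {
    write_tag_fasta(study$libraries[[lib]]$tags,
                    file.path(dir, paste0(lib, ".fa")))
  }
  write_matrix_tsv(study$mrna$expr, file.path(dir, "mrna_matrix.tsv"))
  utils::write.table(study$mrna$targets, file.path(dir, "targets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(study$truth, file.path(dir, "ground_truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  cfg <- unclass(study$config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
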