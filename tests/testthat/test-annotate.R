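test_that("preprocessing drops short tags and non-ACGT tags, keeps counts", {
  raw <- c(stats::setNames(10L, strrep("A", 17)),
           stats::setNames(5L, strrep("ACGT", 6)))  # 17-mer and 24-mer
  out <- preprocess_tags(raw)
  expect_identical(names(out), strrep("ACGT", 6))
  expect_identical(as.integer(out), 5L)

  withN <- c(stats::setNames(3L, paste0(strrep("A", 20), "NA")),
             stats::setNames(7L, strrep("G", 20)))
  out2 <- preprocess_tags(withN)
  expect_identical(names(out2), strrep("G", 20))

  clean <- stats::setNames(c(2L, 4L), c(strrep("A", 18), strrep("C", 30)))
  expect_identical(preprocess_tags(clean)[names(clean)], clean)

  expect_warning(out3 <- preprocess_tags(stats::setNames(integer(0), character(0))),
                 "empty")
  expect_length(out3, 0)
})

test_that("preprocessing emits a per-length count histogram", {
  raw <- stats::setNames(c(5L, 3L, 2L), c(strrep("A", 20), strrep("C", 20),
                                          strrep("G", 22)))
  h <- attr(preprocess_tags(raw), "length_histogram")
  expect_identical(h, c("20" = 8L, "22" = 2L))
})

# brute-force exact-match scan over every genome offset, both strands
naive_scan <- function(tag, chrom_seq) {
  L <- nchar(tag); n <- nchar(chrom_seq)
  hits <- list()
  rc <- revcomp(tag)
  for (s in 0:(n - L)) {
    sub <- substr(chrom_seq, s + 1, s + L)
    if (sub == tag) hits[[length(hits) + 1]] <- c(s, "+")
    if (sub == rc) hits[[length(hits) + 1]] <- c(s, "-")
  }
  hits
}

test_that("exact mapping reports all loci on both strands (naive scan oracle)", {
  set.seed(31)
  chrom <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  tag1 <- substr(chrom, 101, 122)
  # plant tag1 at a second locus and its reverse complement at a third
  substr(chrom, 501, 522) <- tag1
  substr(chrom, 901, 922) <- revcomp(tag1)
  ann <- toy_annotation(chrom, toy_features())
  tag2 <- substr(chrom, 1501, 1524)
  unmapped <- strrep("AC", 11)  # alternating dimer very unlikely in random seq
  res <- map_tags(c(tag1, tag2, unmapped), ann)
  for (tg in c(tag1, tag2)) {
    got <- res$hits[res$hits$tag == tg, ]
    oracle <- naive_scan(tg, chrom)
    expect_equal(nrow(got), length(oracle))
    expect_setequal(paste(got$start, got$strand),
                    vapply(oracle, paste, "", collapse = " "))
  }
  expect_gte(nrow(res$hits[res$hits$tag == tag1, ]), 3)
  if (length(naive_scan(unmapped, chrom)) == 0) {
    expect_true(unmapped %in% res$unmapped)
  }
})

test_that("minus-strand hits mean the tag matches the reverse complement", {
  chrom <- paste0(strrep("A", 50), "GGGTTTCCCAAAGGGTTTCCCAT", strrep("A", 50))
  tag <- revcomp("GGGTTTCCCAAAGGGTTTCCCAT")
  res <- map_tags(tag, toy_annotation(chrom, toy_features()))
  expect_equal(nrow(res$hits), 1)
  expect_identical(res$hits$strand, "-")
  expect_equal(res$hits$start, 50)
  expect_equal(res$hits$end, 73)
})

test_that("the priority rule assigns exactly one category per tag", {
  set.seed(7)
  chrom <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  tag <- substr(chrom, 101, 122)
  ann <- toy_annotation(chrom, toy_features(
    list(90L, 140L, "+", "known_miRNA"),
    list(95L, 150L, "+", "exon")))
  hits <- map_tags(tag, ann)$hits
  expect_identical(annotate_tags(hits, ann)$category, "known_miRNA")

  # GenBank beats Rfam within the rRNA-class
  ann2 <- toy_annotation(chrom, toy_features(
    list(90L, 140L, "+", "rRNAetc_rfam"),
    list(95L, 150L, "+", "rRNAetc_genbank")))
  expect_identical(annotate_tags(hits, ann2)$category, "rRNAetc_genbank")

  # mapped tag overlapping nothing
  ann3 <- toy_annotation(chrom, toy_features(list(500L, 600L, "+", "exon")))
  expect_identical(annotate_tags(hits, ann3)$category, "unann")
})

test_that("adding a lower-priority overlapping feature never changes the category", {
  set.seed(8)
  chrom <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  tag <- substr(chrom, 201, 222)
  hits <- map_tags(tag, toy_annotation(chrom, toy_features()))$hits
  cats <- c("rRNAetc_genbank", "rRNAetc_rfam", "known_miRNA", "repeat",
            "exon", "intron")
  for (k in seq_along(cats)) {
    base <- toy_features(list(195L, 230L, "+", cats[k]))
    got1 <- annotate_tags(hits, toy_annotation(chrom, base))$category
    for (lower in cats[seq_along(cats) > k]) {
      both <- rbind(base, toy_features(list(190L, 240L, "+", lower)))
      got2 <- annotate_tags(hits, toy_annotation(chrom, both))$category
      expect_identical(got2, got1)
    }
  }
})

test_that("miRNA annotation is strand-specific, other categories are not", {
  set.seed(9)
  chrom <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  tag <- substr(chrom, 101, 122)  # maps on the plus strand
  hits <- map_tags(tag, toy_annotation(chrom, toy_features()))$hits
  hits <- hits[hits$strand == "+", ]
  ann_minus_mir <- toy_annotation(chrom, toy_features(
    list(95L, 130L, "-", "known_miRNA")))
  expect_identical(annotate_tags(hits, ann_minus_mir)$category, "unann")
  ann_minus_exon <- toy_annotation(chrom, toy_features(
    list(95L, 130L, "-", "exon")))
  expect_identical(annotate_tags(hits, ann_minus_exon)$category, "exon")
})

test_that("unknown categories in the annotation are an input error", {
  chrom <- strrep("ACGT", 100)
  hits <- data.frame(tag = "ACGTACGTACGTACGTACGT", chrom = "chr1",
                     start = 0L, end = 20L, strand = "+")
  ann <- toy_annotation(chrom, toy_features(list(0L, 50L, "+", "promoter")))
  expect_error(annotate_tags(hits, ann), "unknown annotation category")
})

test_that("quantification honors the +/-2 isomiR tolerance with tie-breaking", {
  set.seed(11)
  chrom <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  mature <- substr(chrom, 201, 222)
  catalog <- data.frame(mirna_id = "miR-a", mature_seq = mature,
                        chrom = "chr1", mat_start = 200L, mat_end = 222L,
                        strand = "+", pre_start = 180L, pre_end = 260L,
                        stringsAsFactors = FALSE)
  ann <- toy_annotation(chrom,
                        toy_features(list(180L, 260L, "+", "known_miRNA")),
                        catalog)
  exact <- mature
  shifted <- substr(chrom, 203, 224)      # +2 at both ends
  faraway <- substr(chrom, 206, 227)      # +5: outside tolerance
  libs <- list(L1 = list(meta = list(library_id = "L1", breed = "TC",
                                     stage = 40, total_reads = 1000L),
                         tags = stats::setNames(c(40L, 7L, 9L),
                                                c(exact, shifted, faraway))))
  mapres <- map_tags(names(libs$L1$tags), ann)
  annot <- annotate_tags(mapres$hits, ann)
  expr <- quantify_known_mirnas(mapres$hits, annot, ann, libs)
  expect_equal(expr$counts["miR-a", "L1"], 47L)  # exact + shifted, not faraway
})

test_that("quantification requires library metadata", {
  study <- small_study()
  res <- small_pipeline()
  libs <- study$libraries
  libs[[1]]$meta <- NULL
  expect_error(
    quantify_known_mirnas(res$mapping$hits, res$annotation_table,
                          study$annotation, libs),
    "metadata")
})

test_that("category counts conserve totals and every mapped tag has one category", {
  study <- small_study()
  res <- small_pipeline()
  annot <- res$annotation_table
  expect_false(anyDuplicated(annot$tag) > 0)
  expect_true(all(annot$category %in%
                    c(mirdevnet:::PRIORITY_CATEGORIES, "unann")))
  comp <- res$composition
  for (lib in names(study$libraries)) {
    tags <- preprocess_tags(study$libraries[[lib]]$tags)
    cc <- comp[comp$library_id == lib, ]
    expect_equal(sum(cc$reads), sum(tags))
    mapped_reads <- sum(tags[names(tags) %in% res$mapping$hits$tag])
    expect_equal(sum(cc$reads[cc$category != "unmapped"]), mapped_reads)
  }
})

test_that("planted miRNA counts are recovered exactly by the quantification", {
  study <- small_study()
  res <- small_pipeline()
  expect_equal(res$expr$counts[rownames(study$mirna_counts),
                               colnames(study$mirna_counts)],
               study$mirna_counts)
})
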