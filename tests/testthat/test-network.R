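test_that("seed matching finds 7-mer sites and reports positions", {
  mir <- c(mirA = "UGAGGUAGUAGGUUGUAUAGUU")   # seed = GAGGUAG
  site <- revcomp("GAGGTAG")
  utr <- c(g1 = paste0("AAAA", site, "CCCC"),
           g2 = "ACGTACGTACGTACGT")
  hits <- seed_match_targets(mir, utr)
  expect_equal(nrow(hits), 1)
  expect_identical(hits$mrna_id, "g1")
  expect_identical(hits$positions, "5")
  expect_error(seed_match_targets(c(bad = "ACGUACG"), utr), ">= 8")
})

test_that("seed matching equals a naive substring scan on random pairs", {
  set.seed(61)
  for (r in 1:100) {
    mir <- paste(sample(c("A", "C", "G", "U"), 22, TRUE), collapse = "")
    utr <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    got <- seed_match_targets(c(m = mir), c(g = utr))
    site <- revcomp(chartr("U", "T", substr(mir, 2, 8)))
    oracle <- integer(0)
    for (s in 1:(60 - 6)) {
      if (substr(utr, s, s + 6) == site) oracle <- c(oracle, s)
    }
    if (length(oracle) == 0) {
      expect_equal(nrow(got), 0)
    } else {
      expect_identical(got$positions, paste(oracle, collapse = ","))
    }
  }
})

test_that("rank correlation handles ties and degenerate input", {
  expect_equal(spearman_rho(1:5, 5:1), -1)
  expect_equal(spearman_rho(1:5, 1:5), 1)
  expect_true(is.na(spearman_rho(1:5, rep(2, 5))))
  expect_error(spearman_rho(1:4, 1:5), "mismatch")
  # tied case against the reference implementation and the hand value
  a <- c(1, 2, 2, 4); b <- c(4, 3, 3, 1)
  expect_equal(spearman_rho(a, b), cor(a, b, method = "spearman"))
  expect_equal(spearman_rho(a, b), -1)   # mirrored tie pattern
  set.seed(62)
  for (r in 1:20) {
    x <- sample(1:4, 6, TRUE); y <- sample(1:4, 6, TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearman_rho(x, y), cor(x, y, method = "spearman"))
  }
})

toy_pairing <- function() {
  stages <- c(40L, 55L, 63L, 70L, 90L)
  lib_ids <- as.vector(vapply(c("TC", "YK"), function(b) paste0(b, stages),
                              character(5)))
  counts <- rbind(m1 = rep(c(100L, 80L, 60L, 40L, 20L), 2),
                  m2 = rep(50L, 10))
  colnames(counts) <- lib_ids
  meta <- data.frame(library_id = lib_ids,
                     breed = rep(c("TC", "YK"), each = 5),
                     stage = rep(stages, 2), total_reads = 1e6,
                     stringsAsFactors = FALSE)
  expr <- tpm_normalize(mir_expr(counts, meta))
  mrna <- rbind(gUp = rep(c(10, 20, 30, 40, 50), 2),       # mirrors m1
                gFlat = rep(c(30, 31, 29, 30, 31), 2))     # weak trend
  colnames(mrna) <- lib_ids
  list(expr = expr, mrna = mrna)
}

test_that("pairing requires prediction, breed-DE membership and strong anticorrelation", {
  tp <- toy_pairing()
  predicted <- data.frame(mirna_id = c("m1", "m1", "m2"),
                          mrna_id = c("gUp", "gFlat", "gUp"))
  pairs <- pair_breed_de(c("m1"), predicted, tp$expr, tp$mrna)
  # m2 rows are absent (not breed-DE); m1/gUp passes; m1/gFlat does not
  expect_setequal(pairs$mirna_id, "m1")
  expect_true(pairs$passes_pairing[pairs$mrna_id == "gUp"])
  expect_equal(pairs$rho_TC[pairs$mrna_id == "gUp"], -1)
  expect_false(pairs$passes_pairing[pairs$mrna_id == "gFlat"])
  # an unpredicted pair never appears, whatever its correlation
  expect_false("m2" %in% pairs$mirna_id)
  # threshold gate: rho = -0.4 would need a laxer threshold to pass
  lax <- pair_breed_de(c("m1"), predicted, tp$expr, tp$mrna,
                       rho_threshold = 0.99)
  expect_true(all(lax$passes_pairing))
})

test_that("the breed-DE mRNA intersection keeps exactly the matching pairs", {
  pairs <- data.frame(mirna_id = c("m1", "m1", "m2"),
                      mrna_id = c("g1", "g2", "g3"),
                      passes_pairing = c(TRUE, TRUE, TRUE))
  expect_equal(nrow(intersect_breed_de_mrna(pairs, character(0))), 0)
  all_in <- intersect_breed_de_mrna(pairs, c("g1", "g2", "g3"))
  expect_equal(nrow(all_in), 3)
  some <- intersect_breed_de_mrna(pairs, c("g2"))
  expect_identical(some$mrna_id, "g2")
})

test_that("correlation filter and mRNA intersection commute", {
  set.seed(63)
  pairs <- data.frame(mirna_id = paste0("m", sample(1:5, 30, TRUE)),
                      mrna_id = paste0("g", sample(1:8, 30, TRUE)),
                      passes_pairing = sample(c(TRUE, FALSE), 30, TRUE))
  pairs <- unique(pairs)
  de_mrnas <- c("g1", "g3", "g5")
  a <- intersect_breed_de_mrna(pairs, de_mrnas)
  b0 <- pairs[pairs$mrna_id %in% de_mrnas, ]
  b <- b0[b0$passes_pairing, ]
  expect_setequal(paste(a$mirna_id, a$mrna_id), paste(b$mirna_id, b$mrna_id))
})

test_that("a star network has one hub and degree-5 nodes are hubs (inclusive)", {
  star <- data.frame(mirna_id = "m1", mrna_id = paste0("g", 1:6))
  net <- build_network(star)
  n <- net$nodes
  expect_equal(n$degree[n$name == "m1"], 6)
  expect_true(n$hub[n$name == "m1"])
  expect_true(all(!n$hub[n$type == "mRNA"]))
  five <- build_network(data.frame(mirna_id = "m1", mrna_id = paste0("g", 1:5)))
  expect_true(five$nodes$hub[five$nodes$name == "m1"])
  four <- build_network(data.frame(mirna_id = "m1", mrna_id = paste0("g", 1:4)))
  expect_false(four$nodes$hub[four$nodes$name == "m1"])
})

test_that("degrees equal a brute-force edge tally on random bipartite graphs", {
  set.seed(64)
  for (r in 1:50) {
    pairs <- unique(data.frame(
      mirna_id = paste0("m", sample(1:6, 20, TRUE)),
      mrna_id = paste0("g", sample(1:10, 20, TRUE))))
    net <- build_network(pairs)
    for (i in seq_len(nrow(net$nodes))) {
      nm <- net$nodes$name[i]
      tally <- sum(pairs$mirna_id == nm) + sum(pairs$mrna_id == nm)
      expect_equal(net$nodes$degree[i], tally)
    }
  }
})

test_that("adding an edge never decreases a degree or removes a hub", {
  set.seed(65)
  pairs <- unique(data.frame(mirna_id = paste0("m", sample(1:4, 12, TRUE)),
                             mrna_id = paste0("g", sample(1:6, 12, TRUE))))
  net1 <- build_network(pairs)
  extra <- data.frame(mirna_id = "m1", mrna_id = "gNew")
  net2 <- build_network(rbind(pairs, extra))
  common <- intersect(net1$nodes$name, net2$nodes$name)
  d1 <- stats::setNames(net1$nodes$degree, net1$nodes$name)[common]
  d2 <- stats::setNames(net2$nodes$degree, net2$nodes$name)[common]
  expect_true(all(d2 >= d1))
  h1 <- net1$nodes$name[net1$nodes$hub]
  expect_true(all(h1 %in% net2$nodes$name[net2$nodes$hub]))
})

test_that("network exports are valid and GraphML round-trips degrees", {
  empty <- build_network(data.frame(mirna_id = character(0),
                                    mrna_id = character(0)))
  sif0 <- withr::local_tempfile(fileext = ".sif")
  gml0 <- withr::local_tempfile(fileext = ".graphml")
  export_network(empty, sif0, gml0)
  expect_length(readLines(sif0), 0)
  expect_silent(igraph::read_graph(gml0, format = "graphml"))

  pairs <- data.frame(mirna_id = c("m1", "m1", "m2"),
                      mrna_id = c("g1", "g2", "g1"))
  net <- build_network(pairs)
  sif <- withr::local_tempfile(fileext = ".sif")
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, sif, gml)
  expect_length(readLines(sif), 3)
  back <- igraph::read_graph(gml, format = "graphml")
  deg_back <- igraph::degree(back)[igraph::V(back)$name]
  deg_mine <- stats::setNames(net$nodes$degree, net$nodes$name)
  expect_equal(unname(deg_back[names(deg_mine)]), unname(deg_mine))
})

test_that("binomial overrepresentation matches closed forms", {
  ann <- data.frame(term = c(rep("t1", 5), rep("t2", 10)),
                    gene = c(paste0("g", 1:5), paste0("g", 1:10)))
  # q = 1 for t2 over a 10-gene universe: never enriched
  res <- binomial_overrepresentation(paste0("g", 1:5), ann)
  expect_equal(res$p_value[res$term == "t2"], 1)
  # n = k = 5 at q = 0.5: p = 0.5^5
  expect_equal(res$p_value[res$term == "t1"], 0.03125)
  expect_true(res$enriched[res$term == "t1"])
  # k = 0 gives p = 1
  ann2 <- data.frame(term = "t1", gene = c("g1", "g2"))
  r2 <- binomial_overrepresentation("g3", ann2, universe = paste0("g", 1:3))
  expect_equal(r2$p_value, 1)
  expect_error(binomial_overrepresentation("g1", ann2, universe = character(0)),
               "universe")
  expect_error(binomial_overrepresentation("gX", ann2), "subset")
})

test_that("final network edges equal the planted qualifying pairs exactly", {
  study <- small_study()
  res <- small_pipeline()
  qual <- study$truth$target_pairs[study$truth$target_pairs$qualifying, ]
  expect_setequal(paste(res$final_pairs$mirna_id, res$final_pairs$mrna_id),
                  paste(qual$mirna_id, qual$mrna_id))
})
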