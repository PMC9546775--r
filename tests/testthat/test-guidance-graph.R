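make_toy_features <- function() {
  genes <- genomic_features(
    id = c("gA", "gB", "gC"), chrom = c("chr1", "chr1", "chr2"),
    start = c(10000, 50000, 3000), end = c(20000, 58000, 9000),
    strand = c("+", "-", "+"), kind = "gene")
  peaks <- genomic_features(
    id = c("p1", "p2", "p3", "p4"), chrom = c("chr1", "chr1", "chr1", "chr3"),
    start = c(9000, 57000, 300000, 100), end = c(9500, 60500, 300500, 600),
    strand = ".", kind = "peak")
  list(genes = genes, peaks = peaks)
}

test_that("power-law weight matches the high-precision power evaluations", {
  expect_identical(power_law_weight(0), 1)
  expect_equal(power_law_weight(1), 0.5946035575013605, tolerance = 1e-14)
  expect_equal(power_law_weight(150), 0.023214925245477008,
               tolerance = 1e-14)
  d <- seq(0, 300, by = 7.3)
  w <- power_law_weight(d)
  expect_true(all(diff(w) < 0))
  expect_true(all(w > 0 & w <= 1))
  expect_error(power_law_weight(-1), "non-negative")
})

test_that("overlap graph handles promoters, strands and half-open edges", {
  f <- make_toy_features()
  g <- build_overlap_graph(f$genes, f$peaks)
  ce <- omicbridge:::cross_edges(g)
  key <- sort(paste(ce$i, ce$j))
  # p1 overlaps gA's promoter [8000,10000); p2 overlaps gB body and its
  # (minus-strand) promoter [58000,60000); p3 too far; p4 wrong chrom
  expect_identical(key, sort(c("p1 gA", "p2 gB")))
  expect_true(all(ce$weight == 1 & ce$sign == 1))
  # touching but half-open disjoint: peak ending exactly at promoter start
  peaks2 <- genomic_features("pt", "chr1", 0, 8000, ".", "peak")
  g2 <- build_overlap_graph(f$genes, peaks2)
  expect_identical(nrow(omicbridge:::cross_edges(g2)), 0L)
})

test_that("overlap and window graphs match all-pairs brute force", {
  set.seed(99)
  n_g <- 20; n_p <- 50
  gs <- sort(sample.int(2e6, n_g))
  genes <- genomic_features(sprintf("g%02d", 1:n_g),
                            sample(c("chr1", "chr2"), n_g, TRUE),
                            gs, gs + sample(500:20000, n_g, TRUE),
                            sample(c("+", "-"), n_g, TRUE), "gene")
  ps <- sample.int(2e6, n_p)
  peaks <- genomic_features(sprintf("p%02d", 1:n_p),
                            sample(c("chr1", "chr2"), n_p, TRUE),
                            ps, ps + sample(200:1000, n_p, TRUE), ".",
                            "peak")
  g <- build_overlap_graph(genes, peaks)
  ce <- omicbridge:::cross_edges(g)
  ref <- oracle_overlap_edges(peaks, genes)
  expect_setequal(paste(ce$i, ce$j), paste(ref$i, ref$j))

  gw <- build_window_graph(genes, peaks, window_kb = 150)
  cw <- omicbridge:::cross_edges(gw)
  refw <- oracle_window_edges(peaks, genes, 150)
  expect_setequal(paste(cw$i, cw$j), paste(refw$i, refw$j))
  ord <- match(paste(cw$i, cw$j), paste(refw$i, refw$j))
  expect_equal(cw$weight, refw$w[ord], tolerance = 1e-12)
})

test_that("window graph limit reduces to the all-pairs bipartite graph", {
  f <- make_toy_features()
  g <- build_window_graph(f$genes, f$peaks, window_kb = Inf,
                          decay_exponent = 0)
  ce <- omicbridge:::cross_edges(g)
  # every same-chromosome pair connects with weight 1
  same_chr <- sum(outer(f$peaks$chrom, f$genes$chrom, "=="))
  expect_identical(nrow(ce), as.integer(same_chr))
  expect_true(all(ce$weight == 1))
})

test_that("evidence composition sums, clips and keeps parallel edges", {
  g <- guidance_graph(c("p1", "gA"),
                      data.frame(i = "p1", j = "gA", sign = 1, weight = 0.4))
  # two pcHi-C contacts for one pair: weights summed then clipped to 1
  ev <- data.frame(i = c("p1", "p1"), j = c("gA", "gA"),
                   weight = c(0.6, 0.7), tag = "pchic")
  g2 <- compose_evidence_graph(g, ev)
  ce <- omicbridge:::cross_edges(g2)
  expect_identical(nrow(ce), 2L) # window edge + one merged pcHi-C edge
  expect_equal(ce$weight[ce$tag == "pchic"], 1)
  # identity on empty evidence
  expect_identical(compose_evidence_graph(g, NULL)$edges, g$edges)
  # distinct tags stay as parallel edges
  ev2 <- data.frame(i = c("p1", "p1"), j = c("gA", "gA"),
                    weight = c(0.5, 1), tag = c("pchic", "eqtl"))
  g3 <- compose_evidence_graph(g, ev2)
  expect_identical(nrow(omicbridge:::cross_edges(g3)), 3L)
  expect_error(compose_evidence_graph(
    g, data.frame(i = "p1", j = "gA", weight = 0, tag = "x")), "positive")
})

test_that("graph corruption preserves counts, is deterministic, replaces fully at rate 1", {
  sim <- small_sim()
  g <- sim$graph
  n_cross <- nrow(omicbridge:::cross_edges(g))
  expect_identical(corrupt_graph(g, 0)$edges, g$edges)
  c1 <- corrupt_graph(g, 0.5, seed = 11)
  c2 <- corrupt_graph(g, 0.5, seed = 11)
  expect_identical(c1$edges, c2$edges)
  expect_identical(nrow(omicbridge:::cross_edges(c1)), n_cross)
  expect_identical(c1$vertices, g$vertices)
  full <- corrupt_graph(g, 1, seed = 3)
  orig <- paste(pmin(g$edges$i, g$edges$j), pmax(g$edges$i, g$edges$j))
  new <- omicbridge:::cross_edges(full)
  expect_false(any(paste(pmin(new$i, new$j), pmax(new$i, new$j)) %in%
                     orig[g$edges$i != g$edges$j]))
  expect_identical(nrow(new), n_cross)
  expect_error(corrupt_graph(g, 1.2), "rate")
})

test_that("graph validation flags broken invariants and unguided features", {
  g <- guidance_graph(c("a", "b"),
                      data.frame(i = "a", j = "b", sign = 1, weight = 0.5))
  expect_silent(validate_graph(g))
  gbad <- g
  gbad$edges$weight[1] <- 1.5
  expect_error(validate_graph(gbad), "a--b")
  gbad2 <- g
  gbad2$edges <- gbad2$edges[gbad2$edges$i != "b" | gbad2$edges$j != "b", ]
  expect_error(validate_graph(gbad2), "self-loop")
  sim <- small_sim()
  rep <- validate_graph(sim$graph, sim$layers, error = FALSE)
  linked <- unique(unlist(omicbridge:::cross_edges(sim$graph)[c("i", "j")]))
  all_feats <- unlist(lapply(sim$layers, function(l) l$features))
  expect_setequal(rep$unguided, setdiff(all_feats, linked))
})

test_that("graphs survive a GraphML round trip losslessly", {
  sim <- small_sim()
  g <- compose_evidence_graph(
    sim$graph, data.frame(i = sim$layers$atac$features[1:3],
                          j = sim$layers$rna$features[1:3],
                          weight = c(0.25, 1, 0.7), tag = "pchic",
                          sign = c(1, -1, 1)))
  path <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(g, path)
  g2 <- read_graphml(path)
  key <- function(gg) {
    e <- gg$edges
    sort(paste(pmin(e$i, e$j), pmax(e$i, e$j), e$sign,
               signif(e$weight, 9), e$tag))
  }
  expect_identical(key(g2), key(g))
  expect_setequal(g2$vertices$id, g$vertices$id)
  expect_identical(
    g2$vertices$layer[match(g$vertices$id, g2$vertices$id)],
    g$vertices$layer)
})

test_that("guidance graph construction is symmetric in argument layers", {
  f <- make_toy_features()
  g1 <- build_overlap_graph(f$genes, f$peaks)
  ce <- omicbridge:::cross_edges(g1)
  # undirected semantics: each edge describes an unordered pair
  expect_setequal(paste(pmin(ce$i, ce$j), pmax(ce$i, ce$j)),
                  c("gA p1", "gB p2"))
})
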