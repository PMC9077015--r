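test_that("canonicalization unifies the published spelling variants", {
  expect_equal(canonicalizeName("Glycolysis/gluconeogenesis"),
               canonicalizeName("glycolysis or gluconeogenesis"))
  expect_equal(canonicalizeName("Glycolysis / Gluconeogenesis"),
               canonicalizeName("Glycolysis/gluconeogenesis"))
  # stereo-prefixes survive
  expect_match(canonicalizeName("d-Glutamine and d-glutamate metabolism"), "d-glutamine")
  # idempotence
  x <- c("Valine, leucine and isoleucine biosynthesis", "Taurine (serum)")
  expect_equal(canonicalizeName(canonicalizeName(x)), canonicalizeName(x))
})

test_that("random case and spacing perturbations leave keys invariant", {
  set.seed(1)
  base <- c("Arginine and proline metabolism", "Pyruvate metabolism",
            "Glycine, serine and threonine metabolism")
  for (i in 1:50) {
    nm <- sample(base, 1)
    chars <- strsplit(nm, "")[[1]]
    flip <- runif(length(chars)) < 0.3
    chars[flip] <- ifelse(runif(sum(flip)) < 0.5, toupper(chars[flip]),
                          tolower(chars[flip]))
    messy <- gsub(" ", "  ", paste(chars, collapse = ""), fixed = TRUE)
    expect_equal(canonicalizeName(paste0("  ", messy, " ")),
                 canonicalizeName(nm))
  }
})

test_that("pathway overlap partitions the metabonomics set", {
  metab <- c("Pyruvate metabolism", "Galactose metabolism")
  sys <- c("pyruvate  Metabolism", "MAPK signaling pathway")
  ov <- overlapPathways(metab, sys)
  expect_equal(ov$overlapping, "Pyruvate metabolism")
  expect_equal(ov$non_overlapping, "Galactose metabolism")
  disj <- overlapPathways(metab, "something else")
  expect_equal(disj$overlapping, character(0))
  expect_setequal(disj$non_overlapping, metab)
  # brute-force oracle on random sets
  set.seed(2)
  a <- sprintf("pw %02d", sample(40, 15))
  b <- sprintf("PW %02d", sample(40, 15))
  ov2 <- overlapPathways(a, b)
  oracle <- a[canonicalizeName(a) %in% canonicalizeName(b)]
  expect_setequal(ov2$overlapping, oracle)
})

test_that("the published overlap structure is reproduced from bundled tables", {
  tab <- referencePathwayResults()
  sig <- tab$name[tab$raw_p < 0.05]
  expect_equal(length(sig), 10L)
  ov <- overlapPathways(sig, exampleSyspharmPathways())
  expect_equal(length(ov$overlapping), 6L)
  expect_equal(length(ov$non_overlapping), 4L)
  expect_setequal(ov$non_overlapping, c(
    "d-Glutamine and d-glutamate metabolism",
    "Alanine, aspartate and glutamate metabolism",
    "Ubiquinone and other terpenoid-quinone biosynthesis",
    "Galactose metabolism"
  ))
})

test_that("a one-to-one chain reverse-maps to a 4-node path with unit degrees", {
  nw <- reverseMap(
    "pw",
    protein_pathway = data.frame(protein = "pr", pathway = "pw"),
    compound_protein = data.frame(compound = "cp", protein = "pr"),
    herb_compound = data.frame(herb = "hb", compound = "cp")
  )
  expect_equal(unname(tierCounts(nw)), c(1L, 1L, 1L, 1L))
  g <- networkGraph(nw)
  expect_equal(igraph::ecount(g), 3)
  expect_true(all(igraph::degree(g) <= 2))
  expect_equal(sort(unname(igraph::degree(g)))[c(1, 4)], c(1, 2))
})

test_that("reverse mapping keeps exactly the connected tiers and is monotone", {
  pp <- data.frame(protein = c("p1", "p2", "p3"),
                   pathway = c("A", "B", "C"))
  cp <- data.frame(compound = c("c1", "c1", "c2", "c3"),
                   protein = c("p1", "p2", "p2", "p3"))
  hc <- data.frame(herb = c("h1", "h2", "h2"),
                   compound = c("c1", "c2", "c3"))
  nw1 <- reverseMap("A", pp, cp, hc)
  expect_equal(tierCounts(nw1), c(herb = 1L, compound = 1L, protein = 1L,
                                  pathway = 1L))
  nw2 <- reverseMap(c("A", "B"), pp, cp, hc)
  n1 <- igraph::V(networkGraph(nw1))$name
  n2 <- igraph::V(networkGraph(nw2))$name
  expect_true(all(n1 %in% n2))
  # no node unreachable from a pathway node
  g2 <- networkGraph(nw2)
  pn <- which(igraph::V(g2)$tier == "pathway")
  dist <- igraph::distances(g2, v = pn)
  expect_true(all(is.finite(apply(dist, 2, min))))
  # empty overlap warns and returns an empty network
  expect_warning(nw0 <- reverseMap("zzz", pp, cp, hc), "empty")
  expect_equal(sum(tierCounts(nw0)), 0L)
})

test_that("network exports round-trip through GraphML and SIF line counts match", {
  nw <- reverseMap(
    c("A", "B"),
    protein_pathway = data.frame(protein = c("p1", "p2"), pathway = c("A", "B")),
    compound_protein = data.frame(compound = c("c1", "c2"), protein = c("p1", "p2")),
    herb_compound = data.frame(herb = "h1", compound = c("c1", "c2"))
  )
  path <- tempfile("net")
  files <- exportNetwork(nw, path)
  sif <- readLines(paste0(path, ".sif"))
  expect_equal(length(sif), igraph::ecount(networkGraph(nw)))
  back <- readNetworkGraphML(paste0(path, ".graphml"))
  expect_equal(tierCounts(back), tierCounts(nw))
  g0 <- networkGraph(nw); g1 <- networkGraph(back)
  expect_true(igraph::isomorphic(g0, g1))
  expect_setequal(igraph::V(g1)$name, igraph::V(g0)$name)
  expect_equal(sum(tierCounts(back)), igraph::vcount(g1))
  expect_error(exportNetwork(nw, path, formats = "dot"), "unsupported")
})
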