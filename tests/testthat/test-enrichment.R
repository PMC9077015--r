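test_that("metabolite matching equals brute-force set intersection", {
  set.seed(1)
  membs <- replicate(8, sprintf("C%03d", sample(40, 6)), simplify = FALSE)
  lib <- toyLibrary(membs)
  q <- data.frame(query = letters[1:10], kegg = sprintf("C%03d", sample(40, 10)),
                  stringsAsFactors = FALSE)
  hits <- matchMetabolites(q, lib)
  for (i in seq_along(membs))
    expect_setequal(hits[[sprintf("P%02d", i)]], intersect(membs[[i]], q$kegg))
  empty <- matchMetabolites(q[0, ], lib)
  expect_true(all(lengths(empty) == 0))
})

test_that("query names fall back when KEGG ids are missing", {
  lib <- toyLibrary(list(c("C00183", "valine-like")))
  q <- data.frame(query = c("Valine-Like", "absent"),
                  kegg = c(NA_character_, NA_character_),
                  stringsAsFactors = FALSE)
  hits <- matchMetabolites(q, lib)
  expect_equal(hits$P01, "valine-like")
  expect_equal(attr(hits, "unmatched"), "absent")
})

test_that("hypergeometric tail matches trivial cases and rejects bad counts", {
  expect_equal(oraPvalue(0, 5, 3, 10), 1)
  expect_equal(oraPvalue(3, 3, 3, 3), 1)
  expect_error(oraPvalue(4, 3, 5, 10), "inconsistent")
})

test_that("ORA equals literal draw enumeration for small universes", {
  # enumerate every C(universe, query) draw and count those with >= h marked
  enum <- function(h, total, q, u) {
    marked <- seq_len(total)
    draws <- utils::combn(u, q)
    mean(colSums(matrix(draws %in% marked, nrow = q)) >= h)
  }
  for (u in c(6, 8, 10)) {
    for (total in c(2, u %/% 2)) {
      for (q in c(2, u %/% 2)) {
        for (h in 0:min(total, q)) {
          expect_equal(oraPvalue(h, total, q, u), enum(h, total, q, u),
                       tolerance = 1e-12,
                       label = sprintf("h=%d total=%d q=%d u=%d", h, total, q, u))
        }
      }
    }
  }
})

test_that("ORA equals an exact choose()-based tail for universes up to 20", {
  tailp <- function(h, total, q, u) {
    ks <- h:min(total, q)
    sum(choose(total, ks) * choose(u - total, q - ks)) / choose(u, q)
  }
  set.seed(2)
  for (i in 1:60) {
    u <- sample(2:20, 1)
    total <- sample(u, 1)
    q <- sample(u, 1)
    h <- sample(0:min(total, q), 1)
    expect_equal(oraPvalue(h, total, q, u), tailp(h, total, q, u),
                 tolerance = 1e-12)
  }
})

test_that("ORA is non-increasing in hits and its pmf sums to one", {
  for (u in c(5, 12, 20)) {
    total <- u %/% 2; q <- u %/% 3 + 1
    ps <- vapply(0:min(total, q), function(h) oraPvalue(h, total, q, u),
                 numeric(1))
    expect_true(all(diff(ps) <= 1e-12))
    pmf <- vapply(0:min(total, q), function(h)
      choose(total, h) * choose(u - total, q - h) / choose(u, q), numeric(1))
    expect_equal(sum(pmf), 1, tolerance = 1e-12)
    expect_equal(sum(stats::dhyper(0:min(total, q), total, u - total, q)), 1,
                 tolerance = 1e-12)
  }
})

test_that("-log(p) is the natural log and rejects nonpositive input", {
  expect_equal(negLogP(1), 0)
  expect_equal(negLogP(exp(-3)), 3)
  expect_error(negLogP(0), "must lie")
  expect_error(negLogP(-0.1), "must lie")
})

test_that("pathway impact handles the trivial and path-graph cases", {
  members <- c("a", "b", "c")
  edges <- rbind(c("a", "b"), c("b", "c"))
  expect_equal(pathwayImpact(character(0), members, edges), 0)
  expect_equal(pathwayImpact("b", members, edges), 1)   # only b has betweenness
  expect_equal(pathwayImpact("a", members, edges), 0)
  expect_equal(pathwayImpact(members, members, edges), 1)
  # all centralities zero (2-node pathway)
  expect_equal(pathwayImpact("x", c("x", "y"), rbind(c("x", "y"))), 0)
  expect_error(pathwayImpact("zz", members, edges), "absent")
})

test_that("per-pathway importances sum to one whenever positive", {
  set.seed(3)
  for (i in 1:5) {
    n <- sample(4:8, 1)
    members <- sprintf("n%02d", 1:n)
    edges <- cbind(members[-n], members[-1])
    extra <- cbind(sample(members, 2), sample(members, 2))
    g_imp <- pathwayImpact(members, members, rbind(edges, extra))
    expect_equal(g_imp, 1, tolerance = 1e-12)
  }
})

test_that("the enrichment table ranks a planted pathway first across seeds", {
  q <- queryMetabolites()
  for (s in 1:20) {
    cfg <- syntheticConfig(seed = s, planted_overlap_names = "Pyruvate metabolism")
    ct <- generateCompoundTable(cfg)
    tl <- generateTargetPathwayLibrary(cfg, ct$truth)
    et <- buildEnrichmentTable(q, tl$library)
    expect_gt(nrow(et), 0)
    expect_equal(et$name[1], "Pyruvate metabolism")
    expect_true(et$significant[1])
  }
})

test_that("enrichment rows respect their own invariants", {
  set.seed(4)
  membs <- replicate(6, sprintf("C%03d", sample(50, 8)), simplify = FALSE)
  lib <- toyLibrary(membs)
  q <- data.frame(query = paste0("m", 1:12),
                  kegg = sprintf("C%03d", sample(50, 12)))
  et <- buildEnrichmentTable(q, lib)
  expect_true(all(et$hits <= et$total))
  expect_true(all(et$hits >= 1))
  expect_equal(et$neg_log_p, -log(et$raw_p), tolerance = 1e-12)
  expect_true(!is.unsorted(et$raw_p))
  expect_true(all(et$impact >= 0 & et$impact <= 1))
})

test_that("a pathway library round-trips through its text format", {
  set.seed(5)
  membs <- replicate(4, sprintf("C%03d", sample(30, 5)), simplify = FALSE)
  prots <- replicate(4, sprintf("p%02d", sample(20, 3)), simplify = FALSE)
  lib <- toyLibrary(membs, prots)
  f <- tempfile(fileext = ".txt")
  writePathwayLibrary(lib, f)
  back <- readPathwayLibrary(f)
  expect_equal(back@pathways, lib@pathways)
  expect_equal(back@compounds, lib@compounds)
  expect_equal(back@proteins, lib@proteins)
  for (id in pathwayIds(lib))
    expect_equal(unname(back@edges[[id]]), unname(lib@edges[[id]]))
})
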