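test_that("configuration invariants are enforced", {
  expect_error(syntheticConfig(n_herbs = 0), "positive")
  expect_error(syntheticConfig(n_planted_active = 1000), "planted")
  expect_error(syntheticConfig(noise_cv = -0.1), "noise_cv")
  et <- defaultEffectTable(); et$fold_change[1] <- -1
  expect_error(syntheticConfig(effect_table = et), "fold")
  et2 <- defaultEffectTable(); et2$metabolite[1] <- "unobtainium"
  expect_error(syntheticConfig(effect_table = et2), "unknown metabolite")
})

test_that("compound generator plants exactly the requested actives", {
  cfg <- syntheticConfig(seed = 7, n_herbs = 2, n_compounds_per_herb = 3,
                         n_planted_active = 2)
  out <- generateCompoundTable(cfg)
  expect_equal(nrow(out$table), 6L)
  screened <- screenCompounds(out$table)
  expect_setequal(screened$compound_id, out$truth$active_compound_ids)
  expect_equal(nrow(screened), 2L)
  none <- generateCompoundTable(syntheticConfig(seed = 7, n_planted_active = 0))
  expect_equal(nrow(screenCompounds(none$table)), 0L)
})

test_that("screen consistency holds over a grid of small configurations", {
  for (nh in c(1, 3)) for (nc in c(2, 5)) for (na in c(0, 2, nh * nc)) {
    cfg <- syntheticConfig(seed = 13, n_herbs = nh, n_compounds_per_herb = nc,
                           n_planted_active = na)
    out <- generateCompoundTable(cfg)
    expect_equal(nrow(screenCompounds(out$table)), na,
                 label = sprintf("nh=%d nc=%d na=%d", nh, nc, na))
  }
})

test_that("all three generators are seed-deterministic", {
  cfg <- syntheticConfig(seed = 7)
  a <- generateCompoundTable(cfg); b <- generateCompoundTable(cfg)
  expect_identical(a, b)
  expect_false(identical(
    a$table, generateCompoundTable(syntheticConfig(seed = 8))$table))
  ta <- generateTargetPathwayLibrary(cfg, a$truth)
  tb <- generateTargetPathwayLibrary(cfg, b$truth)
  expect_identical(ta$hits, tb$hits)
  expect_identical(ta$library@compounds, tb$library@compounds)
  sa <- generateSpectra(cfg, npoints = 4096)
  sb <- generateSpectra(cfg, npoints = 4096)
  expect_identical(sa$spectra@spectra[[5]]@intensity,
                   sb$spectra@spectra[[5]]@intensity)
  # generators do not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(generateCompoundTable(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("every planted active receives a passing target hit", {
  cfg <- syntheticConfig(seed = 3)
  ct <- generateCompoundTable(cfg)
  tl <- generateTargetPathwayLibrary(cfg, ct$truth)
  ok <- tl$hits[tl$hits$z_score >= 0.8 & tl$hits$fit_rank <= 300, ]
  expect_setequal(unique(ok$compound_id), ct$truth$active_compound_ids)
  expect_error(generateTargetPathwayLibrary(cfg, list()), "consistency")
})

test_that("planted overlap pathways contain both active targets and biomarker ids", {
  cfg <- syntheticConfig(seed = 5, planted_overlap_names = "Pyruvate metabolism")
  ct <- generateCompoundTable(cfg)
  tl <- generateTargetPathwayLibrary(cfg, ct$truth)
  nm <- pathwayNames(tl$library)
  pid <- names(nm)[nm == "Pyruvate metabolism"]
  expect_length(pid, 1L)
  prots <- pathwayProteins(tl$library)[[pid]]
  expect_gt(length(intersect(prots, tl$truth$target_proteins)), 0)
  kegg <- biomarkerAnnotationTable()$kegg
  expect_gt(length(intersect(pathwayCompounds(tl$library)[[pid]], kegg)), 0)
  # line-graph members: a 3+ member pathway has members - 1 edges
  for (id in pathwayIds(tl$library)) {
    m <- length(pathwayCompounds(tl$library)[[id]])
    expect_equal(nrow(pathwayEdges(tl$library)[[id]]), m - 1L)
  }
})

test_that("planted directions shape the bucketed group means (valine down)", {
  gen <- generateSpectra(syntheticConfig(seed = 2), npoints = 8192)
  raw <- bucketSpectra(gen$spectra, bucketSpec())
  g <- attr(raw, "group")
  ppm <- as.numeric(colnames(raw))
  val <- ppm >= 0.96 & ppm <= 1.03
  m_ctl <- mean(raw[g == "control", val])
  m_mod <- mean(raw[g == "model", val])
  expect_lt(m_mod, m_ctl)
})

test_that("noiseless spectra within a group are identical", {
  gen <- generateSpectra(syntheticConfig(seed = 4, noise_cv = 0), npoints = 2048)
  g <- groupLabels(gen$spectra)
  ctl <- which(g == "control")
  for (i in ctl[-1])
    expect_identical(gen$spectra@spectra[[i]]@intensity,
                     gen$spectra@spectra[[ctl[1]]]@intensity)
  # but groups differ through the planted effects
  mod <- which(g == "model")[1]
  expect_false(identical(gen$spectra@spectra[[mod]]@intensity,
                         gen$spectra@spectra[[ctl[1]]]@intensity))
})

test_that("a lone unit singlet integrates to the Lorentzian area", {
  et <- defaultEffectTable()
  et$dir_model_vs_control <- "none"; et$dir_treated_vs_model <- "none"
  cfg <- syntheticConfig(seed = 1, noise_cv = 0, effect_table = et,
                         groups = "control", n_per_group = 1)
  gen <- generateSpectra(cfg, npoints = 32768)
  sp <- gen$spectra@spectra[[1]]
  asc <- rev(sp@ppm); y <- rev(sp@intensity)
  # acetate singlet at 1.91: integrate a window after removing the local
  # envelope baseline, and compare with height * pi * hw (hw = fwhm / 2)
  win <- asc >= 1.885 & asc <= 1.935
  base <- approx(c(1.885, 1.935),
                 y[c(which.min(abs(asc - 1.885)), which.min(abs(asc - 1.935)))],
                 xout = asc[win])$y
  area <- sum(diff(asc[win]) * (head(y[win] - base, -1) + (y[win] - base)[-1]) / 2)
  oracle <- 0.8 * pi * 0.0015  # conc 0.8, FWHM 0.003
  expect_equal(area, oracle, tolerance = 0.08)
})

test_that("raising a fold change moves only that metabolite's buckets", {
  et <- defaultEffectTable()
  base <- generateSpectra(syntheticConfig(seed = 6, noise_cv = 0,
                                          effect_table = et), npoints = 8192)
  et2 <- et; sel <- et2$metabolite == "valine"
  et2$fold_change[sel] <- 4
  more <- generateSpectra(syntheticConfig(seed = 6, noise_cv = 0,
                                          effect_table = et2), npoints = 8192)
  rb <- bucketSpectra(base$spectra, bucketSpec(), calibrate = FALSE)
  rm_ <- bucketSpectra(more$spectra, bucketSpec(), calibrate = FALSE)
  g <- attr(rb, "group")
  ppm <- as.numeric(colnames(rb))
  val <- ppm >= 0.96 & ppm <= 1.03
  taur <- ppm >= 3.24 & ppm <= 3.26
  dbase <- mean(rb[g == "control", val]) - mean(rb[g == "model", val])
  dmore <- mean(rm_[g == "control", val]) - mean(rm_[g == "model", val])
  expect_gt(dmore, dbase)
  # other metabolites' raw integrals unchanged (up to far Lorentzian tails)
  expect_equal(rm_[g == "model", taur], rb[g == "model", taur], tolerance = 1e-6)
})

test_that("ground truth and spectra write out as text sidecars", {
  cfg <- syntheticConfig(seed = 3, n_per_group = 2)
  gen <- generateSpectra(cfg, npoints = 2048)
  d <- tempfile("gt")
  dir.create(d)
  writeGroundTruth(gen$truth["concentrations"], file.path(d, "truth.yaml"))
  expect_true(file.exists(file.path(d, "truth.yaml")))
  writeSpectra(gen$spectra, file.path(d, "spectra"))
  expect_true(file.exists(file.path(d, "spectra", "manifest.tsv")))
})
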