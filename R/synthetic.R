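#' Multiplet templates for serum metabolites
#'
#' The bundled resonance template used by the spectrum generator: one row per
#' multiplet with its center shift, multiplicity code (s/d/t/q/dd/m) and the
#' metabolite's relative baseline concentration. Shifts follow the serum
#' assignments of the bundled case study.
#'
#' @return data.frame with columns `metabolite`, `center`, `mult`, `conc`.
#' @export
metaboliteTemplates <- function() {
  tb <- rbind(
    c("HDL",                   0.84, "m",  2.0),
    c("lipids",                0.89, "m",  1.0),
    c("lipids",                1.29, "m",  1.0),
    c("leucine",               0.95, "d",  0.8),
    c("valine",                0.97, "d",  0.8),
    c("valine",                1.02, "d",  0.8),
    c("lactate",               1.33, "d", 10.0),
    c("lactate",               4.11, "q", 10.0),
    c("alanine",               1.48, "d",  1.0),
    c("arginine",              1.68, "m",  0.6),
    c("acetate",               1.91, "s",  0.8),
    c("N-acetyl glycoprotein", 2.04, "s",  1.2),
    c("methionine",            2.13, "s",  0.5),
    c("glutamate",             2.14, "m",  0.7),
    c("glutamine",             2.41, "m",  0.8),
    c("creatine",              3.04, "s",  0.9),
    c("taurine",               3.25, "t",  0.9),
    c("taurine",               3.41, "t",  0.9),
    c("TMAO/betaine",          3.27, "s",  1.0),
    c("threonine",             3.56, "dd", 0.9),
    c("myo-inositol",          3.63, "dd", 1.0),
    c("glycerol",              3.64, "dd", 0.9),
    c("glycerol",              3.87, "m",  0.9),
    c("beta-glucose",          4.64, "d",  2.0),
    c("tyrosine",              6.87, "m",  0.4),
    c("tyrosine",              7.17, "m",  0.4)
  )
  data.frame(
    metabolite = tb[, 1], center = as.numeric(tb[, 2]), mult = tb[, 3],
    conc = as.numeric(tb[, 4]), stringsAsFactors = FALSE
  )
}

# Lines (position, relative weight, fwhm) of one multiplet. J fixed at
# 0.014 ppm (7 Hz at 500 MHz); unresolved multiplets (m) are modelled as a
# broadened singlet.
.multipletLines <- function(center, mult, fwhm = 0.003) {
  J <- 0.014
  switch(mult,
    s = data.frame(pos = center, rel = 1, fwhm = fwhm),
    d = data.frame(pos = center + c(-1, 1) * J / 2, rel = c(.5, .5), fwhm = fwhm),
    t = data.frame(pos = center + c(-1, 0, 1) * J, rel = c(.25, .5, .25),
                   fwhm = fwhm),
    q = data.frame(pos = center + c(-1.5, -0.5, 0.5, 1.5) * J,
                   rel = c(.125, .375, .375, .125), fwhm = fwhm),
    dd = data.frame(pos = center + c(-0.75, -0.25, 0.25, 0.75) * J,
                    rel = rep(.25, 4), fwhm = fwhm),
    m = data.frame(pos = center, rel = 1, fwhm = fwhm * 1.2),
    stop("unknown multiplicity: ", mult)
  )
}

# Lorentzian line with unit peak height.
.lorentz <- function(x, pos, fwhm) {
  hw2 <- (fwhm / 2)^2
  hw2 / ((x - pos)^2 + hw2)
}

#' Default planted effect table
#'
#' Per-contrast regulation directions taken from the bundled biomarker panel
#' with a single free fold-change parameter (the study reports directions and
#' significance only, not effect sizes).
#'
#' @param fold_change fold change applied per planted direction (> 1).
#' @return data.frame with columns `metabolite`, `dir_model_vs_control`,
#'   `dir_treated_vs_model`, `fold_change`.
#' @export
defaultEffectTable <- function(fold_change = 2) {
  b <- referenceBiomarkerTable()
  data.frame(
    metabolite = b$metabolite,
    dir_model_vs_control = b$dir_model_vs_control,
    dir_treated_vs_model = b$dir_treated_vs_model,
    fold_change = fold_change, stringsAsFactors = FALSE
  )
}

#' Configuration of the synthetic-data generators
#'
#' One object drives all three generators; identical configurations produce
#' identical outputs. Defaults mirror the bundled case-study design: nine
#' herbs, three groups of eight animals, planted effects in the panel's
#' directions at 2-fold, 10 percent multiplicative biological noise.
#'
#' @param seed integer seed; all randomness flows from it.
#' @param n_herbs number of herbs.
#' @param n_compounds_per_herb compounds per herb.
#' @param n_planted_active number of compounds planted to pass the ADME
#'   screen (every other compound fails at least one criterion).
#' @param n_pathways pathway-library size.
#' @param planted_overlap_names names of the pathways planted to overlap
#'   between the two arms.
#' @param groups group labels.
#' @param n_per_group animals per group.
#' @param effect_table see [defaultEffectTable()].
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (0 switches all stochastic spectral components off).
#' @return a list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(seed = 1, n_herbs = 9, n_compounds_per_herb = 10,
                            n_planted_active = 12, n_pathways = 8,
                            planted_overlap_names = c(
                              "Valine, leucine and isoleucine biosynthesis",
                              "Glycine, serine and threonine metabolism"
                            ),
                            groups = c("control", "model", "treated"),
                            n_per_group = 8,
                            effect_table = defaultEffectTable(),
                            noise_cv = 0.1) {
  if (n_herbs < 1 || n_compounds_per_herb < 1 || n_per_group < 1 ||
      n_pathways < 1)
    stop("configuration error: counts must be positive")
  if (n_planted_active < 0 || n_planted_active > n_herbs * n_compounds_per_herb)
    stop("configuration error: n_planted_active must be <= total compounds")
  if (n_pathways < length(planted_overlap_names))
    stop("configuration error: need n_pathways >= planted overlap names")
  if (any(effect_table$fold_change <= 0))
    stop("configuration error: fold changes must be > 0")
  if (noise_cv < 0) stop("configuration error: noise_cv must be >= 0")
  known <- unique(metaboliteTemplates()$metabolite)
  unknown <- setdiff(effect_table$metabolite, known)
  if (length(unknown))
    stop("template error: unknown metabolite(s) ",
         paste(unknown, collapse = ", "))
  structure(list(
    seed = seed, n_herbs = n_herbs,
    n_compounds_per_herb = n_compounds_per_herb,
    n_planted_active = n_planted_active, n_pathways = n_pathways,
    planted_overlap_names = planted_overlap_names, groups = groups,
    n_per_group = n_per_group, effect_table = effect_table,
    noise_cv = noise_cv
  ), class = "SyntheticConfig")
}

#' Generate a per-herb compound table with planted actives
#'
#' Planted active compounds satisfy all four default ADME thresholds; every
#' other compound is forced to fail at least one. Deterministic for a given
#' configuration.
#'
#' @param config a [syntheticConfig()].
#' @return list with `table` (columns `compound_id`, `name`, `herb`, `OB`,
#'   `BBB`, `DL`, `HL`) and `truth` (list with `active_compound_ids`).
#' @export
generateCompoundTable <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  withSeed(config$seed, {
    n <- config$n_herbs * config$n_compounds_per_herb
    ids <- sprintf("CMP%03d", seq_len(n))
    herbs <- rep(sprintf("H%02d", seq_len(config$n_herbs)),
                 each = config$n_compounds_per_herb)
    active <- sort(sample(ids, config$n_planted_active))
    is_active <- ids %in% active
    OB <- ifelse(is_active, runif(n, 35, 90), runif(n, 5, 95))
    BBB <- ifelse(is_active, runif(n, 0.4, 1.5), runif(n, -0.5, 1.5))
    DL <- ifelse(is_active, runif(n, 0.25, 0.9), runif(n, 0.02, 0.9))
    HL <- ifelse(is_active, runif(n, 6, 24), runif(n, 0.5, 24))
    # force every non-planted compound under at least one threshold
    for (i in which(!is_active)) {
      fail <- sample(4, sample(1:2, 1))
      if (1 %in% fail) OB[i] <- runif(1, 2, 29.9)
      if (2 %in% fail) BBB[i] <- runif(1, -0.5, 0.29)
      if (3 %in% fail) DL[i] <- runif(1, 0.01, 0.17)
      if (4 %in% fail) HL[i] <- runif(1, 0.2, 3.9)
    }
    tbl <- data.frame(
      compound_id = ids, name = paste0("compound-", tolower(ids)),
      herb = herbs, OB = OB, BBB = BBB, DL = DL, HL = HL,
      stringsAsFactors = FALSE
    )
    list(table = tbl, truth = list(active_compound_ids = active))
  })
}

#' Generate target hits and a pathway library with planted overlap
#'
#' Every planted active compound receives at least one target hit passing the
#' rank/Z filter; pathways named in `planted_overlap_names` contain both the
#' proteins those hits point at and the KEGG identifiers of the metabolites
#' planted as discriminative, so the end-to-end integration recovers exactly
#' the planted names. Filler pathways contain neither. Compound members of
#' each pathway are connected as a line graph.
#'
#' @param config a [syntheticConfig()].
#' @param truth the truth component of [generateCompoundTable()] under the
#'   same configuration.
#' @return list with `hits` (target-hit table), `library` (a
#'   [PathwayLibrary-class]) and `truth` (with `overlap_pathway_names`,
#'   `target_proteins`, `discriminative_metabolites` added).
#' @export
generateTargetPathwayLibrary <- function(config, truth) {
  stopifnot(inherits(config, "SyntheticConfig"))
  if (is.null(truth$active_compound_ids))
    stop("consistency error: truth lacks active_compound_ids")
  eff <- config$effect_table
  disc <- eff$metabolite[eff$dir_model_vs_control != "none" |
                         eff$dir_treated_vs_model != "none"]
  ann <- biomarkerAnnotationTable()
  disc_q <- trimws(unlist(strsplit(disc, "/", fixed = TRUE)))
  disc_ids <- ann$kegg[match(tolower(disc_q), tolower(ann$query))]
  disc_ids <- disc_ids[!is.na(disc_ids)]
  withSeed(config$seed + 1L, {
    actives <- truth$active_compound_ids
    prots <- sprintf("PROT%02d", seq_len(max(4, ceiling(length(actives) / 2))))
    rows <- list()
    for (cid in actives) {
      tp <- sample(prots, sample(1:3, 1))
      rk <- seq_along(tp)
      rows[[length(rows) + 1L]] <- data.frame(
        compound_id = cid, protein_id = tp, fit_rank = rk,
        z_score = round(runif(length(tp), 0.9, 2.5), 3),
        stringsAsFactors = FALSE
      )
      # sub-threshold decoy hit
      rows[[length(rows) + 1L]] <- data.frame(
        compound_id = cid, protein_id = "PROTX",
        fit_rank = max(rk) + 1L, z_score = round(runif(1, 0.1, 0.7), 3),
        stringsAsFactors = FALSE
      )
    }
    hits <- do.call(rbind, rows)
    used_prots <- unique(hits$protein_id[hits$z_score >= 0.8])

    n_overlap <- length(config$planted_overlap_names)
    nms <- c(config$planted_overlap_names,
             sprintf("Background pathway %02d", seq_len(config$n_pathways - n_overlap)))
    ids <- sprintf("PWY%02d", seq_len(config$n_pathways))
    compounds <- list(); proteins <- list(); edges <- list()
    for (k in seq_len(config$n_pathways)) {
      if (k <= n_overlap) {
        mem <- sample(disc_ids, min(6, length(disc_ids)))
        mem <- unique(c(mem, sprintf("C9%04d", sample(9000, 4))))
        pr <- sample(used_prots, min(3, length(used_prots)))
      } else {
        mem <- sprintf("C8%04d", sample(9000, 8))
        pr <- sprintf("PROTBG%02d", sample(90, 3))
      }
      compounds[[ids[k]]] <- mem
      proteins[[ids[k]]] <- pr
      edges[[ids[k]]] <- if (length(mem) >= 2)
        cbind(mem[-length(mem)], mem[-1]) else NULL
    }
    lib <- pathwayLibrary(
      data.frame(pathway_id = ids, name = nms, stringsAsFactors = FALSE),
      compounds, proteins, edges, provenance = "synthetic"
    )
    truth$overlap_pathway_names <- config$planted_overlap_names
    truth$target_proteins <- used_prots
    truth$discriminative_metabolites <- disc
    list(hits = hits, library = lib, truth = truth)
  })
}

#' Bucket annotation windows for the bundled metabolite template
#'
#' One window per dominant multiplet line (weak outer lines of triplets and
#' quartets are not annotated, matching how assignment shifts are quoted in
#' practice), each extending `width` ppm either side of the line center.
#'
#' @param width half-width around each annotated line center (ppm).
#' @return data.frame with columns `metabolite`, `lo`, `hi`, one row per
#'   annotated multiplet line.
#' @export
metaboliteBucketMap <- function(width = 0.002) {
  tpl <- metaboliteTemplates()
  rows <- lapply(seq_len(nrow(tpl)), function(i) {
    ln <- .multipletLines(tpl$center[i], tpl$mult[i])
    ln <- ln[ln$rel >= 0.4 * max(ln$rel), , drop = FALSE]
    data.frame(metabolite = tpl$metabolite[i], lo = ln$pos - width,
               hi = ln$pos + width, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate three-group serum-like spectra with planted effects
#'
#' Each animal's spectrum is a sum of Lorentzian multiplets at the template
#' shifts, scaled by group-specific concentrations from the effect table, on
#' top of a stable broad macromolecule envelope, a smooth per-sample baseline,
#' a large residual-water hump inside delta 4.7-5.2, a per-spectrum
#' multiplicative log-normal dilution factor (what total-sum normalization is
#' meant to remove) and an additive Gaussian noise floor. All stochastic
#' components scale with `noise_cv`; at 0 the spectra within a group are
#' identical.
#'
#' @param config a [syntheticConfig()].
#' @param npoints points on the descending delta 0.2-9.0 ppm axis.
#' @return list with `spectra` (a [SpectrumSet-class]) and `truth` (list with
#'   `concentrations` metabolite-by-group means and `bucket_map` annotation
#'   windows).
#' @export
generateSpectra <- function(config, npoints = 16384) {
  stopifnot(inherits(config, "SyntheticConfig"))
  tpl <- metaboliteTemplates()
  eff <- config$effect_table
  unknown <- setdiff(eff$metabolite, tpl$metabolite)
  if (length(unknown))
    stop("template error: unknown metabolite(s) ", paste(unknown, collapse = ", "))
  sgn <- function(d) ifelse(d == "up", 1, ifelse(d == "down", -1, 0))
  mets <- unique(tpl$metabolite)
  conc <- matrix(1, length(mets), length(config$groups),
                 dimnames = list(mets, config$groups))
  for (i in seq_len(nrow(eff))) {
    m <- eff$metabolite[i]; fc <- eff$fold_change[i]
    if ("model" %in% config$groups)
      conc[m, "model"] <- conc[m, "control"] *
        fc^sgn(eff$dir_model_vs_control[i])
    if ("treated" %in% config$groups)
      conc[m, "treated"] <- conc[m, "model"] *
        fc^sgn(eff$dir_treated_vs_model[i])
  }
  ppm <- seq(9.0, 0.2, length.out = npoints)
  # precompute unit-concentration line shapes per metabolite
  shapes <- lapply(mets, function(m) {
    sub <- tpl[tpl$metabolite == m, , drop = FALSE]
    y <- numeric(npoints)
    for (i in seq_len(nrow(sub))) {
      ln <- .multipletLines(sub$center[i], sub$mult[i])
      for (j in seq_len(nrow(ln)))
        y <- y + sub$conc[i] * ln$rel[j] * .lorentz(ppm, ln$pos[j], ln$fwhm[j])
    }
    y
  })
  names(shapes) <- mets
  # stable macromolecule envelope dominating the total integral, so total-sum
  # normalization does not turn planted decreases into spurious increases
  env_centers <- c(0.9, 1.3, 2.2, 3.0, 3.8, 4.3, 5.4, 7.3)
  envelope <- Reduce(`+`, lapply(env_centers, function(ct)
    1.2 * exp(-((ppm - ct)^2) / (2 * 0.35^2))))
  # residual water: a broad hump confined to the discarded 4.7-5.2 window so
  # its amplitude cannot influence any retained bucket
  water <- 10 * max(vapply(shapes, max, numeric(1))) *
    exp(-((ppm - 4.95)^2) / (2 * 0.05^2)) * (ppm > 4.7 & ppm < 5.2)
  cv <- config$noise_cv
  sdlog <- sqrt(log(1 + cv^2))
  withSeed(config$seed + 2L, {
    spectra <- list(); k <- 0
    for (g in config$groups) for (a in seq_len(config$n_per_group)) {
      k <- k + 1
      y <- envelope + water
      for (m in mets) y <- y + conc[m, g] * shapes[[m]]
      # per-spectrum multiplicative dilution, smooth baseline drift and an
      # additive floor, all tied to noise_cv
      b <- rnorm(3, 0, cv)
      y <- y * exp(rnorm(1, 0, sdlog)) +
        0.1 * (b[1] + b[2] * ppm / 9 + b[3] * (ppm / 9)^2) +
        rnorm(npoints, 0, 0.7 * cv)
      spectra[[k]] <- nmrSpectrum(ppm, y,
        sample_id = sprintf("%s_%02d", g, a), group = g)
    }
    list(
      spectra = spectrumSet(spectra),
      truth = list(concentrations = conc, bucket_map = metaboliteBucketMap())
    )
  })
}

#' Write the synthetic ground truth as a text sidecar
#'
#' @param truth a truth list from the generators.
#' @param path file path.
#' @return the path, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  writeLines(yaml::as.yaml(lapply(truth, function(x)
    if (is.matrix(x)) as.data.frame(x) else x)), path)
  invisible(path)
}
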