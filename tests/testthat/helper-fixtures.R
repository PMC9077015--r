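# Shared fixtures, built in code.

# A synthetic spectrum holding a single Lorentzian doublet on a flat baseline.
doubletSpectrum <- function(center = 1.33, sep = 0.014, fwhm = 0.003,
                            height = 5, baseline = 1,
                            lo = 0.2, hi = 9, n = 8001,
                            sample_id = "s1", group = "g") {
  ppm <- seq(hi, lo, length.out = n)
  hw2 <- (fwhm / 2)^2
  y <- baseline +
    height * hw2 / ((ppm - (center - sep / 2))^2 + hw2) +
    height * hw2 / ((ppm - (center + sep / 2))^2 + hw2)
  nmrSpectrum(ppm, y, sample_id = sample_id, group = group)
}

# Random compound property tables straddling the four ADME thresholds.
randomCompounds <- function(n, seed) {
  set.seed(seed)
  data.frame(
    compound_id = sprintf("R%03d", seq_len(n)),
    name = sprintf("cmpd-%03d", seq_len(n)),
    herb = sample(c("HA", "HB", "HC"), n, replace = TRUE),
    OB = runif(n, 0, 60),
    BBB = runif(n, -0.5, 1),
    DL = runif(n, 0, 0.5),
    HL = runif(n, 0, 10),
    stringsAsFactors = FALSE
  )
}

# A small pathway library with an optional line-graph topology per pathway.
toyLibrary <- function(members, proteins = NULL, names = NULL) {
  ids <- sprintf("P%02d", seq_along(members))
  if (is.null(names)) names <- paste("pathway", ids)
  if (is.null(proteins)) proteins <- lapply(members, function(x) character(0))
  edges <- lapply(members, function(m)
    if (length(m) >= 2) cbind(m[-length(m)], m[-1]) else NULL)
  names(members) <- names(proteins) <- names(edges) <- ids
  pathwayLibrary(
    data.frame(pathway_id = ids, name = names, stringsAsFactors = FALSE),
    members, proteins, edges, provenance = "test"
  )
}

# The metabolites planted with a model-vs-control effect under the default
# effect table.
plantedModelVsControl <- function() {
  et <- defaultEffectTable()
  et$metabolite[et$dir_model_vs_control != "none"]
}
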