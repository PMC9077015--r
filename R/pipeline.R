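#' Pipeline configuration with the study-default thresholds
#'
#' Collects every stage parameter: the four ADME thresholds, the target
#' rank/Z filter, the bucketing geometry, the significance levels and the
#' seed. The defaults are the published conventions for this analysis.
#' Configurations round-trip through [writePipelineConfig()] /
#' [readPipelineConfig()] unchanged.
#'
#' @param ob_min,bbb_min,dl_min,hl_min ADME screen thresholds.
#' @param top_n,z_min target-hit filter.
#' @param bucket_width,region,exclusion bucketing geometry (ppm).
#' @param alpha two-tailed level for the critical |r| and univariate calls.
#' @param p_cut,impact_cut enrichment selection cutoffs.
#' @param cv_folds cross-validation folds.
#' @param n_orth orthogonal OPLS-DA components.
#' @param seed integer seed for every stochastic step.
#' @return a named list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(ob_min = 30, bbb_min = 0.3, dl_min = 0.18,
                           hl_min = 4, top_n = 300, z_min = 0.8,
                           bucket_width = 0.004, region = c(0.5, 8.5),
                           exclusion = c(4.7, 5.2), alpha = 0.05,
                           p_cut = 0.05, impact_cut = 0.1, cv_folds = 7,
                           n_orth = 1, seed = 1) {
  structure(list(
    ob_min = ob_min, bbb_min = bbb_min, dl_min = dl_min, hl_min = hl_min,
    top_n = top_n, z_min = z_min, bucket_width = bucket_width,
    region = region, exclusion = exclusion, alpha = alpha, p_cut = p_cut,
    impact_cut = impact_cut, cv_folds = cv_folds, n_orth = n_orth, seed = seed
  ), class = "PipelineConfig")
}

#' @rdname pipelineConfig
#' @param config a `PipelineConfig`.
#' @param path file path (YAML).
#' @export
writePipelineConfig <- function(config, path) {
  writeLines(yaml::as.yaml(unclass(config)), path)
  invisible(path)
}

#' @rdname pipelineConfig
#' @export
readPipelineConfig <- function(path) {
  v <- yaml::yaml.load_file(path)
  do.call(pipelineConfig, v)
}

.stage <- function(log, name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  cat(sprintf("[%s] %s: %.2fs\n", format(Sys.time(), "%H:%M:%S"), name,
              as.numeric(difftime(Sys.time(), t0, units = "secs"))),
      file = log, append = TRUE)
  res
}

.writeTable <- function(x, dir, name) {
  write.table(x, file.path(dir, name), sep = "\t", row.names = FALSE,
              quote = FALSE)
}

#' Run the full dual-arm pipeline
#'
#' Executes screen -> targets -> pathway annotation (pharmacology arm) and
#' calibrate/bucket/normalize -> OPLS-DA -> biomarker selection -> univariate
#' stats -> enrichment (metabonomics arm), then intersects the two pathway
#' sets and reverse-maps the overlap. Every intermediate table, a resolved
#' copy of the configuration, a stage log and a run summary are written into
#' `out_dir`.
#'
#' In `simulate` mode all inputs come from the synthetic generators under
#' `config$seed`; otherwise `input_dir` must contain `compounds.tsv`,
#' `target_hits.tsv`, `pathway_library.txt` and a `spectra/` directory with a
#' manifest.
#'
#' @param config a [pipelineConfig()].
#' @param out_dir run directory (created).
#' @param input_dir directory of input files (ignored when `simulate`).
#' @param simulate logical; generate inputs synthetically.
#' @param syn_config optional [syntheticConfig()]; defaults to one derived
#'   from `config$seed`.
#' @return invisibly, a list with the main stage results (`active`,
#'   `proteins`, `syspharm_pathways`, `enrichment`, `overlap`, `network`,
#'   `summary`).
#' @export
runPipeline <- function(config = pipelineConfig(), out_dir,
                        input_dir = NULL, simulate = FALSE,
                        syn_config = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- file.path(out_dir, "run.log")
  cat("", file = log)
  writePipelineConfig(config, file.path(out_dir, "config.yaml"))

  if (simulate) {
    if (is.null(syn_config)) syn_config <- syntheticConfig(seed = config$seed)
    gen <- .stage(log, "simulate", {
      ct <- generateCompoundTable(syn_config)
      tl <- generateTargetPathwayLibrary(syn_config, ct$truth)
      sp <- generateSpectra(syn_config)
      list(compounds = ct$table, hits = tl$hits, library = tl$library,
           spectra = sp$spectra, truth = c(tl$truth, sp$truth))
    })
    compounds <- gen$compounds; hits <- gen$hits
    library <- gen$library; spectra <- gen$spectra
    bucket_map <- gen$truth$bucket_map
  } else {
    if (is.null(input_dir)) stop("input_dir is required unless simulate = TRUE")
    for (f in c("compounds.tsv", "target_hits.tsv", "pathway_library.txt"))
      if (!file.exists(file.path(input_dir, f)))
        stop("missing input: ", file.path(input_dir, f))
    compounds <- read.delim(file.path(input_dir, "compounds.tsv"),
                            stringsAsFactors = FALSE)
    hits <- read.delim(file.path(input_dir, "target_hits.tsv"),
                       stringsAsFactors = FALSE)
    library <- readPathwayLibrary(file.path(input_dir, "pathway_library.txt"))
    spectra <- readSpectra(file.path(input_dir, "spectra"))
    bucket_map <- metaboliteBucketMap()
  }

  # -- pharmacology arm -------------------------------------------------------
  criteria <- screenCriteria(config$ob_min, config$bbb_min, config$dl_min,
                             config$hl_min)
  active <- .stage(log, "screen",
    screenCompounds(compounds, criteria, defaultWhitelist()))
  .writeTable(active, out_dir, "active_compounds.tsv")
  tg <- .stage(log, "targets", filterTargets(hits, config$top_n, config$z_min))
  .writeTable(tg$hits, out_dir, "filtered_hits.tsv")
  syspharm <- .stage(log, "annotate",
    annotatePathways(tg$proteins$protein_id, library))
  .writeTable(syspharm, out_dir, "syspharm_pathways.tsv")

  # -- metabonomics arm -------------------------------------------------------
  spec <- bucketSpec(width = config$bucket_width, region = config$region,
                     exclusions = list(config$exclusion))
  bm <- .stage(log, "nmr", {
    raw <- bucketSpectra(spectra, spec)
    normalizeBuckets(raw)
  })
  groups <- groupLabels(bm)
  x <- bucketValues(bm)
  # the two supervised contrasts of the study design
  contrasts <- list(
    model_vs_control = c("control", "model"),
    treated_vs_model = c("model", "treated")
  )
  contrasts <- Filter(function(ct) all(ct %in% groups), contrasts)
  if (length(contrasts) == 0)
    stop("no supported contrast present in the group labels")
  models <- list(); biomarkers <- list()
  for (cn in names(contrasts)) {
    selc <- groups %in% contrasts[[cn]]
    model <- .stage(log, paste0("fit:", cn), {
      m <- fitOPLSDA(x[selc, ], groups[selc], n_orth = config$n_orth)
      m@Q2 <- as.numeric(crossValidateQ2(x[selc, ], groups[selc],
        n_orth = config$n_orth, folds = config$cv_folds, seed = config$seed))
      m
    })
    cl <- correlationLoadings(model, x[selc, ], alpha = config$alpha,
                              n = min(table(groups[selc])))
    .writeTable(cl, out_dir, paste0("correlation_loadings_", cn, ".tsv"))
    bio <- .stage(log, paste0("biomarkers:", cn),
                  selectBiomarkers(cl, bucket_map))
    .writeTable(bio, out_dir, paste0("biomarkers_", cn, ".tsv"))
    models[[cn]] <- model
    biomarkers[[cn]] <- bio
  }
  model <- models[[1]]

  stats <- .stage(log, "stats", {
    # per-metabolite mean normalized intensity over its annotated buckets
    ppm <- bucketPPM(bm)
    mets <- unique(bucket_map$metabolite)
    vals <- vapply(mets, function(m) {
      win <- bucket_map[bucket_map$metabolite == m, , drop = FALSE]
      inm <- rep(FALSE, length(ppm))
      for (j in seq_len(nrow(win)))
        inm <- inm | (ppm >= win$lo[j] & ppm <= win$hi[j])
      rowMeans(x[, inm, drop = FALSE])
    }, numeric(nrow(x)))
    compareGroups(vals, groups, alpha = config$alpha)
  })
  .writeTable(stats, out_dir, "univariate_stats.tsv")

  ann <- biomarkerAnnotationTable()
  called <- setdiff(unique(unlist(lapply(biomarkers, `[[`, "metabolite"))),
                    "unassigned")
  queries <- trimws(unlist(strsplit(called, "/", fixed = TRUE)))
  query <- data.frame(
    query = queries,
    kegg = ann$kegg[match(tolower(queries), tolower(ann$query))],
    stringsAsFactors = FALSE
  )
  enrichment <- .stage(log, "enrich",
    buildEnrichmentTable(query, library, p_cut = config$p_cut,
                         impact_cut = config$impact_cut))
  .writeTable(enrichment, out_dir, "enrichment.tsv")

  # -- integration ------------------------------------------------------------
  ov <- .stage(log, "integrate", {
    sig <- enrichment$name[enrichment$significant]
    overlapPathways(sig, syspharm$name)
  })
  protein_pathway <- do.call(rbind, lapply(pathwayIds(library), function(pid)
    if (length(library@proteins[[pid]]))
      data.frame(protein = library@proteins[[pid]],
                 pathway = unname(pathwayNames(library)[pid]),
                 stringsAsFactors = FALSE)))
  compound_protein <- tg$hits[, c("compound_id", "protein_id")]
  names(compound_protein) <- c("compound", "protein")
  herb_pairs <- do.call(rbind, lapply(seq_len(nrow(active)), function(i)
    data.frame(herb = strsplit(active$herbs[i], ",")[[1]],
               compound = active$compound_id[i], stringsAsFactors = FALSE)))
  network <- if (length(ov$overlapping)) {
    nw <- reverseMap(ov$overlapping, protein_pathway, compound_protein,
                     herb_pairs)
    exportNetwork(nw, file.path(out_dir, "network"))
    nw
  } else NULL

  model_stats <- unlist(lapply(names(models), function(cn) {
    m <- models[[cn]]
    setNames(
      c(round(sum(r2x(m)), 4), round(r2y(m), 4), round(q2(m), 4)),
      paste0(c("R2X ", "R2Y ", "Q2 "), cn)
    )
  }))
  summary <- data.frame(
    quantity = c(
      "active compounds", "herbs with actives", "target proteins",
      "syspharm pathways", "retained buckets", names(model_stats),
      "biomarkers called", "significant pathways", "overlapping pathways",
      "non-overlapping pathways"
    ),
    value = c(
      nrow(active), length(unique(unlist(strsplit(active$herbs, ",")))),
      nrow(tg$proteins), nrow(syspharm), nrow(bm), unname(model_stats),
      length(called), sum(enrichment$significant),
      paste(sort(ov$overlapping), collapse = "; "),
      paste(sort(ov$non_overlapping), collapse = "; ")
    ),
    stringsAsFactors = FALSE
  )
  .writeTable(summary, out_dir, "summary.tsv")
  invisible(list(
    active = active, proteins = tg$proteins, syspharm_pathways = syspharm,
    bucket_matrix = bm, models = models, model = model,
    biomarkers = biomarkers, stats = stats, enrichment = enrichment,
    overlap = ov, network = network, summary = summary
  ))
}
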