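#' Reference serum biomarker panel
#'
#' The bundled case-study biomarker panel for hydrocortisone-induced
#' kidney-yang deficiency in rats treated with the ten-herb You-gui pill:
#' twenty serum resonances with their chemical shifts, multiplicities and the
#' per-contrast regulation direction (model vs control and treated vs model)
#' with ANOVA/Bonferroni significance stars. Lipid-class entries (HDL,
#' VLDL/LDL lipids, N-acetyl glycoprotein) carry `lipid_class = TRUE` and are
#' excluded from pathway queries, which identifier-based enrichment cannot
#' resolve.
#'
#' @return data.frame with columns `metabolite`, `shifts` (ppm/multiplicity
#'   string), `dir_model_vs_control`, `stars_model_vs_control`,
#'   `dir_treated_vs_model`, `stars_treated_vs_model`, `lipid_class`.
#' @export
referenceBiomarkerTable <- function() {
  tb <- rbind(
    c("HDL",                    "0.84 (m)",           "none", "ns", "none", "ns", TRUE),
    c("lipids",                 "0.89 (m), 1.29 (m)", "up",   "**", "down", "**", TRUE),
    c("leucine",                "0.95 (d)",           "none", "ns", "up",   "**", FALSE),
    c("valine",                 "0.97 (d), 1.02 (d)", "down", "*",  "up",   "**", FALSE),
    c("lactate",                "1.33 (d), 4.11 (t)", "none", "ns", "up",   "**", FALSE),
    c("alanine",                "1.48 (d)",           "none", "ns", "up",   "**", FALSE),
    c("arginine",               "1.68 (m)",           "down", "*",  "up",   "**", FALSE),
    c("acetate",                "1.91 (s)",           "none", "ns", "up",   "**", FALSE),
    c("N-acetyl glycoprotein",  "2.04 (s)",           "up",   "**", "none", "ns", TRUE),
    c("methionine",             "2.13 (s)",           "none", "ns", "up",   "**", FALSE),
    c("glutamate",              "2.14 (m)",           "down", "**", "up",   "**", FALSE),
    c("glutamine",              "2.41 (m)",           "down", "*",  "up",   "**", FALSE),
    c("creatine",               "3.04 (s)",           "down", "*",  "up",   "**", FALSE),
    c("taurine",                "3.25 (t), 3.41 (t)", "down", "*",  "up",   "*",  FALSE),
    c("threonine",              "3.56 (dd)",          "down", "*",  "up",   "**", FALSE),
    c("myo-inositol",           "3.63 (dd)",          "down", "*",  "up",   "**", FALSE),
    c("glycerol",               "3.64 (dd), 3.87 (m)","down", "*",  "up",   "**", FALSE),
    c("TMAO/betaine",           "3.27 (s)",           "down", "**", "up",   "**", FALSE),
    c("tyrosine",               "6.87 (m), 7.17 (m)", "down", "*",  "up",   "**", FALSE),
    c("beta-glucose",           "4.64 (d)",           "down", "**", "up",   "**", FALSE)
  )
  out <- data.frame(
    metabolite = tb[, 1], shifts = tb[, 2],
    dir_model_vs_control = tb[, 3], stars_model_vs_control = tb[, 4],
    dir_treated_vs_model = tb[, 5], stars_treated_vs_model = tb[, 6],
    lipid_class = as.logical(tb[, 7]),
    stringsAsFactors = FALSE
  )
  out
}

#' Identifier annotations for the query metabolites
#'
#' HMDB and KEGG compound identifiers for the 18 pathway-query metabolites of
#' the bundled case study (the biomarker panel minus the lipid-class entries,
#' with the composite TMAO/betaine resonance split into its two compounds).
#'
#' @return data.frame with columns `query`, `hit`, `hmdb`, `kegg`.
#' @export
biomarkerAnnotationTable <- function() {
  tb <- rbind(
    c("leucine",      "l-Leucine",               "HMDB00687", "C00123"),
    c("valine",       "l-Valine",                "HMDB00883", "C00183"),
    c("lactate",      "l-Lactic acid",           "HMDB00190", "C00186"),
    c("alanine",      "l-Alanine",               "HMDB00161", "C00041"),
    c("arginine",     "l-Arginine",              "HMDB00517", "C00062"),
    c("acetate",      "Acetic acid",             "HMDB00042", "C00033"),
    c("methionine",   "l-Methionine",            "HMDB00696", "C00073"),
    c("glutamate",    "d-Glutamic acid",         "HMDB03339", "C00217"),
    c("glutamine",    "l-Glutamine",             "HMDB00641", "C00064"),
    c("creatine",     "Creatine",                "HMDB00064", "C00300"),
    c("taurine",      "Taurine",                 "HMDB00251", "C00245"),
    c("threonine",    "l-Threonine",             "HMDB00167", "C00188"),
    c("myo-inositol", "Myo-inositol",            "HMDB00211", "C00137"),
    c("glycerol",     "Glycerol",                "HMDB00131", "C00116"),
    c("betaine",      "Betaine",                 "HMDB00043", "C00719"),
    c("TMAO",         "Trimethylamine N-oxide",  "HMDB00925", "C01104"),
    c("tyrosine",     "l-Tyrosine",              "HMDB00158", "C00082"),
    c("beta-glucose", "Beta-d-glucose",          "HMDB00516", "C00221")
  )
  data.frame(
    query = tb[, 1], hit = tb[, 2], hmdb = tb[, 3], kegg = tb[, 4],
    stringsAsFactors = FALSE
  )
}

#' Derive the pathway-query metabolites from a biomarker panel
#'
#' Applies the enrichment-eligibility rule: lipid-class / membrane resonances
#' (which have no single compound identifier) are dropped, and composite
#' resonances written as "a/b" are expanded into their constituent compounds.
#' KEGG and HMDB identifiers are attached from [biomarkerAnnotationTable()]
#' where known.
#'
#' @param biomarkers data.frame shaped like [referenceBiomarkerTable()].
#' @return data.frame with columns `query`, `kegg`, `hmdb` (identifiers NA
#'   when not annotated).
#' @export
queryMetabolites <- function(biomarkers = referenceBiomarkerTable()) {
  keep <- biomarkers[!biomarkers$lipid_class, , drop = FALSE]
  queries <- unlist(strsplit(keep$metabolite, "/", fixed = TRUE))
  queries <- trimws(queries)
  ann <- biomarkerAnnotationTable()
  idx <- match(tolower(queries), tolower(ann$query))
  data.frame(
    query = queries,
    kegg = ifelse(is.na(idx), NA_character_, ann$kegg[idx]),
    hmdb = ifelse(is.na(idx), NA_character_, ann$hmdb[idx]),
    stringsAsFactors = FALSE
  )
}

#' Reference pathway-analysis results for the case study
#'
#' The 27-row MetPA-style over-representation result for the 18 query
#' metabolites of the bundled case study: per pathway the matched hit count,
#' pathway size, raw hypergeometric p, printed -log(p) and topology impact.
#' Row 10's printed -log(p) repeats row 9's value and is inconsistent with the
#' natural log of its own p; the printed number is kept verbatim here and the
#' discrepancy is handled by recomputation where it matters.
#'
#' @return data.frame with columns `no`, `name`, `hits`, `total`, `raw_p`,
#'   `neg_log_p_printed`, `impact`.
#' @export
referencePathwayResults <- function() {
  tb <- read.delim(text = paste(
    "no\tname\thits\ttotal\traw_p\tneg_log_p_printed\timpact",
    "1\tAminoacyl-tRNA biosynthesis\t8\t67\t5.3584e-07\t14.439\t0.0",
    "2\td-Glutamine and d-glutamate metabolism\t2\t5\t0.0015226\t6.4874\t0.0",
    "3\tGlycolysis/gluconeogenesis\t3\t26\t0.0038445\t5.5611\t0.02862",
    "4\tGlycine, serine and threonine metabolism\t3\t32\t0.0069872\t4.9637\t0.0",
    "5\tValine, leucine and isoleucine biosynthesis\t2\t11\t0.0079994\t4.8284\t0.66666",
    "6\tArginine and proline metabolism\t3\t44\t0.016934\t4.0784\t0.09426",
    "7\tPyruvate metabolism\t2\t22\t0.030903\t3.4769\t0.05583",
    "8\tAlanine, aspartate and glutamate metabolism\t2\t24\t0.036368\t3.3141\t0.14979",
    "9\tUbiquinone and other terpenoid-quinone biosynthesis\t1\t3\t0.038051\t3.2688\t0.0",
    "10\tGalactose metabolism\t2\t26\t0.042181\t3.2688\t0.0",
    "11\tPhenylalanine, tyrosine and tryptophan biosynthesis\t1\t4\t0.050428\t2.9872\t0.5",
    "12\tValine, leucine and isoleucine degradation\t2\t38\t0.083347\t2.4847\t0.0",
    "13\tTaurine and hypotaurine metabolism\t1\t8\t0.098447\t2.3182\t0.42857",
    "14\tAscorbate and aldarate metabolism\t1\t9\t0.11009\t2.2065\t0.0",
    "15\tPhenylalanine metabolism\t1\t9\t0.11009\t2.2065\t0.0",
    "16\tNitrogen metabolism\t1\t9\t0.11009\t2.2065\t0.0",
    "17\tSelenoamino acid metabolism\t1\t15\t0.17701\t1.7316\t0.0",
    "18\tPantothenate and CoA biosynthesis\t1\t15\t0.17701\t1.7316\t0.0",
    "19\tGlycerolipid metabolism\t1\t18\t0.20866\t1.5671\t0.28098",
    "20\tPentose phosphate pathway\t1\t19\t0.21895\t1.5189\t0.0",
    "21\tStarch and sucrose metabolism\t1\t23\t0.25887\t1.3514\t0.0021",
    "22\tInositol phosphate metabolism\t1\t26\t0.28753\t1.2464\t0.09464",
    "23\tCysteine and methionine metabolism\t1\t28\t0.30606\t1.184\t0.09464",
    "24\tPyrimidine metabolism\t1\t41\t0.41583\t0.87749\t0.0",
    "25\tTyrosine metabolism\t1\t42\t0.41583\t0.85908\t0.14045",
    "26\tPrimary bile acid biosynthesis\t1\t46\t0.4535\t0.79076\t0.02976",
    "27\tPurine metabolism\t1\t68\t0.59365\t0.52147\t0.0",
    sep = "\n"
  ), stringsAsFactors = FALSE)
  tb
}

#' Synthetic systems-pharmacology pathway list
#'
#' Loads the bundled synthetic stand-in for a formula-level systems-pharmacology
#' pathway annotation (`inst/extdata/syspharm_pathways_synthetic.txt`). The
#' original annotation behind the case study is not public; this stand-in was
#' constructed so that its intersection with the case study's significant
#' metabolic pathways reproduces the published overlap structure (six
#' overlapping, four non-overlapping), with KEGG-style spellings that exercise
#' name canonicalization.
#'
#' @return character vector of pathway names.
#' @export
exampleSyspharmPathways <- function() {
  path <- system.file("extdata", "syspharm_pathways_synthetic.txt",
                      package = "pharmetab", mustWork = TRUE)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}
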