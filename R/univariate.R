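#' Per-metabolite group comparison with Bonferroni correction
#'
#' For each metabolite: a one-way ANOVA across all groups, then the two
#' pairwise contrasts of interest (model vs control, treated vs model) as
#' pooled-variance t tests, Bonferroni-adjusted over the whole family of
#' metabolites x contrasts. Direction is the sign of the mean difference
#' (second group listed minus first reference), reported as `"none"` when the
#' adjusted p is not significant.
#'
#' @param values samples-by-metabolites numeric matrix (column names are
#'   metabolite names).
#' @param groups character/factor of group labels per sample.
#' @param contrasts list of `c(reference, comparison)` label pairs; the
#'   default tests model vs control and treated vs model.
#' @param alpha significance level for the direction call.
#' @param welch logical; use Welch (unequal-variance) t tests instead of the
#'   pooled-variance tests.
#' @return data.frame with columns `metabolite`, `contrast`, `anova_p`,
#'   `p_raw`, `p_adj`, `direction`, `stars`.
#' @export
compareGroups <- function(values, groups,
                          contrasts = list(c("control", "model"),
                                           c("model", "treated")),
                          alpha = 0.05, welch = FALSE) {
  values <- as.matrix(values)
  groups <- as.character(groups)
  if (any(table(groups) < 2)) stop("need >= 2 samples per group")
  mets <- colnames(values) %||% as.character(seq_len(ncol(values)))
  m <- length(mets) * length(contrasts)
  rows <- list()
  for (j in seq_len(ncol(values))) {
    v <- values[, j]
    fit <- aov(v ~ factor(groups))
    an <- summary(fit)[[1]]
    anova_p <- an[["Pr(>F)"]][1]
    for (ct in contrasts) {
      a <- v[groups == ct[1]]; b <- v[groups == ct[2]]
      if (length(a) == 0 || length(b) == 0)
        stop("contrast group not present: ", paste(ct, collapse = " vs "))
      va <- var(a); vb <- var(b)
      dmean <- mean(b) - mean(a)
      if (va == 0 && vb == 0) {
        warning("zero within-group variance for ", mets[j], "; exact-tie handling")
        p_raw <- if (dmean == 0) 1 else 0
      } else if (welch) {
        p_raw <- stats::t.test(b, a)$p.value
      } else {
        sp2 <- ((length(a) - 1) * va + (length(b) - 1) * vb) /
          (length(a) + length(b) - 2)
        tstat <- dmean / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
        p_raw <- 2 * pt(-abs(tstat), df = length(a) + length(b) - 2)
      }
      p_adj <- min(1, m * p_raw)
      rows[[length(rows) + 1L]] <- data.frame(
        metabolite = mets[j],
        contrast = paste(ct[2], "vs", ct[1]),
        anova_p = anova_p, p_raw = p_raw, p_adj = p_adj,
        direction = if (p_adj < alpha) (if (dmean > 0) "up" else "down") else "none",
        stars = pStars(p_adj), stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
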