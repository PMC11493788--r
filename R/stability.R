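#' @title Storage stability assessment by ANOVA
#' @name stability
#' @description Analyte/IS response ratios measured over a storage
#'   temperature x time grid are tested factor by factor with one-way
#'   ANOVA (pooling over the other factor), separately at each
#'   concentration. A factor is flagged significant at p < 0.05; a stable
#'   analyte shows no significant effect of either storage temperature or
#'   storage time.
NULL

#' One-way stability ANOVA on a storage factor
#'
#' @param records stability records with condition columns `temp_c` and
#'   `time_d`; the response is `area_analyte / area_is`.
#' @param factor `"temperature"` or `"time"`.
#' @param alpha significance level.
#' @return list: `factor`, `f`, `df`, `p_value`, `significant`,
#'   `group_means` (named by factor level).
#' @export
stability_anova <- function(records, factor = c("temperature", "time"),
                            alpha = 0.05) {
  factor <- match.arg(factor)
  col <- if (factor == "temperature") "temp_c" else "time_d"
  if (!col %in% names(records)) stop("records lack condition column ", col)
  g <- base::factor(records[[col]])
  y <- records$area_analyte / records$area_is
  if (nlevels(g) < 2) stop("need >= 2 groups")
  if (any(table(g) < 2)) stop("each group needs >= 2 replicates")
  group_means <- tapply(y, g, mean)

  if (stats::var(y) == 0) {
    warning("all observations identical; F set to 0")
    return(list(factor = factor, f = 0, df = c(nlevels(g) - 1,
                                               length(y) - nlevels(g)),
                p_value = 1, significant = FALSE,
                group_means = group_means))
  }
  fit <- stats::aov(y ~ g)
  tab <- summary(fit)[[1]]
  f <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  list(factor = factor, f = f, df = tab[["Df"]],
       p_value = p, significant = p < alpha, group_means = group_means)
}

#' Stability report across concentrations and factors
#'
#' Runs [stability_anova()] for temperature and time at each concentration
#' present in the records. No multiplicity correction is applied by
#' default, with an optional Bonferroni adjustment of the significance
#' level.
#'
#' @param records stability records.
#' @param alpha per-test significance level.
#' @param bonferroni divide `alpha` by the number of tests.
#' @return data.frame: concentration, factor, F, p_value, significant.
#' @export
stability_report <- function(records, alpha = 0.05, bonferroni = FALSE) {
  concs <- sort(unique(records$level_ng_ml))
  combos <- expand.grid(conc = concs, factor = c("temperature", "time"),
                        stringsAsFactors = FALSE)
  alpha_eff <- if (bonferroni) alpha / nrow(combos) else alpha
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    res <- stability_anova(records[records$level_ng_ml == combos$conc[i], ],
                           combos$factor[i], alpha_eff)
    data.frame(conc_ng_ml = combos$conc[i], factor = combos$factor[i],
               f = res$f, p_value = res$p_value,
               significant = res$significant)
  })
  do.call(rbind, rows)
}
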