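#' @title Extraction optimization: full-factorial design, PCA, MLR
#' @name doe
#' @description The extraction step (solvent volume, sonication time) is
#'   optimized with a 3^2 full-factorial design executed in random order.
#'   The runs x analytes response matrix is first explored by PCA
#'   (autoscaled by default, standard chemometric practice when analyte
#'   response magnitudes differ); a multiple linear regression of the PC1
#'   scores on the coded factors then quantifies each factor's influence
#'   on the average extraction yield.
NULL

code_levels <- function(values, levels) {
  codes <- seq_along(levels) - (length(levels) + 1) / 2
  codes <- codes / max(abs(codes))
  codes[match(values, levels)]
}

#' Build a full-factorial design
#'
#' Cartesian product of the factor levels, with orthogonal coded levels
#' (-1, 0, +1 for three-level factors) and a seeded random run order.
#'
#' @param factors named list of factor levels, e.g.
#'   `list(volume = c(250, 500, 750), time = c(10, 20, 30))`.
#' @param seed integer seed for the run-order shuffle.
#' @return a `factorial_design`: list with `factors` and `runs`, a
#'   data.frame with `run_id`, one column per factor (physical level), and
#'   `coded_<factor>` columns, in randomized execution order.
#' @export
full_factorial <- function(factors = list(volume = c(250, 500, 750),
                                          time = c(10, 20, 30)),
                           seed = 1L) {
  if (length(factors) == 0) stop("need >= 1 factor")
  if (any(vapply(factors, length, integer(1)) < 2)) {
    stop("each factor needs >= 2 levels")
  }
  runs <- expand.grid(factors, KEEP.OUT.ATTRS = FALSE)
  for (nm in names(factors)) {
    runs[[paste0("coded_", nm)]] <- code_levels(runs[[nm]], factors[[nm]])
  }
  runs$run_id <- seq_len(nrow(runs))
  set.seed(derive_seed(seed, "doe_order"))
  runs <- runs[sample(nrow(runs)), c("run_id", setdiff(names(runs), "run_id"))]
  rownames(runs) <- NULL
  structure(list(factors = factors, runs = runs),
            class = "factorial_design")
}

#' PCA of a DoE response matrix
#'
#' Standard principal component analysis of the runs x analytes matrix
#' after column scaling. Components are sign-fixed so that each
#' component's largest-magnitude loading is positive, making outputs
#' reproducible across platforms.
#'
#' @param responses numeric matrix, runs x analytes.
#' @param scaling `"autoscale"` (center + unit variance, default) or
#'   `"center"`.
#' @return list: `scores` (runs x components), `loadings` (orthonormal),
#'   `explained_variance` (fractions, non-increasing, summing to 1 over
#'   all components).
#' @export
pca_decompose <- function(responses, scaling = c("autoscale", "center")) {
  scaling <- match.arg(scaling)
  responses <- as.matrix(responses)
  if (nrow(responses) < 2 || ncol(responses) < 2) {
    stop("need a matrix with >= 2 rows and >= 2 columns")
  }
  if (anyNA(responses)) stop("missing values in the response matrix")
  if (scaling == "autoscale") {
    sds <- apply(responses, 2, stats::sd)
    if (any(sds == 0)) {
      stop("constant column(s) cannot be autoscaled: ",
           paste(colnames(responses)[sds == 0], collapse = ", "))
    }
  }
  pc <- stats::prcomp(responses, center = TRUE,
                      scale. = scaling == "autoscale")
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  scores <- sweep(pc$x, 2, flip, `*`)
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  list(scores = scores, loadings = loadings,
       explained_variance = pc$sdev^2 / sum(pc$sdev^2))
}

#' MLR of PC1 scores on coded design factors
#'
#' Ordinary least squares of a response (typically PC1 scores) on the
#' coded volume and time factors, with an optional interaction term.
#' Because the balanced factorial's coded columns are orthogonal,
#' dropping one factor leaves the other's coefficient unchanged.
#'
#' @param scores response vector, one value per run, aligned with
#'   `design$runs`.
#' @param design a [full_factorial()] design with coded columns
#'   `coded_volume` and `coded_time`.
#' @param include_interaction include the volume x time product term.
#' @return data.frame: term, estimate, std_error, p_value.
#' @export
mlr_fit <- function(scores, design, include_interaction = TRUE) {
  stopifnot(inherits(design, "factorial_design"))
  runs <- design$runs
  if (length(scores) != nrow(runs)) stop("scores/design size mismatch")
  dat <- data.frame(score = scores, volume = runs$coded_volume,
                    time = runs$coded_time)
  fml <- if (include_interaction) score ~ volume * time
         else score ~ volume + time
  n_par <- if (include_interaction) 4 else 3
  if (nrow(dat) < n_par + 1) stop("too few runs for the requested model")
  fit <- stats::lm(fml, data = dat)
  if (any(is.na(stats::coef(fit)))) stop("singular design")
  cf <- summary(fit)$coefficients
  data.frame(term = rownames(cf), estimate = cf[, "Estimate"],
             std_error = cf[, "Std. Error"],
             p_value = cf[, "Pr(>|t|)"], row.names = NULL)
}

#' Run the full DoE analysis
#'
#' @param responses runs x analytes response matrix aligned with
#'   `design$runs`.
#' @param design a [full_factorial()] design.
#' @param scaling passed to [pca_decompose()].
#' @param include_interaction passed to [mlr_fit()].
#' @return a `doe_analysis` list: `pca` and `mlr` (fit on PC1 scores).
#' @export
doe_analysis <- function(responses, design,
                         scaling = c("autoscale", "center"),
                         include_interaction = TRUE) {
  pca <- pca_decompose(responses, scaling)
  mlr <- mlr_fit(pca$scores[, 1], design, include_interaction)
  structure(list(pca = pca, mlr = mlr), class = "doe_analysis")
}
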