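#' @title Blue Applicability Grade Index (BAGI)
#' @name bagi
#' @description BAGI scores the practicability ("blueness") of an
#'   analytical method through ten attributes of equal importance, each
#'   graded on the scale 2.5 / 5 / 7.5 / 10, for a total between 25 and
#'   100 points. A method is considered practical at 60 points or more.
#'   In the pictogram the grades map to shades of blue: 2.5 white (low),
#'   5 and 7.5 light blue (medium), 10 dark blue (high). Note: a method
#'   description reporting a 4 low / 4 medium / 2 high shade split reaches
#'   the 60-point threshold only with medium = 7.5, which is the mapping
#'   [bagi_assessment()] uses for `"medium"`.
NULL

BAGI_GRADES <- c(2.5, 5, 7.5, 10)

BAGI_ATTRIBUTES <- c(
  "type of analysis", "number of analytes", "instrumentation",
  "samples per hour", "sample preparation steps", "samples per preparation",
  "reagent availability", "preconcentration requirement",
  "automation degree", "sample amount")

#' Build a BAGI assessment
#'
#' @param grades ten grades, each one of 2.5, 5, 7.5, 10, or the labels
#'   `"low"` (2.5), `"medium"` (7.5), `"high"` (10).
#' @param attributes ten attribute names.
#' @param justification optional character vector of per-attribute notes.
#' @return a `bagi_assessment` data.frame (attribute, grade, color,
#'   justification).
#' @export
bagi_assessment <- function(grades, attributes = BAGI_ATTRIBUTES,
                            justification = rep("", 10)) {
  if (is.character(grades)) {
    grades <- c(low = 2.5, medium = 7.5, high = 10)[grades]
    if (anyNA(grades)) stop("grade labels must be 'low', 'medium' or 'high'")
    grades <- unname(grades)
  }
  if (length(grades) != 10 || length(attributes) != 10) {
    stop("BAGI requires exactly 10 graded attributes")
  }
  if (!all(grades %in% BAGI_GRADES)) {
    stop("grades must be one of ", paste(BAGI_GRADES, collapse = ", "))
  }
  color <- c("2.5" = "white", "5" = "light blue", "7.5" = "light blue",
             "10" = "dark blue")[as.character(grades)]
  structure(data.frame(attribute = attributes, grade = grades,
                       color = unname(color),
                       justification = justification,
                       stringsAsFactors = FALSE),
            class = c("bagi_assessment", "data.frame"))
}

#' Total BAGI score and practicality verdict
#'
#' @param assessment a [bagi_assessment()].
#' @param threshold practicality threshold in points.
#' @return list: `total` (sum of the ten grades, in [25, 100]),
#'   `practical` (total >= threshold), `threshold`.
#' @examples
#' a <- bagi_assessment(rep(c("low", "medium", "high"), c(4, 4, 2)))
#' bagi_score(a)$total  # 60: at the practicality threshold
#' @export
bagi_score <- function(assessment, threshold = 60) {
  stopifnot(inherits(assessment, "bagi_assessment"))
  if (nrow(assessment) != 10) stop("BAGI requires exactly 10 attributes")
  if (!all(assessment$grade %in% BAGI_GRADES)) {
    stop("grades must be one of ", paste(BAGI_GRADES, collapse = ", "))
  }
  total <- sum(assessment$grade)
  list(total = total, practical = total >= threshold,
       threshold = threshold)
}

#' @export
print.bagi_assessment <- function(x, ...) {
  score <- bagi_score(x)
  shade <- c("white" = "[ ]", "light blue" = "[+]", "dark blue" = "[#]")
  cat("BAGI assessment\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf(" %s %-28s %4.1f\n", shade[x$color[i]], x$attribute[i],
                x$grade[i]))
  }
  cat(sprintf("Total: %g / 100 (threshold %g) -> %s\n", score$total,
              score$threshold,
              if (score$practical) "practical" else "not practical"))
  invisible(x)
}
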