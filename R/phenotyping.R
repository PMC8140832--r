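#' Classify patients into decline phenotypes from first-component scores
#'
#' Cohort-wide first and third quartiles (linear-interpolation quantile
#' convention, R type 7) split the first functional principal component
#' scores into three groups: score below Q1 = late decliner, score above
#' Q3 = early (rapid) decliner, scores in \[Q1, Q3\] (boundaries
#' inclusive) = middle decliner. By construction the middle group holds
#' half the cohort when scores are distinct.
#'
#' @param scores named numeric vector of first-component scores (names =
#'   patient ids), or an `fpca_model` whose first score column is used.
#' @return data.frame of class `phenotype_assignment`: `patient_id`,
#'   `fpc1_score`, `label` (factor early/middle/late), `q1`, `q3`.
#' @export
classify_decliners <- function(scores) {
  if (inherits(scores, "fpca_model")) {
    s <- scores$scores[, 1]
    names(s) <- rownames(scores$scores)
    scores <- s
  }
  if (length(scores) < 4) stop("need at least 4 patients to classify")
  if (any(!is.finite(scores))) stop("scores must be finite")
  ids <- names(scores)
  if (is.null(ids)) ids <- as.character(seq_along(scores))
  if (stats::sd(scores) == 0) {
    warning("degenerate quartiles: all scores identical; everyone labelled middle")
    q1 <- q3 <- scores[1]
    label <- rep("middle", length(scores))
  } else {
    q <- stats::quantile(scores, c(0.25, 0.75), type = 7, names = FALSE)
    q1 <- q[1]; q3 <- q[2]
    label <- ifelse(scores < q1, "late", ifelse(scores > q3, "early", "middle"))
  }
  out <- data.frame(patient_id = ids,
                    fpc1_score = as.numeric(scores),
                    label = factor(label, levels = c("early", "middle", "late")),
                    q1 = q1, q3 = q3,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("phenotype_assignment", class(out))
  out
}

#' Peak decline of a fitted trajectory
#'
#' The extent of maximal decline is the lowest point of the
#' rate-of-change curve; the age of occurrence is the grid age attaining
#' it (first such age on ties).
#'
#' @param deriv derivative values on `grid` (percent predicted per
#'   year), or a `fitted_curve` object.
#' @param grid ages matching `deriv` (ignored when a `fitted_curve` is
#'   given).
#' @return data.frame with `extent` and `age_at_peak`.
#' @export
peak_decline <- function(deriv, grid = fpca_grid()) {
  if (inherits(deriv, "fitted_curve")) {
    grid <- deriv$grid
    deriv <- deriv$deriv
  }
  stopifnot(length(deriv) == length(grid))
  if (any(!is.finite(deriv))) stop("derivative contains non-finite values")
  i <- which.min(deriv)
  data.frame(extent = deriv[i], age_at_peak = grid[i])
}

#' Peak decline for every patient in a model
#'
#' @param model an `fpca_model`.
#' @return data.frame: `patient_id`, `extent`, `age_at_peak`.
#' @export
peak_decline_all <- function(model) {
  fc <- fitted_curves(model)
  idx <- apply(fc$deriv, 2, which.min)
  data.frame(patient_id = colnames(fc$deriv),
             extent = fc$deriv[cbind(idx, seq_along(idx))],
             age_at_peak = model$grid[idx],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write the phenotype labels table
#'
#' @param labels a `phenotype_assignment`.
#' @param path CSV path; columns patient_id, fpc1_score, label, q1, q3.
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(as.data.frame(labels), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
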