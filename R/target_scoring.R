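#' Drug-target scoring criteria
#'
#' Operationalizes the receptor-target guidelines: an ideal target is (1)
#' highly available - a high fraction of cells carry it above a therapeutic
#' concentration; (2) of low heterogeneity - low quadratic entropy; and (3)
#' tumor-specific - elevated versus a healthy-tissue reference.
#' Independently, a receptor carried at very high concentration by a small
#' minority subpopulation is flagged as an alternative-pathway candidate for
#' combination therapy.
#'
#' @param availability_fraction_min Minimum fraction of cells above the
#'   availability threshold (default 0.70).
#' @param availability_receptors_min Receptors/cell counting as "available"
#'   (default 6,000).
#' @param qe_max Maximum quadratic entropy for a low-heterogeneity target
#'   (default 0.7).
#' @param specificity_fold_min Minimum tumor-vs-healthy fold-change
#'   (default 2).
#' @param minority_weight_max Maximum mixture-component weight counting as a
#'   "small" subpopulation (default 0.15; the reference minority
#'   subpopulations are ~8-10% of cells, and fitted weights scatter around
#'   the true value, so a strict 0.10 cutoff would exclude a true 10%
#'   subpopulation about half the time).
#' @param minority_fold_min Minimum component-mean fold over the ensemble
#'   geometric mean counting as "high concentration" (default 10).
#' @return A `target_criteria` object.
#' @export
target_criteria <- function(availability_fraction_min = 0.70,
                            availability_receptors_min = 6000,
                            qe_max = 0.7,
                            specificity_fold_min = 2.0,
                            minority_weight_max = 0.15,
                            minority_fold_min = 10) {
  crit <- structure(list(
    availability_fraction_min = availability_fraction_min,
    availability_receptors_min = availability_receptors_min,
    qe_max = qe_max, specificity_fold_min = specificity_fold_min,
    minority_weight_max = minority_weight_max,
    minority_fold_min = minority_fold_min),
    class = "target_criteria")
  validate_criteria(crit)
  crit
}

validate_criteria <- function(crit) {
  bad <- character(0)
  if (!all(vapply(crit, function(v) is.numeric(v) && v > 0, logical(1)))) {
    bad <- c(bad, "criteria: all thresholds must be strictly positive")
  }
  for (f in c("availability_fraction_min", "minority_weight_max")) {
    if (is.numeric(crit[[f]]) && (crit[[f]] <= 0 || crit[[f]] > 1)) {
      bad <- c(bad, paste0("criteria$", f, ": must lie in (0, 1]"))
    }
  }
  if (length(bad)) stop(paste(bad, collapse = "\n  - "), call. = FALSE)
  invisible(crit)
}

#' Score one population x marker as a drug target
#'
#' Computes availability (fraction of cells with receptors strictly above
#' `availability_receptors_min`), carries the quadratic entropy, and - when
#' a healthy reference is supplied - the specificity fold-change of the
#' ensemble geometric mean over the reference. Flags:
#' * `primary_target`: availability >= minimum, QE below `qe_max`, and (if a
#'   reference is present) fold >= `specificity_fold_min`. Without a
#'   reference the specificity criterion is skipped and the score is marked
#'   `specificity = "unscored"` rather than failed.
#' * `combination_candidate`: the fitted mixture contains a component of
#'   weight at most `minority_weight_max` whose mean concentration is at
#'   least `minority_fold_min` times the ensemble geometric mean - a
#'   minority subpopulation that could sustain an alternative signaling
#'   pathway under mono-therapy.
#'
#' @param dist A [receptor_distribution()].
#' @param qe A `qe_result` for the same distribution.
#' @param fit A `mixture_fit` for the same distribution.
#' @param reference_gm Healthy-reference geometric-mean receptors/cell for
#'   this marker, or `NULL` when unavailable.
#' @param criteria A [target_criteria()].
#' @return A `target_score`: list with `population`, `marker`,
#'   `availability`, `qe`, `k`, `specificity_fold` (NA when unscored),
#'   `specificity` (`"scored"`/`"unscored"`), `primary_target`,
#'   `combination_candidate`, `ensemble_gm`.
#' @export
score_target <- function(dist, qe, fit, reference_gm = NULL,
                         criteria = target_criteria()) {
  stopifnot(inherits(dist, "receptor_distribution"),
            inherits(qe, "qe_result"), inherits(fit, "mixture_fit"))
  if (!dist$n_cells) stop("empty receptor distribution", call. = FALSE)
  availability <- mean(dist$values > criteria$availability_receptors_min)
  pos <- dist$values[dist$values > 0]
  gm <- if (length(pos)) 10^mean(log10(pos)) else 0
  fold <- if (!is.null(reference_gm)) gm / reference_gm else NA_real_
  primary <- availability >= criteria$availability_fraction_min &&
    qe$qe < criteria$qe_max &&
    (is.null(reference_gm) || fold >= criteria$specificity_fold_min)
  comp_means <- 10^fit$components$mu_log10
  combo <- gm > 0 && any(
    fit$components$weight <= criteria$minority_weight_max &
      comp_means >= criteria$minority_fold_min * gm)
  structure(list(population = dist$population, marker = dist$marker,
                 availability = availability, qe = qe$qe, k = fit$k,
                 specificity_fold = fold,
                 specificity = if (is.null(reference_gm)) "unscored" else "scored",
                 primary_target = primary, combination_candidate = combo,
                 ensemble_gm = gm),
            class = "target_score")
}

#' @export
print.target_score <- function(x, ...) {
  cat(sprintf(
    "<target_score> %s / %s: availability %.1f%%, QE %.3f, k=%d%s -> %s%s\n",
    x$population, x$marker, 100 * x$availability, x$qe, x$k,
    if (x$specificity == "scored")
      sprintf(", fold %.1f", x$specificity_fold) else "",
    if (x$primary_target) "PRIMARY TARGET" else "not primary",
    if (x$combination_candidate) " + combination candidate" else ""))
  invisible(x)
}

#' Rank target scores
#'
#' Primary targets first (by descending availability), then combination
#' candidates that are not primary targets (by descending availability),
#' then the rest. The sort is stable, so permuting the input does not change
#' the ranking.
#'
#' @param scores List of `target_score` objects (>= 1).
#' @return A data frame, one row per score, ordered as above, with a `rank`
#'   column.
#' @export
rank_targets <- function(scores) {
  if (!length(scores)) stop("no target scores to rank", call. = FALSE)
  df <- do.call(rbind, lapply(scores, function(s)
    data.frame(population = s$population, marker = s$marker,
               availability = s$availability, qe = s$qe, k = s$k,
               specificity_fold = s$specificity_fold,
               specificity = s$specificity,
               primary_target = s$primary_target,
               combination_candidate = s$combination_candidate,
               ensemble_gm = s$ensemble_gm)))
  tier <- ifelse(df$primary_target, 0L,
                 ifelse(df$combination_candidate, 1L, 2L))
  ord <- order(tier, -df$availability, method = "radix")  # stable
  out <- df[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
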