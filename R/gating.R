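#' Define a node of a hierarchical gating tree
#'
#' Gates are 1-D intensity thresholds applied in sequence down a tree,
#' mirroring the manual scheme used for xenograft samples: live cells
#' (viability-dye negative) -> CD45-negative (non-hematopoietic) -> CD34+
#' endothelial-like cells and CD133+ stem cells. A node's
#' `marker`/`threshold`/`direction` is the condition an event must satisfy to
#' *enter* the node; `marker = NULL` is an always-true fallback (used for the
#' root and for catch-all leaves such as "other"). Nodes without children are
#' leaves and must carry a population `label`.
#'
#' Boundary convention: `"positive"` means intensity >= threshold,
#' `"negative"` means intensity < threshold.
#'
#' @param marker Channel name, or `NULL` for an unconditional node.
#' @param threshold Gate threshold in a.u. (required when `marker` given).
#' @param direction `"positive"` (>= threshold) or `"negative"` (< threshold).
#' @param children List of child `gate_node`s, tried in order; an event
#'   descends into the first child whose condition it satisfies.
#' @param label Population label (required at leaves).
#' @return A `gate_node`.
#' @examples
#' tree <- gate_node(children = list(
#'   gate_node("CD34", 1000, "positive", label = "EC-like"),
#'   gate_node(label = "other")))
#' @export
gate_node <- function(marker = NULL, threshold = NULL,
                      direction = c("positive", "negative"),
                      children = list(), label = NULL) {
  if (!is.null(marker)) {
    direction <- match.arg(direction)
    if (is.null(threshold) || !is.finite(threshold)) {
      stop("gate on '", marker, "' needs a finite threshold", call. = FALSE)
    }
  } else {
    direction <- NULL
    threshold <- NULL
  }
  if (!length(children) && is.null(label)) {
    stop("leaf gate nodes must carry a population label", call. = FALSE)
  }
  node <- structure(list(marker = marker, threshold = threshold,
                         direction = direction, children = children,
                         label = label),
                    class = "gate_node")
  labs <- leaf_labels(node)
  if (anyDuplicated(labs)) {
    stop("leaf labels must be unique across the gate tree: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "), call. = FALSE)
  }
  node
}

leaf_labels <- function(node) {
  if (!length(node$children)) return(node$label)
  unlist(lapply(node$children, leaf_labels))
}

gate_markers <- function(node) {
  unique(c(node$marker, unlist(lapply(node$children, gate_markers))))
}

gate_node_from_list <- function(x) {
  gate_node(marker = x$marker, threshold = x$threshold,
            direction = x$direction %||% "positive",
            children = lapply(x$children %||% list(), gate_node_from_list),
            label = x$label)
}

gate_node_to_list <- function(node) {
  if (is.null(node)) return(NULL)
  out <- list(marker = node$marker, threshold = node$threshold,
              direction = node$direction, label = node$label)
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(node$children)) {
    out$children <- lapply(node$children, gate_node_to_list)
  }
  out
}

#' Assign a population label to every event
#'
#' Walks each event down the gate tree; events that satisfy no leaf condition
#' receive `"ungated"` (e.g. dead or hematopoietic cells in the standard
#' scheme). Assignment is deterministic in the thresholds.
#'
#' @param events An [event_table()].
#' @param tree A [gate_node()] whose markers are all channels of `events`.
#' @return Character vector of length `n_events`: a leaf label or `"ungated"`.
#' @export
apply_gates <- function(events, tree) {
  stopifnot(inherits(events, "event_table"), inherits(tree, "gate_node"))
  mk <- gate_markers(tree)
  missing <- setdiff(mk, events$channels)
  if (length(missing)) {
    stop("gate marker channel(s) missing from event table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  labels <- rep("ungated", events$n_events)
  node_cond <- function(node, idx) {
    if (is.null(node$marker)) return(rep(TRUE, length(idx)))
    v <- events$intensities[idx, node$marker]
    if (node$direction == "positive") v >= node$threshold else v < node$threshold
  }
  descend <- function(node, idx) {
    if (!length(idx)) return(invisible())
    if (!length(node$children)) {
      labels[idx] <<- node$label
      return(invisible())
    }
    remaining <- idx
    for (child in node$children) {
      if (!length(remaining)) break
      keep <- node_cond(child, remaining)
      descend(child, remaining[keep])
      remaining <- remaining[!keep]
    }
    invisible()
  }
  root_ok <- node_cond(tree, seq_len(events$n_events))
  descend(tree, which(root_ok))
  labels
}

#' Summarize population composition
#'
#' Percentages are computed over gated (live, in-scheme) events only;
#' `"ungated"` events are counted but excluded from the denominator,
#' mirroring the convention of reporting subpopulations as a percent of live
#' cells.
#'
#' @param labels Per-event labels from [apply_gates()].
#' @return A `composition_report`: data frame with columns `population`,
#'   `count`, `percent`, plus attributes `total_live` and `n_ungated`.
#' @export
composition <- function(labels) {
  gated <- labels[labels != "ungated"]
  if (!length(gated)) {
    stop("no gated (live) events: every event fell outside the gate tree",
         call. = FALSE)
  }
  tab <- table(gated)
  out <- data.frame(population = names(tab),
                    count = as.integer(tab),
                    percent = 100 * as.integer(tab) / length(gated),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$count, out$population), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total_live") <- length(gated)
  attr(out, "n_ungated") <- sum(labels == "ungated")
  class(out) <- c("composition_report", "data.frame")
  out
}

#' @export
print.composition_report <- function(x, ...) {
  cat(sprintf("<composition_report> %d live events (%d ungated)\n",
              attr(x, "total_live"), attr(x, "n_ungated")))
  df <- as.data.frame(x)
  df$percent <- sprintf("%.2f%%", df$percent)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Suggest a gate threshold for a bimodal channel
#'
#' Convenience helper: places the threshold at the deepest valley of a kernel
#' density estimate of log10 intensity between the two largest modes. Gating
#' itself always uses explicit configured thresholds.
#'
#' @param values Positive channel intensities.
#' @return Suggested threshold in a.u.
#' @export
suggest_threshold <- function(values) {
  v <- log10(values[values > 0])
  if (length(v) < 10) stop("need at least 10 positive values", call. = FALSE)
  d <- stats::density(v, n = 512)
  y <- d$y
  is_max <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(is_max) < 2) {
    return(10^stats::median(v))
  }
  peaks <- is_max[order(y[is_max], decreasing = TRUE)][1:2]
  lo <- min(peaks); hi <- max(peaks)
  valley <- lo + which.min(y[lo:hi]) - 1L
  10^d$x[valley]
}
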