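# Evaluation against expert reference labels: label mapping rules,
# overlap-matched cycle confusion matrices, and technique-distribution
# summaries.

# Classes on which algorithm and expert labels are compared after mapping.
CMP_LEVELS <- c("DIA", "DP", "DK", "HRB", "TRN", "noTech")

#' Map expert reference labels onto the comparison classes
#'
#' Tucking (`TCK`) occurs between cycles and is mapped to `noTech`.
#' Transition cycles are mapped by scheme: under scheme `"a"` both `tDIA`
#' and `fDIA` count as `DIA`; under scheme `"b"` `tDIA` counts as `DIA` but
#' `fDIA` as `DK` (transitions out of the diagonal stride typically carry
#' correlated arm work plus a kick, i.e. DK mechanics).
#'
#' @param ref a `ski_reference` data frame (or factor of reference labels).
#' @param scheme `"a"` or `"b"`.
#' @return same shape as the input with labels as a factor over
#'   `DIA, DP, DK, HRB, TRN, noTech`.
#' @export
map_reference_labels <- function(ref, scheme = c("a", "b")) {
  scheme <- match.arg(scheme)
  map1 <- function(l) {
    l <- as.character(l)
    l[l == "TCK"] <- "noTech"
    l[l == "tDIA"] <- "DIA"
    l[l == "fDIA"] <- if (scheme == "a") "DIA" else "DK"
    factor(l, levels = CMP_LEVELS)
  }
  if (is.data.frame(ref)) { ref$label <- map1(ref$label); ref }
  else map1(ref)
}

#' Map algorithm cycle labels onto the comparison classes
#'
#' The two rotational-kick classes `DPrK` and `rK` are merged into the turn
#' class `TRN`; other labels pass through.
#'
#' @param label factor/character of algorithm labels.
#' @return factor over the comparison classes.
#' @export
map_predicted_labels <- function(label) {
  l <- as.character(label)
  l[l %in% c("DPrK", "rK")] <- "TRN"
  factor(l, levels = CMP_LEVELS)
}

# Temporal overlap of interval (s1, e1) with each row of (s2, e2).
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

#' Cycle-level confusion matrix against a reference cycle set
#'
#' Each predicted cycle is matched to the reference cycle with which it
#' shares the largest temporal overlap; cycles overlapping their best match
#' by less than `min_overlap` of their own duration are excluded (and
#' counted).  Rows of the matrix are the algorithm classes, columns the
#' expert classes.  Precision is per row, sensitivity per column, accuracy
#' the trace over the total.
#'
#' @param pred a `ski_cycles` data frame (algorithm cycles); labels are
#'   mapped with [map_predicted_labels()] unless already comparison classes.
#' @param ref a `ski_reference` already mapped with [map_reference_labels()],
#'   or a data frame `start, stop, label` over the comparison classes.
#' @param min_overlap minimum fractional overlap for a match (default 0.5).
#' @return object of class `ski_confusion`: list with `table` (counts),
#'   `precision`, `sensitivity`, `accuracy`, `n_matched`, `n_excluded`.
#' @export
confusion <- function(pred, ref, min_overlap = 0.5) {
  if (!nrow(pred)) stop("empty prediction cycle set")
  if (!nrow(ref)) stop("empty reference cycle set")
  if (max(pred$start) >= max(ref$stop) && min(pred$stop) <= min(ref$start) ||
      min(pred$start) >= max(ref$stop) || max(pred$stop) <= min(ref$start))
    stop("prediction and reference spans are disjoint")
  plab <- if (all(as.character(pred$label) %in% CMP_LEVELS))
    factor(as.character(pred$label), levels = CMP_LEVELS)
  else map_predicted_labels(pred$label)
  rlab <- factor(as.character(ref$label), levels = CMP_LEVELS)
  if (anyNA(rlab)) stop("reference labels must be mapped first (map_reference_labels)")

  best <- integer(nrow(pred)); frac <- numeric(nrow(pred))
  for (i in seq_len(nrow(pred))) {
    ov <- interval_overlap(pred$start[i], pred$stop[i], ref$start, ref$stop)
    j <- which.max(ov)
    best[i] <- j
    frac[i] <- ov[j] / (pred$stop[i] - pred$start[i])
  }
  keep <- frac >= min_overlap
  tab <- table(classified = plab[keep], reference = rlab[best][keep])
  diag_ <- diag(tab)
  rs <- rowSums(tab); cs <- colSums(tab)
  precision <- ifelse(rs > 0, diag_ / rs, NA_real_)
  sensitivity <- ifelse(cs > 0, diag_ / cs, NA_real_)
  structure(list(table = tab,
                 precision = precision, sensitivity = sensitivity,
                 accuracy = sum(diag_) / sum(tab),
                 n_matched = sum(keep), n_excluded = sum(!keep)),
            class = "ski_confusion")
}

#' @export
print.ski_confusion <- function(x, digits = 3, ...) {
  cat("<ski_confusion> rows = classified, columns = reference\n")
  print(x$table)
  cat("\naccuracy:", format(100 * x$accuracy, digits = digits), "% on",
      x$n_matched, "matched cycles")
  if (x$n_excluded) cat(" (", x$n_excluded, "unmatched excluded )")
  cat("\nprecision:  ",
      paste(names(x$precision),
            format(100 * x$precision, digits = digits), collapse = " | "), "\n")
  cat("sensitivity:",
      paste(names(x$sensitivity),
            format(100 * x$sensitivity, digits = digits), collapse = " | "), "\n")
  invisible(x)
}

#' Technique distribution and cycle-frequency summary
#'
#' Per technique: the percentage of classified samples and the mean cycle
#' frequency over cycles carrying that label (`NA` when the technique is
#' absent from the session).
#'
#' @param cycles a `ski_cycles` data frame.
#' @param samples a `ski_labels` data frame (per-sample labels).
#' @param exclude optional logical vector over samples to leave out of the
#'   percentages (e.g. transition flags).
#' @return data frame with columns `technique`, `pct_samples`, `mean_freq`.
#' @export
distribution_summary <- function(cycles, samples, exclude = NULL) {
  lab <- samples$label
  if (!is.null(exclude)) lab <- lab[!exclude]
  pct <- 100 * table(factor(lab, levels = TECH_LEVELS)) / length(lab)
  freq <- vapply(TECH_LEVELS, function(tech) {
    f <- cycles$frequency[as.character(cycles$label) == tech]
    if (length(f)) mean(f) else NA_real_
  }, numeric(1L))
  data.frame(technique = TECH_LEVELS,
             pct_samples = as.numeric(pct),
             mean_freq = freq, row.names = NULL)
}
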