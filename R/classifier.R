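# Rule-based decision layer: boolean compositions of tolerance-thresholded
# motion components that assign exactly one sub-technique per sample.  All
# comparisons are strict, so values equal to a tolerance deterministically
# fall to the "not exceeding" side.

#' Raw decision functions evaluated on component rows
#'
#' Returns the logical value of each sub-technique decision function for
#' every row of a component table.  The construction guarantees the six
#' technique sets are pairwise disjoint:
#' * poling super-class: `armMo > tol_armMo & armCorr > tol_armPole`
#' * diagonal super-class: `armMo > tol_armMo & legMoS > tol_legMoS &
#'   armCorr < tol_armDiagHrb`
#' * `HRB` = diagonal & `epsi > tol_epsi`
#' * `DIA` = diagonal & !HRB & `armCorr < tol_armDiagD`
#' * `DPrK` = poling & `kickRot > tol_kickRot & legMoST > tol_legMoST`
#' * `DK` = poling & `legMoS > tol_legMoS` & !DPrK
#' * `DP` = poling & `legMoST < tol_legMoST & legMoS < tol_legMoS`
#' * `rK` = `kickRot > tol_kickRot & armMo < tol_armMo & legMoST > tol_legMoST`
#' * `noTech` = none of the above.
#'
#' The diagonal super-class condition includes the leg-motion requirement and
#' the DIA bound `tol_armDiagD` is stricter than the herringbone bound
#' (`tol_armDiagD < tol_armDiagHrb`), separating DIA from HRB robustly.
#'
#' @param comp data frame with columns `legMoS`, `legMoST`, `armMo`,
#'   `armCorr`, `kickRot`, `epsi`.
#' @param tol a [ski_tolerances].
#' @param leg_gate which leg-motion measure gates the diagonal super-class:
#'   `"legMoS"` (default; diagonal legwork is sagittal-dominant) or `"legMoST"`.
#' @return logical matrix with columns `DIA, DP, DK, DPrK, rK, HRB`.
#' @export
decision_functions <- function(comp, tol, leg_gate = c("legMoS", "legMoST")) {
  leg_gate <- match.arg(leg_gate)
  leg_tol <- if (leg_gate == "legMoS") tol$tol_legMoS else tol$tol_legMoST
  l_DParm <- comp$armMo > tol$tol_armMo & comp$armCorr > tol$tol_armPole
  l_HRBDIA <- comp$armMo > tol$tol_armMo & comp[[leg_gate]] > leg_tol &
    comp$armCorr < tol$tol_armDiagHrb
  l_HRB <- l_HRBDIA & comp$epsi > tol$tol_epsi
  l_DIA <- l_HRBDIA & !l_HRB & comp$armCorr < tol$tol_armDiagD
  l_DPrK <- l_DParm & comp$kickRot > tol$tol_kickRot &
    comp$legMoST > tol$tol_legMoST
  l_DK <- l_DParm & comp$legMoS > tol$tol_legMoS & !l_DPrK
  l_DP <- l_DParm & comp$legMoST < tol$tol_legMoST &
    comp$legMoS < tol$tol_legMoS
  l_rK <- comp$kickRot > tol$tol_kickRot & comp$armMo < tol$tol_armMo &
    comp$legMoST > tol$tol_legMoST
  cbind(DIA = l_DIA, DP = l_DP, DK = l_DK, DPrK = l_DPrK, rK = l_rK,
        HRB = l_HRB)
}

#' Classify one motion-component sample
#'
#' Evaluates the decision functions on a single component vector and returns
#' the unique sub-technique whose decision function is true, or `noTech` when
#' none is.
#'
#' @param x named list / one-row data frame with `legMoS`, `legMoST`,
#'   `armMo`, `armCorr`, `kickRot`, `epsi`; all finite.
#' @param tol a [ski_tolerances].
#' @param leg_gate see [decision_functions()].
#' @return factor of length 1 over the technique levels.
#' @export
decide_sample <- function(x, tol = ski_tolerances(),
                          leg_gate = c("legMoS", "legMoST")) {
  x <- as.data.frame(as.list(x))
  vals <- unlist(x[c("legMoS", "legMoST", "armMo", "armCorr", "kickRot", "epsi")])
  if (any(!is.finite(vals)))
    stop("non-finite motion component; mask edge samples before classifying")
  L <- decision_functions(x, tol, leg_gate)
  hit <- which(L[1L, ])
  lab <- if (length(hit) == 1L) colnames(L)[hit]
         else if (length(hit) == 0L) "noTech"
         else stop("decision functions not disjoint at this point: ",
                   paste(colnames(L)[hit], collapse = ", "))
  factor(lab, levels = TECH_LEVELS)
}

#' Classify a motion-component series
#'
#' Applies the decision functions per timestamp.  Samples flagged `edge`
#' (truncated analysis window) are labelled `noTech`.
#'
#' @param comp a `ski_components` data frame (from [assemble_components()]),
#'   or any data frame with the component columns.
#' @param tol a [ski_tolerances].
#' @param leg_gate see [decision_functions()].
#' @return data frame of class `ski_labels` with columns `t`, `label`.
#' @export
classify_series <- function(comp, tol = ski_tolerances(),
                            leg_gate = c("legMoS", "legMoST")) {
  L <- decision_functions(comp, tol, leg_gate)
  multi <- rowSums(L) > 1L
  if (any(multi))
    stop("decision functions not disjoint at sample ", which(multi)[1L])
  idx <- max.col(cbind(L, noTech = rowSums(L) == 0L), ties.method = "first")
  lab <- factor(c(colnames(L), "noTech")[idx], levels = TECH_LEVELS)
  if (!is.null(comp$edge)) lab[comp$edge] <- "noTech"
  t <- if (!is.null(comp$t)) comp$t else seq_len(nrow(comp))
  structure(data.frame(t = t, label = lab),
            class = c("ski_labels", "data.frame"))
}

#' Verify pairwise disjointness / uniqueness of the decision functions
#'
#' Evaluates the decision layer on a full factorial grid of component values
#' and reports every grid point at which the number of true sub-technique
#' labels (counting `noTech` as the complement) differs from one.  With the
#' default grid each component takes values strictly below, just below, just
#' above, and clearly above every one of its tolerances.
#'
#' @param tol a [ski_tolerances].
#' @param grid_spec named list of value vectors per component
#'   (`legMoS`, `legMoST`, `armMo`, `armCorr`, `kickRot`, `epsi`); defaults
#'   to [tolerance_grid()].
#' @param decision_fun function `(comp, tol) -> logical matrix`; defaults to
#'   [decision_functions()].  Supplying a variant lets one demonstrate how a
#'   broken rule set violates disjointness.
#' @return list with `ok` (logical), `n_points`, and `violations`, a data
#'   frame of offending grid points with the count of simultaneous labels.
#' @export
check_disjointness <- function(tol = ski_tolerances(), grid_spec = NULL,
                               decision_fun = decision_functions) {
  if (is.null(grid_spec)) grid_spec <- tolerance_grid(tol)
  need <- c("legMoS", "legMoST", "armMo", "armCorr", "kickRot", "epsi")
  miss <- setdiff(need, names(grid_spec))
  if (length(miss)) stop("grid_spec missing component(s): ",
                         paste(miss, collapse = ", "))
  grid <- expand.grid(grid_spec[need], KEEP.OUT.ATTRS = FALSE)
  L <- decision_fun(grid, tol)
  nlab <- rowSums(L)            # noTech fires iff nlab == 0, so unique <=> nlab <= 1
  bad <- which(nlab > 1L)
  violations <- if (length(bad)) {
    cbind(grid[bad, , drop = FALSE], n_labels = nlab[bad],
          labels = apply(L[bad, , drop = FALSE], 1L,
                         function(z) paste(colnames(L)[z], collapse = "+")))
  } else {
    cbind(grid[0, , drop = FALSE], n_labels = integer(0), labels = character(0))
  }
  list(ok = length(bad) == 0L, n_points = nrow(grid), violations = violations)
}

#' Factorial component grid bracketing every tolerance
#'
#' For each component, values strictly below, at -eps, at +eps, and strictly
#' above each of its tolerances (plus representative extremes), for use with
#' [check_disjointness()].
#'
#' @param tol a [ski_tolerances].
#' @param eps bracketing offset.
#' @return named list of value vectors.
#' @export
tolerance_grid <- function(tol, eps = 1e-6) {
  around <- function(v) sort(unique(c(v - eps, v + eps)))
  list(legMoS = c(0, around(tol$tol_legMoS), 10 * tol$tol_legMoS),
       legMoST = c(0, around(tol$tol_legMoST), 10 * tol$tol_legMoST),
       armMo = c(0, around(tol$tol_armMo), 10 * tol$tol_armMo),
       armCorr = c(-1, around(tol$tol_armDiagD), around(tol$tol_armDiagHrb),
                   0, around(tol$tol_armPole), 1),
       kickRot = c(0, around(tol$tol_kickRot), 10 * tol$tol_kickRot),
       epsi = c(-1, 0, around(tol$tol_epsi), 1))
}
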