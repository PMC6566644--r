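tol <- ski_tolerances()

test_that("single samples are assigned the expected sub-technique", {
  expect_equal(as.character(decide_sample(
    comp_row(legMoS = 1, legMoST = 4, armMo = 2e4, armCorr = 0.8,
             kickRot = 1, epsi = 0))), "DP")
  expect_equal(as.character(decide_sample(
    comp_row(legMoS = 10, legMoST = 20, armMo = 2e4, armCorr = -0.6,
             kickRot = 1, epsi = 0.01))), "DIA")
  expect_equal(as.character(decide_sample(
    comp_row(legMoS = 10, legMoST = 120, armMo = 5e3, armCorr = 0,
             kickRot = 3, epsi = 0))), "rK")
  expect_equal(as.character(decide_sample(comp_row())), "noTech")
  # herringbone needs the positive ski-orientation estimate
  expect_equal(as.character(decide_sample(
    comp_row(legMoS = 10, legMoST = 20, armMo = 2e4, armCorr = -0.35,
             kickRot = 1, epsi = 0.1))), "HRB")
  # same arm/leg work with epsi below tolerance and a mild anti-correlation
  # is neither HRB nor DIA (the DIA bound is stricter)
  expect_equal(as.character(decide_sample(
    comp_row(legMoS = 10, legMoST = 20, armMo = 2e4, armCorr = -0.35,
             kickRot = 1, epsi = 0))), "noTech")
  # kick rotation turns DK into DPrK only with enough total leg motion
  expect_equal(as.character(decide_sample(
    comp_row(legMoS = 10, legMoST = 120, armMo = 2e4, armCorr = 0.8,
             kickRot = 3, epsi = 0))), "DPrK")
  expect_equal(as.character(decide_sample(
    comp_row(legMoS = 10, legMoST = 40, armMo = 2e4, armCorr = 0.8,
             kickRot = 3, epsi = 0))), "DK")
  expect_error(decide_sample(comp_row(armMo = NaN)), "non-finite")
})

test_that("comparisons are strict: tolerance-equal values do not fire", {
  # armMo exactly at tolerance fails the poling and diagonal classes
  expect_equal(as.character(decide_sample(
    comp_row(legMoS = 10, armMo = tol$tol_armMo, armCorr = 0.8))), "noTech")
  # legMoS exactly at tolerance: DP (requires <) also fails -> noTech
  expect_equal(as.character(decide_sample(
    comp_row(legMoS = tol$tol_legMoS, legMoST = 4, armMo = 2e4,
             armCorr = 0.8))), "noTech")
  # just above / below resolve deterministically
  expect_equal(as.character(decide_sample(
    comp_row(legMoS = tol$tol_legMoS + 1e-9, legMoST = 4, armMo = 2e4,
             armCorr = 0.8))), "DK")
  expect_equal(as.character(decide_sample(
    comp_row(legMoS = tol$tol_legMoS - 1e-9, legMoST = 4, armMo = 2e4,
             armCorr = 0.8))), "DP")
})

test_that("series classification masks edges and applies per sample", {
  n <- 40
  comp <- comp_row(legMoS = 1, legMoST = 4, armMo = 2e4, armCorr = 0.8)[
    rep(1, n), ]
  comp$t <- (seq_len(n) - 1) / 20
  lab <- classify_series(comp, tol)
  expect_true(all(lab$label == "DP"))
  # alternating DP-like / rK-like rows alternate labels
  rk <- comp_row(legMoS = 10, legMoST = 120, armMo = 5e3, kickRot = 3)
  comp2 <- comp
  comp2[seq(2, n, by = 2), names(rk)] <- rk[rep(1, n / 2), ]
  lab2 <- classify_series(comp2, tol)
  expect_true(all(lab2$label[seq(1, n, 2)] == "DP"))
  expect_true(all(lab2$label[seq(2, n, 2)] == "rK"))
  # edge-flagged samples are forced to noTech
  comp$edge <- c(TRUE, rep(FALSE, n - 2), TRUE)
  lab3 <- classify_series(comp, tol)
  expect_equal(as.character(lab3$label[c(1, n)]), c("noTech", "noTech"))
  expect_true(all(lab3$label[2:(n - 1)] == "DP"))
})

test_that("exactly one label fires for any finite component vector", {
  set.seed(51)
  n <- 1e5
  comp <- data.frame(
    legMoS = runif(n, 0, 20),
    armMo = exp(runif(n, 0, log(1e6))),
    armCorr = runif(n, -1, 1),
    kickRot = runif(n, 0, 5),
    epsi = runif(n, -0.3, 0.3))
  comp$legMoST <- comp$legMoS + runif(n, 0, 200)
  L <- decision_functions(comp, tol)
  expect_true(all(rowSums(L) <= 1L))          # disjoint
  lab <- classify_series(comp, tol)$label     # total: every sample labelled
  expect_false(anyNA(lab))
})

test_that("monotone consistency of the arm-correlation super-classes", {
  set.seed(52)
  n <- 2e4
  comp <- data.frame(
    legMoS = runif(n, 0, 20), armMo = runif(n, 0, 5e4),
    armCorr = runif(n, tol$tol_armPole + 1e-9, 1),
    kickRot = runif(n, 0, 5), epsi = runif(n, -0.3, 0.3))
  comp$legMoST <- comp$legMoS + runif(n, 0, 200)
  lab <- classify_series(comp, tol)$label
  expect_false(any(lab %in% c("DIA", "HRB")))  # correlated arms never diagonal
  comp$armMo <- runif(n, 0, tol$tol_armMo - 1e-9)
  lab2 <- classify_series(comp, tol)$label
  expect_false(any(lab2 %in% c("DP", "DK", "DPrK")))  # weak arms never poling
})

test_that("disjointness verification passes the true rules and catches broken ones", {
  rep_ok <- check_disjointness(tol)
  expect_true(rep_ok$ok)
  expect_gte(rep_ok$n_points, 4^6)
  expect_equal(nrow(rep_ok$violations), 0L)

  # all-zero point classifies as noTech only
  z <- check_disjointness(tol, grid_spec = list(
    legMoS = 0, legMoST = 0, armMo = 0, armCorr = 0, kickRot = 0, epsi = 0))
  expect_true(z$ok)
  expect_equal(as.character(decide_sample(comp_row())), "noTech")

  # dropping the DPrK exclusion from DK breaks disjointness exactly where
  # a strong rotational kick accompanies strong poling and leg motion
  broken <- function(comp, tol, ...) {
    L <- decision_functions(comp, tol, ...)
    l_DParm <- comp$armMo > tol$tol_armMo & comp$armCorr > tol$tol_armPole
    L[, "DK"] <- l_DParm & comp$legMoS > tol$tol_legMoS
    L
  }
  rep_bad <- check_disjointness(tol, decision_fun = broken)
  expect_false(rep_bad$ok)
  v <- rep_bad$violations
  expect_true(all(v$kickRot > tol$tol_kickRot & v$legMoST > tol$tol_legMoST &
                    v$legMoS > tol$tol_legMoS))
  expect_true(all(v$labels == "DK+DPrK"))
})
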