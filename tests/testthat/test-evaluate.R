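test_that("reference mapping rules follow the two transition schemes", {
  ref <- reference_cycles(start = 0:4, stop = 1:5,
                          label = c("fDIA", "tDIA", "TCK", "DP", "HRB"))
  a <- map_reference_labels(ref, "a")
  expect_equal(as.character(a$label), c("DIA", "DIA", "noTech", "DP", "HRB"))
  b <- map_reference_labels(ref, "b")
  expect_equal(as.character(b$label), c("DK", "DIA", "noTech", "DP", "HRB"))
  expect_error(map_reference_labels(ref, "c"))
  # algorithm-side rotational kicks merge into the turn class
  expect_equal(as.character(map_predicted_labels(c("DPrK", "rK", "DP"))),
               c("TRN", "TRN", "DP"))
})

test_that("confusion counts, precision and sensitivity match hand enumeration", {
  pred <- data.frame(start = 0:9, stop = 1:10,
                     label = rep(c("DP", "DIA"), 5))
  ref <- data.frame(start = 0:9, stop = 1:10,
                    label = rep(c("DP", "DIA"), 5))
  cm <- confusion(pred, ref)
  expect_equal(cm$accuracy, 1)
  expect_equal(sum(cm$table), 10)
  expect_equal(unname(diag(cm$table)[c("DIA", "DP")]), c(5, 5))

  # pred (DP, DP, DIA) vs ref (DP, DIA, DIA): accuracy 2/3,
  # precision(DP) = 1/2, sensitivity(DP) = 1, sensitivity(DIA) = 1/2
  pred2 <- data.frame(start = 0:2, stop = 1:3, label = c("DP", "DP", "DIA"))
  ref2 <- data.frame(start = 0:2, stop = 1:3, label = c("DP", "DIA", "DIA"))
  cm2 <- confusion(pred2, ref2)
  expect_equal(cm2$accuracy, 2 / 3)
  expect_equal(unname(cm2$precision["DP"]), 1 / 2)
  expect_equal(unname(cm2$sensitivity["DP"]), 1)
  expect_equal(unname(cm2$precision["DIA"]), 1)
  expect_equal(unname(cm2$sensitivity["DIA"]), 1 / 2)
  # row/column sums tally the class totals; total equals matched cycles
  expect_equal(unname(rowSums(cm2$table)[c("DIA", "DP")]), c(1, 2))
  expect_equal(unname(colSums(cm2$table)[c("DIA", "DP")]), c(2, 1))
  expect_equal(sum(cm2$table), cm2$n_matched)

  expect_error(confusion(pred2[0, ], ref2), "empty prediction")
  expect_error(confusion(data.frame(start = 100, stop = 101, label = "DP"),
                         ref2), "disjoint")
})

test_that("misaligned cycles are matched by maximal overlap and filtered", {
  # predicted boundaries shifted 0.3 s against 1 s reference cycles
  pred <- data.frame(start = 0:4 + 0.3, stop = 1:5 + 0.3,
                     label = rep("DP", 5))
  ref <- data.frame(start = 0:5, stop = 1:6, label = rep("DP", 6))
  cm <- confusion(pred, ref)
  expect_equal(cm$n_matched, 5)
  expect_equal(cm$accuracy, 1)
  # a predicted cycle with < 50% overlap is excluded and counted
  pred2 <- rbind(pred, data.frame(start = 20, stop = 30, label = "DP"))
  pred2$stop[6] <- 30; pred2$start[6] <- 5.8   # only 0.2/24.2 overlaps
  cm2 <- confusion(pred2, ref)
  expect_equal(cm2$n_excluded, 1)
  expect_equal(cm2$n_matched, 5)
})

test_that("switching transition scheme moves only DIA/DK confusion cells", {
  set.seed(71)
  labs <- sample(c("DIA", "DP", "DK", "fDIA", "tDIA", "TCK"), 40,
                 replace = TRUE)
  ref <- reference_cycles(start = 0:39, stop = 1:40, label = labs)
  # algorithm labels: call fDIA cycles DK (their mechanics), others correct
  pred_lab <- ifelse(labs == "fDIA", "DK",
                     ifelse(labs == "tDIA", "DIA",
                            ifelse(labs == "TCK", "noTech", labs)))
  pred <- data.frame(start = 0:39, stop = 1:40, label = pred_lab)
  cma <- confusion(pred, map_reference_labels(ref, "a"))
  cmb <- confusion(pred, map_reference_labels(ref, "b"))
  delta <- cmb$table - cma$table
  moved <- colnames(delta)[colSums(delta != 0) > 0]
  expect_true(all(moved %in% c("DIA", "DK")))
  # under scheme b the fDIA cycles count as correct DK, so DK precision rises
  expect_gte(cmb$precision["DK"], cma$precision["DK"])
  expect_gte(cmb$accuracy, cma$accuracy)
})

test_that("distribution summaries report percentages and frequencies", {
  cyc <- structure(data.frame(start = 0:9, stop = 1:10,
                              label = factor(rep(c("DP", "DIA"), 5),
                                             levels = xcski:::TECH_LEVELS),
                              duration = 1, frequency = rep(c(0.8, 0.75), 5),
                              freq_ok = TRUE),
                   class = c("ski_cycles", "data.frame"))
  samp <- data.frame(t = (0:199) / 20,
                     label = factor(rep(c("DP", "DIA"), each = 100),
                                    levels = xcski:::TECH_LEVELS))
  d <- distribution_summary(cyc, samp)
  expect_equal(d$pct_samples[d$technique == "DP"], 50)
  expect_equal(d$pct_samples[d$technique == "DIA"], 50)
  expect_equal(sum(d$pct_samples), 100, tolerance = 0.1)
  expect_equal(d$mean_freq[d$technique == "DP"], 0.8)
  expect_true(is.na(d$mean_freq[d$technique == "HRB"]))  # absent technique

  # a synthetic half-and-half session splits ~50/50 excluding transitions
  syn <- generate_session(list(technique_motif("DIA", duration = 30),
                               technique_motif("DP", duration = 30)),
                          seed = 4)
  cl <- classify_session(syn$session, preprocess = FALSE)
  d2 <- distribution_summary(cl$cycles, cl$samples,
                             exclude = syn$labels$transition |
                               cl$components$edge)
  expect_equal(d2$pct_samples[d2$technique == "DIA"], 50, tolerance = 2)
  expect_equal(d2$pct_samples[d2$technique == "DP"], 50, tolerance = 2)
})
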