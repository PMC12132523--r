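# Exclusion rules and the QC audit log.

test_that("severe movement rule follows |control| > IRV with absolute values", {
  expect_false(severeMovementCheck(2.8, 0.1, -0.2))
  expect_true(severeMovementCheck(1.0, 1.5, 0.0))
  expect_true(severeMovementCheck(1.0, -1.2, 0.0))
  # exact tie is kept: the rule requires strictly greater
  expect_false(severeMovementCheck(1.0, 1.0, -1.0))
  # negative IRV with any nonzero control is flagged
  expect_true(severeMovementCheck(-0.5, 0.1, 0))
  expect_error(severeMovementCheck(1, NA, 0), class = "rq_validation_error")
})

makeMeasurements <- function(n, irv = 2.5, orth = 0.05, par = -0.05) {
  data.frame(recording_id = sprintf("R%02d", seq_len(n)),
             embryo_id = sprintf("E%02d", rep(seq_len(ceiling(n / 2)),
                                              each = 2)[seq_len(n)]),
             irv = rep_len(irv, n), orth_irv = rep_len(orth, n),
             par_irv = rep_len(par, n),
             insufficient_landmarks = FALSE, region = "lateral",
             orientation = "ML", bubbles = FALSE, outside_region = FALSE,
             stringsAsFactors = FALSE)
}

makeMetadata <- function(ids, sex = "F", somites = 7) {
  data.frame(embryo_id = ids, sex = rep_len(sex, length(ids)),
             somites = rep_len(somites, length(ids)), heartbeat_ok = TRUE,
             stringsAsFactors = FALSE)
}

test_that("unknown sex or stage and bubbles are excluded with the right reasons", {
  mm <- makeMeasurements(10)
  meta <- makeMetadata(unique(mm$embryo_id))
  meta$sex[1] <- "unknown"
  res <- applyExclusions(mm, meta)
  dropped <- res$decisions[!res$decisions$kept, ]
  expect_equal(nrow(res$analysis), 8)  # embryo E01 has 2 ablations
  expect_true(all(dropped$reasons == "unknown_sex_or_stage"))

  mm2 <- makeMeasurements(10)
  mm2$bubbles[4] <- TRUE
  res2 <- applyExclusions(mm2, makeMetadata(unique(mm2$embryo_id)))
  expect_false(res2$decisions$kept[4])
  expect_equal(res2$decisions$reasons[4], "bubbles")
  expect_equal(sum(res2$decisions$kept), 9)
})

test_that("constructed severe-movement fixtures are dropped exactly", {
  mm <- makeMeasurements(20)
  crossing <- c(3, 11, 17)
  mm$orth_irv[crossing] <- mm$irv[crossing] + 0.4  # |orth| > irv by hand
  res <- applyExclusions(mm, makeMetadata(unique(mm$embryo_id)))
  expect_setequal(which(!res$decisions$kept), crossing)
  expect_true(all(grepl("severe_movement",
                        res$decisions$reasons[crossing])))
})

test_that("decisions partition the input: kept + dropped = all, no duplicates", {
  mm <- makeMeasurements(15)
  mm$orth_irv[2] <- 5
  mm$bubbles[7] <- TRUE
  res <- applyExclusions(mm, makeMetadata(unique(mm$embryo_id)))
  expect_equal(nrow(res$decisions), 15)
  expect_equal(nrow(res$analysis) + sum(!res$decisions$kept), 15)
  expect_false(anyDuplicated(res$decisions$recording_id) > 0)
  expect_true(all(res$decisions$kept == (res$decisions$reasons == "")))
  expect_equal(unname(res$counts["ablations"]), nrow(res$analysis))
})

test_that("relaxing the severe-movement rule never decreases the kept count", {
  set.seed(9)
  mm <- makeMeasurements(30, irv = rnorm(30, 2, 1),
                         orth = rnorm(30, 0, 1.5), par = rnorm(30, 0, 1.5))
  meta <- makeMetadata(unique(mm$embryo_id))
  kept1 <- sum(applyExclusions(mm, meta)$decisions$kept)
  mm2 <- mm
  mm2$orth_irv <- mm2$orth_irv * 0.5
  mm2$par_irv <- mm2$par_irv * 0.5
  kept2 <- sum(applyExclusions(mm2, meta)$decisions$kept)
  expect_gte(kept2, kept1)
})

test_that("exclusions are idempotent", {
  set.seed(10)
  mm <- makeMeasurements(30, irv = rnorm(30, 2, 1),
                         orth = rnorm(30, 0, 1.5), par = rnorm(30, 0, 1.5))
  meta <- makeMetadata(unique(mm$embryo_id))
  first <- applyExclusions(mm, meta)
  second <- applyExclusions(
    first$analysis[, names(mm)], meta)
  expect_true(all(second$decisions$kept))
  expect_equal(nrow(second$analysis), nrow(first$analysis))
})

test_that("embryo-scope severe movement drops all ablations of the embryo", {
  mm <- makeMeasurements(10)
  mm$orth_irv[1] <- 10  # embryo E01 has recordings 1 and 2
  perAblation <- applyExclusions(mm, makeMetadata(unique(mm$embryo_id)))
  expect_equal(sum(!perAblation$decisions$kept), 1)
  perEmbryo <- applyExclusions(mm, makeMetadata(unique(mm$embryo_id)),
                               severeMovementScope = "embryo")
  expect_equal(sum(!perEmbryo$decisions$kept), 2)
})

test_that("duplicate recording ids and unjoined embryos are handled", {
  mm <- makeMeasurements(4)
  mm$recording_id[2] <- mm$recording_id[1]
  expect_error(applyExclusions(mm, makeMetadata(unique(mm$embryo_id))),
               class = "rq_validation_error")
  mm2 <- makeMeasurements(4)
  meta <- makeMetadata(unique(mm2$embryo_id)[1])  # second embryo missing
  res <- applyExclusions(mm2, meta)
  expect_true(all(grepl("unknown_sex_or_stage",
                        res$decisions$reasons[3:4])))
})
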