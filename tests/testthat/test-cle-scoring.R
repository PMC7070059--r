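# every rubric grade's defining frame, written out as in the scoring table
table_frames <- list(
  `0` = frame_annotation(),  # no architecture change, NE680 absent
  `1` = frame_annotation(ne680_lumen = "present"),
  `2` = frame_annotation(healthy_crypt_fraction = 0.8,
                         crypt_architecture_change = "present",
                         ne680_lumen = "high", collapsed_crypts = "present"),
  `3` = frame_annotation(crypt_architecture_change = "present",
                         collapsed_crypts = "significant",
                         ne680_area = "high", ne680_lumen = "high",
                         healthy_crypt_fraction = 0.4),
  `4` = frame_annotation(crypt_architecture_change = "present",
                         acriflavine_unstained_fraction = 0.7,
                         ne680_lumen = "high", ne680_area = "high",
                         collapsed_crypts = "significant",
                         ne680_cells_in_erosions = "present",
                         crypt_loss = "present",
                         healthy_crypt_fraction = 0.2),
  `5` = frame_annotation(crypt_architecture_change = "present",
                         ne680_cells_in_erosions = "exclusive",
                         crypt_loss = "significant",
                         collapsed_crypts = "significant",
                         ne680_lumen = "high", ne680_area = "high",
                         acriflavine_unstained_fraction = 0.9,
                         healthy_crypt_fraction = 0)
)

test_that("each grade's defining frame receives its own score", {
  for (s in names(table_frames)) {
    expect_identical(score_frame(table_frames[[s]]), as.integer(s))
  }
})

# finite severity lattice used for the exhaustive properties
.lattice <- function() {
  grid <- expand.grid(
    healthy_crypt_fraction = c(1, 0.6, 0.4, 0),
    crypt_architecture_change = c("none", "present"),
    collapsed_crypts = c("none", "present", "significant"),
    ne680_lumen = c("absent", "present", "high"),
    ne680_area = c("low", "high"),
    acriflavine_unstained_fraction = c(0, 0.4, 0.6, 1),
    ne680_cells_in_erosions = c("none", "present", "exclusive"),
    crypt_loss = c("none", "present", "significant"),
    stringsAsFactors = FALSE
  )
  ok <- !(grid$crypt_architecture_change == "none" &
            (grid$collapsed_crypts != "none" | grid$crypt_loss != "none"))
  grid[ok, ]
}

test_that("every valid annotation maps to exactly one score in 0..5", {
  grid <- .lattice()
  scores <- vapply(seq_len(nrow(grid)), function(i) {
    score_frame(do.call(frame_annotation, as.list(grid[i, ])))
  }, integer(1))
  expect_true(all(scores %in% 0:5))
  expect_setequal(unique(scores), 0:5)
})

test_that("worsening any single feature never decreases the score", {
  grid <- .lattice()
  scores <- vapply(seq_len(nrow(grid)), function(i) {
    score_frame(do.call(frame_annotation, as.list(grid[i, ])))
  }, integer(1))
  key <- do.call(paste, c(grid, sep = "|"))
  lookup <- stats::setNames(scores, key)

  worsen <- list(
    healthy_crypt_fraction = function(v) c(`1` = 0.6, `0.6` = 0.4,
                                           `0.4` = 0)[as.character(v)],
    crypt_architecture_change = function(v) c(none = "present")[v],
    collapsed_crypts = function(v) c(none = "present",
                                     present = "significant")[v],
    ne680_lumen = function(v) c(absent = "present", present = "high")[v],
    ne680_area = function(v) c(low = "high")[v],
    acriflavine_unstained_fraction = function(v) c(`0` = 0.4, `0.4` = 0.6,
                                                   `0.6` = 1)[as.character(v)],
    ne680_cells_in_erosions = function(v) c(none = "present",
                                            present = "exclusive")[v],
    crypt_loss = function(v) c(none = "present", present = "significant")[v]
  )
  n_checked <- 0L
  for (feat in names(worsen)) {
    stepped <- worsen[[feat]](grid[[feat]])
    has_step <- !is.na(stepped)
    g2 <- grid[has_step, ]
    g2[[feat]] <- stepped[has_step]
    k2 <- do.call(paste, c(g2, sep = "|"))
    valid <- k2 %in% names(lookup)  # skip steps leaving the valid lattice
    expect_true(all(lookup[k2[valid]] >= scores[has_step][valid]))
    n_checked <- n_checked + sum(valid)
  }
  expect_gt(n_checked, 10000)
})

test_that("annotations violating the architecture invariant are rejected", {
  expect_error(frame_annotation(collapsed_crypts = "present"),
               "architecture")
  expect_error(frame_annotation(crypt_loss = "significant"), "architecture")
  expect_error(frame_annotation(healthy_crypt_fraction = 1.2), "fraction")
  expect_error(frame_annotation(ne680_lumen = "extreme"), "one of")
})

test_that("per-animal aggregation follows mode with upward ties", {
  f <- function(s) rubric_exemplar(s)
  expect_equal(score_animal(list(f(2), f(2), f(3)))$score, 2)
  expect_warning(two <- score_animal(list(f(1), f(3))), "fewer than 3")
  expect_equal(two$score, 3)
  expect_warning(one <- score_animal(list(f(5))), "fewer than 3")
  expect_equal(one$score, 5)
  expect_equal(score_animal(list(f(1), f(1), f(4)), method = "max")$score, 4)
  expect_equal(score_animal(list(f(1), f(2), f(2), f(4)),
                            method = "median")$score, 2)
  expect_error(score_animal(list()), "no frames")
})

test_that("aggregate score stays within the frame score range", {
  withr::with_seed(21, {
    for (i in 1:25) {
      sc <- sample(0:5, sample(3:7, 1), replace = TRUE)
      frames <- lapply(sc, rubric_exemplar)
      for (m in c("mode", "max", "median")) {
        agg <- score_animal(frames, method = m)$score
        expect_gte(agg, min(sc))
        expect_lte(agg, max(sc))
      }
    }
  })
})
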