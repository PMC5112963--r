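test_that("square indices map corners and channels correctly", {
  # top-left corner of the red map, row-major (0-based offsets + 1)
  expect_equal(square_indices(grid_position(0, 0), "red"),
               sort(c(1:5, 26:30, 51:55, 76:80, 101:105)))
  # opposite corner stays inside the 625-unit red segment
  br <- square_indices(grid_position(20, 20), "red")
  expect_length(br, 25)
  expect_equal(max(br), 625)
  # action channel is the red layout shifted by 625 + 625 + 25 + 25
  expect_equal(square_indices(grid_position(0, 0), "action"),
               square_indices(grid_position(0, 0), "red") + 1300L)
  expect_equal(square_indices(grid_position(3, 7), "green"),
               square_indices(grid_position(3, 7), "red") + 625L)
})

test_that("invalid grid positions are rejected by coordinate", {
  expect_error(grid_position(21, 0), "row 21")
  expect_error(grid_position(0, -1), "col -1")
  expect_error(grid_position(0, 25), "col 25")
})

test_that("single-stimulus specs pair colour with context and action", {
  set.seed(11)
  for (i in 1:20) {
    sA <- sample_spec(FALSE, "A")
    expect_null(sA$green_pos)
    expect_identical(sA$action_pos, sA$red_pos)
    sB <- sample_spec(FALSE, "B")
    expect_null(sB$red_pos)
    expect_identical(sB$action_pos, sB$green_pos)
  }
})

test_that("double-stimulus footprints are always spatially disjoint", {
  set.seed(12)
  for (i in 1:300) {
    sp <- sample_spec(TRUE, sample(c("A", "B"), 1))
    expect_length(intersect(square_indices(sp$red_pos, "red") - 0L,
                            square_indices(sp$green_pos, "red")), 0)
  }
})

test_that("two-locations sampler only ever produces the two corner layouts", {
  set.seed(13)
  combos <- replicate(2000, {
    sp <- sample_spec(TRUE, "A", two_locations = TRUE)
    paste(format(sp$red_pos), format(sp$green_pos))
  })
  # brute-force enumeration over the sampler: exactly two assignments,
  # red and green never in the same corner
  expect_setequal(unique(combos),
                  c("(0,0) (20,20)", "(20,20) (0,0)"))
})

test_that("rendered patterns have the exact unit counts of the layout", {
  set.seed(14)
  sp1 <- sample_spec(FALSE, "A")
  v1 <- render(sp1)
  expect_length(v1, 1925)
  expect_equal(sum(v1), 75) # 25 stimulus + 25 context + 25 action
  sp2 <- sample_spec(TRUE, "B")
  v2 <- render(sp2, include_action = FALSE)
  expect_equal(sum(v2), 75) # 25 red + 25 green + 25 context
  expect_equal(sum(v2[1301:1925]), 0) # action channel empty
  v3 <- render(sp2, include_action = TRUE)
  expect_equal(sum(v3), 100)
})

test_that("region masks exactly tile the active units of a rendered pattern", {
  set.seed(15)
  for (i in 1:20) {
    sp <- sample_spec(TRUE, sample(c("A", "B"), 1))
    v <- render(sp, include_action = TRUE)
    m <- region_masks(sp)
    on_idx <- sort(c(m$relevant_stim, m$irrelevant_stim, m$correct_action,
                     m$correct_context))
    expect_equal(which(v == 1), on_idx)
  }
})

test_that("generated vectors satisfy the visible-layer invariants", {
  set.seed(16)
  for (i in 1:200) {
    two <- i %% 2 == 0
    sp <- sample_spec(two, sample(c("A", "B"), 1))
    v <- render(sp)
    expect_true(all(v %in% c(0, 1)))
    ctxA <- v[1251:1275]; ctxB <- v[1276:1300]
    expect_true(all(ctxA == 1) != all(ctxB == 1)) # mutually exclusive blocks
    expect_true(all(ctxA == 0) || all(ctxA == 1))
    expect_equal(sum(v[1:625]), if (is.null(sp$red_pos)) 0 else 25)
    expect_equal(sum(v[626:1250]), if (is.null(sp$green_pos)) 0 else 25)
  }
})

test_that("training set has the prescribed composition", {
  set.seed(17)
  d <- generate_training_set(5000)
  expect_equal(d$n, 5000)
  two <- vapply(d$specs, attnet:::is_double_stimulus, logical(1))
  ctx <- vapply(d$specs, function(s) s$context, character(1))
  expect_equal(sum(two), 2500)
  expect_equal(sum(ctx[two] == "A"), 1250)
  expect_equal(sum(ctx[!two] == "A"), 1250)
  expect_true(all(vapply(d$specs, function(s) s$action_present, logical(1))))
})

test_that("double-only training set contains no single-stimulus patterns", {
  set.seed(18)
  d <- generate_training_set(200, double_only = TRUE)
  expect_true(all(vapply(d$specs, attnet:::is_double_stimulus, logical(1))))
  ctx <- vapply(d$specs, function(s) s$context, character(1))
  expect_equal(sum(ctx == "A"), 100)
})

test_that("test sets are double-stimulus, context-balanced, and respect the condition", {
  set.seed(19)
  ts <- generate_test_set(1000, "complete")
  expect_equal(ts$n, 1000)
  expect_true(all(vapply(ts$specs, attnet:::is_double_stimulus, logical(1))))
  ctx <- vapply(ts$specs, function(s) s$context, character(1))
  expect_equal(sum(ctx == "A"), 500)
  expect_true(all(rowSums(ts$V) == 100))
  tn <- generate_test_set(100, "no_action")
  expect_true(all(tn$V[, 1301:1925] == 0))
  expect_true(all(rowSums(tn$V) == 75))
})

test_that("dataset generation is deterministic given the seed", {
  set.seed(20); a <- generate_training_set(100)
  set.seed(20); b <- generate_training_set(100)
  expect_identical(a, b)
})

test_that("stimulus positions are uniform over the 441 admissible cells", {
  set.seed(21)
  pos <- replicate(10000, {
    sp <- sample_spec(FALSE, "A")
    sp$red_pos$row * 21L + sp$red_pos$col
  })
  counts <- tabulate(pos + 1L, nbins = 441L)
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.001)
})
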