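# Replicate-consistent fold-change classification, intersections, invariant
# controls, and fold-change ranking.

norm2 <- function(...) as_norm(count_mat(...))

test_that("per-window fold change is (a+p)/(b+p) with documented degeneracies", {
  m <- norm2(c(20, 9), c(0, 0), c(5, 5))
  colnames(m) <- c("a", "b"); m <- as_norm(m)
  fc <- per_window_fold(m, c("a", "b"), 1)
  expect_equal(unname(fc), c(21 / 10, 1, 1))

  fc0 <- per_window_fold(m, c("a", "b"), 0)
  expect_equal(unname(fc0[1]), 20 / 9)
  expect_true(is.nan(fc0[2]))                       # 0/0 with p = 0
  m2 <- norm2(c(3, 0)); colnames(m2) <- c("a", "b"); m2 <- as_norm(m2)
  expect_equal(unname(per_window_fold(m2, c("a", "b"), 0)), Inf)

  expect_error(per_window_fold(count_mat(c(1, 2)), c("s1", "s2")),
               class = "cp_config_error")
})

test_that("call_dependent applies the two-replicate rule exactly on the toy matrix", {
  m <- norm2(c(41, 9, 61, 19),
             c(41, 9, 25, 19),
             c(8, 1, 9, 1),
             windows = c("w1", "w2", "w3"))
  colnames(m) <- c("A1", "B1", "A2", "B2"); m <- as_norm(m)
  ct <- contrast_spec("dep", list(c("A1", "B1"), c("A2", "B2")))
  calls <- call_dependent(m, ct, class_params(2, 1, 10))
  expect_equal(calls$members, "w1")
  expect_equal(unname(calls$fc["w1", ]), c(42 / 10, 62 / 20))

  # equal conditions -> empty call set
  eq <- norm2(c(30, 30, 30, 30), c(7, 7, 7, 7))
  colnames(eq) <- c("A1", "B1", "A2", "B2"); eq <- as_norm(eq)
  expect_length(call_dependent(eq, ct)$members, 0)

  # fold 1.0 admits every window passing min_count
  all_in <- call_dependent(m, ct, class_params(1, 1, 10))
  expect_equal(all_in$members, c("w1", "w2"))
})

test_that("call_dependent equals the exhaustive rule oracle on random matrices", {
  set.seed(700)
  for (i in 1:40) {
    n <- sample(10:200, 1)
    m <- matrix(rnbinom(n * 4, mu = sample(5:60, 1), size = 2), n, 4,
                dimnames = list(sprintf("w%04d", 1:n), c("A1", "B1", "A2", "B2")))
    m <- as_norm(m)
    params <- class_params(sample(c(1.5, 2, 3), 1), sample(c(0, 1), 1),
                           sample(c(0, 10, 20), 1))
    pairs <- list(c("A1", "B1"), c("A2", "B2"))
    got <- call_dependent(m, contrast_spec("x", pairs), params)$members
    expect_identical(got, oracle_call_dependent(m, pairs, params))
  }
})

test_that("raising fold_threshold or min_count never adds members", {
  p <- shared_pipeline_objects()
  base <- call_dependent(p$norm, pdhs_contrast(), class_params(2, 1, 20))$members
  tighter_fold <- call_dependent(p$norm, pdhs_contrast(), class_params(3, 1, 20))$members
  tighter_count <- call_dependent(p$norm, pdhs_contrast(), class_params(2, 1, 40))$members
  expect_true(all(tighter_fold %in% base))
  expect_true(all(tighter_count %in% base))
})

test_that("shuffled replicate labels collapse sensitivity to near the FP rate", {
  p <- shared_pipeline_objects()
  cls <- match_truth(p$windows, p$ds$truth)
  planted <- !is.na(cls) & cls == "dependent_primed"

  ok <- call_dependent(p$norm, pdhs_contrast())$members
  sens <- sum(p$windows$window_id %in% ok & planted) / sum(planted)

  # swap condition labels within replicate 2: A_rep2 <-> A_nil_rep2
  shuffled <- contrast_spec("shuf", list(c("A_rep1", "A_nil_rep1"),
                                         c("A_nil_rep2", "A_rep2")))
  bad <- call_dependent(p$norm, shuffled)$members
  sens_shuf <- sum(p$windows$window_id %in% bad & planted) / sum(planted)
  expect_gt(sens, 0.5)
  expect_lt(sens_shuf, 0.05)
})

test_that("intersect_calls is set intersection with provenance", {
  m <- norm2(c(1, 1), c(1, 1), c(1, 1), c(1, 1), windows = paste0("w", 1:4))
  mk <- function(members, label) structure(
    list(label = label, members = members, fc = NULL,
         params = class_params(), window_ids = paste0("w", 1:4)),
    class = "dhs_call_set")
  a <- mk(c("w1", "w2", "w3"), "a"); b <- mk(c("w2", "w3", "w4"), "b")
  expect_equal(intersect_calls(a, b)$members, c("w2", "w3"))
  expect_equal(intersect_calls(a, a)$members, a$members)
  expect_length(intersect_calls(a, mk("w4", "c"))$members, 0)
  expect_equal(intersect_calls(a, b)$parents, c("a", "b"))

  other <- mk("w1", "d"); other$window_ids <- paste0("v", 1:4)
  expect_error(intersect_calls(a, other), class = "cp_windowset_mismatch")
})

test_that("select_invariant picks the flattest eligible windows deterministically", {
  # perfectly invariant matrix: ties resolved by coordinate (row) order
  m <- as_norm(count_mat(matrix(30, 8, 4) + 0,
                         windows = sprintf("w%d", 1:8)))
  colnames(m) <- c("A1", "B1", "A2", "B2"); m <- as_norm(m)
  ct <- contrast_spec("c", list(c("A1", "B1"), c("A2", "B2")))
  sel <- select_invariant(m, list(ct), 5)
  expect_equal(sel$members, sprintf("w%d", 1:5))
  expect_length(select_invariant(m, list(ct), 0)$members, 0)

  # known fold changes: matches an exhaustive sort oracle
  vals <- rbind(c(40, 40, 40, 40),    # |log2FC| = 0
                c(80, 40, 40, 40),    # ~1 in pair 1
                c(40, 40, 60, 40),    # ~0.57 in pair 2
                c(200, 25, 200, 25),  # large
                c(45, 40, 40, 45),    # small
                c(40, 200, 40, 40))   # large (downward)
  m2 <- as_norm(count_mat(vals, windows = paste0("w", 1:6)))
  colnames(m2) <- c("A1", "B1", "A2", "B2"); m2 <- as_norm(m2)
  score <- apply(vals, 1, function(r)
    max(abs(log2((r[1] + 1) / (r[2] + 1))), abs(log2((r[3] + 1) / (r[4] + 1)))))
  want <- paste0("w", sort(order(score)[1:3]))
  expect_equal(select_invariant(m2, list(ct), 3)$members, want)

  expect_error(select_invariant(m2, list(ct), 7),
               class = "cp_insufficient_windows")
})

test_that("rank_windows sorts ascending by fold change with stable ties", {
  m <- as_norm(count_mat(c(5, 10), c(20, 10), c(10, 10),
                         windows = c("w1", "w2", "w3")))
  colnames(m) <- c("a", "b"); m <- as_norm(m)
  expect_equal(rank_windows(m, c("a", "b"), 0), c("w1", "w3", "w2"))

  flat <- as_norm(count_mat(c(5, 5), c(5, 5), c(5, 5),
                            windows = c("w1", "w2", "w3")))
  colnames(flat) <- c("a", "b"); flat <- as_norm(flat)
  expect_equal(rank_windows(flat, c("a", "b")), c("w1", "w2", "w3"))

  # reversing the pair reverses the order (p = 0, distinct FCs)
  expect_equal(rank_windows(m, c("b", "a"), 0), rev(rank_windows(m, c("a", "b"), 0)))
})
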