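make_five_sample_fixture <- function() {
  # tumors t1:{A,B} t2:{A} t3:{B}; normals n1:{A,B} n2:{}
  list(matrix = toy_matrix(list(t1 = c("A", "B"), t2 = "A", t3 = "B",
                                n1 = c("A", "B"), n2 = character(0)),
                           genes = c("A", "B")),
       labels = toy_labels(c("t1", "t2", "t3"), c("n1", "n2")))
}

test_that("covers tests joint mutation of every combination gene", {
  m <- toy_matrix(list(s1 = c("A", "B", "C"), s2 = "A"))
  expect_true(covers(m["s1", ], c("A", "B")))
  expect_false(covers(m["s2", ], c("A", "B")))
  expect_error(covers(m["s1", ], character(0)))
  expect_error(covers(m["s1", ], c("A", "Z")), "Z")
})

test_that("confusion counts enumerate covered/uncovered by cohort", {
  f <- make_five_sample_fixture()
  cc <- confusion_counts(c("A", "B"), f$matrix, f$labels)
  expect_equal(cc, c(tp = 1L, fp = 1L, tn = 1L, fn = 2L))
  # nothing covered: combination gene mutated in no sample
  m2 <- cbind(f$matrix, Z = 0L, Y = 0L)
  expect_equal(confusion_counts(c("Y", "Z"), m2, f$labels),
               c(tp = 0L, fp = 0L, tn = 2L, fn = 3L))
  # everything covered
  m3 <- f$matrix; m3[, ] <- 1L
  expect_equal(confusion_counts(c("A", "B"), m3, f$labels),
               c(tp = 3L, fp = 2L, tn = 0L, fn = 0L))
  # empty active set signals termination, not an error
  expect_equal(confusion_counts(c("A", "B"), f$matrix, f$labels,
                                active = character(0)),
               c(tp = 0L, fp = 0L, tn = 0L, fn = 0L))
  # counts always partition the active set
  expect_equal(sum(cc), 5L)
})

test_that("combination weight is the inverse scaled accuracy", {
  expect_equal(combination_weight(tp = 10, tn = 10, n_tumor = 10,
                                  n_normal = 10, alpha = 0.1), 20 / 11)
  # a perfect combination at alpha = 1 has weight exactly 1
  expect_equal(combination_weight(tp = 7, tn = 5, n_tumor = 7,
                                  n_normal = 5, alpha = 1), 1)
  expect_identical(combination_weight(tp = 0, tn = 0, n_tumor = 3,
                                      n_normal = 0, alpha = 0.5), Inf)
  expect_error(combination_weight(tp = -1, tn = 0, n_tumor = 3,
                                  n_normal = 3))
})

test_that("every finite weight respects the alpha <= 1 lower bound", {
  set.seed(11)
  for (i in 1:50) {
    n_t <- sample(1:20, 1); n_n <- sample(1:20, 1)
    tp <- sample(0:n_t, 1); tn <- sample(0:n_n, 1)
    alpha <- runif(1)
    w <- combination_weight(tp, tn, n_t, n_n, alpha)
    if (is.finite(w)) {
      expect_gte(w, (n_t + n_n) / (alpha * n_t + n_n))
      expect_gte(w, 1)
    }
  }
})

test_that("search space arithmetic matches binomial sums", {
  expect_equal(search_space_size(4, 2), 6)
  expect_equal(search_space_size(10, 3), choose(10, 2) + choose(10, 3))
  expect_equal(greedy_complexity(100, N = 7, h_max = 2),
               7 * choose(100, 2))
})

test_that("candidate enumeration is lexicographic and prunes TP=0 tuples", {
  m <- toy_matrix(list(t1 = c("A", "B"), t2 = c("C", "D"),
                       n1 = c("A", "Z")),
                  genes = c("A", "B", "C", "D", "Z"))
  labels <- toy_labels(c("t1", "t2"), "n1")
  cand <- enumerate_candidates(m, labels, h = 2)
  # Z is mutated in no tumor: no tuple containing Z
  expect_false(any(cand == "Z"))
  # only tuples actually covering >=1 tumor survive
  keys <- apply(cand, 2, paste, collapse = "+")
  expect_equal(keys, c("A+B", "C+D"))
  # without TP pruning all C(4,2)=6 tuples over mutated genes would appear
  m2 <- toy_matrix(list(t1 = c("A", "B", "C", "D")))
  cand2 <- enumerate_candidates(m2, toy_labels("t1", character(0)), h = 2)
  expect_equal(ncol(cand2), 6L)
  expect_equal(apply(cand2, 2, paste, collapse = "+"),
               c("A+B", "A+C", "A+D", "B+C", "B+D", "C+D"))
  # h larger than the mutated-gene pool yields an empty stream
  expect_equal(ncol(enumerate_candidates(m2, toy_labels("t1", character(0)),
                                         h = 5)), 0L)
})

test_that("a single perfect combination is found in one iteration", {
  m <- toy_matrix(list(t1 = c("g1", "g2"), t2 = c("g1", "g2"),
                       n1 = character(0), n2 = "g1"),
                  genes = c("g1", "g2"))
  fit <- hit_cover(m, toy_labels(c("t1", "t2"), c("n1", "n2")))
  expect_equal(length(fit$combinations), 1L)
  expect_equal(fit$combinations[[1]], c("g1", "g2"))
  expect_equal(fit$table$tp, 2L)
  expect_equal(fit$table$fp, 0L)
  expect_equal(fit$table$weight,
               combination_weight(2, 2, 2, 2, alpha = 0.1))
})

test_that("zero tumor samples give an empty solution and empty trace", {
  m <- toy_matrix(list(n1 = "A", n2 = "B"))
  fit <- hit_cover(m, toy_labels(character(0), c("n1", "n2")))
  expect_equal(length(fit$combinations), 0L)
  expect_equal(nrow(fit$table), 0L)
  expect_equal(fit$total_weight, 0)
  expect_equal(as.character(predict(fit, m)), c("normal", "normal"))
})

test_that("tumors with fewer than h mutated genes end as a partial cover", {
  m <- toy_matrix(list(t1 = c("A", "B"), t2 = "A", n1 = character(0)),
                  genes = c("A", "B"))
  expect_warning(
    fit <- hit_cover(m, toy_labels(c("t1", "t2"), "n1")),
    "cannot be covered")
  expect_equal(fit$uncoverable, "t2")
  expect_equal(length(fit$combinations), 1L)
  expect_lt(summary(fit)$training_tpr, 1)
})

test_that("each greedy iteration matches the exhaustive per-step oracle", {
  # deterministic 6-tumor / 3-normal / 6-gene fixture needing >1 iteration
  m <- toy_matrix(list(
    t1 = c("A", "B"), t2 = c("A", "B", "E"), t3 = c("A", "B"),
    t4 = c("C", "D"), t5 = c("C", "D", "F"), t6 = c("E", "F"),
    n1 = c("A", "C"), n2 = c("B", "F"), n3 = c("E", "F")),
    genes = c("A", "B", "C", "D", "E", "F"))
  labels <- toy_labels(paste0("t", 1:6), paste0("n", 1:3))
  fit <- hit_cover(m, labels)
  expect_gte(length(fit$combinations), 2L)
  steps <- replay_active_sets(fit, m, labels)
  for (i in seq_along(steps)) {
    act <- c(steps[[i]]$tumor, steps[[i]]$normal)
    best <- exhaustive_best_step(m, labels, active = act)
    expect_equal(fit$combinations[[i]], best$genes)
    expect_equal(fit$table$weight[i], best$weight)
  }
  # every tumor is covered at the end
  expect_equal(as.character(predict(fit, m[paste0("t", 1:6), ])),
               rep("tumor", 6))
})

test_that("exhaustive_best_step enforces its instance cap and boundaries", {
  f <- make_five_sample_fixture()
  expect_error(exhaustive_best_step(f$matrix, f$labels, max_candidates = 0),
               "cap")
  # single usable candidate: returns it
  best <- exhaustive_best_step(f$matrix, f$labels)
  expect_equal(best$genes, c("A", "B"))
  # all candidates useless at alpha = 0 with no uncovered normal
  m <- toy_matrix(list(t1 = c("A", "B"), n1 = c("A", "B")),
                  genes = c("A", "B"))
  expect_error(exhaustive_best_step(m, toy_labels("t1", "n1"), alpha = 0),
               "no usable candidate")
})

test_that("permuting sample and gene order leaves the solution unchanged", {
  set.seed(99)
  inst <- random_instance(8, 10, 6, p = 0.4)
  fit1 <- suppressWarnings(hit_cover(inst$matrix, inst$labels))
  perm <- inst$matrix[sample(nrow(inst$matrix)),
                      sample(ncol(inst$matrix))]
  lab_perm <- inst$labels[sample(nrow(inst$labels)), , drop = FALSE]
  fit2 <- suppressWarnings(hit_cover(perm, lab_perm))
  key <- function(f) sort(vapply(f$combinations, paste, "", collapse = "+"))
  expect_equal(key(fit1), key(fit2))
  expect_equal(sort(fit1$table$weight), sort(fit2$table$weight))
})

test_that("iteration count never exceeds the tumor count (termination)", {
  set.seed(7)
  for (i in 1:5) {
    inst <- random_instance(sample(5:9, 1), sample(3:8, 1),
                            sample(2:5, 1), p = 0.5)
    fit <- suppressWarnings(hit_cover(inst$matrix, inst$labels))
    n_t <- sum(inst$labels$status == "tumor")
    expect_lte(length(fit$combinations), n_t)
    # active tumor count strictly decreases along the trace
    if (nrow(fit$table) > 1) {
      expect_true(all(diff(fit$table$n_active_tumor) < 0))
    }
  }
})

test_that("keeping covered normals active is supported and changes weights only later", {
  set.seed(3)
  inst <- random_instance(8, 8, 6, p = 0.4)
  fit <- suppressWarnings(
    hit_cover(inst$matrix, inst$labels, exclude_covered_normals = FALSE))
  # normals stay active: the active normal total is constant in the trace
  if (nrow(fit$table) > 0) {
    expect_true(all(fit$table$n_active_normal ==
                      fit$table$n_active_normal[1]))
  }
  # coverage guarantee still holds
  tum <- inst$labels$sample_id[inst$labels$status == "tumor"]
  coverable <- tum[rowSums(inst$matrix[tum, , drop = FALSE]) >= 2]
  pred <- predict(fit, inst$matrix[coverable, , drop = FALSE])
  expect_true(all(pred == "tumor"))
})
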