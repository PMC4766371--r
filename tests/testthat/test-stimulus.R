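g <- default_grammar()

test_that("learning stream: length, grammaticality, determinism", {
  s <- generate_learning_stream(g, 180, seed = 3)
  expect_length(s, 180)
  expect_equal(count_violations(g, s), 0)
  expect_identical(s, generate_learning_stream(g, 180, seed = 3))
  expect_false(identical(s, generate_learning_stream(g, 180, seed = 4)))
  expect_error(generate_learning_stream(g, 1), ">= 2")
})

test_that("classify_transitions matches the attested labelings", {
  lab <- classify_transitions(g, c("V1", "A2", "A3", "V3", "A1", "V1"))
  expect_equal(sum(lab$relation == "cross"), 4)
  expect_equal(sum(lab$relation == "within"), 1)
  expect_true(all(lab$status == "grammatical"))

  lab2 <- classify_transitions(g, c("V1", "A2", "A1"))
  expect_equal(lab2$relation, c("cross", "within"))
  expect_equal(lab2$status, c("grammatical", "violation"))

  expect_equal(nrow(classify_transitions(g, c("V1", "V2"))), 1)
  expect_error(classify_transitions(g, c("V1")), ">= 2")
  expect_error(classify_transitions(g, c("V1", "Z9")), "unknown")
})

test_that("count_violations agrees with a brute-force scan on random strings", {
  set.seed(5)
  labs <- g$elements$label
  for (i in 1:1000) {
    seq <- sample(labs, sample(2:8, 1), replace = TRUE)
    expect_equal(count_violations(g, seq), oracle_count_violations(g, seq))
  }
})

test_that("grammatical items are novel, distinct and violation-free", {
  stream <- generate_learning_stream(g, 180, seed = 21)
  items <- generate_grammatical_items(g, 20, seed = 22, exclusion = stream)
  expect_length(items, 20)
  keys <- vapply(items, function(it) paste(it$elements, collapse = "-"), "")
  expect_false(any(duplicated(keys)))
  for (it in items) {
    expect_equal(it$violation_count, 0)
    expect_false(oracle_window_match(it$elements, stream))
  }
  # infeasible request: more distinct length-2 items than walks exist
  expect_error(generate_grammatical_items(g, 20, length = 2, seed = 1),
               "could only generate")
})

test_that("violation injection reproduces the worked replacement", {
  # within-domain step A2 -> A3 must become A2 -> A1: the only same-domain
  # element that is neither the successor nor a repeat of the predecessor
  expect_identical(aglsim:::replace_element(g, "A2", "A3", "within"), "A1")
  expect_identical(aglsim:::replace_element(g, "V1", "V2", "within"), "V3")
  # cross-domain replacement picks one of the two wrong other-domain elements
  set.seed(1)
  picks <- replicate(200, aglsim:::replace_element(g, "V1", "A2", "cross"))
  expect_setequal(unique(picks), c("A1", "A3"))
})

test_that("violation items are pure: all mode transitions violated, rest legal", {
  for (mode in c("within", "cross")) {
    items <- make_violation_items(g, 50, mode = mode, seed = 31)
    expect_length(items, 50)
    for (it in items) {
      lab <- oracle_labels(g, it$elements)
      expect_true(all(lab[lab[, "relation"] == mode, "status"] == "violation"))
      expect_true(all(lab[lab[, "relation"] != mode, "status"] == "grammatical"))
      expect_gte(it$violation_count, 1)
      expect_equal(it$violation_count, oracle_count_violations(g, it$elements))
    }
  }
  expect_error(make_violation_items(g, 5, mode = "sideways"))
})

test_that("mean violation load matches the truncated-binomial expectation", {
  items <- make_violation_items(g, 10000, mode = "cross", seed = 41)
  counts <- vapply(items, function(it) it$violation_count, 0)
  expect_lt(abs(mean(counts) - oracle_truncated_mean), 0.05)
})

test_that("audit_item_sets reports totals and the textbook t", {
  w <- c(3, 3, 3, 3, 3, 3, 3, 2, 2, 3)
  x <- c(3, 2, 3, 2, 3, 2, 3, 2, 3, 2)
  bal <- audit_item_sets(w, x)
  expect_equal(bal$within_total, 28)
  expect_equal(bal$cross_total, 25)
  expect_equal(bal$within_mean_per_seq, 2.8)
  expect_equal(bal$t_statistic, oracle_two_sample_t(w, x), tolerance = 1e-12)

  same <- audit_item_sets(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(audit_item_sets(numeric(0), x), "non-empty")

  # conservation on generated sets
  ts <- build_test_set(g, seed = 17)
  wi <- aglsim:::subset_items(ts, "within_violation")
  cr <- aglsim:::subset_items(ts, "cross_violation")
  bal2 <- audit_item_sets(wi, cr)
  expect_equal(bal2$within_total,
               sum(vapply(wi, function(it) oracle_count_violations(g, it$elements), 0)))
  expect_equal(bal2$cross_total,
               sum(vapply(cr, function(it) oracle_count_violations(g, it$elements), 0)))
})

test_that("token mappings are domain-wise bijections, uniform over seeds", {
  inv <- token_inventory("exp1")
  m <- assign_tokens(inv, g, seed = 8)
  expect_identical(m, assign_tokens(inv, g, seed = 8))
  for (d in names(inv)) {
    els <- g$elements$label[g$elements$domain == d]
    expect_setequal(unname(m[els]), inv[[d]])
  }
  expect_error(assign_tokens(list(A = inv$A, V = inv$V[1:2]), g),
               "3 distinct tokens")
  # uniformity of the 6 per-domain permutations across many seeds
  perms <- vapply(1:6000, function(s) {
    paste(assign_tokens(inv, g, seed = s)[c("A1", "A2", "A3")], collapse = "|")
  }, "")
  expect_equal(length(unique(perms)), 6)
  expect_true(all(abs(table(perms) / 6000 - 1 / 6) < 0.02))
})

test_that("schedules carry the 6-minute learning phase and seeded test order", {
  stream <- generate_learning_stream(g, 180, seed = 51)
  ts <- build_test_set(g, seed = 52, exclusion = stream)
  mapping <- assign_tokens(token_inventory("exp1"), g, seed = 53)
  sch <- build_schedule(stream, ts, mapping, g, seed = 54)
  learn <- sch[sch$phase == "learning", ]
  expect_equal(nrow(learn), 180)
  expect_equal(sum(learn$duration_ms + learn$isi_ms), 6 * 60 * 1000)
  expect_equal(learn$onset_ms, 2000 * (seq_len(180) - 1))
  test_rows <- sch[sch$phase == "test", ]
  expect_equal(nrow(test_rows), 40 * 6)
  sch2 <- build_schedule(stream, ts, mapping, g, seed = 99)
  o1 <- unique(test_rows$item_id)
  o2 <- unique(sch2$item_id[sch2$phase == "test"])
  expect_setequal(o1, o2)
  expect_false(identical(o1, o2))
  expect_error(build_schedule(stream, ts, mapping[-1], g, seed = 1),
               "no token mapped")
})

test_that("test-set JSON round-trips", {
  ts <- build_test_set(g, seed = 61)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_test_set_json(ts, path)
  ts2 <- read_test_set_json(path, g)
  expect_equal(ts2$seed, ts$seed)
  expect_equal(unname(ts2$counts), unname(ts$counts))
  for (i in seq_along(ts$items)) {
    expect_identical(ts2$items[[i]]$elements, ts$items[[i]]$elements)
    expect_identical(ts2$items[[i]]$condition, ts$items[[i]]$condition)
    expect_equal(ts2$items[[i]]$violation_count, ts$items[[i]]$violation_count)
  }
})
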