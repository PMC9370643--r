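# Venn partitioning, same-direction intersections, percentage arithmetic.

ds <- function(label, ids, dir = "UP_A") directional_set(label, ids, rep_len(dir, length(ids)))

test_that("small Venn partitions assign every transcript to its signature", {
  v <- venn_partition(list(ds("A", c("1", "2")), ds("B", c("2", "3"))))
  expect_equal(v[["A"]], "1")
  expect_equal(v[["B"]], "3")
  expect_equal(v[["A&B"]], "2")

  # identical sets: everything in the intersection region
  v2 <- venn_partition(list(ds("A", c("x", "y")), ds("B", c("x", "y"))))
  expect_equal(sort(v2[["A&B"]]), c("x", "y"))
  expect_length(v2[["A"]], 0)

  expect_error(venn_partition(lapply(1:7, function(i) ds(letters[i], "a"))),
               class = "canedet_size_error")
  expect_error(venn_partition(list(ds("A", "a"), ds("A", "b"))),
               class = "canedet_spec_error")
})

test_that("random set families match the membership-signature oracle", {
  set.seed(99)
  for (rep in 1:10) {
    k <- sample(2:6, 1)
    labels <- LETTERS[seq_len(k)]
    members <- lapply(labels, function(l) {
      as.character(sample(1:120, 50))
    })
    names(members) <- labels
    sets <- lapply(labels, function(l) ds(l, members[[l]]))
    v <- venn_partition(sets)
    oracle <- venn_signature_oracle(members)

    # disjointness and coverage
    all_members <- unlist(unname(v))
    expect_false(any(duplicated(all_members)))
    expect_setequal(all_members, unique(unlist(members)))
    # region contents match the element-wise oracle
    for (nm in names(v)) {
      want <- if (is.null(oracle[[nm]])) character(0) else oracle[[nm]]
      expect_setequal(v[[nm]], want)
    }
    # per-label count conservation
    cnt <- attr(v, "counts")
    for (l in labels) {
      in_l <- grepl(paste0("(^|&)", l, "(&|$)"), names(cnt))
      expect_equal(sum(cnt[in_l]), length(members[[l]]), info = l)
    }
  }
})

test_that("directional mode separates opposite calls of the same transcript", {
  a <- directional_set("A", c("t1", "t2"), c("UP_A", "UP_B"))
  b <- directional_set("B", c("t1", "t2"), c("UP_B", "UP_B"))
  v <- venn_partition(list(a, b), ignore_direction = FALSE)
  expect_setequal(v[["A&B"]], "t2|UP_B")
  expect_setequal(v[["A"]], c("t1|UP_A", "t2|UP_B")[1])
  # by transcript id the two sets coincide
  v2 <- venn_partition(list(a, b), ignore_direction = TRUE)
  expect_setequal(v2[["A&B"]], c("t1", "t2"))
})

test_that("common_pattern keeps only same-direction shared transcripts", {
  col <- directional_set("stalk", c("t1", "t2", "t3"),
                         c("UP_A", "UP_A", "UP_B"))
  free <- directional_set("hydro", c("t1", "t2", "t4"),
                          c("UP_A", "UP_B", "UP_A"))
  cp <- common_pattern(col, free)
  expect_equal(cp$transcript_id, "t1")
  expect_equal(cp$direction, "UP_A")

  # |common| <= min sizes; self-intersection is the identity
  expect_lte(nrow(cp), min(nrow(col), nrow(free)))
  self <- common_pattern(col, col)
  expect_equal(self$transcript_id, col$transcript_id)
  expect_equal(self$direction, col$direction)
})

test_that("mapping percentages use half-up rounding", {
  expect_equal(mapping_percentage(1, 2), 50)
  expect_equal(mapping_percentage(1, 8, 2), 12.5)
  expect_equal(mapping_percentage(125, 1000, 1), 12.5)
  expect_equal(mapping_percentage(1, 3, 2), 33.33)
  expect_equal(mapping_percentage(2, 3, 2), 66.67)
  # half-up at the boundary: 0.125 -> 12.5 -> 13 at 0 decimals
  expect_equal(mapping_percentage(125, 1000, 0), 13)
  expect_error(mapping_percentage(1, 0), class = "canedet_domain_error")
})

test_that("directional sets enforce one direction per transcript", {
  expect_error(directional_set("A", c("t", "t"), c("UP_A", "UP_B")),
               class = "canedet_duplicate_key_error")
  expect_error(directional_set("A", "t", "SIDEWAYS"),
               class = "canedet_vocabulary_error")
})
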