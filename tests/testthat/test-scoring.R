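test_that("prevalence bands map to 0/1/2 with a closed middle band", {
  expect_identical(proportion_to_score(0.50), 1L)
  expect_identical(proportion_to_score(0.10), 0L)
  expect_identical(proportion_to_score(c(0, 0.2499, 0.25, 0.75, 0.7500001, 1)),
                   c(0L, 0L, 1L, 1L, 2L, 2L))
  expect_error(proportion_to_score(1.2), "\\[0, 1\\]")
  expect_error(proportion_to_score(-0.1), "\\[0, 1\\]")
})

test_that("descriptor points multiply answer by weight, NA excludes", {
  expect_equal(descriptor_points(2, 5), 10)
  expect_equal(descriptor_points(0, 3), 0)
  expect_true(is.na(descriptor_points(NA, 4)))
  expect_error(descriptor_points(2, 5, modifier = "penalty"),
               "penalty")
})

test_that("the single-housing penalty is linear then saturates at the cap", {
  expect_equal(penalty_points(0), 0)
  expect_equal(penalty_points(50), 20)
  # brute force over n = 0..25: min(n, 20) at the default rate and cap
  expect_equal(penalty_points(0:25), pmin(0:25, 20))
  expect_equal(penalty_points(5, rate = 3), 15)
  expect_equal(penalty_points(10, rate = 3, cap = 12), 12)
  expect_error(penalty_points(-1), "non-negative")
})

test_that("score_scope reproduces the worked arithmetic", {
  instr <- mini_instrument(weights = c(5L, 3L))
  b <- score_scope(tibble::tibble(descriptor_id = c("d1", "d2"),
                                  value = c(2, 1)), instr)
  expect_equal(b$earned, 13)
  expect_equal(b$possible, 16)
  expect_equal(b$percentage, 81.25)

  # NA excluded from numerator and denominator
  b_na <- score_scope(tibble::tibble(descriptor_id = c("d1", "d2"),
                                     value = c(2, NA)), instr)
  expect_equal(b_na$earned, 10)
  expect_equal(b_na$possible, 10)
  expect_equal(b_na$percentage, 100)

  # all-NA scope: undefined, not an error
  b_all_na <- score_scope(tibble::tibble(descriptor_id = c("d1", "d2"),
                                         value = c(NA, NA)), instr)
  expect_equal(b_all_na$possible, 0)
  expect_true(is.na(b_all_na$percentage))
})

test_that("bonus points can push a score above 100%", {
  # standard possible exactly 100 (ten descriptors of weight 5), plus one
  # answered bonus of weight 2
  instr <- pwat_instrument(tibble::tibble(
    id = c(paste0("s", 1:10), "b1"),
    label = c(paste("std", 1:10), "bonus"),
    category = "environmental", subcategory = "outdoor and exercise",
    form = "room", weight = c(rep(5L, 10), 2L),
    modifier = c(rep("standard", 10), "bonus")))
  answers <- tibble::tibble(descriptor_id = c(paste0("s", 1:10), "b1"),
                            value = 2)
  b <- score_scope(answers, instr)
  expect_equal(b$possible, 100)
  expect_equal(b$bonus, 4)
  expect_equal(b$percentage, 104)

  # an NA bonus simply contributes nothing
  answers$value[11] <- NA
  expect_equal(score_scope(answers, instr)$percentage, 100)
})

test_that("score_scope matches the brute-force oracle on random cases", {
  set.seed(101)
  for (i in 1:300) {
    instr <- random_mini_instrument()
    answers <- random_answers(instr, fractional = runif(1) < 0.3)
    got <- score_scope(answers, instr)
    want <- oracle_breakdown(answers, instr)
    expect_equal(got$earned, want$earned)
    expect_equal(got$possible, want$possible)
    expect_equal(got$bonus, want$bonus)
    expect_equal(got$percentage, want$percentage)
    # and on one random category scope
    cc <- sample(unique(instr$category), 1)
    ids <- instr$id[instr$category == cc]
    got_c <- score_scope(answers, instr, "category", cc)
    want_c <- oracle_breakdown(answers, instr, ids_in_scope = ids)
    expect_equal(got_c$percentage, want_c$percentage)
  }
})

test_that("raising any single answer never lowers an enclosing percentage", {
  set.seed(202)
  for (i in 1:50) {
    instr <- random_mini_instrument()
    answers <- random_answers(instr, na_rate = 0.1)
    raisable <- which(!is.na(answers$value) & answers$value < 2)
    if (length(raisable) == 0) next
    j <- sample(raisable, 1)
    bumped <- answers
    bumped$value[j] <- bumped$value[j] + 1
    d <- tibble::as_tibble(instr)[match(answers$descriptor_id[j],
                                        tibble::as_tibble(instr)$id), ]
    for (scope in list(c("total", NA), c("category", d$category),
                       c("subcategory", d$subcategory))) {
      nm <- if (is.na(scope[2])) NULL else scope[2]
      before <- score_scope(answers, instr, scope[1], nm)$percentage
      after <- score_scope(bumped, instr, scope[1], nm)$percentage
      # a scope whose standard descriptors are all excluded stays undefined
      if (is.na(before)) expect_true(is.na(after)) else
        expect_gte(after, before)
    }
  }
})

test_that("answering NA is equivalent to deleting the descriptor", {
  set.seed(303)
  for (i in 1:50) {
    instr <- random_mini_instrument()
    answers <- random_answers(instr, na_rate = 0)
    j <- sample(nrow(answers), 1)
    with_na <- answers
    with_na$value[j] <- NA
    pruned_instr <- pwat_instrument(
      tibble::as_tibble(instr)[-j, ],
      penalty_config = attr(instr, "penalty_config"))
    pruned_answers <- answers[-j, ]
    a <- score_scope(with_na, instr)
    b <- score_scope(pruned_answers, pruned_instr)
    expect_equal(a$earned, b$earned)
    expect_equal(a$possible, b$possible)
    expect_equal(a$bonus, b$bonus)
    expect_equal(a$percentage, b$percentage)
  }
})

test_that("a maximal answer set scores exactly 100 in every scope", {
  set.seed(404)
  for (i in 1:20) {
    instr <- random_mini_instrument()
    x <- tibble::as_tibble(instr)
    answers <- tibble::tibble(descriptor_id = x$id,
                              value = ifelse(x$modifier == "standard", 2,
                                             NA_real_))
    expect_equal(score_scope(answers, instr)$percentage, 100)
    for (cc in unique(x$category[x$modifier == "standard"])) {
      expect_equal(score_scope(answers, instr, "category", cc)$percentage,
                   100)
    }
  }
})

test_that("the penalty is bounded by its cap in the final percentage", {
  instr <- mini_instrument(weights = c(5L, 5L))
  answers <- tibble::tibble(descriptor_id = c("d1", "d2"), value = c(2, 2))
  pen <- penalty_points(10^6)
  b <- score_scope(answers, instr, penalty = pen)
  expect_equal(b$penalty, 20)
  expect_equal(b$percentage, 100 * (20 - 20) / 20)
  expect_gte(b$percentage, 100 * (b$earned + b$bonus - 20) / b$possible)
})

test_that("answers for unknown descriptors are ignored with a warning", {
  instr <- mini_instrument()
  answers <- tibble::tibble(descriptor_id = c("d1", "d2", "ghost"),
                            value = c(2, 1, 2))
  expect_warning(b <- score_scope(answers, instr), "ghost")
  expect_equal(b$earned, 13)
})
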