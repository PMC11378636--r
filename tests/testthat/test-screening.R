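test_that("activity calling is strict at the threshold", {
  expect_identical(call_active(c(-3, -2, -1.999, 0)),
                   c(TRUE, FALSE, FALSE, FALSE))
  expect_true(all(call_active(c(-5, 0, 5), threshold = Inf)))
  expect_false(any(call_active(rep(0, 4))))
  expect_error(call_active(c(1, NA)), "finite")
})

test_that("lowering the threshold never increases the active count", {
  set.seed(51)
  scores <- matrix(rnorm(200, mean = -1.5), 20, 10)
  counts <- sapply(c(0, -1, -2, -3, -4), function(th)
    sum(call_active(scores, th)))
  expect_true(all(diff(counts) <= 0))
})

test_that("fisher_exact matches enumeration on fixed tables", {
  even <- fisher_exact(matrix(c(5, 5, 5, 5), 2))
  expect_equal(even$p_value, 1)
  expect_equal(even$odds_ratio, 1)

  extreme <- fisher_exact(matrix(c(10, 0, 0, 10), 2))
  expect_equal(extreme$p_value, oracle_fisher_p(matrix(c(10, 0, 0, 10), 2)),
               tolerance = 1e-12)
  expect_equal(extreme$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(extreme$odds_ratio, Inf)

  mid <- matrix(c(3, 1, 1, 3), 2)
  expect_equal(fisher_exact(mid)$p_value, oracle_fisher_p(mid),
               tolerance = 1e-12)
  expect_equal(fisher_exact(mid)$odds_ratio, 9)

  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
  expect_error(fisher_exact(matrix(0, 2, 2)), "positive")
})

test_that("fisher_exact equals the hypergeometric oracle on random tables <= 40", {
  set.seed(52)
  for (i in 1:200) {
    repeat {
      tab <- matrix(rpois(4, sample(1:6, 1)), 2)
      if (sum(tab) > 0 && sum(tab) <= 40) break
    }
    expect_equal(fisher_exact(tab)$p_value, oracle_fisher_p(tab),
                 tolerance = 1e-9)
  }
})

make_screen <- function() {
  # 10 in-group lines, 40 out-group; drugA perfectly selective, drugB
  # active everywhere, drugC random
  set.seed(53)
  lines <- paste0("CL", 1:50)
  grp <- rep(c("ewing", "other"), c(10, 40))
  tibble::tibble(
    cell_line = rep(lines, times = 3),
    group = rep(grp, times = 3),
    drug = rep(c("drugA", "drugB", "drugC"), each = 50),
    active = c(grp == "ewing", rep(TRUE, 50), sample(c(TRUE, FALSE), 50,
                                                     replace = TRUE)))
}

test_that("a perfectly in-group-selective drug attains the smallest p", {
  sel <- drug_selectivity(make_screen(), "ewing")
  expect_s3_class(sel, "selectivity_result")
  pA <- sel$p_value[sel$drug == "drugA"]
  expect_equal(pA, min(sel$p_value))
  expect_lt(pA, 1e-8)
  expect_true(sel$selective[sel$drug == "drugA"])
})

test_that("a drug active everywhere is uninformative (p = 1)", {
  sel <- drug_selectivity(make_screen(), "ewing")
  expect_equal(sel$p_value[sel$drug == "drugB"], 1)
  expect_false(sel$selective[sel$drug == "drugB"])
})

test_that("selectivity is invariant to relabeling out-group lines", {
  screen <- make_screen()
  relabeled <- dplyr::mutate(screen, group = ifelse(group == "other",
                                                    sample(c("osteo", "rhabdo"),
                                                           dplyr::n(), TRUE),
                                                    group))
  a <- drug_selectivity(screen, "ewing")
  b <- drug_selectivity(relabeled, "ewing")
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$odds_ratio, b$odds_ratio)
})

test_that("selectivity guards its inputs", {
  screen <- make_screen()
  expect_error(drug_selectivity(screen, "nope"), "unknown group")
  single <- dplyr::mutate(screen, group = "ewing")
  expect_error(drug_selectivity(single, "ewing"), "two cancer groups")
})

test_that("score columns are thresholded on the fly", {
  screen <- tibble::tibble(
    cell_line = rep(paste0("CL", 1:6), 2),
    group = rep(c("a", "a", "a", "b", "b", "b"), 2),
    drug = rep(c("d1", "d2"), each = 6),
    score = c(-3, -3, -3, 0, 0, 0, rep(-1, 6)))
  sel <- drug_selectivity(screen, "a")
  expect_equal(sel$active_in[sel$drug == "d1"], 3)
  expect_equal(sel$active_out[sel$drug == "d1"], 0)
  expect_equal(sel$active_in[sel$drug == "d2"], 0)
})

test_that("drugs are classified by their active fraction", {
  screen <- make_screen()
  cls <- classify_drugs(screen)
  expect_equal(cls$class[cls$drug == "drugB"], "non_selective_effective")
  expect_equal(cls$class[cls$drug == "drugA"], "intermediate")  # 20% active
  expect_equal(cls$frac_active[cls$drug == "drugB"], 1)

  never <- tibble::tibble(cell_line = paste0("CL", 1:20),
                          group = rep(c("a", "b"), 10),
                          drug = "d0", active = FALSE)
  expect_equal(classify_drugs(never)$class, "ineffective")
})
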