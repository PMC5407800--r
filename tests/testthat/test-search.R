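# Candidate grids and the exhaustive cutpoint search.

test_that("candidate grid excludes cuts violating the group-size floor", {
  g <- candidate_cutpoints(1:10, min_group_frac = 0.2)
  expect_equal(g$values, 3:9)
  # frac 0: all distinct values except the minimum
  g0 <- candidate_cutpoints(1:10, min_group_frac = 0)
  expect_equal(g0$values, 2:10)
  expect_error(candidate_cutpoints(rep(2, 5)), "fewer than 2 distinct")
  # midpoint option
  gm <- candidate_cutpoints(c(1, 2, 4), min_group_frac = 0, midpoints = TRUE)
  expect_equal(gm$values, c(1.5, 3))
})

test_that("K = 2 on three distinct values is forced to the interior boundaries", {
  z <- rep(c(1, 2, 3), each = 10)
  set.seed(8)
  y <- rbinom(30, 1, rep(c(0.1, 0.5, 0.9), each = 10))
  co <- as_cohort(data.frame(z = z, y = y), outcome_spec("binary", "z", y = "y"))
  grid <- candidate_cutpoints(z, min_group_frac = 0)
  res <- search_cutpoints(co, 2, "chi2", grid)
  expect_equal(as.numeric(res$best), c(2, 3))
  expect_equal(sum(res$surface$valid), 1L)
})

test_that("search equals the naive double-loop oracle on small cohorts", {
  co <- make_surv_cohort(seed = 5, n = 100)
  grid <- candidate_cutpoints(co$z)
  for (K in 1:2) {
    mine <- search_cutpoints(co, K, "logrank", grid)
    orac <- naive_search(co, K, "logrank", grid)
    expect_equal(as.numeric(mine$best), as.numeric(orac$best))
    expect_equal(mine$best_value, orac$value, tolerance = 1e-8)
  }
  cb <- make_bin_cohort(seed = 5, n = 100)
  gridb <- candidate_cutpoints(cb$z)
  mine <- search_cutpoints(cb, 2, "max_auc", gridb)
  orac <- naive_search(cb, 2, "max_auc", gridb)
  expect_equal(as.numeric(mine$best), as.numeric(orac$best))
  expect_equal(mine$best_value, orac$value, tolerance = 1e-10)
})

test_that("chi-square baseline finds a perfect separator with statistic n", {
  z <- c(rep(1, 20), rep(5, 20))
  y <- c(rep(0, 20), rep(1, 20))
  co <- as_cohort(data.frame(z = z, y = y), outcome_spec("binary", "z", y = "y"))
  res <- chi2_baseline_search(co, 1, candidate_cutpoints(z))
  expect_equal(as.numeric(res$best), 5)
  expect_equal(res$best_value, 40)  # chi2 = n for a perfect balanced 2x2
  expect_error(chi2_baseline_search(make_surv_cohort(1), 1), "binary outcome")
})

test_that("rank-based criteria are equivariant under increasing transforms", {
  co <- make_bin_cohort(seed = 13, n = 120)
  tr <- function(v) log(v) * 2 + 0.1 * v
  dat <- as.data.frame(co)
  dat$z <- tr(dat$z)
  co_tr <- as_cohort(dat, attr(co, "spec"))
  for (crit in c("logistic_lrt", "max_auc", "chi2")) {
    a <- search_cutpoints(co, 2, crit)
    b <- search_cutpoints(co_tr, 2, crit)
    expect_equal(as.numeric(b$best), tr(as.numeric(a$best)), tolerance = 1e-10)
    expect_equal(a$best_value, b$best_value, tolerance = 1e-10)
  }
})

test_that("tuple bookkeeping is combinatorially exact", {
  co <- make_bin_cohort(seed = 17, n = 80)
  grid <- candidate_cutpoints(co$z)
  m <- length(grid$values)
  res <- search_cutpoints(co, 2, "chi2", grid)
  expect_equal(res$n_evaluated + res$n_invalid, choose(m, 2))
  expect_equal(nrow(res$surface), choose(m, 2))
  # all reported groups at the optimum respect the size floor
  minsz <- ceiling(grid$min_group_frac * nrow(co))
  best_row <- res$surface[res$surface$valid &
                            res$surface$value == res$best_value, ][1, ]
  expect_true(all(best_row[c("n0", "n1", "n2")] >= minsz))
})

test_that("ties break toward the lexicographically smallest cutpoints", {
  # a symmetric layout with two equally significant single cuts
  z <- c(1, 1, 2, 2, 3, 3, 4, 4)
  y <- c(0, 0, 0, 1, 0, 1, 1, 1)
  co <- as_cohort(data.frame(z = z, y = y), outcome_spec("binary", "z", y = "y"))
  res <- search_cutpoints(co, 1, "chi2", candidate_cutpoints(z, 0.2))
  surf <- res$surface
  top <- surf$value[surf$valid]
  expect_gte(sum(abs(top - res$best_value) < 1e-12), 2L)  # genuine tie exists
  tied <- surf$cut1[surf$valid][abs(top - res$best_value) < 1e-12]
  expect_equal(as.numeric(res$best), min(tied))
})

test_that("mode/criterion mismatches and infeasible grids raise errors", {
  co <- make_surv_cohort(seed = 2)
  expect_error(search_cutpoints(co, 1, "max_auc"), "binary outcome")
  cb <- make_bin_cohort(seed = 2)
  expect_error(search_cutpoints(cb, 1, "logrank"), "survival outcome")
  expect_error(search_cutpoints(co, 3, "logrank"), "K must be 1 or 2")
  # every tuple infeasible: demand more events per group than exist
  grid <- candidate_cutpoints(co$z, min_events_per_group = 10000)
  expect_error(search_cutpoints(co, 1, "logrank", grid), "no feasible split")
})

test_that("search surfaces export to TSV and JSON", {
  co <- make_bin_cohort(seed = 23, n = 80)
  res <- search_cutpoints(co, 1, "logistic_lrt")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_surface(res, tsv)
  surf <- read.delim(tsv)
  expect_equal(nrow(surf), nrow(res$surface))
  js <- withr::local_tempfile(fileext = ".json")
  export_surface(res, js, format = "json")
  parsed <- jsonlite::read_json(js)
  expect_equal(as.numeric(parsed$best[[1]]), as.numeric(res$best))
})
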