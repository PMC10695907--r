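test_that("exact p-values match hand-enumerable cases", {
  cmp <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(cmp$u_statistic, 0)
  expect_equal(cmp$p_two_sided, 0.1)   # 2 of the 20 assignments as extreme
  expect_equal(cmp$method, "exact")

  sym <- mann_whitney(c(1, 2), c(1, 2))
  expect_equal(sym$p_two_sided, 1)

  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
  same <- mann_whitney(rep(2, 4), rep(2, 5))
  expect_equal(same$p_two_sided, 1)
})

test_that("exact branch equals the full-enumeration oracle on small groups", {
  set.seed(401)
  for (rep in 1:50) {
    n_a <- sample(2:8, 1)
    n_b <- sample(2:(10 - n_a), 1)
    a <- sample(1:6, n_a, replace = TRUE)  # integer data: ties likely
    b <- sample(1:6, n_b, replace = TRUE)
    cmp <- mann_whitney(a, b, method = "exact")
    expect_equal(cmp$p_two_sided, oracle_mw_p(a, b))
  }
})

test_that("tie-free exact p agrees with the classical reference test", {
  set.seed(402)
  for (rep in 1:20) {
    a <- rnorm(sample(4:9, 1)); b <- rnorm(sample(4:9, 1))
    cmp <- mann_whitney(a, b, method = "exact")
    wt <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(cmp$u_statistic, unname(wt$statistic))
    expect_equal(cmp$p_two_sided, wt$p.value)
  }
})

test_that("U statistics of swapped groups are complementary; p is invariant", {
  set.seed(403)
  for (rep in 1:20) {
    a <- rnorm(sample(3:10, 1)); b <- rnorm(sample(3:10, 1))
    c1 <- mann_whitney(a, b); c2 <- mann_whitney(b, a)
    expect_equal(c1$u_statistic + c2$u_statistic, c1$n_a * c1$n_b)
    expect_lte(c1$u_statistic, c1$n_a * c1$n_b)
    expect_equal(c1$p_two_sided, c2$p_two_sided)
  }
})

test_that("normal approximation tracks the exact p for moderate samples", {
  set.seed(404)
  for (rep in 1:200) {
    a <- rnorm(sample(8:10, 1)); b <- rnorm(sample(8:10, 1))
    pe <- mann_whitney(a, b, method = "exact")$p_two_sided
    pn <- mann_whitney(a, b, method = "normal_approx")$p_two_sided
    expect_lt(abs(pe - pn), 0.02)
  }
})

test_that("the exact cap routes large problems to the approximation", {
  a <- rnorm(30); b <- rnorm(30)
  cmp <- mann_whitney(a, b)
  expect_equal(cmp$method, "normal_approx")
  expect_error(mann_whitney(a, b, method = "exact"), "exceeds")
  small_cap <- mann_whitney(1:4, 5:8, exact_cap = 10)
  expect_equal(small_cap$method, "normal_approx")
})

test_that("set poolability approves same-distribution sets, rejects shifts", {
  set.seed(405)
  d <- data.frame(group = "B1", set_id = rep(1:3, each = 6),
                  inner = rnorm(18, 0.98, 0.01))
  res <- check_set_poolability(d, "inner")
  expect_equal(nrow(res$pairwise), 3)
  # identical copies: all p = 1
  d2 <- data.frame(group = "B1", set_id = rep(1:2, each = 4),
                   inner = rep(c(1, 2, 3, 4), 2))
  res2 <- check_set_poolability(d2, "inner")
  expect_true(all(res2$pairwise$p_two_sided == 1))
  expect_true(res2$decision$pooling_approved)
  # one set shifted by 10 SD: power ~ 1
  d3 <- d
  d3$inner[d3$set_id == 3] <- d3$inner[d3$set_id == 3] + 0.1
  res3 <- check_set_poolability(d3, "inner")
  expect_false(res3$decision$pooling_approved)
  expect_error(check_set_poolability(d[d$set_id == 1, ], "inner"),
               "fewer than 2 sets")
})

test_that("cutting success summarises per-animal rates per bioptome", {
  one <- data.frame(animal_id = "a", bioptome = "B1", n_manoeuvres = 8,
                    n_biopsies = 6, major_complication = FALSE)
  expect_equal(cutting_success(one)$mean_percent, 75)

  three <- data.frame(animal_id = c("a", "b", "c"), bioptome = "B1",
                      n_manoeuvres = c(6, 8, 8), n_biopsies = c(6, 7, 7),
                      major_complication = FALSE)
  cs <- cutting_success(three)
  expect_equal(cs$mean_percent, mean(c(100, 87.5, 87.5)))
  expect_equal(round(cs$mean_percent, 1), 91.7)
  expect_equal(cs$sd_percent, sd(c(100, 87.5, 87.5)))
  expect_equal(round(cs$sd_percent, 1), 7.2)

  bad <- one; bad$n_biopsies <- 9
  expect_error(cutting_success(bad), "exceed")
  zero <- one; zero$n_manoeuvres <- 0
  expect_error(cutting_success(zero), "at least one")
})

test_that("procedural success applies the biopsy and complication criteria", {
  rec <- data.frame(animal_id = c("a", "b", "c"), bioptome = "B1",
                    n_manoeuvres = 10, n_biopsies = c(6, 7, 8),
                    major_complication = FALSE)
  expect_equal(procedural_success(rec)$percent_success, 100)
  rec$n_biopsies[1] <- 5                 # below threshold
  expect_equal(procedural_success(rec)$percent_success, 100 * 2 / 3)
  rec$n_biopsies[1] <- 7
  rec$major_complication[1] <- TRUE      # complication voids success
  expect_equal(procedural_success(rec)$percent_success, 100 * 2 / 3)
})

test_that("bundled synthetic procedure records reproduce the summary shape", {
  rec <- read_procedure_records(
    system.file("extdata", "procedure_records_synthetic.csv",
                package = "bioptiq"))
  ps <- procedural_success(rec)
  expect_equal(ps$percent_success, c(100, 100))
  cs <- cutting_success(rec)
  expect_equal(cs$bioptome, c("B1", "B2"))
  expect_equal(round(cs$mean_percent[cs$bioptome == "B1"], 1), 91.7)
})
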