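make_act <- function(rows, samples) {
  matrix(unlist(rows), nrow = length(rows), byrow = TRUE,
         dimnames = list(names(rows), samples))
}

two_group_ann <- function(n_case, n_control) {
  data.frame(
    sample_id = c(sprintf("c%d", 1:n_case), sprintf("k%d", 1:n_control)),
    condition = rep(c("case", "control"), c(n_case, n_control)),
    stringsAsFactors = FALSE
  )
}

test_that("the condition t test matches the pooled two-sample t", {
  ann <- two_group_ann(3, 3)
  act <- make_act(list(P1 = c(1, 2, 3, 4, 5, 6)), ann$sample_id)
  tbl <- fit_differential(act, ann, case_level = "case")
  expect_equal(tbl$effect, -3)
  expect_equal(tbl$t, -3.674235, tolerance = 1e-6)
  expect_equal(tbl$p_value, 0.02131164, tolerance = 1e-6)
  expect_equal(tbl$direction, "DOWN")
  # oracle: classical pooled t test
  tt <- t.test(act[1, 1:3], act[1, 4:6], var.equal = TRUE)
  expect_equal(tbl$t, unname(tt$statistic))
  expect_equal(tbl$p_value, tt$p.value)
})

test_that("equal group means give t = 0 and p = 1", {
  ann <- two_group_ann(3, 3)
  act <- make_act(list(P1 = c(1, 2, 3, 3, 2, 1)), ann$sample_id)
  tbl <- fit_differential(act, ann)
  expect_equal(tbl$t, 0)
  expect_equal(tbl$p_value, 1)
})

test_that("no-covariate fits equal pooled t tests on random matrices", {
  set.seed(11)
  ann <- two_group_ann(6, 5)
  act <- matrix(rnorm(8 * 11), 8,
                dimnames = list(paste0("P", 1:8), ann$sample_id))
  tbl <- fit_differential(act, ann, case_level = "case")
  for (p in rownames(act)) {
    tt <- t.test(act[p, 1:6], act[p, 7:11], var.equal = TRUE)
    row <- tbl[tbl$pathway == p, ]
    expect_equal(row$t, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(row$p_value, tt$p.value, tolerance = 1e-12)
  }
})

test_that("covariates are adjusted for and collinearity is caught", {
  set.seed(12)
  ann <- two_group_ann(6, 6)
  ann$batch <- rep(c("b1", "b2"), 6)
  ann$age <- rnorm(12, 50, 8)
  act <- matrix(rnorm(3 * 12), 3,
                dimnames = list(paste0("P", 1:3), ann$sample_id))
  tbl <- fit_differential(act, ann, covariates = c("batch", "age"))
  # oracle: per-pathway lm
  for (p in rownames(act)) {
    fit <- lm(act[p, ] ~ factor(condition, c("control", "case")) +
                factor(batch) + age, data = ann)
    co <- summary(fit)$coefficients[2, ]
    row <- tbl[tbl$pathway == p, ]
    expect_equal(row$effect, unname(co[1]), tolerance = 1e-10)
    expect_equal(row$p_value, unname(co[4]), tolerance = 1e-10)
  }
  ann$dup <- as.integer(ann$condition == "case")
  expect_error(fit_differential(act, ann, covariates = "dup"),
               "rank deficient.*dup")
})

test_that("swapping condition labels flips directions, keeps p", {
  set.seed(13)
  ann <- two_group_ann(5, 5)
  act <- matrix(rnorm(6 * 10), 6,
                dimnames = list(paste0("P", 1:6), ann$sample_id))
  a <- fit_differential(act, ann, case_level = "case")
  b <- fit_differential(act, ann, case_level = "control")
  b <- b[match(a$pathway, b$pathway), ]
  expect_equal(a$effect, -b$effect)
  expect_equal(a$p_value, b$p_value)
  expect_true(all(a$direction != b$direction))
})

test_that("moderated fits agree closely with OLS at large n", {
  set.seed(14)
  ann <- two_group_ann(40, 40)
  act <- matrix(rnorm(20 * 80), 20,
                dimnames = list(paste0("P", 1:20), ann$sample_id))
  a <- fit_differential(act, ann, moderated = FALSE)
  b <- fit_differential(act, ann, moderated = TRUE)
  b <- b[match(a$pathway, b$pathway), ]
  expect_equal(a$effect, b$effect, tolerance = 1e-10)
  # moderation shrinks variances but leaves the ordering intact
  expect_gt(cor(a$t, b$t), 0.99)
  expect_true(all(sign(a$t) == sign(b$t)))
})

test_that("BH adjustment matches arithmetic examples and brute force", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_fdr(c(0.05, 0.01)), c(0.05, 0.02))
  expect_equal(adjust_fdr(0.2), 0.2)
  expect_error(adjust_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  grid <- seq(0.05, 1, by = 0.05)
  # all ordered tuples of grid values up to length 2, systematic slice of
  # length 3, random draws at lengths 4-6
  cases <- c(as.list(grid),
             unlist(lapply(grid, function(a) lapply(grid, c, a)),
                    recursive = FALSE))
  g3 <- expand.grid(grid, grid, grid)
  cases <- c(cases,
             lapply(seq(1, nrow(g3), by = 11), function(i) unlist(g3[i, ])))
  set.seed(15)
  for (i in 1:60) {
    cases[[length(cases) + 1]] <- sample(grid, sample(4:6, 1),
                                         replace = TRUE)
  }
  ok <- vapply(cases, function(p) {
    isTRUE(all.equal(unname(adjust_fdr(p)), unname(bh_brute(p))))
  }, logical(1))
  expect_true(all(ok))
})

test_that("top-pathway selection orders and warns as specified", {
  tbl <- data.frame(pathway = c("B", "A", "C"),
                    effect = c(1, -2, 3), t = c(2, -4, 1),
                    p_value = c(0.02, 0.001, 0.5),
                    adjusted_p = c(0.03, 0.003, 0.5),
                    direction = c("UP", "DOWN", "UP"))
  expect_equal(select_top_pathways(tbl, "top_k", 2), c("A", "B"))
  expect_warning(all3 <- select_top_pathways(tbl, "top_k", 10), "exceeds")
  expect_equal(all3, c("A", "B", "C"))
  expect_warning(none <- select_top_pathways(tbl, "top_k", 0), "k = 0")
  expect_length(none, 0)
  expect_equal(select_top_pathways(tbl, "fdr_threshold", 0.01), "A")
  # p tie broken by |t| descending then name
  tie <- data.frame(pathway = c("Z", "Y", "X"), effect = 1,
                    t = c(2, 5, 2), p_value = 0.01, adjusted_p = 0.01,
                    direction = "UP")
  expect_equal(select_top_pathways(tie, "top_k", 3), c("Y", "X", "Z"))
})

test_that("degenerate designs are rejected", {
  ann <- two_group_ann(2, 2)
  act <- make_act(list(P = c(1, 2, 3, 4)), ann$sample_id)
  expect_error(fit_differential(act, ann), "residual degrees")
  ann3 <- data.frame(sample_id = paste0("s", 1:6),
                     condition = rep(c("a", "b", "c"), 2))
  act3 <- matrix(rnorm(6), 1, dimnames = list("P", ann3$sample_id))
  expect_error(fit_differential(act3, ann3), "exactly 2 levels")
})
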