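genes <- function(n, prefix = "g") sprintf("%s%03d", prefix, seq_len(n))

test_that("overlap p-value equals the hypergeometric tail", {
  bg <- genes(10)
  p <- overlap_pvalue(bg[1:4], bg[1:5], bg)   # overlap 4 of 4 drawn
  expect_equal(p, 1 / 42)
  # minimum attainable overlap gives p = 1
  expect_equal(overlap_pvalue(bg[6:7], bg[1:5], bg[1:7]), 1)
  expect_warning(p1 <- overlap_pvalue("zzz", bg[1:5], bg), "no target")
  expect_equal(p1, 1)
  expect_error(overlap_pvalue(bg[1], bg[1:2], character(0)), "background")
})

test_that("overlap p-values match Fisher's exact test on all small designs", {
  mismatch <- 0
  for (N in 3:12) {
    bg <- genes(N)
    for (K in 1:(N - 1)) {
      for (n in 1:N) {
        for (k in max(0, n + K - N):min(n, K)) {
          # targets: k inside the pathway, n - k outside
          targets <- c(bg[seq_len(k)], bg[K + seq_len(n - k)])
          p <- overlap_pvalue(targets, bg[1:K], bg)
          oracle <- fisher.test(
            matrix(c(k, n - k, K - k, N - K - (n - k)), 2),
            alternative = "greater")$p.value
          if (!isTRUE(all.equal(p, oracle, tolerance = 1e-10))) {
            mismatch <- mismatch + 1
          }
        }
      }
    }
  }
  expect_equal(mismatch, 0)
})

test_that("overlap matrix excludes miRNAs without expressed targets", {
  bg <- genes(20)
  pw <- list(P1 = bg[1:5], P2 = bg[6:12], P3 = bg[c(1, 13:15)])
  db <- list(m1 = bg[1:4], m2 = c("x1", "x2"), m3 = bg)
  expect_message(pm <- overlap_matrix(db, pw, bg), "excluded 1")
  expect_equal(dim(pm), c(2L, 3L))
  expect_true(all(pm > 0 & pm <= 1))
  # m3 targets the whole background: forced overlap = |pathway|
  expect_equal(unname(pm["m3", "P1"]),
               overlap_pvalue(bg, pw$P1, bg))
  # element-wise agreement with the scalar operation
  for (m in rownames(pm)) {
    for (p in colnames(pm)) {
      expect_equal(pm[m, p], overlap_pvalue(db[[m]], pw[[p]], bg))
    }
  }
})

test_that("cluster-targeting score is the mean inverse-normal transform", {
  pr <- c(P1 = 0.5, P2 = 0.025, P3 = 0.5)
  expect_equal(cluster_targeting_score(pr, c("P1", "P3")), 0)
  expect_equal(cluster_targeting_score(c(P1 = 0.025, P2 = 0.025),
                                       c("P1", "P2")),
               qnorm(0.975), tolerance = 1e-6)
  expect_equal(cluster_targeting_score(pr, c("P1", "P2")),
               qnorm(0.975) / 2, tolerance = 1e-6)
  expect_error(cluster_targeting_score(pr, c("P1", "P9")), "P9")
})

test_that("decreasing any member p-value strictly increases the score", {
  set.seed(51)
  pr <- setNames(runif(8), paste0("P", 1:8))
  cl <- c("P2", "P5", "P7")
  s0 <- cluster_targeting_score(pr, cl)
  for (y in cl) {
    pr2 <- pr
    pr2[y] <- pr[y] / 2
    expect_gt(cluster_targeting_score(pr2, cl), s0)
  }
})

test_that("bootstrap null is deterministic and degenerates correctly", {
  pr <- setNames(rep(0.5, 10), paste0("P", 1:10))
  null <- bootstrap_null(pr, 4, names(pr), B = 100, seed = 3)
  expect_equal(null, rep(0, 100), tolerance = 1e-12)
  set.seed(52)
  pr2 <- setNames(runif(10), paste0("P", 1:10))
  a <- bootstrap_null(pr2, 4, names(pr2), B = 150, seed = 9)
  b <- bootstrap_null(pr2, 4, names(pr2), B = 150, seed = 9)
  expect_identical(a, b)
  # exhaustive draw: every null score equals the full-universe score
  full <- bootstrap_null(pr2, 10, names(pr2), B = 100, seed = 1)
  expect_equal(full, rep(cluster_targeting_score(pr2, names(pr2)), 100))
  expect_error(bootstrap_null(pr2, 11, names(pr2), B = 100), "smaller")
})

test_that("empirical p-values use the add-one exceedance formula", {
  expect_equal(empirical_pvalue(5, rep(0, 999)), 0.001)
  expect_equal(empirical_pvalue(1, c(0.5, 2, 3, 0)), 0.6)
  expect_equal(empirical_pvalue(-10, c(1, 2, 3)), 1)
})

test_that("gaussian p-values are the fitted normal upper tail", {
  set.seed(53)
  null <- rnorm(5000)
  p <- gaussian_pvalue(qnorm(0.975), null)
  expect_equal(p, 0.025, tolerance = 0.05)
  expect_equal(gaussian_pvalue(mean(null), null), 0.5, tolerance = 1e-10)
  expect_gt(gaussian_pvalue(-50, null), 0.999)
  expect_warning(pz <- gaussian_pvalue(1, rep(2, 40)), "zero")
  expect_equal(pz, 1)
  expect_warning(pz2 <- gaussian_pvalue(3, rep(2, 40)))
  expect_equal(pz2, .Machine$double.xmin)
})

test_that("p-value aggregation baselines match closed forms", {
  pr <- c(A = 0.5, B = 0.5, C = 1, D = 1)
  pf <- aggregate_pvalues(pr, c("A", "B"), "fisher")
  x <- -2 * log(0.25)
  expect_equal(pf, exp(-x / 2) * (1 + x / 2), tolerance = 1e-6)
  expect_equal(pf, 0.5966, tolerance = 1e-3)
  expect_equal(aggregate_pvalues(pr, c("C", "D"), "fisher"), 1,
               tolerance = 1e-10)
  expect_equal(aggregate_pvalues(pr, c("A", "B"), "stouffer"), 0.5)
})

test_that("hit counting applies BH within the cluster", {
  pr <- c(P1 = 0.01, P2 = 0.3, P3 = 0.002, P4 = 0.2)
  expect_equal(count_enriched_pathways(pr, c("P1", "P2", "P3"), 0.25), 2)
  expect_equal(count_enriched_pathways(c(A = 1, B = 1), c("A", "B")), 0)
  expect_equal(count_enriched_pathways(c(A = 0.2), "A", 0.25), 1)
})

test_that("prioritize recovers a planted cluster-covering miRNA", {
  set.seed(54)
  pw <- make_pathways(800, 40, c(15, 30), seed = 61)
  bg <- sprintf("g%05d", 1:800)
  cluster <- names(pw)[1:10]
  db <- suppressWarnings(
    make_interactions(pw, bg, n_decoys = 50, size_range = c(60, 120),
                      planted = list(planted = cluster), coverage = 0.3,
                      seed = 62))
  cfg <- prioritization_config(B = 500, seed = 63)
  res <- suppressMessages(
    prioritize(db, pw, list(A = cluster), bg, cfg))
  expect_equal(res$mirna[1], "planted")
  expect_equal(unique(res$method), "bootstrap")  # cluster of 10 <= 30
  expect_true(all(res$adjusted_p >= res$p_value - 1e-12))
  expect_true(all(res$p_value >= 1 / (cfg$B + 1)))
  expect_gte(res$hits[1], 5)
})

test_that("prioritize switches to the Gaussian null for large clusters", {
  fx <- targeting_fixture(3, n_genes = 1000, n_pathways = 60,
                          pathway_size = c(10, 30), n_mirnas = 20,
                          target_size = c(30, 200), cluster_size = 35)
  cfg <- prioritization_config(B = 200, seed = 64)
  res <- prioritize(fx$interactions, fx$pathways, list(A = fx$cluster),
                    fx$background, cfg, pmat = fx$pmat)
  expect_equal(unique(res$method), "gaussian")
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
})

test_that("prioritize is reproducible and interactions off-background p ~ 1", {
  fx <- targeting_fixture(4, n_genes = 600, n_pathways = 30,
                          pathway_size = c(10, 25), n_mirnas = 15,
                          target_size = c(20, 80), cluster_size = 8)
  cfg <- prioritization_config(B = 300, seed = 65)
  r1 <- prioritize(fx$interactions, fx$pathways, list(A = fx$cluster),
                   fx$background, cfg, pmat = fx$pmat)
  r2 <- prioritize(fx$interactions, fx$pathways, list(A = fx$cluster),
                   fx$background, cfg, pmat = fx$pmat)
  expect_identical(r1, r2)
  # targets entirely outside the background: flat p rows, score minimal
  off <- list(m_off = paste0("x", 1:50), m_on = fx$background[1:40])
  expect_message(res <- prioritize(off, fx$pathways, list(A = fx$cluster),
                                   fx$background, cfg),
                 "excluded 1")
  expect_false("m_off" %in% res$mirna)
})

test_that("null miRNA empirical p-values are near-uniform", {
  fx <- targeting_fixture(5, n_genes = 2000, n_pathways = 100,
                          pathway_size = c(20, 60), n_mirnas = 200,
                          target_size = c(100, 600), cluster_size = 10)
  cfg <- prioritization_config(B = 400, seed = 66)
  res <- prioritize(fx$interactions, fx$pathways, list(A = fx$cluster),
                    fx$background, cfg, pmat = fx$pmat)
  frac <- mean(res$p_value < 0.05)
  expect_lt(abs(frac - 0.05), 0.04)
})

test_that("jackknife single-member reduction matches the transform", {
  pr_set <- rbind(m1 = c(0.1, 0.4), m2 = c(0.9, 0.02))
  colnames(pr_set) <- c("y1", "y2")
  cfg <- prioritization_config(B = 200, seed = 67)
  jk <- jackknife_pvalues(pr_set, c("y1", "y2"), cfg)
  expect_equal(dim(jk$jackknife_p), c(2L, 2L))
  expect_error(jackknife_pvalues(pr_set, "y1", cfg), "size >= 2")
  # identical p-rows give identical jackknifed p-values
  same <- rbind(a = c(0.2, 0.3, 0.4), b = c(0.2, 0.3, 0.4))
  colnames(same) <- paste0("y", 1:3)
  jk2 <- jackknife_pvalues(same, paste0("y", 1:3), cfg)
  expect_equal(jk2$jackknife_p["a", ], jk2$jackknife_p["b", ])
})
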