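test_that("Euclidean distances match hand computation", {
  m <- rbind(c(0, 0), c(3, 4))
  d <- euclidean_distance_matrix(m)
  expect_equal(d[1, 2], 5)
  expect_equal(unname(diag(d)), c(0, 0))
  m3 <- rbind(a = c(1, 2), b = c(1, 2), c = c(4, 6))
  d3 <- euclidean_distance_matrix(m3)
  expect_equal(d3["a", "b"], 0)
  expect_equal(d3["a", "c"], 5)
  expect_equal(d3, t(d3))
  m3[1, 1] <- NA
  expect_error(euclidean_distance_matrix(m3), "substitute")
})

test_that("pseudo-F agrees with vegan's PERMANOVA partition", {
  set.seed(31)
  x <- matrix(rnorm(12 * 4), nrow = 12)
  labels <- rep(c("g1", "g2", "g3"), each = 4)
  d <- euclidean_distance_matrix(x)
  ours <- permanova_oneway(d, labels, n_perm = 99, seed = 5)
  ref <- vegan::adonis2(stats::dist(x) ~ labels, permutations = 99)
  expect_equal(ours$pseudo_F, ref$F[1], tolerance = 1e-10)
})

test_that("well-separated groups hit the permutation floor; p is seed-stable", {
  # groups big enough that a random permutation essentially never
  # recreates the observed split (2 / choose(20, 10) per draw)
  set.seed(88)
  x <- rbind(matrix(rnorm(20, 0, 0.1), ncol = 2),
             matrix(rnorm(20, 50, 0.1), ncol = 2))
  labels <- rep(c("lo", "hi"), each = 10)
  d <- euclidean_distance_matrix(x)
  r <- permanova_oneway(d, labels, n_perm = 199, seed = 7)
  expect_equal(r$p_value, 1 / 200)
  r2 <- permanova_oneway(d, labels, n_perm = 199, seed = 7)
  expect_identical(r$p_value, r2$p_value)
  expect_identical(r$pseudo_F, r2$pseudo_F)
})

test_that("PERMANOVA guards degenerate inputs", {
  x <- matrix(rnorm(10), ncol = 2)
  d <- euclidean_distance_matrix(x)
  expect_error(permanova_oneway(d, c("a", "a", "a", "a", "b"), 9), "at least")
  expect_error(permanova_oneway(d, rep("a", 5), 9), "two groups")
  d0 <- matrix(0, 5, 5)
  expect_error(permanova_oneway(d0, c("a", "a", "b", "b", "b"), 9),
               "constant")
})

test_that("exact enumeration matches an adonis2-based brute force", {
  set.seed(77)
  for (rep in 1:3) {
    x <- matrix(rnorm(6 * 3), nrow = 6)
    labels <- rep(c("A", "B"), each = 3)
    d <- euclidean_distance_matrix(x)
    ours <- permanova_exact(d, labels)
    expect_equal(ours$n_assignments, 20)
    # oracle: recompute F for all 20 assignments via vegan
    combos <- utils::combn(6, 3)
    f_of <- function(lab) {
      vegan::adonis2(stats::as.dist(d) ~ lab, permutations = 2)$F[1]
    }
    f_obs <- f_of(labels)
    f_all <- apply(combos, 2, function(idx) {
      lab <- rep("B", 6); lab[idx] <- "A"; f_of(lab)
    })
    expect_equal(ours$pseudo_F, f_obs, tolerance = 1e-10)
    expect_equal(ours$p_value, mean(f_all >= f_obs - 1e-12))
  }
})

test_that("Kruskal-Wallis H matches hand ranking and stats::kruskal.test", {
  # hand-ranked instance, no ties: H = 3.857 (27/7)
  kw <- kruskal_wallis(c(1, 2, 3, 10, 20, 30), rep(c("a", "b"), each = 3))
  expect_equal(kw$H, 27 / 7, tolerance = 1e-12)
  # identical groups -> H = 0
  expect_equal(kruskal_wallis(rep(5, 6), rep(c("a", "b"), each = 3))$H, 0)
  expect_equal(kruskal_wallis(rep(5, 6), rep(c("a", "b"), each = 3))$p_value, 1)
  # tied instance against the reference implementation
  v <- c(1, 2, 2, 3, 5, 5, 5, 8, 9, 9)
  g <- rep(c("a", "b"), each = 5)
  ref <- stats::kruskal.test(v, factor(g))
  ours <- kruskal_wallis(v, g)
  expect_equal(ours$H, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("Dunn z and Bonferroni p match a from-scratch recomputation", {
  v <- c(1, 3, 4, 2, 2, 6, 7, 9, 12, 15)
  g <- c("a", "a", "a", "b", "b", "b", "c", "c", "c", "c")
  r <- dunn_posthoc(v, g)
  # independent recomputation, written directly from the rank formula
  rk <- rank(v)
  n <- length(v)
  tie_tab <- table(v)
  tie_sum <- sum(tie_tab^3 - tie_tab)
  vt <- n * (n + 1) / 12 - tie_sum / (12 * (n - 1))
  for (row in seq_len(nrow(r$pairs))) {
    gi <- r$pairs$group_i[row]; gj <- r$pairs$group_j[row]
    zi <- mean(rk[g == gi]) - mean(rk[g == gj])
    se <- sqrt(vt * (1 / sum(g == gi) + 1 / sum(g == gj)))
    z_exp <- zi / se
    expect_equal(r$pairs$z[row], z_exp, tolerance = 1e-12)
    p_exp <- 2 * pnorm(-abs(z_exp))
    expect_equal(r$pairs$p_raw[row], p_exp, tolerance = 1e-12)
    expect_equal(r$pairs$p_adj[row], min(1, p_exp * 3), tolerance = 1e-12)
  }
  expect_true(all(r$pairs$p_adj >= r$pairs$p_raw))
})

test_that("compact letters separate shifted groups and merge exchangeable ones", {
  set.seed(12)
  base <- rnorm(8)
  v <- c(base, base + 0.1, base + 100)
  g <- rep(c("a", "b", "shift"), each = 8)
  r <- dunn_posthoc(v, g)
  expect_true(nchar(r$letters[["shift"]]) > 0)
  common_ab <- intersect(strsplit(r$letters[["a"]], "")[[1]],
                         strsplit(r$letters[["b"]], "")[[1]])
  common_as <- intersect(strsplit(r$letters[["a"]], "")[[1]],
                         strsplit(r$letters[["shift"]], "")[[1]])
  expect_true(length(common_ab) > 0)   # a and b share a letter
  expect_equal(length(common_as), 0)   # the shifted group shares none

  v2 <- rnorm(24)
  r2 <- dunn_posthoc(v2, g)
  expect_equal(length(unique(r2$letters)), 1)  # all exchangeable: one letter
  expect_error(dunn_posthoc(v[1:16], g[1:16][g[1:16] != "shift"]), ">= 3")
})

test_that("two-stage protocol gates the univariate tests on PERMANOVA", {
  set.seed(5)
  # exchangeable data: PERMANOVA should usually not fire at alpha = 0.05
  x_null <- matrix(rnorm(30 * 3), nrow = 30)
  g <- rep(c("a", "b", "c"), each = 10)
  r_null <- compare_groups(x_null, g, n_perm = 199, seed = 3, alpha = 0.001)
  expect_null(r_null$kruskal)
  # strongly separated data: both stages run
  x_sep <- x_null
  x_sep[g == "c", ] <- x_sep[g == "c", ] + 50
  r_sep <- compare_groups(x_sep, g, n_perm = 199, seed = 3)
  expect_false(is.null(r_sep$kruskal))
  expect_false(is.null(r_sep$dunn))
  expect_lt(r_sep$permanova$p_value, 0.05)
})
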