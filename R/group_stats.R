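#' Euclidean distance matrix from a complete value matrix
#'
#' @param value_matrix Complete numeric matrix (samples x analytes),
#'   typically the output of [substitute_nondetects()]; missing cells are
#'   an error because substitution must run first.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
euclidean_distance_matrix <- function(value_matrix) {
  if (anyNA(value_matrix)) {
    stop("value matrix has missing cells; run substitute_nondetects() first",
         call. = FALSE)
  }
  as.matrix(stats::dist(value_matrix, method = "euclidean"))
}

# Within-group sum of squared interpoint distances for a label vector,
# from the squared distance matrix: sum over groups of
# (sum of within-group d^2) / (2 * n_g).
.ss_within <- function(d2, group_idx, group_sizes) {
  sw <- 0
  for (g in seq_along(group_sizes)) {
    idx <- group_idx[[g]]
    sw <- sw + sum(d2[idx, idx]) / (2 * group_sizes[[g]])
  }
  sw
}

.pseudo_f <- function(d2, labels, ss_total) {
  groups <- split(seq_along(labels), labels)
  sizes <- lengths(groups)
  a <- length(groups)
  n <- length(labels)
  ss_w <- .ss_within(d2, groups, sizes)
  ss_b <- ss_total - ss_w
  (ss_b / (a - 1)) / (ss_w / (n - a))
}

#' One-way PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance using the direct
#' partition of the squared interpoint distances: total sum of squares
#' SS_T = sum_{i<j} d_ij^2 / N, within-group SS_W summed per group over
#' within-group pairs, SS_A = SS_T - SS_W, and
#' pseudo-F = (SS_A/(a-1)) / (SS_W/(N-a)). Significance comes from
#' random permutation of the group labels; the permutation p-value
#' includes the observed statistic in both numerator and denominator,
#' p = (1 + #\{F* >= F\}) / (1 + n_perm), so p is never zero and the floor
#' is 1/(n_perm+1). The test is sensitive to both location (centroid)
#' and dispersion differences among groups.
#'
#' @param dist_matrix Symmetric distance matrix (or `dist` object).
#' @param labels Group labels, one per row; at least two groups with two
#'   or more members each.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Integer seed for the permutation stream (local RNG; the
#'   caller's RNG state is untouched).
#' @return List of class `permanova_result`: `pseudo_F`, `p_value`,
#'   `n_permutations`, `seed`, `df_between`, `df_within`.
#' @export
permanova_oneway <- function(dist_matrix, labels, n_perm = 9999, seed = 1L) {
  d <- as.matrix(dist_matrix)
  labels <- as.character(labels)
  n <- length(labels)
  if (nrow(d) != n) stop("labels length must match distance matrix", call. = FALSE)
  sizes <- table(labels)
  if (length(sizes) < 2) stop("need at least two groups", call. = FALSE)
  if (any(sizes < 2)) stop("every group needs at least two members", call. = FALSE)
  d2 <- d^2
  ss_total <- sum(d2) / (2 * n)
  if (ss_total <= 0) {
    stop("constant distances: pseudo-F undefined", call. = FALSE)
  }
  f_obs <- .pseudo_f(d2, labels, ss_total)
  n_ge <- 0L
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    f_perm <- .pseudo_f(d2, sample(labels), ss_total)
    if (f_perm >= f_obs - 1e-12) n_ge <- n_ge + 1L
  }
  structure(list(
    pseudo_F = f_obs,
    p_value = (1 + n_ge) / (1 + n_perm),
    n_permutations = n_perm,
    seed = seed,
    df_between = length(sizes) - 1L,
    df_within = n - length(sizes)
  ), class = "permanova_result")
}

#' Exact PERMANOVA p by exhaustive enumeration of label assignments
#'
#' Brute-force reference for small instances: enumerates every distinct
#' assignment of the multiset of labels to the observations and computes
#' the exact proportion of assignments whose pseudo-F is at least the
#' observed one (the observed assignment is among them, so p > 0).
#' Intended for testing the permutation test at small n.
#'
#' @inheritParams permanova_oneway
#' @return List: `pseudo_F`, `p_value`, `n_assignments`.
#' @export
permanova_exact <- function(dist_matrix, labels) {
  d2 <- as.matrix(dist_matrix)^2
  labels <- as.character(labels)
  n <- length(labels)
  ss_total <- sum(d2) / (2 * n)
  f_obs <- .pseudo_f(d2, labels, ss_total)
  lev <- sort(unique(labels))
  if (length(lev) != 2) stop("exact enumeration supports two groups", call. = FALSE)
  k <- sum(labels == lev[1])
  combos <- utils::combn(n, k)
  f_all <- apply(combos, 2, function(idx) {
    lab <- rep(lev[2], n)
    lab[idx] <- lev[1]
    .pseudo_f(d2, lab, ss_total)
  })
  list(pseudo_F = f_obs,
       p_value = mean(f_all >= f_obs - 1e-12),
       n_assignments = ncol(combos))
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("<permanova_result> pseudo-F(%d,%d) = %.4g, p = %.4g (%d permutations, seed %d)\n",
              x$df_between, x$df_within, x$pseudo_F, x$p_value,
              x$n_permutations, x$seed))
  invisible(x)
}

# Midranks and the tie-correction sum Sum(t^3 - t) over tied groups.
.rank_info <- function(values) {
  r <- rank(values)
  ties <- table(values)
  list(ranks = r, tie_sum = sum(ties^3 - ties))
}

#' Kruskal-Wallis one-way analysis of variance by ranks
#'
#' H statistic with tie correction:
#' H = \[(12/(N(N+1))) * sum n_i (Rbar_i - (N+1)/2)^2\] / \[1 - sum(t^3 - t)/(N^3 - N)\],
#' with the p-value from the chi-square approximation on a-1 degrees of
#' freedom. All-identical values give H = 0, p = 1.
#'
#' @param values Numeric response.
#' @param groups Group labels (>= 2 groups).
#' @return List: `H`, `p_value`, `df`, `n`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.character(groups)
  if (length(unique(groups)) < 2) stop("need at least two groups", call. = FALSE)
  n <- length(values)
  ri <- .rank_info(values)
  rbar <- tapply(ri$ranks, groups, mean)
  ni <- tapply(ri$ranks, groups, length)
  h_raw <- 12 / (n * (n + 1)) * sum(ni * (rbar - (n + 1) / 2)^2)
  corr <- 1 - ri$tie_sum / (n^3 - n)
  if (corr <= 0) return(list(H = 0, p_value = 1, df = length(ni) - 1L, n = n))
  h <- h_raw / corr
  df <- length(ni) - 1L
  list(H = h, p_value = pchisq(h, df = df, lower.tail = FALSE), df = df, n = n)
}

#' Dunn pairwise post hoc test with Bonferroni correction
#'
#' For each pair of groups computes the Dunn z statistic from the pooled
#' midranks with tie correction:
#' z = (Rbar_i - Rbar_j) / sqrt\{\[N(N+1)/12 - sum(t^3-t)/(12(N-1))\] (1/n_i + 1/n_j)\},
#' two-sided p from the standard normal, Bonferroni-adjusted over all
#' a(a-1)/2 pairs (adjusted p = min(1, raw p x pairs)). A compact letter
#' display is attached: groups sharing no letter differ at `alpha`.
#'
#' @param values Numeric response.
#' @param groups Group labels (3 or more groups; with 2 the pairwise
#'   comparison is the Kruskal-Wallis test itself).
#' @param alpha Significance level for the letter display (default 0.05).
#' @return List of class `dunn_result`: `pairs` (tibble group_i, group_j,
#'   z, p_raw, p_adj), `letters` (named character per group).
#' @export
dunn_posthoc <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  a <- length(lev)
  if (a < 3) stop("post hoc needs >= 3 groups; use kruskal_wallis for 2",
                  call. = FALSE)
  n <- length(values)
  ri <- .rank_info(values)
  rbar <- tapply(ri$ranks, groups, mean)[lev]
  ni <- tapply(ri$ranks, groups, length)[lev]
  var_term <- n * (n + 1) / 12 - ri$tie_sum / (12 * (n - 1))
  k <- a * (a - 1) / 2
  out <- vector("list", k)
  idx <- 1
  for (i in seq_len(a - 1)) {
    for (j in seq(i + 1, a)) {
      se <- sqrt(var_term * (1 / ni[i] + 1 / ni[j]))
      z <- (rbar[i] - rbar[j]) / se
      p_raw <- 2 * stats::pnorm(-abs(z))
      out[[idx]] <- tibble(group_i = lev[i], group_j = lev[j],
                           z = unname(z), p_raw = unname(p_raw),
                           p_adj = min(1, unname(p_raw) * k))
      idx <- idx + 1
    }
  }
  pairs <- bind_rows(out)
  structure(list(pairs = pairs,
                 letters = compact_letters(pairs, lev, alpha = alpha)),
            class = "dunn_result")
}

#' Compact letter display from pairwise comparisons
#'
#' Insert-and-absorb assignment: groups that are not significantly
#' different (adjusted p >= alpha) share at least one letter; any pair
#' with adjusted p < alpha shares none.
#'
#' @param pairs Tibble with columns group_i, group_j, p_adj.
#' @param groups Character vector of all group labels (display order).
#' @param alpha Significance level.
#' @return Named character vector of letter strings per group.
#' @export
compact_letters <- function(pairs, groups, alpha = 0.05) {
  a <- length(groups)
  differ <- matrix(FALSE, a, a, dimnames = list(groups, groups))
  for (r in seq_len(nrow(pairs))) {
    if (pairs$p_adj[r] < alpha) {
      differ[pairs$group_i[r], pairs$group_j[r]] <- TRUE
      differ[pairs$group_j[r], pairs$group_i[r]] <- TRUE
    }
  }
  # each letter set holds a maximal clique of mutually non-different groups
  sets <- list(groups[1])
  for (g in groups[-1]) {
    placed <- FALSE
    for (s in seq_along(sets)) {
      if (!any(differ[g, sets[[s]]])) {
        sets[[s]] <- c(sets[[s]], g)
        placed <- TRUE
      }
    }
    if (!placed) sets[[length(sets) + 1]] <- g
  }
  # absorb letter sets fully contained in another
  keep <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (i != j && keep[i] && keep[j] && all(sets[[i]] %in% sets[[j]])) {
        keep[i] <- FALSE
      }
    }
  }
  sets <- sets[keep]
  letters_out <- setNames(rep("", a), groups)
  for (s in seq_along(sets)) {
    for (g in sets[[s]]) {
      letters_out[g] <- paste0(letters_out[g], letters[s])
    }
  }
  letters_out
}

#' Two-stage group comparison protocol
#'
#' Encodes the study's testing protocol: a one-way PERMANOVA on the
#' Euclidean distances of the (substituted) concentration matrix; only
#' when it detects a difference at `alpha` is the univariate
#' Kruskal-Wallis test run on the per-sample summary variable, followed
#' by the Dunn post hoc with Bonferroni correction when three or more
#' groups are compared.
#'
#' @param value_matrix Complete sample x analyte matrix (ug/L).
#' @param labels Group labels per sample.
#' @param summary_values Per-sample univariate response for the
#'   Kruskal-Wallis stage (default: row sums of `value_matrix`, i.e.
#'   cumulative concentration).
#' @param n_perm,seed Passed to [permanova_oneway()].
#' @param alpha Gate for stage two (default 0.05).
#' @return List: `permanova`, `kruskal` (NULL unless gated in), `dunn`
#'   (NULL unless >= 3 groups and gated in).
#' @export
compare_groups <- function(value_matrix, labels,
                           summary_values = rowSums(value_matrix),
                           n_perm = 9999, seed = 1L, alpha = 0.05) {
  dm <- euclidean_distance_matrix(value_matrix)
  perm <- permanova_oneway(dm, labels, n_perm = n_perm, seed = seed)
  kw <- NULL
  dn <- NULL
  if (perm$p_value < alpha) {
    kw <- kruskal_wallis(summary_values, labels)
    if (length(unique(labels)) >= 3) {
      dn <- dunn_posthoc(summary_values, labels, alpha = alpha)
    }
  }
  list(permanova = perm, kruskal = kw, dunn = dn)
}
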