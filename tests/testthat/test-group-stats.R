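test_that("pathway profiles report percent activated with a closed-left cutoff", {
  atlas <- as_fiber_atlas(dplyr::bind_rows(lapply(1:10, function(i)
    straight_fiber(c(i, 0, 0), c(i, 5, 0), id = as.integer(i),
                   pathway = if (i <= 10) "alpha" else "beta"))))
  act <- tibble::tibble(fiber_id = 1:10,
                        binary = c(rep(TRUE, 3), rep(FALSE, 7)))
  pr <- pathway_profile(atlas, act)
  expect_equal(pr$pct_activated, 30)

  none <- pathway_profile(atlas,
                          tibble::tibble(fiber_id = 1:10, binary = FALSE))
  expect_equal(none$pct_activated, 0)

  two <- pathway_profile(atlas[atlas$fiber_id <= 2, ],
                         tibble::tibble(fiber_id = 1:2, p_a = c(0.5, 0.49)))
  expect_equal(two$pct_activated, 50)

  expect_error(pathway_profile(atlas,
                               tibble::tibble(fiber_id = 99L, binary = TRUE)),
               "unknown fiber_id")
})

test_that("Spearman profile comparison matches a brute-force rank evaluation", {
  prof <- function(v) tibble::tibble(pathway = letters[seq_along(v)],
                                     pct_activated = v)
  same <- compare_profiles_spearman(prof(c(10, 40, 20, 70)),
                                    prof(c(10, 40, 20, 70)))
  expect_equal(same$rho, 1)
  revd <- compare_profiles_spearman(prof(c(10, 20, 30, 40)),
                                    prof(c(40, 30, 20, 10)))
  expect_equal(revd$rho, -1)

  a <- c(10, 20, 30, 40); b <- c(15, 10, 45, 40)
  got <- compare_profiles_spearman(prof(a), prof(b))
  # independent oracle: Pearson correlation of the rank vectors
  ra <- rank(a); rb <- rank(b)
  rho_brute <- sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  expect_equal(got$rho, rho_brute, tolerance = 1e-12)
  expect_equal(got$rho, 0.6, tolerance = 1e-12)
  expect_equal(got$n_pathways, 4)

  # invariance under strictly monotone transforms
  got2 <- compare_profiles_spearman(prof(log1p(a)), prof(b^3 / 1e3))
  expect_equal(got2$rho, got$rho, tolerance = 1e-12)

  expect_error(compare_profiles_spearman(prof(c(5, 5, 5, 5)), prof(b)),
               class = "undefined_correlation_error")
  expect_error(compare_profiles_spearman(prof(a),
                                         tibble::tibble(pathway = c("x", "y", "z", "w"),
                                                        pct_activated = b)),
               "different pathway sets")
})

test_that("paired comparison of correlation sets works on Fisher z-scores", {
  idn <- compare_correlation_sets(c(0.5, 0.6, 0.7), c(0.5, 0.6, 0.7))
  expect_equal(idn$t, 0)
  expect_equal(idn$p_value, 1)

  ra <- c(0.5, 0.6, 0.7); rb <- c(0.4, 0.5, 0.6)
  got <- compare_correlation_sets(ra, rb)
  d <- atanh(ra) - atanh(rb)           # independent hand evaluation
  t_hand <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(got$t, t_hand, tolerance = 1e-12)
  expect_equal(got$df, 2)

  # antisymmetric differences with zero mean
  sym <- compare_correlation_sets(atanh_inv <- tanh(c(0.1, 0.2, 0.3, 0.4)),
                                  tanh(c(0.2, 0.1, 0.4, 0.3)))
  expect_equal(sym$t, 0, tolerance = 1e-12)

  expect_error(compare_correlation_sets(c(1, 0.5, 0.2), c(0.1, 0.2, 0.3)),
               "clamp")
  ok <- compare_correlation_sets(c(1, 0.5, 0.2), c(0.1, 0.2, 0.3),
                                 clamp = TRUE)
  expect_true(is.finite(ok$t))
})

test_that("the prevalence filter keeps fibres with both groups populated", {
  m <- matrix(0, nrow = 30, ncol = 3,
              dimnames = list(NULL, c("1", "2", "3")))
  m[1:6, 1] <- 1    # 6/30 = 20 %: in
  m[1:5, 2] <- 1    # 5/30: out
  m[, 3] <- 1       # no comparison group: out
  f <- prevalence_filter(m)
  expect_equal(f$included, c(TRUE, FALSE, FALSE))
  expect_equal(f$n_activated, c(6L, 5L, 30L))
})

test_that("the fibre-wise pooled t-test matches hand and t.test oracles", {
  # hand fixture: activated {60,50,40} vs non-activated {20,30,10}
  m <- matrix(c(1, 1, 1, 0, 0, 0), ncol = 1, dimnames = list(NULL, "7"))
  y <- c(60, 50, 40, 20, 30, 10)
  st <- fiber_ttest(m, y)
  expect_equal(st$t, 30 / (10 * sqrt(2 / 3)), tolerance = 1e-12)
  expect_equal(round(st$t, 3), 3.674)
  expect_equal(st$n_act, 3L)
  expect_gt(st$t, 0)   # activated group improved more

  eq <- fiber_ttest(matrix(c(1, 1, 0, 0), ncol = 1,
                           dimnames = list(NULL, "1")),
                    c(5, 7, 7, 5))
  expect_equal(eq$t, 0)

  # row permutation invariance and agreement with stats::t.test
  set.seed(8)
  mm <- matrix(rbinom(60, 1, 0.4), nrow = 12)
  colnames(mm) <- as.character(1:5)
  yy <- rnorm(12, 50, 15)
  st1 <- fiber_ttest(mm, yy)
  perm <- sample(12)
  st2 <- fiber_ttest(mm[perm, ], yy[perm])
  expect_equal(st1$t, st2$t, tolerance = 1e-12)
  for (j in 1:5) {
    if (is.na(st1$t[j])) next
    ref <- t.test(yy[mm[, j] == 1], yy[mm[, j] == 0], var.equal = TRUE)
    expect_equal(st1$t[j], unname(ref$statistic), tolerance = 1e-12)
  }
})

test_that("the probability-weighted t-test reduces to the pooled test and matches its formula", {
  set.seed(13)
  mb <- matrix(rbinom(80, 1, 0.5), nrow = 16)
  colnames(mb) <- as.character(1:5)
  y <- rnorm(16, 40, 12)
  a <- fiber_ttest(mb, y)
  b <- weighted_fiber_ttest(mb, y)
  expect_equal(a$t, b$t, tolerance = 1e-12)

  half <- matrix(0.5, nrow = 10, ncol = 1, dimnames = list(NULL, "1"))
  expect_equal(weighted_fiber_ttest(half, rnorm(10))$t, 0, tolerance = 1e-12)

  # hand-evaluated oracle for fractional weights
  w <- c(1, 0.8, 0.2, 0)
  yy <- c(60, 50, 30, 20)
  got <- weighted_fiber_ttest(matrix(w, ncol = 1, dimnames = list(NULL, "1")),
                              yy)
  sw1 <- sum(w); sw0 <- sum(1 - w)
  m1 <- sum(w * yy) / sw1; m0 <- sum((1 - w) * yy) / sw0
  ss1 <- sum(w * (yy - m1)^2); ss0 <- sum((1 - w) * (yy - m0)^2)
  ne1 <- sw1^2 / sum(w^2); ne0 <- sw0^2 / sum((1 - w)^2)
  sp2 <- (ss1 + ss0) / (ne1 + ne0 - 2)
  t_hand <- (m1 - m0) / sqrt(sp2 * (1 / ne1 + 1 / ne0))
  expect_equal(got$t, t_hand, tolerance = 1e-12)
  expect_gt(got$t, 0)

  degen <- matrix(1, nrow = 6, ncol = 1, dimnames = list(NULL, "1"))
  expect_true(is.na(weighted_fiber_ttest(degen, rnorm(6))$t))
})

test_that("weighted odds ratios follow the 2x2 construction", {
  w <- c(rep(1, 6), rep(0, 2), rep(1, 2), rep(0, 6))
  y <- c(rep(1, 8), rep(0, 8))
  got <- weighted_odds_ratio(w, y)   # a=6 b=2 c=2 d=6
  expect_equal(got$odds_ratio, 9)
  expect_false(got$corrected)

  flat <- weighted_odds_ratio(rep(0.5, 10), rep(c(0, 1), 5))
  expect_equal(flat$odds_ratio, 1)

  zer <- weighted_odds_ratio(c(1, 1, 1, 0, 0, 0), c(1, 1, 1, 0, 0, 0))
  expect_true(zer$corrected)
  expect_true(is.finite(zer$odds_ratio))
  expect_error(weighted_odds_ratio(c(0.5, 0.5), c(1, 1)), "degenerate")
})

test_that("top-k distributions count pathways deterministically", {
  atlas <- as_fiber_atlas(dplyr::bind_rows(lapply(1:6, function(i)
    straight_fiber(c(i, 0, 0), c(i, 5, 0), id = as.integer(i),
                   pathway = if (i <= 3) "alpha" else "beta"))))
  st <- tibble::tibble(fiber_id = 1:6, t = c(5, 4, 3, 2, 2, 1),
                       n_act = 3L, n_nonact = 3L)
  class(st) <- c("fiber_stats", class(st))
  top <- top_fiber_distribution(st, atlas, k = 4)
  expect_equal(sum(top$n_fibers), 4)
  # tie at rank 4 between fibres 4 and 5: lower id kept
  expect_equal(top$n_fibers[top$pathway == "alpha"], 3L)
  expect_equal(top$n_fibers[top$pathway == "beta"], 1L)

  expect_warning(all_used <- top_fiber_distribution(st, atlas, k = 100),
                 "using all")
  expect_equal(sum(all_used$n_fibers), 6)
})

test_that("mirroring pools hemispheres without changing the per-fibre contrast", {
  mirror_map <- tibble::tibble(left_id = 101:103, right_id = 1:3)
  pats <- letters[1:4]
  outc <- setNames(c(60, 50, 30, 20), pats)
  cohort <- tidyr::expand_grid(pat = pats, hemi = c("R", "L")) |>
    dplyr::mutate(stim_id = paste0(pat, "_", hemi),
                  hemisphere = ifelse(hemi == "R", "right", "left"),
                  outcome_percent = outc[pat]) |>
    dplyr::select("stim_id", "hemisphere", "outcome_percent")
  act <- tidyr::expand_grid(stim_id = cohort$stim_id, fid = 1:3) |>
    dplyr::mutate(fiber_id = ifelse(grepl("_L", stim_id), fid + 100L, fid),
                  p_a = as.numeric(fid == 1 & grepl("a|b", stim_id))) |>
    dplyr::select(-"fid")
  folded <- mirror_stimulations(act, cohort, mirror_map)
  expect_true(all(folded$fiber_id %in% 1:3))

  m <- activation_matrix(folded)
  y <- cohort$outcome_percent[match(rownames(m), cohort$stim_id)]
  st_both <- fiber_ttest((m >= 0.5) * 1, y)

  # identical data in both hemispheres: pooling must reproduce the
  # single-hemisphere T recomputed with doubled group sizes
  right <- act[grepl("_R", act$stim_id), ]
  m1 <- activation_matrix(right)
  y1 <- cohort$outcome_percent[match(rownames(m1), cohort$stim_id)]
  n1 <- colSums(m1 >= 0.5); n0 <- nrow(m1) - n1
  for (j in seq_len(ncol(m1))) {
    g1 <- y1[m1[, j] >= 0.5]; g0 <- y1[m1[, j] < 0.5]
    if (length(g1) < 1 || length(g0) < 1) next
    ss <- sum((g1 - mean(g1))^2) + sum((g0 - mean(g0))^2)
    sp2 <- 2 * ss / (2 * length(g1) + 2 * length(g0) - 2)
    t_dbl <- (mean(g1) - mean(g0)) /
      sqrt(sp2 * (1 / (2 * length(g1)) + 1 / (2 * length(g0))))
    if (!is.finite(t_dbl)) next
    expect_equal(st_both$t[j], t_dbl, tolerance = 1e-12)
  }
})
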