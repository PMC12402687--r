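#' Pathway activation profile
#'
#' Per pathway, the percentage of its fibres deemed activated under one
#' stimulation.  Probabilistic activations are binarised at `prob_cutoff`
#' first (closed on the left: p(A) >= cutoff counts as activated); fibres
#' absent from `activations` count as not activated.
#'
#' @param atlas a `fiber_atlas`.
#' @param activations tibble with `fiber_id` and either `p_a`
#'   (probabilities) or `binary` (logical); every fiber_id must exist in
#'   the atlas.
#' @param prob_cutoff binarisation cutoff for probabilistic entries,
#'   default 0.5.
#' @return tibble of class `activation_profile`: `pathway`, `n_fibers`,
#'   `n_activated`, `pct_activated` (0-100).
#' @export
pathway_profile <- function(atlas, activations, prob_cutoff = 0.5) {
  info <- fiber_info(atlas)
  unknown <- setdiff(activations$fiber_id, info$fiber_id)
  if (length(unknown) > 0) {
    abort(paste0("activation entries for unknown fiber_id(s): ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  act <- if ("binary" %in% names(activations)) {
    as.logical(activations$binary)
  } else if ("p_a" %in% names(activations)) {
    activations$p_a >= prob_cutoff
  } else {
    abort("activations need a 'p_a' or 'binary' column")
  }
  act[is.na(act)] <- FALSE
  info$activated <- FALSE
  info$activated[match(activations$fiber_id, info$fiber_id)] <- act
  out <- info |>
    dplyr::group_by(.data$pathway) |>
    dplyr::summarise(n_fibers = dplyr::n(),
                     n_activated = sum(.data$activated),
                     pct_activated = 100 * mean(.data$activated)) |>
    dplyr::arrange(.data$pathway)
  class(out) <- c("activation_profile", class(out))
  out
}

#' Spearman comparison of two activation profiles
#'
#' Rank correlation (average ranks for ties) between the per-pathway
#' activation percentages of two metrics or stimulations, with a
#' two-sided p-value from the t approximation.
#'
#' @param a,b `activation_profile` tibbles over identical pathway sets
#'   (>= 3 pathways).
#' @return a `profile_comparison` list: `rho`, `p_value`, `n_pathways`.
#' @export
compare_profiles_spearman <- function(a, b) {
  if (!setequal(a$pathway, b$pathway)) {
    abort("profiles cover different pathway sets")
  }
  if (nrow(a) < 3) abort("need >= 3 pathways for a rank correlation")
  x <- a$pct_activated
  y <- b$pct_activated[match(a$pathway, b$pathway)]
  if (sd(x) == 0 || sd(y) == 0) {
    abort("rank correlation undefined: a profile has zero variance",
          class = "undefined_correlation_error")
  }
  rho <- stats::cor(x, y, method = "spearman")
  n <- length(x)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  structure(list(rho = rho, p_value = p, n_pathways = n),
            class = "profile_comparison")
}

#' @export
print.profile_comparison <- function(x, ...) {
  cat(sprintf("Spearman profile comparison: rho = %.3f, p = %.3g (n = %d pathways)\n",
              x$rho, x$p_value, x$n_pathways))
  invisible(x)
}

#' Paired comparison of two sets of rank correlations
#'
#' Fisher z-transforms each correlation (atanh) and runs a paired
#' two-tailed t-test on the element-wise differences — the comparison used
#' to ask whether two activation metrics agree equally well with a third.
#'
#' @param rhos_a,rhos_b equal-length (>= 3) vectors of correlations with
#'   `|rho| < 1`.
#' @param clamp if `TRUE`, correlations at exactly +-1 are clamped to
#'   +-(1 - 1e-12) instead of raising an error.
#' @return tibble: `t`, `p_value`, `df`, `n`, `mean_dz`.
#' @export
compare_correlation_sets <- function(rhos_a, rhos_b, clamp = FALSE) {
  if (length(rhos_a) != length(rhos_b) || length(rhos_a) < 3) {
    abort("need two equal-length vectors with >= 3 correlations")
  }
  fix <- function(r) {
    if (any(abs(r) >= 1)) {
      if (!clamp) abort("|rho| = 1 cannot be Fisher z-transformed; set clamp = TRUE")
      r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
    }
    r
  }
  za <- atanh(fix(rhos_a)); zb <- atanh(fix(rhos_b))
  d <- za - zb
  if (sd(d) == 0) {
    tt <- list(statistic = c(t = 0), p.value = 1,
               parameter = c(df = length(d) - 1))
  } else {
    tt <- stats::t.test(za, zb, paired = TRUE)
  }
  tibble::tibble(t = unname(tt$statistic), p_value = tt$p.value,
                 df = unname(tt$parameter), n = length(d), mean_dz = mean(d))
}

as_activation_matrix <- function(matrix) {
  m <- as.matrix(matrix)
  if (any(!is.finite(m)) || any(m < -1e-12) || any(m > 1 + 1e-12)) {
    abort("activation matrix entries must be finite probabilities in [0, 1]")
  }
  if (is.null(colnames(m))) colnames(m) <- as.character(seq_len(ncol(m)))
  m
}

#' Prevalence filter for fibre-wise statistics
#'
#' A fibre enters the fibre-filtering t-tests only if it was activated
#' (p(A) >= `prob_cutoff`) in at least `min_frac` of the stimulations —
#' guarding against overfitting to rarely recruited fibres — and was
#' non-activated in at least 2 stimulations, so both comparison groups
#' exist.
#'
#' @param matrix stimulations-by-fibres matrix of activation probabilities
#'   (or 0/1); columns named by fiber_id.
#' @param min_frac minimum activated fraction, default 0.2.
#' @param prob_cutoff binarisation cutoff, default 0.5.
#' @return tibble `fiber_id`, `n_activated`, `n_nonactivated`, `frac`,
#'   `included`.
#' @export
prevalence_filter <- function(matrix, min_frac = 0.2, prob_cutoff = 0.5) {
  m <- as_activation_matrix(matrix)
  bin <- m >= prob_cutoff
  n <- nrow(bin)
  n_act <- colSums(bin)
  tibble::tibble(
    fiber_id = as.integer(colnames(m)),
    n_activated = as.integer(unname(n_act)),
    n_nonactivated = as.integer(unname(n - n_act)),
    frac = unname(n_act / n),
    included = unname((n_act / n >= min_frac) & (n - n_act >= 2)))
}

#' Fibre-wise two-sample t-test against outcomes
#'
#' For every fibre, contrasts the outcome (e.g. % motor improvement)
#' between stimulations in which the fibre was activated and those in
#' which it was not, with a pooled-variance (Student) unpaired t-test.
#' T > 0 means the activated group improved more.  No multiple-comparison
#' correction is applied and p-values are only computed on request; the
#' T-values are used as a ranking, not as formal significance tests.
#'
#' @param matrix binary stimulations-by-fibres activation matrix (columns
#'   named by fiber_id), typically pre-filtered with [prevalence_filter()].
#' @param outcomes numeric outcome per stimulation (row).
#' @param welch use Welch's unequal-variance t instead of the pooled form.
#' @param report_p also report (uncorrected) two-sided p-values.
#' @return tibble of class `fiber_stats`: `fiber_id`, `t`, `n_act`,
#'   `n_nonact` (`t` is `NA` when the pooled variance is zero).
#' @export
fiber_ttest <- function(matrix, outcomes, welch = FALSE, report_p = FALSE) {
  m <- as_activation_matrix(matrix)
  if (!all(m %in% c(0, 1))) {
    abort("fiber_ttest needs a binary matrix; use weighted_fiber_ttest for probabilities")
  }
  if (length(outcomes) != nrow(m)) {
    abort("outcomes length must equal the number of stimulations (rows)")
  }
  if (any(!is.finite(outcomes))) abort("outcomes must be finite")
  y <- as.numeric(outcomes)
  n1 <- colSums(m)                      # activated group sizes
  n0 <- nrow(m) - n1
  s1 <- colSums(m * y)
  s0 <- sum(y) - s1
  m1 <- ifelse(n1 > 0, s1 / n1, NA_real_)
  m0 <- ifelse(n0 > 0, s0 / n0, NA_real_)
  ss1 <- colSums(m * y^2) - n1 * m1^2
  ss0 <- (sum(y^2) - colSums(m * y^2)) - n0 * m0^2
  if (welch) {
    v1 <- ss1 / (n1 - 1); v0 <- ss0 / (n0 - 1)
    se <- sqrt(v1 / n1 + v0 / n0)
    df <- (v1 / n1 + v0 / n0)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  } else {
    sp2 <- (ss1 + ss0) / (n1 + n0 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n0))
    df <- n1 + n0 - 2
  }
  t <- ifelse(n1 < 1 | n0 < 1 | se == 0 | !is.finite(se),
              NA_real_, (m1 - m0) / se)
  out <- tibble::tibble(fiber_id = as.integer(colnames(m)), t = unname(t),
                        n_act = as.integer(unname(n1)),
                        n_nonact = as.integer(unname(n0)))
  if (report_p) out$p_value <- unname(2 * pt(-abs(t), df = df))
  class(out) <- c("fiber_stats", class(out))
  out
}

#' Probability-weighted fibre-wise t-test
#'
#' The probability-weighted counterpart of [fiber_ttest()]: each
#' stimulation contributes to the "activated" group with weight
#' `w = p(A)` and to the "non-activated" group with weight `1 - w`.
#' Group means and sums of squares are weighted, group sizes are Kish
#' effective sample sizes `n_eff = (sum w)^2 / sum w^2`, and T comes from
#' the pooled two-sample formula with those effective sizes.  With binary
#' weights this reduces exactly to the unweighted pooled t-test.
#'
#' @param matrix stimulations-by-fibres matrix of activation probabilities
#'   in `[0, 1]`, columns named by fiber_id.
#' @inheritParams fiber_ttest
#' @return tibble of class `fiber_stats`: `fiber_id`, `t`, `n_act`,
#'   `n_nonact` (effective sizes, fractional); `t` is `NA` for fibres
#'   whose weights are all 0 or all 1.
#' @export
weighted_fiber_ttest <- function(matrix, outcomes, report_p = FALSE) {
  w <- as_activation_matrix(matrix)
  if (length(outcomes) != nrow(w)) {
    abort("outcomes length must equal the number of stimulations (rows)")
  }
  y <- as.numeric(outcomes)
  sw1 <- colSums(w); sw0 <- colSums(1 - w)
  m1 <- colSums(w * y) / sw1
  m0 <- colSums((1 - w) * y) / sw0
  ss1 <- colSums(w * y^2) - sw1 * m1^2
  ss0 <- colSums((1 - w) * y^2) - sw0 * m0^2
  ne1 <- sw1^2 / colSums(w^2)
  ne0 <- sw0^2 / colSums((1 - w)^2)
  sp2 <- (ss1 + ss0) / (ne1 + ne0 - 2)
  se <- sqrt(sp2 * (1 / ne1 + 1 / ne0))
  bad <- sw1 < 1e-12 | sw0 < 1e-12 | !is.finite(se) | se == 0
  t <- ifelse(bad, NA_real_, (m1 - m0) / se)
  out <- tibble::tibble(fiber_id = as.integer(colnames(w)), t = unname(t),
                        n_act = unname(ne1), n_nonact = unname(ne0))
  if (report_p) out$p_value <- unname(2 * pt(-abs(t), df = ne1 + ne0 - 2))
  class(out) <- c("fiber_stats", class(out))
  out
}

#' Probability-weighted odds ratio for a binary outcome
#'
#' Builds a weighted 2x2 table (activation side x outcome) with cell
#' masses given by summed activation probabilities, applies the
#' Haldane-Anscombe 0.5 correction when any cell is empty, and reports
#' the odds ratio with a Wald log-scale confidence interval.
#'
#' @param weights activation probabilities p(A), one per stimulation.
#' @param outcome binary outcome vector (0/1 or logical).
#' @param conf_level confidence level, default 0.95.
#' @return tibble: `odds_ratio`, `conf_low`, `conf_high`, `corrected`.
#' @export
weighted_odds_ratio <- function(weights, outcome, conf_level = 0.95) {
  y <- as.numeric(outcome)
  if (!all(y %in% c(0, 1))) abort("outcome must be binary (0/1)")
  if (all(y == 0) || all(y == 1)) {
    abort("odds ratio undefined: outcome vector is degenerate")
  }
  if (any(weights < 0 | weights > 1)) abort("weights must lie in [0, 1]")
  a <- sum(weights[y == 1]); b <- sum(weights[y == 0])
  cc <- sum((1 - weights)[y == 1]); d <- sum((1 - weights)[y == 0])
  corrected <- any(c(a, b, cc, d) == 0)
  if (corrected) { a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5 }
  or <- (a * d) / (b * cc)
  zq <- qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  tibble::tibble(odds_ratio = or,
                 conf_low = exp(log(or) - zq * se),
                 conf_high = exp(log(or) + zq * se),
                 corrected = corrected)
}

#' Pathway distribution of the top-k fibres by T-value
#'
#' Ranks fibres by descending T (ties broken by ascending fiber_id) and
#' counts how many of the top k fall in each pathway — the summary used to
#' ask which pathways a metric associates with outcome improvement.
#'
#' @param stats a `fiber_stats` tibble (rows with `NA` T are dropped).
#' @param atlas the `fiber_atlas` supplying pathway labels.
#' @param k number of top fibres, default 100; when fewer fibres are
#'   available, all are used with a warning.
#' @return tibble of class `topk_distribution`: `pathway`, `n_fibers`,
#'   over all atlas pathways (zero counts included).
#' @export
top_fiber_distribution <- function(stats, atlas, k = 100) {
  st <- stats[!is.na(stats$t), ]
  if (nrow(st) < k) {
    warn(sprintf("only %d fibres with defined T; using all of them", nrow(st)))
    k <- nrow(st)
  }
  st <- st[order(-st$t, st$fiber_id), ]
  top <- head(st, k)
  info <- fiber_info(atlas)
  top$pathway <- info$pathway[match(top$fiber_id, info$fiber_id)]
  if (any(is.na(top$pathway))) abort("top fibres contain ids unknown to the atlas")
  out <- tibble::tibble(pathway = sort(unique(info$pathway))) |>
    dplyr::left_join(dplyr::count(top, .data$pathway, name = "n_fibers"),
                     by = "pathway") |>
    dplyr::mutate(n_fibers = dplyr::coalesce(.data$n_fibers, 0L))
  class(out) <- c("topk_distribution", class(out))
  out
}

#' Pool bilateral stimulations onto one hemisphere
#'
#' Assuming mirror-symmetric effects, left-hemisphere stimulations are
#' "mirrored": their activation entries are re-indexed onto the
#' corresponding right-hemisphere fibres via a mirror map (`left_id`,
#' `right_id`), so all stimulations can enter one fibre-wise analysis.
#'
#' @param activation long tibble: `stim_id`, `fiber_id`, `p_a`.
#' @param cohort tibble with `stim_id` and `hemisphere`.
#' @param mirror_map tibble with `left_id`, `right_id`.
#' @return the activation tibble with left-stimulation fiber_ids replaced
#'   by their right-hemisphere mirrors.
#' @export
mirror_stimulations <- function(activation, cohort, mirror_map) {
  hemi <- cohort$hemisphere[match(activation$stim_id, cohort$stim_id)]
  if (any(is.na(hemi))) abort("activation contains stim_ids missing from the cohort")
  left <- hemi == "left"
  idx <- match(activation$fiber_id[left], mirror_map$left_id)
  if (any(is.na(idx))) {
    abort("mirror map does not cover all left-hemisphere fiber_ids")
  }
  activation$fiber_id[left] <- mirror_map$right_id[idx]
  activation
}

#' Long activation records to a stimulations-by-fibres matrix
#' @param activation long tibble: `stim_id`, `fiber_id`, `p_a`.
#' @return numeric matrix, rows ordered by stim_id, columns by fiber_id;
#'   missing combinations are 0.
#' @export
activation_matrix <- function(activation) {
  wide <- activation |>
    dplyr::select("stim_id", "fiber_id", "p_a") |>
    dplyr::arrange(.data$stim_id) |>
    tidyr::pivot_wider(names_from = "fiber_id", values_from = "p_a",
                       values_fill = 0, names_sort = TRUE)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- as.character(wide$stim_id)
  m[is.na(m)] <- 0
  m
}
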