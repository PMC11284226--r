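# Nonparametric two-group / paired / k-group comparisons with exact
# enumeration for small samples (mid-ranks under ties throughout), plus
# delta-delta-Ct relative quantification. All tests are two-sided.

midranks <- function(x) rank(x, ties.method = "average")

tie_term <- function(r) {
  t <- table(r)
  sum(t^3 - t)
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum test for two independent samples. For samples of at most
#' `exact_max` each, the p-value is computed by exact enumeration of all
#' group assignments of the pooled mid-ranks (so ties are handled exactly);
#' otherwise a tie-corrected normal approximation is used. The reported
#' statistic is U for the first sample.
#'
#' @param sample_a,sample_b Numeric vectors.
#' @param exact_max Largest per-group size for the exact branch.
#' @return One-row tibble: `test`, `statistic`, `p_value`, `n_a`, `n_b`,
#'   `method`.
#' @export
mann_whitney <- function(sample_a, sample_b, exact_max = 8) {
  if (length(sample_a) == 0 || length(sample_b) == 0) {
    abort("both samples must be non-empty")
  }
  na <- length(sample_a); nb <- length(sample_b); n <- na + nb
  r <- midranks(c(sample_a, sample_b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if (max(na, nb) <= exact_max) {
    sets <- utils::combn(n, na)
    us <- apply(sets, 2, function(ix) sum(r[ix])) - na * (na + 1) / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-12)
    method <- "exact"
  } else {
    v <- na * nb / 12 * ((n + 1) - tie_term(r) / (n * (n - 1)))
    z <- (u - mu) / sqrt(v)
    p <- min(2 * pnorm(-abs(z)), 1)
    method <- "normal_approx"
  }
  tibble(test = "mann_whitney", statistic = u, p_value = p,
         n_a = na, n_b = nb, method = method)
}

#' Wilcoxon signed-rank test for paired samples (two-sided)
#'
#' Differences `after - before`; zero differences are dropped (Wilcoxon
#' convention), mid-ranks under tied magnitudes. Exact enumeration of all
#' sign patterns for at most `exact_max` non-zero differences, otherwise a
#' tie-corrected normal approximation. The statistic is the positive-rank
#' sum W+. All-zero differences give a degenerate (flagged) result.
#'
#' @param before,after Equal-length numeric vectors.
#' @param exact_max Largest number of non-zero differences enumerated.
#' @return One-row tibble: `test`, `statistic`, `p_value`, `n` (non-zero
#'   pairs), `method`, `degenerate`.
#' @export
wilcoxon_paired <- function(before, after, exact_max = 15) {
  stopifnot(length(before) == length(after))
  d <- after - before
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(tibble(test = "wilcoxon_signed_rank", statistic = NA_real_,
                  p_value = NA_real_, n = 0L, method = "degenerate",
                  degenerate = TRUE))
  }
  r <- midranks(abs(d))
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  if (n <= exact_max) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    ws <- as.numeric(signs %*% r)
    p <- mean(abs(ws - mu) >= abs(w - mu) - 1e-12)
    method <- "exact"
  } else {
    v <- n * (n + 1) * (2 * n + 1) / 24 - tie_term(r) / 48
    z <- (w - mu) / sqrt(v)
    p <- min(2 * pnorm(-abs(z)), 1)
    method <- "normal_approx"
  }
  tibble(test = "wilcoxon_signed_rank", statistic = w, p_value = p,
         n = n, method = method, degenerate = FALSE)
}

#' Kruskal-Wallis omnibus test with Dunn's post-hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H (via [stats::kruskal.test()]) followed by
#' Dunn's pairwise z-tests on the pooled mid-ranks, with Bonferroni
#' correction (p multiplied by the number of reported pairs, capped at 1)
#' by default.
#'
#' @param groups Named list of numeric vectors (>= 3 groups).
#' @param adjust Multiplicity adjustment passed to [stats::p.adjust()].
#' @return A `kruskal_dunn_result`: `omnibus` (one-row tibble with H, df,
#'   p) and `pairwise` (tibble: `group_a`, `group_b`, `z`, `p_value`,
#'   `p_adjusted`).
#' @export
kruskal_dunn <- function(groups, adjust = "bonferroni") {
  if (length(groups) < 3) abort("need at least 3 groups for the omnibus test")
  if (any(lengths(groups) == 0)) abort("empty group")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  kw <- kruskal.test(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  n <- length(x)
  r <- midranks(x)
  rbar <- tapply(r, g, mean)
  sizes <- lengths(groups)
  sig2 <- (n * (n + 1) / 12) - tie_term(r) / (12 * (n - 1))
  pairs <- utils::combn(names(groups), 2)
  pw <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    z <- (rbar[[a]] - rbar[[b]]) /
      sqrt(sig2 * (1 / sizes[[a]] + 1 / sizes[[b]]))
    tibble(group_a = a, group_b = b, z = z,
           p_value = 2 * pnorm(-abs(z)))
  })
  pw$p_adjusted <- p.adjust(pw$p_value, method = adjust)
  structure(list(
    omnibus = tibble(test = "kruskal_wallis",
                     statistic = unname(kw$statistic),
                     df = unname(kw$parameter),
                     p_value = kw$p.value,
                     n = n),
    pairwise = pw), class = "kruskal_dunn_result")
}

#' @export
print.kruskal_dunn_result <- function(x, ...) {
  cat(sprintf("<kruskal_dunn_result> H = %.4g, df = %d, p = %.4g\n",
              x$omnibus$statistic, x$omnibus$df, x$omnibus$p_value))
  print(x$pairwise)
  invisible(x)
}

#' @export
tidy.kruskal_dunn_result <- function(x, ...) x$pairwise

#' @export
glance.kruskal_dunn_result <- function(x, ...) x$omnibus

#' Relative quantification by the delta-delta-Ct method
#'
#' Ct replicates are averaged per (sample, target) first. Then, per sample,
#' delta-Ct = Ct(target) - Ct(reference gene); per target,
#' delta-delta-Ct = delta-Ct(sample) - delta-Ct(calibrator sample); and
#' RQ = 2^(-delta-delta-Ct). The calibrator sample has RQ = 1 exactly.
#'
#' @param ct_table Tibble with `sample`, `target`, `ct` (one row per
#'   replicate).
#' @param reference_gene Endogenous control gene (e.g. GAPDH).
#' @param calibrator_sample Sample every target is normalized to.
#' @return Tibble: `sample`, `target`, `ct_mean`, `delta_ct`,
#'   `delta_delta_ct`, `rq`.
#' @export
ddct_rq <- function(ct_table, reference_gene, calibrator_sample) {
  need <- c("sample", "target", "ct")
  if (!all(need %in% names(ct_table))) {
    abort("ct table needs columns sample, target, ct")
  }
  avg <- dplyr::summarise(dplyr::group_by(ct_table, .data$sample, .data$target),
                          ct_mean = mean(.data$ct), .groups = "drop")
  ref <- dplyr::filter(avg, .data$target == reference_gene)
  no_ref <- setdiff(unique(avg$sample), ref$sample)
  if (length(no_ref) > 0) {
    abort(paste0("reference gene missing for sample(s): ",
                 paste(no_ref, collapse = ", ")))
  }
  if (!calibrator_sample %in% avg$sample) {
    abort("calibrator sample not present in the table")
  }
  out <- dplyr::filter(avg, .data$target != reference_gene)
  out <- dplyr::left_join(out,
                          dplyr::select(ref, "sample", ref_ct = "ct_mean"),
                          by = "sample")
  out$delta_ct <- out$ct_mean - out$ref_ct
  cal <- dplyr::select(dplyr::filter(out, .data$sample == calibrator_sample),
                       "target", cal_delta_ct = "delta_ct")
  out <- dplyr::left_join(out, cal, by = "target")
  out$delta_delta_ct <- out$delta_ct - out$cal_delta_ct
  out$rq <- 2^(-out$delta_delta_ct)
  dplyr::select(out, "sample", "target", "ct_mean", "delta_ct",
                "delta_delta_ct", "rq")
}
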