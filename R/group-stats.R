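#' Null distribution of the Mann-Whitney U statistic by counting recursion
#'
#' Counts, for every value of U from 0 to `n1 * n2`, the number of rank
#' arrangements of two tie-free samples producing that U, via the standard
#' recursion `c(u; n1, n2) = c(u - n2; n1 - 1, n2) + c(u; n1, n2 - 1)`
#' (the largest pooled observation belongs to group 1 or group 2). The
#' counts sum to `choose(n1 + n2, n1)`.
#'
#' @param n1,n2 Group sizes, at least 1.
#' @return Numeric vector of length `n1 * n2 + 1`; element `u + 1` is the
#'   number of arrangements with U = u.
#' @export
mw_null_counts <- function(n1, n2) {
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  if (is.na(n1) || is.na(n2) || n1 < 1 || n2 < 1)
    stop("n1 and n2 must be integers >= 1", call. = FALSE)
  # f[[j + 1]] holds counts for sizes (i, j), updated as i grows
  f <- lapply(0:n2, function(j) 1)  # i = 0: all mass at U = 0
  for (i in seq_len(n1)) {
    g <- vector("list", n2 + 1L)
    g[[1]] <- 1  # j = 0: all mass at U = 0
    for (j in seq_len(n2)) {
      a <- f[[j + 1]]  # (i - 1, j), shifted by j
      b <- g[[j]]      # (i, j - 1)
      len <- i * j + 1L
      av <- c(rep(0, j), a)
      length(av) <- len; av[is.na(av)] <- 0
      bv <- b
      length(bv) <- len; bv[is.na(bv)] <- 0
      g[[j + 1]] <- av + bv
    }
    f <- g
  }
  f[[n2 + 1]]
}

#' Exact two-sided p-value for a Mann-Whitney U statistic
#'
#' Computes the exact two-sided tail probability of an observed U under
#' the tie-free null, from the full null distribution given by
#' [mw_null_counts()]. The two-sided rule is the classical doubled tail
#' including the observed point mass, capped at 1:
#' `p = min(1, 2 * min(P(U <= u), P(U >= u)))`.
#'
#' @param u Observed U, between 0 and `n1 * n2` (conventionally the
#'   smaller of the two orientations).
#' @param n1,n2 Group sizes.
#' @return The exact two-sided p-value.
#' @examples
#' exact_p_from_u(6, 7, 7)  # 0.0175
#' exact_p_from_u(7, 7, 7)  # 0.0262
#' exact_p_from_u(6, 8, 5)  # 0.0451
#' @export
exact_p_from_u <- function(u, n1, n2) {
  if (length(u) != 1 || is.na(u) || u < 0 || u > n1 * n2 || u != round(u))
    stop("u must be an integer in [0, n1 * n2]", call. = FALSE)
  counts <- mw_null_counts(n1, n2)
  total <- sum(counts)
  lo <- sum(counts[seq_len(u + 1)]) / total            # P(U <= u)
  hi <- sum(counts[(u + 1):length(counts)]) / total    # P(U >= u)
  min(1, 2 * min(lo, hi))
}

#' Exact Mann-Whitney U test for two small samples
#'
#' Rank-based two-sample test as used for between-cell-type comparisons of
#' small electrophysiology groups. U is computed from pooled ranks and
#' reported as the smaller of the two orientations. For tie-free data with
#' `n1 + n2 <= 30` the two-sided p-value is exact, from the full null
#' distribution of U ([mw_null_counts()], doubled-tail rule of
#' [exact_p_from_u()]). With ties (mid-ranks) the exact recursion does not
#' apply and a seeded permutation p-value is reported instead, defined as
#' the probability of a permuted min-orientation U at or below the
#' observed one.
#'
#' @param x,y Numeric samples, non-empty.
#' @param n_perm Number of permutations for the tie fallback (default
#'   1e5).
#' @param perm_seed Seed for the permutation fallback.
#' @return A `group_comparison`: `n1`, `n2`, `u_stat`, `p_two_sided`,
#'   `method` (`"exact"` or `"permutation"`), `tie_count` (pooled
#'   observations minus distinct values).
#' @examples
#' mann_whitney_exact(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mann_whitney_exact <- function(x, y, n_perm = 1e5, perm_seed = 1L) {
  if (length(x) < 1 || length(y) < 1)
    stop("both groups must be non-empty", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("all values must be finite", call. = FALSE)
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)  # mid-ranks under ties
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u <- min(u1, n1 * n2 - u1)
  tie_count <- length(pooled) - length(unique(pooled))
  if (tie_count == 0 && n1 + n2 <= 30) {
    p <- exact_p_from_u(round(u), n1, n2)
    method <- "exact"
  } else {
    n <- n1 + n2
    u_perm <- withr::with_seed(as.integer(perm_seed), {
      vapply(seq_len(n_perm), function(b) {
        idx <- sample.int(n, n1)
        ub1 <- sum(r[idx]) - n1 * (n1 + 1) / 2
        min(ub1, n1 * n2 - ub1)
      }, 0)
    })
    p <- (1 + sum(u_perm <= u)) / (n_perm + 1)
    method <- "permutation"
  }
  structure(
    list(n1 = n1, n2 = n2, u_stat = u, p_two_sided = p,
         method = method, tie_count = tie_count),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> n = %d vs %d: U = %g, p = %.4g (%s",
              x$n1, x$n2, x$u_stat, x$p_two_sided, x$method))
  if (x$tie_count > 0) cat(sprintf(", %d tied", x$tie_count))
  cat(")\n")
  invisible(x)
}

#' @export
as.data.frame.group_comparison <- function(x, ...) {
  data.frame(n1 = x$n1, n2 = x$n2, u_stat = x$u_stat,
             p_two_sided = x$p_two_sided, method = x$method,
             tie_count = x$tie_count,
             comparison = if (is.null(x$comparison)) "" else x$comparison,
             variable = if (is.null(x$variable)) "" else x$variable,
             stringsAsFactors = FALSE)
}

#' Mean and standard error of a group of values
#'
#' @param values Numeric vector, at least one value.
#' @return A `group_summary`: `mean`, `sem` (`sd / sqrt(n)`; `NA` for a
#'   single value, with `sem_defined = FALSE`), `n`.
#' @export
group_summary <- function(values) {
  if (length(values) < 1 || !all(is.finite(values)))
    stop("values must be non-empty and finite", call. = FALSE)
  n <- length(values)
  structure(
    list(mean = mean(values),
         sem = if (n > 1) stats::sd(values) / sqrt(n) else NA_real_,
         sem_defined = n > 1, n = n),
    class = "group_summary"
  )
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("%.6g +/- %s (n = %d)\n", x$mean,
              if (x$sem_defined) sprintf("%.6g", x$sem) else "NA", x$n))
  invisible(x)
}

#' Relative quantification by the 2^-ddCt method
#'
#' Standard qPCR relative quantification: the target gene's Ct is
#' normalized to a reference gene within each sample
#' (`dCt = Ct_target - Ct_reference`), the calibrator sample's dCt is
#' subtracted (`ddCt = dCt_sample - dCt_calibrator`), and the fold change
#' is `2^-ddCt`.
#'
#' @param ct_target_sample,ct_ref_sample Target and reference-gene Ct of
#'   the sample of interest.
#' @param ct_target_calibrator,ct_ref_calibrator Target and reference-gene
#'   Ct of the calibrator sample.
#' @return A `ddct_result`: `delta_ct_sample`, `delta_ct_calibrator`,
#'   `ddct`, `fold_change`.
#' @examples
#' ddct_fold_change(18, 20, 20, 20)$fold_change  # 4
#' @export
ddct_fold_change <- function(ct_target_sample, ct_ref_sample,
                             ct_target_calibrator, ct_ref_calibrator) {
  cts <- c(ct_target_sample, ct_ref_sample,
           ct_target_calibrator, ct_ref_calibrator)
  if (length(cts) != 4 || !all(is.finite(cts)))
    stop("all four Ct values must be single finite numbers", call. = FALSE)
  d_s <- ct_target_sample - ct_ref_sample
  d_c <- ct_target_calibrator - ct_ref_calibrator
  ddct <- d_s - d_c
  structure(
    list(delta_ct_sample = d_s, delta_ct_calibrator = d_c,
         ddct = ddct, fold_change = 2^(-ddct)),
    class = "ddct_result"
  )
}

#' Compare a per-cell result column between two groups
#'
#' Convenience wrapper used by the pipeline: pulls one numeric column out
#' of a per-cell results data.frame, splits it by group label, and runs
#' [mann_whitney_exact()].
#'
#' @param results_df Per-cell results (as written by
#'   [write_results_table()]).
#' @param variable Column to compare (e.g. `"tonic_current_pa"`).
#' @param groups Character vector of the two group labels to compare.
#' @param ... Passed to [mann_whitney_exact()].
#' @return A `group_comparison` annotated with `comparison` and
#'   `variable`.
#' @export
compare_groups <- function(results_df, variable, groups, ...) {
  stopifnot(is.data.frame(results_df), length(groups) == 2)
  if (!variable %in% names(results_df))
    stop("no column '", variable, "' in results", call. = FALSE)
  vals <- lapply(groups, function(g) {
    v <- results_df[[variable]][results_df$group_label == g]
    v <- v[is.finite(v)]
    if (length(v) == 0)
      stop("group '", g, "' has no finite values for '", variable, "'",
           call. = FALSE)
    v
  })
  cmp <- mann_whitney_exact(vals[[1]], vals[[2]], ...)
  cmp$comparison <- paste(groups, collapse = " vs ")
  cmp$variable <- variable
  cmp
}
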