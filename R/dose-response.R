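# Dose-response validation: exact rank-sum testing and the
# minimum-effective-dose call.
#
# Validation assays run a handful of replicate wells per (dose, E:T ratio)
# cell, so asymptotic rank tests are meaningless; the exact null is obtained
# by full enumeration of all C(nA+nB, nA) rank assignments, which is cheap
# for group sizes up to 10. Ties are handled with mid-ranks, enumerating the
# observed tie pattern.

#' Exact Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Enumerates every assignment of the pooled mid-ranks to group A and
#' compares the observed rank-sum of A against the resulting exact null.
#' The two-tailed p-value uses the tail-doubling convention
#' `min(1, 2 * min(P(W <= w), P(W >= w)))`. One-sided tail probabilities are
#' returned as well for directional hypotheses.
#'
#' @param group_a,group_b Numeric vectors, 2 to 10 values each.
#' @return A list of class `rank_sum_result`: `statistic` (rank-sum of
#'   `group_a`), `p_two_tailed`, `p_greater` (P of a rank-sum at least as
#'   large, i.e. evidence that A > B), `p_less`, and `method` (`"exact"` or
#'   `"midrank_exact"` when ties are present).
#' @export
#' @examples
#' rank_sum_exact(c(1, 2, 3), c(4, 5, 6))$p_two_tailed # 0.1
rank_sum_exact <- function(group_a, group_b) {
  na <- length(group_a)
  nb <- length(group_b)
  if (na < 2 || nb < 2) {
    stop("each group needs at least 2 values for an exact rank-sum test",
         call. = FALSE)
  }
  if (na > 10 || nb > 10) {
    stop("exact enumeration supports group sizes up to 10; ",
         "use an approximate rank test for larger groups", call. = FALSE)
  }
  pooled <- c(group_a, group_b)
  if (any(!is.finite(pooled))) {
    stop("group values must be finite", call. = FALSE)
  }
  r <- rank(pooled) # mid-ranks under ties
  w <- sum(r[seq_len(na)])
  has_ties <- anyDuplicated(pooled) > 0

  combs <- utils::combn(na + nb, na)
  sums <- colSums(matrix(r[combs], nrow = na))
  eps <- 1e-9
  p_le <- mean(sums <= w + eps)
  p_ge <- mean(sums >= w - eps)

  structure(
    list(statistic = w,
         p_two_tailed = min(1, 2 * min(p_le, p_ge)),
         p_greater = p_ge,
         p_less = p_le,
         method = if (has_ties) "midrank_exact" else "exact"),
    class = "rank_sum_result"
  )
}

#' Percent-lysis table of a dose-response experiment
#'
#' Converts long-format luminescence rows into percent specific lysis per
#' (drug, dose, E:T ratio, replicate). Rows are tagged by `role`:
#' `experimental` (effector + target wells, one per dose/ratio/replicate),
#' `spontaneous` (target-alone wells; matched to the same dose when
#' dose-specific rows exist, so direct drug toxicity is absorbed into the
#' baseline, otherwise pooled), and `maximal` (digitonin wells, pooled).
#'
#' @param reads Tibble with columns `drug_id`, `dose_uM`, `et_ratio`,
#'   `replicate`, `role`, `rlu`.
#' @return A `dose_response` tibble: `drug_id`, `dose_uM`, `et_ratio`,
#'   `replicate`, `percent_lysis`, `flag`.
#' @export
dose_response_lysis <- function(reads) {
  need <- c("drug_id", "dose_uM", "et_ratio", "replicate", "role", "rlu")
  stopifnot(all(need %in% names(reads)))
  exp_rows <- dplyr::filter(reads, .data$role == "experimental")
  spont_rows <- dplyr::filter(reads, .data$role == "spontaneous")
  max_rows <- dplyr::filter(reads, .data$role == "maximal")
  if (nrow(spont_rows) == 0 || nrow(max_rows) == 0) {
    stop("dose-response reads need spontaneous and maximal control rows",
         call. = FALSE)
  }
  out <- dplyr::bind_rows(lapply(split(exp_rows, exp_rows$drug_id),
                                 function(d) {
    drug <- d$drug_id[1]
    if (!0 %in% d$dose_uM) {
      stop("dose 0 (vehicle control) missing for drug ", drug, call. = FALSE)
    }
    sp <- dplyr::filter(spont_rows, .data$drug_id == drug)
    mx <- dplyr::filter(max_rows, .data$drug_id == drug)
    if (nrow(mx) == 0) mx <- max_rows
    maximal <- mean(mx$rlu)
    spont_for_dose <- function(dose) {
      sel <- sp$rlu[sp$dose_uM == dose]
      if (length(sel) > 0) mean(sel) else mean(sp$rlu)
    }
    d$percent_lysis <- vapply(seq_len(nrow(d)), function(i) {
      specific_lysis(d$rlu[i], spont_for_dose(d$dose_uM[i]), maximal)
    }, numeric(1))
    d
  }))
  out$flag <- lysis_flags(out$percent_lysis)
  out <- dplyr::select(out, "drug_id", "dose_uM", "et_ratio", "replicate",
                       "percent_lysis", "flag")
  class(out) <- c("dose_response", class(out))
  out
}

#' Per-cell summary of a dose-response table
#'
#' @param dr A `dose_response` tibble from [dose_response_lysis()].
#' @return Tibble with `mean_lysis`, `sd_lysis`, `n` per
#'   (drug, dose, ratio).
#' @export
dose_response_summary <- function(dr) {
  dplyr::summarise(
    dplyr::group_by(dr, .data$drug_id, .data$dose_uM, .data$et_ratio),
    mean_lysis = mean(.data$percent_lysis),
    sd_lysis = stats::sd(.data$percent_lysis),
    n = dplyr::n(),
    .groups = "drop"
  )
}

#' Minimum effective dose
#'
#' For each (drug, E:T ratio), the minimum effective dose (MED) is the
#' smallest non-zero dose whose replicate lysis values exceed the dose-0
#' (vehicle) replicates both statistically and by a biologically relevant
#' margin. "Effective" is an enhancement claim, so the statistical call is
#' directional: the one-sided exact rank-sum tail probability (`p_greater`)
#' must be <= `alpha`. In addition the mean lysis increase over vehicle
#' must exceed `min_effect` percentage points; requiring a relevance margin
#' on top of significance is the standard guard in minimum-effective-dose
#' definitions, and matters here because an exact rank test on a handful of
#' replicates sits at its own significance boundary (with triplicates the
#' smallest attainable one-sided p is exactly 1/20 = 0.05, so a null dose
#' would otherwise be called effective with probability `alpha`). With
#' `min_effect = 0` the call reduces to pure significance with a positive
#' mean difference. A two-tailed criterion (`tail = "two_sided"`) is
#' available but cannot reject at alpha 0.05 with fewer than 4 replicates
#' per cell.
#'
#' @param dr A `dose_response` tibble from [dose_response_lysis()].
#' @param alpha Significance level (default 0.05).
#' @param tail `"greater"` (directional, default) or `"two_sided"`.
#' @param min_effect Relevance margin: minimum mean increase in percent
#'   specific lysis over vehicle (default 5 percentage points, on the order
#'   of the technical-replicate noise band of the assay).
#' @return Tibble per (drug, ratio): `minimum_effective_dose` (NA when no
#'   dose qualifies), `alpha`, `tail`, `min_effect`.
#' @export
minimum_effective_dose <- function(dr, alpha = 0.05,
                                   tail = c("greater", "two_sided"),
                                   min_effect = 5) {
  tail <- match.arg(tail)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  keys <- dplyr::distinct(dr, .data$drug_id, .data$et_ratio)
  dplyr::bind_rows(lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    cell <- dplyr::filter(dr, .data$drug_id == k$drug_id,
                          .data$et_ratio == k$et_ratio)
    base <- cell$percent_lysis[cell$dose_uM == 0]
    if (length(base) < 2) {
      stop("need >= 2 dose-0 replicates for drug ", k$drug_id,
           " at E:T ", k$et_ratio, call. = FALSE)
    }
    doses <- sort(unique(cell$dose_uM[cell$dose_uM > 0]))
    med <- NA_real_
    for (dose in doses) {
      treated <- cell$percent_lysis[cell$dose_uM == dose]
      if (length(treated) < 2) {
        stop("need >= 2 replicates at dose ", dose, " for drug ", k$drug_id,
             call. = FALSE)
      }
      rs <- rank_sum_exact(treated, base)
      p <- if (tail == "greater") rs$p_greater else rs$p_two_tailed
      if (p <= alpha && mean(treated) - mean(base) > min_effect) {
        med <- dose
        break
      }
    }
    tibble::tibble(drug_id = k$drug_id, et_ratio = k$et_ratio,
                   minimum_effective_dose = med, alpha = alpha, tail = tail,
                   min_effect = min_effect)
  }))
}
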