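#' Transcripts-per-million normalization
#'
#' TPM = count / total clean reads of the library × 10^6, so the TPM of a
#' whole library sums to 10^6.
#'
#' @param count nonnegative read count(s).
#' @param total_clean_reads positive library total.
#' @return numeric TPM value(s).
#' @export
compute_tpm <- function(count, total_clean_reads) {
  if (any(total_clean_reads <= 0)) {
    stop("total_clean_reads must be > 0", call. = FALSE)
  }
  if (any(count < 0)) stop("count must be >= 0", call. = FALSE)
  count / total_clean_reads * 1e6
}

# Log point probabilities log p(y'|x) for y' = 0..upto, given r = N2/N1.
# p(y|x) = r^y (x+y)! / (x! y! (1+r)^(x+y+1))
ac_log_terms <- function(x, r, upto) {
  yv <- 0:upto
  yv * log(r) + lgamma(x + yv + 1) - lgamma(x + 1) - lgamma(yv + 1) -
    (x + yv + 1) * log1p(r)
}

# log(sum(exp(lp))) with max-shift for relative precision.
logsumexp <- function(lp) {
  m <- max(lp)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lp - m)))
}

# All three quantities for one x and a vector of y, sharing one term row.
# Sums are computed on max-scaled probabilities, so tiny tails keep their
# full relative precision (the largest term of each tail dominates it).
ac_tail_prob_row <- function(x, ys, n1, n2) {
  r <- n2 / n1
  # p(.|x) is negative binomial (size x+1, prob 1/(1+r)); truncate the
  # upper sum where the remaining mass is < 1e-17 of the total
  qup <- stats::qnbinom(1e-17, size = x + 1, prob = 1 / (1 + r),
                        lower.tail = FALSE)
  upto <- max(c(ys, qup)) + 50
  lp <- ac_log_terms(x, r, upto)
  m <- max(lp)
  sc <- exp(lp - m)
  lower <- cumsum(sc)
  upper <- rev(cumsum(rev(sc)))
  cbind(p_point = exp(lp[ys + 1]),
        C = pmin(1, exp(m) * lower[ys + 1]),
        D = pmin(1, exp(m) * upper[ys + 1]))
}

#' Exact two-library count test: point probability and tails
#'
#' For a sequence observed `x` times in a baseline library of `N1` clean
#' reads and `y` times in a second library of `N2`, the conditional
#' probability of `y` given `x` is
#' \deqn{p(y|x) = (N2/N1)^y \frac{(x+y)!}{x!\,y!\,(1+N2/N1)^{x+y+1}}}
#' (a negative-binomial law derived from independent Poisson sampling).
#' `C` is the lower tail (sum for y' from 0 to y inclusive) and `D` the
#' upper tail (y' from y to infinity); both include the observed point so
#' `C + D = 1 + p_point`. All sums are done in log space; tiny tails keep
#' full relative precision because the upper tail is summed directly
#' rather than via 1 - C.
#'
#' @param x,y observed counts (vectors recycle).
#' @param n1,n2 library totals (clean reads).
#' @return tibble with columns `x`, `y`, `p_point`, `C`, `D`.
#' @export
ac_tail_prob <- function(x, y, n1, n2) {
  stopifnot(all(x >= 0), all(y >= 0), all(n1 > 0), all(n2 > 0))
  m <- max(length(x), length(y), length(n1), length(n2))
  x <- rep_len(x, m); y <- rep_len(y, m)
  n1 <- rep_len(n1, m); n2 <- rep_len(n2, m)
  out <- matrix(NA_real_, m, 3)
  key <- paste(x, n1, n2)
  for (idx in split(seq_len(m), key)) {
    out[idx, ] <- ac_tail_prob_row(x[idx[1]], y[idx], n1[idx[1]], n2[idx[1]])
  }
  tibble(x = x, y = y, p_point = out[, 1], C = out[, 2], D = out[, 3])
}

#' Two-sided p-value of the exact count test
#'
#' Doubles the smaller tail and caps at 1; `sided = "one"` returns the
#' smaller tail itself.
#'
#' @inheritParams ac_tail_prob
#' @param sided `"two"` (default) or `"one"`.
#' @return numeric vector of p-values in \[0, 1\].
#' @export
ac_pvalue <- function(x, y, n1, n2, sided = c("two", "one")) {
  sided <- match.arg(sided)
  tails <- ac_tail_prob(x, y, n1, n2)
  p1 <- pmin(tails$C, tails$D)
  if (sided == "one") pmin(1, p1) else pmin(1, 2 * p1)
}

#' Log2 fold-change with zero-count pseudo handling
#'
#' log2(treatment / control) on TPM values; when either operand is zero a
#' pseudo-TPM is added to both so undetectable stages stay finite without
#' perturbing nonzero ratios.
#'
#' @param tpm_treat,tpm_ctrl TPM values (vectors recycle).
#' @param pseudo pseudo-TPM applied only when an operand is zero
#'   (default 0.01).
#' @return numeric log2 fold-changes.
#' @export
log2_fold_change <- function(tpm_treat, tpm_ctrl, pseudo = 0.01) {
  stopifnot(pseudo > 0)
  zero <- tpm_treat == 0 | tpm_ctrl == 0
  add <- ifelse(zero, pseudo, 0)
  log2((tpm_treat + add) / (tpm_ctrl + add))
}

#' Differential expression scan against a baseline stage
#'
#' Runs the exact two-library count test for every feature at every
#' non-baseline stage versus the baseline, with TPM-based log2
#' fold-changes. Single-library designs (no replicates) are the intended
#' use; significance is on raw p-values by default, mirroring common
#' practice for staged sRNA libraries (a BH option is available).
#'
#' @param counts tibble with an id column (first column) and one integer
#'   count column per stage.
#' @param totals named vector of per-stage total clean reads. Defaults to
#'   column sums of `counts`, which is correct only if `counts` covers the
#'   whole library.
#' @param baseline stage (column) name serving as control.
#' @param alpha significance threshold on p (default 0.05).
#' @param pseudo pseudo-TPM for zero counts (default 0.01).
#' @param sided tail handling, see [ac_pvalue()].
#' @param adjust `"none"` (default) or `"BH"`.
#' @return a `de_result` object; see [tidy.de_result()].
#' @export
de_scan <- function(counts, totals = NULL, baseline, alpha = 0.05,
                    pseudo = 0.01, sided = c("two", "one"),
                    adjust = c("none", "BH")) {
  sided <- match.arg(sided)
  adjust <- match.arg(adjust)
  id_col <- names(counts)[1]
  stages <- setdiff(names(counts), id_col)
  if (length(stages) < 2) stop("need >= 2 stage columns", call. = FALSE)
  if (!baseline %in% stages) {
    stop("baseline stage '", baseline, "' not among columns", call. = FALSE)
  }
  totals <- totals %||% colSums(counts[, stages, drop = FALSE])
  if (!all(stages %in% names(totals))) {
    stop("totals must be named for every stage", call. = FALSE)
  }

  tpm <- counts
  for (s in stages) tpm[[s]] <- compute_tpm(counts[[s]], totals[[s]])

  others <- setdiff(stages, baseline)
  tab <- purrr::map_dfr(others, function(s) {
    p <- ac_pvalue(counts[[baseline]], counts[[s]],
                   totals[[baseline]], totals[[s]], sided = sided)
    tibble(
      !!id_col := counts[[id_col]],
      comparison = paste0(s, "_vs_", baseline),
      stage = s,
      x = counts[[baseline]],
      y = counts[[s]],
      n1 = unname(totals[[baseline]]),
      n2 = unname(totals[[s]]),
      p_value = p,
      log2fc = log2_fold_change(tpm[[s]], tpm[[baseline]], pseudo = pseudo)
    )
  })
  if (adjust == "BH") {
    tab <- tab |>
      group_by(.data$comparison) |>
      mutate(p_adj = stats::p.adjust(.data$p_value, "BH")) |>
      ungroup()
    tab$significant <- tab$p_adj < alpha
  } else {
    tab$significant <- tab$p_value < alpha
  }
  structure(
    list(table = tab, tpm = tpm, counts = counts, totals = totals,
         baseline = baseline, alpha = alpha, id_col = id_col,
         stages = stages),
    class = "de_result"
  )
}

#' @export
print.de_result <- function(x, ...) {
  g <- glance(x)
  cat("Differential expression vs ", x$baseline,
      " (exact count test, alpha = ", x$alpha, ")\n", sep = "")
  cat("  features: ", nrow(x$counts), "; DE in >= 1 comparison: ",
      sum(de_any(x)), "\n", sep = "")
  print(as.data.frame(g), row.names = FALSE)
  invisible(x)
}

# Logical: feature significant in at least one comparison.
de_any <- function(de) {
  sig <- de$table |>
    group_by(.data[[de$id_col]]) |>
    summarise(any_sig = any(.data$significant), .groups = "drop")
  sig$any_sig[match(de$counts[[de$id_col]], sig[[de$id_col]])]
}

#' Tidy a differential expression result
#'
#' @param x a `de_result`.
#' @param ... unused.
#' @return one row per feature x comparison: counts, library totals,
#'   p-value, log2 fold-change and significance flag.
#' @export
tidy.de_result <- function(x, ...) x$table

#' One-row-per-comparison summary of a DE result
#'
#' @param x a `de_result`.
#' @param ... unused.
#' @return tibble with significant / up / down counts per comparison
#'   (direction by log2 fold-change sign among significant features).
#' @export
glance.de_result <- function(x, ...) {
  x$table |>
    group_by(.data$comparison) |>
    summarise(
      n = dplyr::n(),
      significant = sum(.data$significant),
      up = sum(.data$significant & .data$log2fc > 0),
      down = sum(.data$significant & .data$log2fc < 0),
      .groups = "drop"
    )
}

#' @export
autoplot.de_result <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$log2fc,
                               y = -log10(pmax(.data$p_value, 1e-300)),
                               colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::facet_wrap(~comparison) +
    ggplot2::labs(x = "log2 fold-change vs baseline", y = "-log10 p") +
    ggplot2::theme_minimal()
}

#' Keep highly expressed features
#'
#' Retains features whose TPM reaches `tpm_min` in at least one stage
#' (inclusive boundary). With `de_only = TRUE` also requires significance
#' in at least one comparison.
#'
#' @param de a `de_result`.
#' @param tpm_min TPM threshold (default 20).
#' @param de_only additionally require DE in >= 1 comparison
#'   (default FALSE).
#' @return a filtered `de_result`.
#' @export
filter_high_expression <- function(de, tpm_min = 20, de_only = FALSE) {
  stopifnot(inherits(de, "de_result"))
  mx <- do.call(pmax, de$tpm[de$stages])
  keep <- mx >= tpm_min
  if (de_only) keep <- keep & de_any(de)
  ids <- de$counts[[de$id_col]][keep]
  de$counts <- de$counts[keep, , drop = FALSE]
  de$tpm <- de$tpm[keep, , drop = FALSE]
  de$table <- de$table[de$table[[de$id_col]] %in% ids, , drop = FALSE]
  de
}
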