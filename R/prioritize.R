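#' Per-sample tumor / adjacent-normal fold change
#'
#' Raw ratio `tumor / adjacent` with a pseudocount `eps` added only to
#' zero terms; a pair where both members are zero does not contribute
#' (returned as `NA`). `log2_mode` returns the log2 of the ratio.
#'
#' @param tumor,adjacent Non-negative expression values (FPKM scale),
#'   vectorized.
#' @param eps Pseudocount for zero terms (default 0.01).
#' @param log2_mode Return log2 ratios (default `FALSE`).
#' @return Numeric vector; `NA` for non-expressed pairs.
#' @examples
#' sample_fold_change(10, 5)          # 2
#' sample_fold_change(4, 0)           # 400 with the default eps
#' sample_fold_change(0, 0)           # NA: pair does not contribute
#' @export
sample_fold_change <- function(tumor, adjacent, eps = 0.01,
                               log2_mode = FALSE) {
  stopifnot(eps > 0)
  if (any(tumor < 0) || any(adjacent < 0)) stop("expression values must be non-negative")
  num <- ifelse(tumor == 0, eps, tumor)
  den <- ifelse(adjacent == 0, eps, adjacent)
  fc <- num / den
  fc[tumor == 0 & adjacent == 0] <- NA_real_
  if (log2_mode) log2(fc) else fc
}

#' Candidate-prioritization score for one STR
#'
#' The score is the sum over samples of the tumor/adjacent fold change,
#' multiplied by the number of samples that expressed the STR. It rewards
#' STRs that are consistently differentially expressed and/or expressed in
#' many samples. "Expressed" means nonzero in either member of the pair
#' (set `expressed = "tumor"` to count tumor-only expression).
#'
#' @param tumor,adjacent Numeric vectors, one entry per paired sample.
#' @param eps,log2_mode Passed to [sample_fold_change()].
#' @param expressed `"either"` (default) or `"tumor"`.
#' @return A list: `n_expressed`, `sum_fold_change`, `score`
#'   (`= sum_fold_change * n_expressed`).
#' @export
priority_score <- function(tumor, adjacent, eps = 0.01, log2_mode = FALSE,
                           expressed = c("either", "tumor")) {
  expressed <- match.arg(expressed)
  stopifnot(length(tumor) == length(adjacent), length(tumor) >= 1L)
  fc <- sample_fold_change(tumor, adjacent, eps, log2_mode)
  n_expr <- if (expressed == "either") {
    sum(tumor > 0 | adjacent > 0)
  } else {
    sum(tumor > 0)
  }
  s <- sum(fc, na.rm = TRUE)
  list(n_expressed = n_expr, sum_fold_change = s, score = s * n_expr)
}

#' Score a table of paired STR expression values
#'
#' @param pairs `data.frame` with `str_id`, `sample_id`, `tumor`,
#'   `adjacent`.
#' @inheritParams priority_score
#' @return `data.frame` with `str_id`, `n_expressed`, `sum_fold_change`,
#'   `score`, `rank` (1 = highest score; ties by `str_id`).
#' @export
score_all <- function(pairs, eps = 0.01, log2_mode = FALSE,
                      expressed = "either") {
  sp <- split(pairs, pairs$str_id)
  rows <- lapply(names(sp), function(id) {
    p <- sp[[id]]
    stopifnot(!anyDuplicated(p$sample_id))
    sc <- priority_score(p$tumor, p$adjacent, eps, log2_mode, expressed)
    data.frame(str_id = id, n_expressed = sc$n_expressed,
               sum_fold_change = sc$sum_fold_change, score = sc$score,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$str_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Pick the top and bottom candidates by priority score
#'
#' @param scores `data.frame` with `str_id` and `score` (e.g. from
#'   [score_all()]).
#' @param k Number of candidates per tail (default 4).
#' @return A list with `top` and `bottom`: `str_id`s of the `k` largest
#'   and `k` smallest scores. Ties are broken by lexicographic `str_id`
#'   for determinism.
#' @export
select_candidates <- function(scores, k = 4L) {
  if (nrow(scores) < 2L * k) stop("need at least 2k scored STRs")
  up <- scores[order(-scores$score, scores$str_id), , drop = FALSE]
  dn <- scores[order(scores$score, scores$str_id), , drop = FALSE]
  list(top = up$str_id[seq_len(k)], bottom = dn$str_id[seq_len(k)])
}
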