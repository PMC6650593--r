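# Local similarity analysis: series preparation (interpolation + normal
# scores), the banded DP score, permutation p-values, and the all-pairs
# driver over one (site, depth) series set.

#' Fill gaps in a monthly series by linear interpolation
#'
#' Interior missing months are filled linearly on the month index;
#' leading/trailing gaps take the nearest observed value (linear
#' interpolation is undefined outside the observed span).
#'
#' @param values numeric vector with `NA` at missing months, one entry
#'   per month of a complete monthly grid.
#' @return Numeric vector with no missing values; attribute
#'   `interpolated_mask` marks filled positions.
#' @export
interpolate_series <- function(values) {
  obs <- which(!is.na(values))
  if (length(obs) < 2L) stop("need at least 2 observed time points")
  out <- approx(obs, values[obs], xout = seq_along(values),
                method = "linear", rule = 2)$y
  attr(out, "interpolated_mask") <- is.na(values)
  out
}

#' Normal-score (rank) transform
#'
#' Ranks with average ties, mapped through the standard normal quantile
#' function: \eqn{\Phi^{-1}(r_i / (n + 1))}. Any strictly increasing
#' transform of the input yields identical output; a constant series maps
#' to all zeros.
#'
#' @param values complete numeric vector.
#' @return Transformed numeric vector.
#' @export
normal_score_transform <- function(values) {
  stopifnot(all(is.finite(values)))
  n <- length(values)
  qnorm(rank(values, ties.method = "average") / (n + 1))
}

#' Prepare all series of one (site, depth) set for LSA
#'
#' Lays each feature on the complete monthly grid spanning the set,
#' interpolates gaps and applies the normal-score transform.
#'
#' @param series_table an [abundance_table()] holding a single
#'   (site, depth) series (see [split_series()]).
#' @return months x features numeric matrix of transformed series.
#' @export
prepare_series <- function(series_table) {
  mi <- month_index(series_table$samples$date)
  grid <- seq(min(mi), max(mi))
  pos <- match(mi, grid)
  out <- matrix(NA_real_, length(grid), ncol(series_table$values),
                dimnames = list(sprintf("%04d-%02d", grid %/% 12, grid %% 12 + 1),
                                colnames(series_table$values)))
  out[pos, ] <- series_table$values
  apply(out, 2, function(v) normal_score_transform(interpolate_series(v)))
}

#' Local similarity score of two prepared series
#'
#' Banded dynamic program over positive and negative partial sums of
#' products: the score is the largest partial sum over any contiguous
#' aligned segment with offset at most `D` months, divided by the series
#' length. Ties are broken towards smaller |delay|, then positive sign,
#' then earliest alignment start.
#'
#' @param x,y equal-length numeric vectors (normal-scored).
#' @param D maximum |delay| in months (`D < n`).
#' @return One-row data.frame: `ls`, `sign` (`"+"`/`"-"`), `delay`
#'   (positive: `y` lags `x`), `start_a`, `start_b`, `length`.
#' @export
local_similarity_score <- function(x, y, D = 1) {
  r <- ls_dp_cpp(as.numeric(x), as.numeric(y), as.integer(D))
  data.frame(ls = r$ls, sign = if (r$sign > 0) "+" else "-",
             delay = r$delay, start_a = r$start_a, start_b = r$start_b,
             length = r$length, stringsAsFactors = FALSE)
}

make_perms <- function(n, n_perm) {
  vapply(seq_len(n_perm), function(i) sample.int(n) - 1L, integer(n))
}

#' Permutation p-value for a local similarity score
#'
#' Permutes the time order of `y` (holding `x` fixed), recomputes the
#' score, and returns the add-one estimator
#' \eqn{p = (1 + \#\{LS_{perm} \ge LS_{obs}\}) / (1 + n_{perm})}.
#' The smallest attainable p is `1 / (n_perm + 1)`.
#'
#' @param x,y prepared series.
#' @param D delay limit.
#' @param n_perm number of permutations (default 2000, so p < 0.001 is
#'   attainable).
#' @param seed RNG seed.
#' @param alpha optional downstream significance level; a warning (and
#'   attribute `refused = TRUE`) is raised when `n_perm` cannot reach it.
#' @return Numeric p-value in (0, 1].
#' @export
permutation_p_value <- function(x, y, D = 1, n_perm = 2000, seed = 1,
                                alpha = NULL) {
  refused <- FALSE
  if (!is.null(alpha) && 1 / (n_perm + 1) > alpha) {
    warning("n_perm = ", n_perm, " cannot attain p < ", alpha)
    refused <- TRUE
  }
  set.seed(seed)
  perms <- make_perms(length(x), n_perm)
  obs <- ls_dp_cpp(as.numeric(x), as.numeric(y), as.integer(D))
  cnt <- ls_perm_count_cpp(as.numeric(x), as.numeric(y), as.integer(D),
                           perms, obs$ls * length(x))
  p <- (1 + cnt) / (1 + n_perm)
  if (refused) attr(p, "refused") <- TRUE
  p
}

#' All-pairs local similarity analysis over one series set
#'
#' Computes one association per unordered feature pair (OTUs and
#' environmental variables alike), with permutation p-values. One shared
#' set of time permutations, drawn from `seed`, is used for every pair,
#' which keeps the whole scan deterministic and independent of pair
#' enumeration order.
#'
#' @param series_table single-(site, depth) [abundance_table()].
#' @param D delay limit in months (default 1).
#' @param n_perm permutations for the p-value (default 2000).
#' @param seed RNG seed.
#' @param fdr also append Benjamini-Hochberg `q` values (default FALSE;
#'   downstream screening uses raw p-values).
#' @return data.frame of associations: `feature_a`, `feature_b`, `ls`,
#'   `sign`, `delay`, `start_a`, `start_b`, `length`, `p` (and `q`).
#' @export
all_pairs_lsa <- function(series_table, D = 1, n_perm = 2000, seed = 1,
                          fdr = FALSE) {
  prep <- prepare_series(series_table)
  feats <- sort(colnames(prep))
  prep <- prep[, feats, drop = FALSE]
  n <- nrow(prep)
  if (D >= n) stop("delay limit D must be smaller than the series length")
  set.seed(seed)
  perms <- make_perms(n, n_perm)
  pairs <- combn(length(feats), 2)
  res <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    obs <- ls_dp_cpp(prep[, i], prep[, j], as.integer(D))
    cnt <- ls_perm_count_cpp(prep[, i], prep[, j], as.integer(D),
                             perms, obs$ls * n)
    res[[k]] <- data.frame(feature_a = feats[i], feature_b = feats[j],
                           ls = obs$ls,
                           sign = if (obs$sign > 0) "+" else "-",
                           delay = obs$delay, start_a = obs$start_a,
                           start_b = obs$start_b, length = obs$length,
                           p = (1 + cnt) / (1 + n_perm),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (fdr) out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
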