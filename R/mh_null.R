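# Random-joining microhomology null model and enrichment test.
#
# Under blunt random joining of two independent sequences, microhomology can
# extend on either side of the seam. On each side the number of matching
# bases is geometric with per-base match probability p = sum(f_b^2) over the
# base composition f (p = 1/4 for uniform composition). The two sides are
# independent, so total microhomology K = L + R has the negative-binomial
# form P(K = k) = (k + 1) (1 - p)^2 p^k. In particular
# P(K = 0) = (1 - p)^2 = 9/16 and P(K >= 1) = 7/16 = 43.75% for uniform
# composition.

match_prob <- function(composition) {
  if (is.null(composition)) return(0.25)
  if (abs(sum(composition) - 1) > 1e-8) {
    abort("base composition must sum to 1")
  }
  if (any(composition < 0)) abort("base composition must be non-negative")
  sum(composition^2)
}

#' Microhomology null distribution under random joining
#'
#' Probability mass function of the total two-sided microhomology length at
#' a junction formed by blunt random joining of independent sequences, for
#' `k = 0, 1, ..., max_k`. Mass beyond `max_k` is folded into the last bin so
#' the pmf sums to exactly 1 (the fold is below `p^max_k`, negligible for
#' windows of a few tens of bp).
#'
#' @param max_k largest microhomology length tabulated (>= 1).
#' @param composition optional named base frequencies (must sum to 1);
#'   `NULL` means uniform. Only the per-base match probability
#'   `p = sum(f^2)` enters the null.
#' @return tibble with columns `k` and `prob`, classed `mh_null`.
#' @export
#' @examples
#' mh_null_pmf(5)                 # P(k = 0) = 0.5625
#' 1 - mh_null_pmf(5)$prob[1]     # P(k >= 1) = 0.4375, i.e. 44% rounded
mh_null_pmf <- function(max_k = 20, composition = NULL) {
  if (max_k < 1) abort("max_k must be >= 1")
  p <- match_prob(composition)
  k <- 0:max_k
  prob <- (k + 1) * (1 - p)^2 * p^k
  prob[length(prob)] <- 1 - sum(prob[-length(prob)])
  out <- tibble(k = k, prob = prob)
  class(out) <- unique(c("mh_null", class(out)))
  out
}

#' P(microhomology >= 1) under the random-joining null
#'
#' @inheritParams mh_null_pmf
#' @return scalar probability (0.4375 for uniform composition).
#' @export
mh_null_p_any <- function(composition = NULL) {
  p <- match_prob(composition)
  1 - (1 - p)^2
}

#' Monte-Carlo fraction of random joins with microhomology
#'
#' Simulates `n` blunt joins of independent random flanks, calls two-sided
#' microhomology with the same primitive used on real junctions, and returns
#' the fraction with microhomology >= 1. Twin of the analytic
#' [mh_null_p_any()].
#'
#' @param n number of simulated joins.
#' @param seed RNG seed (fixed seed gives identical output).
#' @param composition optional named base frequencies (`A`, `C`, `G`, `T`);
#'   `NULL` = uniform.
#' @param window flank window used by the caller, bp.
#' @return scalar fraction in `[0, 1]`.
#' @export
mh_null_fraction_mc <- function(n, seed = 1, composition = NULL, window = 50) {
  if (n < 1) abort("n must be >= 1")
  mh <- mh_null_mc_lengths(n, seed, composition, window)
  mean(mh >= 1)
}

# Monte-Carlo two-sided microhomology lengths for n random joins.
mh_null_mc_lengths <- function(n, seed = 1, composition = NULL, window = 50) {
  probs <- if (is.null(composition)) rep(0.25, 4) else
    composition[c("A", "C", "G", "T")]
  if (abs(sum(probs) - 1) > 1e-8) abort("base composition must sum to 1")
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      # each join: two independent flank pairs, one per side of the seam
      rand <- function() paste(sample(c("A", "C", "G", "T"), window,
                                      replace = TRUE, prob = probs),
                               collapse = "")
      genome <- list(cA = paste0(rand(), rand()), cB = paste0(rand(), rand()))
      m <- mh_between(genome, "cA", window, "+", "cB", window + 1, "-",
                      max_window = window)
      as.integer(m$mh_left + m$mh_right)
    }, integer(1))
  })
}

#' Exact enrichment test for microhomology at junctions
#'
#' Tests whether the observed fraction of junctions with microhomology
#' (mh >= 1) exceeds the random-joining expectation, with an exact one-sided
#' binomial test, and tabulates observed vs expected counts per
#' microhomology length.
#'
#' @param mh_len integer vector of per-junction microhomology lengths
#'   (insertion-free junctions).
#' @param composition optional base composition for the null.
#' @param max_k largest length tabulated in the observed/expected table.
#' @return object of class `mh_enrichment`: list with `estimate` (observed
#'   fraction mh >= 1), `null_p` (expected fraction), `n`, `k`, `p.value`
#'   (exact, conservative), `midp` (mid-p, the calibrated tail quantity of
#'   a discrete test), and `table` (per-k observed and expected counts).
#' @export
mh_enrichment_test <- function(mh_len, composition = NULL, max_k = NULL) {
  mh_len <- mh_len[!is.na(mh_len)]
  n <- length(mh_len)
  if (n == 0) abort("no junctions supplied to the enrichment test")
  p0 <- mh_null_p_any(composition)
  k <- sum(mh_len >= 1)
  bt <- binom.test(k, n, p = p0, alternative = "greater")
  # mid-p: the calibrated tail quantity of a discrete exact test (the raw
  # exact p is conservative by construction)
  midp <- stats::pbinom(k, n, p0, lower.tail = FALSE) +
    0.5 * stats::dbinom(k, n, p0)
  max_k <- max_k %||% max(5, max(mh_len))
  pmf <- mh_null_pmf(max_k, composition)
  obs <- vapply(pmf$k, function(kk) {
    if (kk < max_k) sum(mh_len == kk) else sum(mh_len >= kk)
  }, numeric(1))
  tab <- tibble(k = pmf$k, observed = obs, expected = pmf$prob * n,
                expected_frac = pmf$prob)
  structure(list(estimate = k / n, null_p = p0, n = n, k = k,
                 p.value = bt$p.value, midp = midp, conf.int = bt$conf.int,
                 table = tab),
            class = "mh_enrichment")
}

#' @export
print.mh_enrichment <- function(x, ...) {
  cat("Microhomology enrichment vs random joining\n")
  cat(sprintf("  observed mh>=1: %d/%d (%.1f%%), expected %.2f%%\n",
              x$k, x$n, 100 * x$estimate, 100 * x$null_p))
  cat(sprintf("  one-sided exact binomial p = %.3g\n", x$p.value))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname mh_enrichment_test
#' @param x an `mh_enrichment` object.
#' @param ... unused.
#' @export
tidy.mh_enrichment <- function(x, ...) x$table

#' @rdname mh_enrichment_test
#' @export
glance.mh_enrichment <- function(x, ...) {
  tibble(n = x$n, n_mh = x$k, estimate = x$estimate, null_p = x$null_p,
         p.value = x$p.value)
}

#' Observed-vs-expected microhomology table
#'
#' Convenience wrapper returning the per-length observed and expected counts
#' (the classic grouped-bar comparison of junction microhomology against the
#' random-joining expectation).
#'
#' @inheritParams mh_enrichment_test
#' @return tibble with `k`, `observed`, `expected`, `expected_frac`.
#' @export
mh_expected_table <- function(mh_len, composition = NULL, max_k = NULL) {
  tidy(mh_enrichment_test(mh_len, composition, max_k))
}
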