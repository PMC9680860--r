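#' Expected genotype-class frequencies for a backcross generation
#'
#' For an individual produced by an interspecific F1 cross followed by `g`
#' backcrosses to the recurrent parent (species A), the expected
#' frequencies of the three diagnostic-site classes are
#' \deqn{q_{AA} = (1-p_{error})(1-2^{-g}),\quad
#'       q_{Aa} = (1-p_{error})\,2^{-g},\quad
#'       q_{aa} = p_{error},}
#' where `p_error` absorbs genotyping error and mis-ascribed fixed
#' differences (the "impossible" aa class). `g = 1` gives the single
#' backcross (BC1F1) row `((1-p)/2, (1-p)/2, p)` and `g = 2` the double
#' backcross (BC2F1) row `(3(1-p)/4, (1-p)/4, p)`; `g = 0` (F1) makes the
#' AA class impossible.
#'
#' @param g Backcross generation, integer >= 0 (0 = F1, 1 = BC1F1, ...).
#' @param p_error Error-class probability in `[0, 1)`.
#' @return Named numeric vector `c(q_AA=, q_Aa=, q_aa=)`, summing to 1.
#' @export
expected_frequencies <- function(g, p_error) {
  if (!is.numeric(g) || length(g) != 1L || g < 0 || g != round(g))
    stop("g must be a non-negative integer")
  if (!is.numeric(p_error) || length(p_error) != 1L ||
      p_error < 0 || p_error >= 1)
    stop("p_error must lie in [0, 1)")
  c(q_AA = (1 - p_error) * (1 - 2^(-g)),
    q_Aa = (1 - p_error) * 2^(-g),
    q_aa = p_error)
}

#' Build a backcross-generation model
#'
#' @inheritParams expected_frequencies
#' @return List of class `backcross_model`: `generation`, `p_error`, `q`
#'   (see [expected_frequencies()]) and a display `label` (`F1`, `BC1F1`,
#'   `BC2F1`, ...).
#' @export
backcross_model <- function(g, p_error) {
  q <- expected_frequencies(g, p_error)
  structure(
    list(generation = as.integer(g), p_error = p_error, q = q,
         label = if (g == 0) "F1" else sprintf("BC%dF1", as.integer(g))),
    class = "backcross_model"
  )
}

#' @export
print.backcross_model <- function(x, ...) {
  cat("<backcross_model>", x$label, " p_error =", x$p_error,
      " q = (", paste(format(x$q, digits = 4), collapse = ", "), ")\n")
  invisible(x)
}

#' Multinomial log-likelihood of observed class counts under a model
#'
#' \deqn{\ln L = \ln\frac{(N_{AA}+N_{Aa}+N_{aa})!}{N_{AA}!\,N_{Aa}!\,N_{aa}!}
#'   + N_{AA}\ln q_{AA} + N_{Aa}\ln q_{Aa} + N_{aa}\ln q_{aa}.}
#' Factorials are evaluated exactly through `lgamma` (no Stirling
#' approximation), and the multinomial coefficient is included, so reported
#' values are full multinomial log-pmfs. A class with expected frequency 0
#' but a positive count yields `-Inf` (an impossible model), returned as a
#' value rather than an error so model ranking can proceed.
#'
#' @param counts Numeric vector `(N_AA, N_Aa, N_aa)` of non-negative
#'   integers with positive total.
#' @param model A [backcross_model()].
#' @return The log-likelihood (scalar; possibly `-Inf`).
#' @export
log_likelihood <- function(counts, model) {
  counts <- check_counts(counts)
  q <- model$q
  lnl <- lgamma(sum(counts) + 1) - sum(lgamma(counts + 1))
  for (k in 1:3) {
    if (counts[k] > 0) {
      if (q[k] == 0) return(-Inf)
      lnl <- lnl + counts[k] * log(q[k])
    }
  }
  unname(lnl)
}

check_counts <- function(counts) {
  if (length(counts) != 3L || !is.numeric(counts) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("counts must be three non-negative integers (N_AA, N_Aa, N_aa)")
  if (sum(counts) <= 0) stop("total count must be positive")
  as.numeric(counts)
}

#' Estimate the error-class probability from observed counts
#'
#' The observed frequency of the aa class, `N_aa / total`, unrounded. This
#' is the natural plug-in for `p_error` (the aa class is impossible under a
#' pure backcross-to-A pedigree, so its mass is attributed to error);
#' callers may override it with a fixed value.
#'
#' @param counts `(N_AA, N_Aa, N_aa)`.
#' @return The estimate in `[0, 1]`.
#' @export
estimate_error_rate <- function(counts) {
  counts <- check_counts(counts)
  p <- counts[3] / sum(counts)
  if (p >= 1)
    warning("all observations fall in the error class; p_error estimate is degenerate")
  unname(p)
}

#' Compare backcross-generation models by likelihood
#'
#' Evaluates the multinomial log-likelihood of the observed class counts
#' under each requested generation, ranks the models, and reports the
#' log-likelihood gap between the top two together with the statistic
#' `2 * delta_lnL` and a heuristic chi-square p-value (df = 1). The
#' chi-square reference is labelled heuristic because the generation models
#' are non-nested point hypotheses; [bootstrap_pvalue()] gives the
#' recommended inferential statement.
#'
#' @param counts `(N_AA, N_Aa, N_aa)`.
#' @param generations Integer vector of generations to fit (>= 2 values;
#'   default `c(1, 2)`).
#' @param p_error Error-class probability shared by all models; default
#'   `NULL` uses [estimate_error_rate()] on the counts.
#' @param bootstrap Number of parametric-bootstrap replicates comparing the
#'   best model against the runner-up (0 = skip).
#' @param seed Optional seed for the bootstrap.
#' @return List of class `model_comparison`: `table` (per-model data.frame
#'   with generation, label, q's and lnL, ranked), `best`, `runner_up`,
#'   `delta_lnL`, `lrt` (= 2 delta), `p_chisq_heuristic`, `p_bootstrap`
#'   (NA unless requested), `p_error`, `counts`.
#' @export
compare_models <- function(counts, generations = c(1, 2), p_error = NULL,
                           bootstrap = 0, seed = NULL) {
  counts <- check_counts(counts)
  generations <- unique(as.integer(generations))
  if (length(generations) < 2L)
    stop("model comparison needs >= 2 generations")
  if (is.null(p_error)) p_error <- estimate_error_rate(counts)
  models <- lapply(generations, backcross_model, p_error = p_error)
  lnl <- vapply(models, function(m) log_likelihood(counts, m), 0)
  tab <- data.frame(
    generation = generations,
    model = vapply(models, `[[`, "", "label"),
    q_AA = vapply(models, function(m) m$q[["q_AA"]], 0),
    q_Aa = vapply(models, function(m) m$q[["q_Aa"]], 0),
    q_aa = vapply(models, function(m) m$q[["q_aa"]], 0),
    lnL = lnl,
    stringsAsFactors = FALSE
  )
  tab <- tab[order(-tab$lnL), ]
  rownames(tab) <- NULL
  delta <- tab$lnL[1] - tab$lnL[2]
  lrt <- 2 * delta
  p_boot <- NA_real_
  if (bootstrap > 0) {
    null_m <- backcross_model(tab$generation[2], p_error)
    alt_m <- backcross_model(tab$generation[1], p_error)
    p_boot <- bootstrap_pvalue(counts, null_m, alt_m,
                               n_reps = bootstrap, seed = seed)
  }
  structure(
    list(table = tab, best = tab$model[1], runner_up = tab$model[2],
         delta_lnL = delta, lrt = lrt,
         p_chisq_heuristic = if (is.finite(lrt))
           stats::pchisq(lrt, df = 1, lower.tail = FALSE) else 0,
         p_bootstrap = p_boot, p_error = p_error, counts = counts),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Backcross-generation model comparison\n")
  cat(sprintf("  counts: N_AA=%d N_Aa=%d N_aa=%d  (p_error = %.6g)\n",
              x$counts[1], x$counts[2], x$counts[3], x$p_error))
  print(x$table, digits = 8)
  cat(sprintf("  best: %s  delta_lnL = %.2f  2*delta = %.2f\n",
              x$best, x$delta_lnL, x$lrt))
  cat(sprintf("  heuristic chi-square p (df=1): %.3g\n", x$p_chisq_heuristic))
  if (!is.na(x$p_bootstrap))
    cat(sprintf("  parametric bootstrap p: %.4g\n", x$p_bootstrap))
  invisible(x)
}

#' Parametric bootstrap p-value for one model against another
#'
#' Simulates class counts from the null model (multinomial with the
#' observed total), recomputes `2 * (lnL_alt - lnL_null)` on each
#' replicate, and reports the fraction of replicates at least as large as
#' the observed statistic. Reproducible under a fixed seed.
#'
#' @param counts Observed `(N_AA, N_Aa, N_aa)`.
#' @param null_model,alt_model [backcross_model()] objects.
#' @param n_reps Number of replicates (>= 100).
#' @param seed Optional integer seed.
#' @return The bootstrap p-value (resolution `1/n_reps`).
#' @export
bootstrap_pvalue <- function(counts, null_model, alt_model, n_reps = 1000,
                             seed = NULL) {
  counts <- check_counts(counts)
  if (n_reps < 100) stop("n_reps must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  obs <- 2 * (log_likelihood(counts, alt_model) -
              log_likelihood(counts, null_model))
  sims <- stats::rmultinom(n_reps, size = sum(counts), prob = null_model$q)
  stat <- apply(sims, 2, function(cnt) {
    2 * (log_likelihood(cnt, alt_model) - log_likelihood(cnt, null_model))
  })
  mean(stat >= obs)
}
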