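#' Invert the trigamma function
#'
#' Solves `trigamma(y) = x` for `y > 0` by Newton iteration. trigamma is
#' strictly decreasing from +Inf to 0 on (0, Inf), so the root is unique.
#'
#' @param x Positive numeric vector.
#' @param tol Convergence tolerance on the step (default 1e-8).
#' @return `y` with `trigamma(y) == x` (elementwise).
#' @keywords internal
trigamma_inverse <- function(x, tol = 1e-8) {
  y <- 0.5 + 1 / x
  for (iter in 1:100) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (max(abs(dif / y)) < tol) break
  }
  y
}

#' Fit the empirical-Bayes variance prior
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s0sq` of
#' a scaled inverse-chi-square prior on the true per-protein variances, by
#' matching the mean and variance of `log(s_g^2)` to the theoretical log-F
#' moments (digamma/trigamma moment equations). If the empirical dispersion
#' of the log variances does not exceed the pure sampling (trigamma) term,
#' the prior is degenerate: `d0 = Inf` and every posterior variance equals
#' `s0sq`. Posterior (shrunken) variances follow
#' `(d0 * s0sq + d_g * s_g^2) / (d0 + d_g)`.
#'
#' @param sample_variances Per-protein residual variances `s_g^2` (>= 0;
#'   at least two must be positive).
#' @param residual_df Residual degrees of freedom, scalar or per protein.
#' @return An object of class `EBayesModel`: list with `d0`, `s0sq`,
#'   `posterior_variances` and `residual_df`.
#' @export
fit_ebayes <- function(sample_variances, residual_df) {
  s2 <- as.numeric(sample_variances)
  d <- rep_len(as.numeric(residual_df), length(s2))
  if (length(s2) < 2L) stop("need at least 2 variances to fit the prior")
  if (all(s2 <= 0)) stop("all sample variances are zero; degenerate input")
  ok <- s2 > 0 & is.finite(s2) & d >= 1
  if (sum(ok) < 2L) stop("fewer than 2 usable positive variances")

  z <- log(s2[ok])
  e <- z - digamma(d[ok] / 2) + log(d[ok] / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (length(e) - 1L) - mean(trigamma(d[ok] / 2))

  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    if (d0 > 1e6) d0 <- Inf
  } else {
    d0 <- Inf
  }
  s0sq <- if (is.finite(d0)) {
    exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    exp(emean)
  }

  post <- .posterior_variance(s2, d, d0, s0sq)
  structure(list(d0 = d0, s0sq = s0sq, posterior_variances = post,
                 residual_df = d),
            class = "EBayesModel")
}

.posterior_variance <- function(s2, d, d0, s0sq) {
  if (!is.finite(d0)) return(rep_len(s0sq, length(s2)))
  if (d0 == 0) return(s2)
  (d0 * s0sq + d * s2) / (d0 + d)
}

#' @export
print.EBayesModel <- function(x, ...) {
  cat(sprintf("EBayesModel: d0 = %s, s0^2 = %.4g (%d proteins)\n",
              format(x$d0), x$s0sq, length(x$posterior_variances)))
  invisible(x)
}

# row variances with n-1 denominator; matrix rows are proteins
.row_var <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1L)
}

#' Moderated two-sample t-test
#'
#' Tests, per protein, mean(case) - mean(control) on the log2 scale using a
#' variance-moderated t-statistic: the pooled two-sample variance `s_g^2`
#' (with `d_g = n_case + n_control - 2` residual df) is shrunk toward the
#' empirical-Bayes prior, and the statistic
#' `t = log2_fc / sqrt(s_post^2 * (1/n_case + 1/n_control))`
#' is referred to a t distribution with `d_g + d0` degrees of freedom
#' (two-sided). With `d0 = 0` this is exactly the classical pooled t-test.
#'
#' @param case,control Numeric matrices (proteins x replicates, matching
#'   rownames) or vectors (treated as a single protein). At least two
#'   complete replicates per side are required.
#' @param model Optional `EBayesModel` supplying `d0` and `s0sq`; by default
#'   the prior is fitted on this contrast's pooled variances.
#' @param contrast_id Label stored in the result.
#' @return data.frame with columns `protein_id`, `contrast_id`, `log2_fc`,
#'   `t`, `df_total`, `p_value`.
#' @export
moderated_t <- function(case, control, model = NULL, contrast_id = "contrast") {
  if (is.null(dim(case))) case <- matrix(case, nrow = 1L,
                                         dimnames = list("protein", NULL))
  if (is.null(dim(control))) control <- matrix(control, nrow = 1L,
                                               dimnames = list("protein", NULL))
  if (nrow(case) != nrow(control)) stop("case/control row mismatch")
  n1 <- ncol(case)
  n2 <- ncol(control)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 replicates per side")
  if (anyNA(case) || anyNA(control)) {
    stop("missing values present; impute before testing")
  }

  fc <- rowMeans(case) - rowMeans(control)
  d <- n1 + n2 - 2L
  s2 <- ((n1 - 1L) * .row_var(case) + (n2 - 1L) * .row_var(control)) / d
  if (is.null(model)) model <- fit_ebayes(s2, d)
  post <- .posterior_variance(s2, rep_len(d, length(s2)), model$d0, model$s0sq)

  se <- sqrt(post * (1 / n1 + 1 / n2))
  t <- ifelse(se > 0, fc / se, ifelse(fc == 0, 0, sign(fc) * Inf))
  df_total <- d + model$d0
  p <- 2 * stats::pt(-abs(t), df = df_total)
  p[t == 0] <- 1
  data.frame(protein_id = rownames(case), contrast_id = contrast_id,
             log2_fc = fc, t = t, df_total = df_total, p_value = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Computes q-values controlling the false discovery rate:
#' `q_(k) = min_{j >= k} m * p_(j) / j` over the ascending order statistics,
#' capped at 1, returned in the input order (ties share a q-value).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  desc <- order(p, decreasing = TRUE)
  back <- order(desc)
  pmin(1, cummin(m / (m:1) * p[desc]))[back]
}

# shared contrast runner: moderated t + BH within the contrast family,
# significance = q < fdr (and positive fold change when require_up)
.run_contrast <- function(values, case_cols, ctrl_cols, contrast_id, fdr,
                          require_up = TRUE) {
  res <- moderated_t(values[, case_cols, drop = FALSE],
                     values[, ctrl_cols, drop = FALSE],
                     contrast_id = contrast_id)
  res$q_value <- bh_adjust(res$p_value)
  res$direction <- ifelse(res$log2_fc >= 0, "up", "down")
  res$significant <- res$q_value < fdr &
    (if (require_up) res$log2_fc > 0 else TRUE)
  res
}

#' Write contrast results as TSV
#'
#' @param results A contrast-result data.frame (from [run_prisma()],
#'   [ptm_differential()] or the BioID callers).
#' @param path Output TSV path.
#' @export
write_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
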