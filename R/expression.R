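#' Transcript-by-sample count matrix
#'
#' @param counts matrix of non-negative integers, transcripts in rows,
#'   samples in columns; dimnames supply transcript and sample ids.
#' @param lengths per-transcript length (nt).
#' @return an object of class \code{count_matrix}.
#' @export
count_matrix <- function(counts, lengths) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == length(lengths), all(lengths >= 1),
            all(counts >= 0))
  if (is.null(rownames(counts)) && nrow(counts))
    rownames(counts) <- paste0("transcript_", seq_len(nrow(counts)))
  if (is.null(colnames(counts)) && ncol(counts))
    colnames(counts) <- paste0("sample_", seq_len(ncol(counts)))
  structure(list(counts = counts, lengths = as.integer(lengths),
                 transcript_ids = rownames(counts),
                 sample_ids = colnames(counts)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d transcripts x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

as_counts <- function(x) {
  if (inherits(x, "count_matrix")) return(x)
  if (is.matrix(x)) return(count_matrix(x, rep(1L, nrow(x))))
  stop_dn("expected a count_matrix or matrix",
          class = "denovotx_validation_error")
}

#' Upper-quartile normalization factors
#'
#' Each sample's factor is its nearest-rank upper quartile of non-zero
#' transcript counts, divided by the geometric mean of those upper quartiles
#' across samples, so that dividing a sample's counts by its factor
#' equalizes upper quartiles.
#'
#' @param matrix a [count_matrix()] (or plain matrix).
#' @return object of class \code{norm_factors} with fields
#'   \code{per_sample_factor}, \code{upper_quartile} and \code{method}.
#' @export
#' @examples
#' m <- count_matrix(cbind(a = c(1, 5, 10), b = c(2, 10, 20)), c(100, 100, 100))
#' upper_quartile_factors(m)$per_sample_factor
upper_quartile_factors <- function(matrix) {
  cm <- as_counts(matrix)
  uq <- apply(cm$counts, 2, function(x) {
    nz <- sort(x[x > 0])
    if (length(nz) == 0L) return(NA_real_)
    nz[ceiling(0.75 * length(nz))]
  })
  if (anyNA(uq))
    stop_dn("sample '%s' has no non-zero counts",
            cm$sample_ids[which(is.na(uq))[1]],
            class = "denovotx_validation_error")
  fac <- uq / exp(mean(log(uq)))
  structure(list(per_sample_factor = setNames(fac, cm$sample_ids),
                 upper_quartile = setNames(uq, cm$sample_ids),
                 method = "upper-quartile"),
            class = "norm_factors")
}

#' @export
print.norm_factors <- function(x, ...) {
  cat("<norm_factors> upper-quartile; factors:\n")
  print(round(x$per_sample_factor, 4))
  invisible(x)
}

#' RPKM-like transcript abundance
#'
#' Reads per transcript divided by transcript length (in kb) and the
#' sample's upper-quartile normalization factor. The per-million normalizer
#' of classical RPKM is replaced by the more robust upper quartile of
#' transcript expression, so values are reads per kilobase per
#' upper-quartile unit; \code{scale} rescales all samples jointly.
#'
#' @param matrix a [count_matrix()].
#' @param factors a \code{norm_factors} object from
#'   [upper_quartile_factors()].
#' @param scale fixed positive constant applied to every value (default 1).
#' @return matrix of abundances, transcripts x samples.
#' @export
abundance <- function(matrix, factors, scale = 1) {
  cm <- as_counts(matrix)
  stopifnot(inherits(factors, "norm_factors"),
            length(factors$per_sample_factor) == ncol(cm$counts),
            scale > 0)
  denom <- outer(cm$lengths / 1000, factors$per_sample_factor * scale)
  cm$counts / denom
}

#' Smooth mean-variance model for normalized counts
#'
#' Per-transcript means and variances of normalized counts are computed
#' within each condition having replicates (all samples pooled as
#' pseudo-replicates when no condition has them), then a locally weighted
#' linear regression of log variance on log mean (tricube weights, bandwidth
#' a fixed fraction of the data span) yields a smooth variance function,
#' clamped below at the Poisson line (variance >= mean).
#'
#' @param matrix a [count_matrix()].
#' @param factors a \code{norm_factors} object.
#' @param condition_labels per-sample condition assignment (character or
#'   factor); \code{NULL} pools all samples.
#' @param bandwidth local-regression bandwidth as a fraction of the span of
#'   log means (default 0.3).
#' @return object of class \code{variance_model}; use [predict_variance()]
#'   to evaluate it.
#' @export
fit_variance <- function(matrix, factors, condition_labels = NULL,
                         bandwidth = 0.3) {
  cm <- as_counts(matrix)
  stopifnot(ncol(cm$counts) >= 2)
  norm <- sweep(cm$counts, 2, factors$per_sample_factor, "/")
  groups <- if (is.null(condition_labels)) list(seq_len(ncol(norm))) else
    split(seq_len(ncol(norm)), condition_labels)
  groups <- groups[lengths(groups) >= 2]
  if (length(groups) == 0L) groups <- list(seq_len(ncol(norm)))
  mu <- vv <- numeric()
  for (g in groups) {
    sub <- norm[, g, drop = FALSE]
    mu <- c(mu, rowMeans(sub))
    vv <- c(vv, apply(sub, 1, var))
  }
  # zero sample variances stay in: s^2 is unbiased for sigma^2 point by
  # point, and dropping the zeros would bias the local fit upward at small
  # replicate numbers
  ok <- is.finite(mu) & is.finite(vv) & mu > 0
  xs <- log(mu[ok]); ys <- vv[ok]
  if (sum(ok) < 2 || sum(ys > 0) < 2) {
    warning("fewer than 2 usable mean-variance points; falling back to a Poisson model")
    return(structure(list(type = "poisson", n_points = sum(ok),
                          bandwidth = bandwidth),
                     class = "variance_model"))
  }
  # Raw sample variances are unbiased but extremely noisy at small replicate
  # numbers, and log-transforming them point-wise biases a log-scale fit
  # downward (E[log s^2] < log sigma^2). Average them on the natural scale
  # within narrow quantile bins of log mean first — the bins are narrow
  # enough that curvature within a bin is negligible — then put the tricube
  # local-linear fit through the binned points in log-log space, where a
  # power-law mean-variance relationship is linear.
  nb <- max(10L, min(100L, as.integer(length(xs) / 40)))
  qs <- unique(stats::quantile(xs, probs = seq(0, 1, length.out = nb + 1)))
  bin <- cut(xs, qs, include.lowest = TRUE)
  bx <- tapply(xs, bin, mean)
  by <- tapply(ys, bin, mean)
  keep <- is.finite(bx) & is.finite(by) & by > 0
  x <- as.numeric(bx[keep]); y <- log(as.numeric(by[keep]))
  if (length(x) < 2) {
    warning("fewer than 2 usable mean-variance points; falling back to a Poisson model")
    return(structure(list(type = "poisson", n_points = sum(ok),
                          bandwidth = bandwidth),
                     class = "variance_model"))
  }
  h <- bandwidth * (max(x) - min(x))
  if (h <= 0) h <- 1
  grid <- seq(min(x), max(x), length.out = 50L)
  fit <- vapply(grid, function(g) {
    w <- (1 - pmin(abs(x - g) / h, 1)^3)^3
    if (sum(w > 0) < 2) {
      nearest <- order(abs(x - g))[1:2]
      w <- numeric(length(x)); w[nearest] <- 1
    }
    xw <- x - g
    sw <- sum(w); swx <- sum(w * xw); swx2 <- sum(w * xw^2)
    swy <- sum(w * y); swxy <- sum(w * xw * y)
    det <- sw * swx2 - swx^2
    if (abs(det) < 1e-12) swy / sw else
      (swx2 * swy - swx * swxy) / det  # local intercept at g
  }, numeric(1))
  structure(list(type = "loclin", grid = grid, fit = fit,
                 n_points = sum(ok), bandwidth = bandwidth),
            class = "variance_model")
}

#' Predict the smoothed variance of a normalized count
#'
#' @param model a \code{variance_model} from [fit_variance()], or
#'   \code{NULL}/a single numeric: \code{NULL} means pure Poisson
#'   (variance = mean) and a numeric value \code{d} means a fixed-dispersion
#'   negative binomial (variance = mean + d mean^2).
#' @param mean vector of means (normalized scale).
#' @return predicted variances, never below \code{mean}.
#' @export
predict_variance <- function(model, mean) {
  if (is.null(model)) return(mean)
  if (is.numeric(model) && length(model) == 1L)
    return(mean + model * mean^2)
  stopifnot(inherits(model, "variance_model"))
  if (model$type == "poisson") return(mean)
  v <- exp(approx(model$grid, model$fit, xout = log(pmax(mean, 1e-300)),
                  rule = 2)$y)
  pmax(v, mean)
}

#' @export
print.variance_model <- function(x, ...) {
  cat(sprintf("<variance_model> %s fit on %d points (bandwidth %.2f)\n",
              x$type, x$n_points, x$bandwidth))
  invisible(x)
}

nb_pmf <- function(x, mu, v) {
  if (mu <= 0) return(as.numeric(x == 0))
  if (v <= mu * (1 + 1e-8)) dpois(x, mu) else
    dnbinom(x, size = mu^2 / (v - mu), mu = mu)
}

#' Negative-binomial exact test for differential expression
#'
#' Conditional test in the style of DESeq: given the observed total
#' \eqn{K = K_A + K_B} of size-adjusted condition sums, the p-value is the
#' probability, under the null of equal expression, of any split \eqn{(a,b)}
#' with \eqn{a + b = K} that is no more likely than the observed one:
#' \deqn{p = \frac{\sum_{a+b=K,\; P(a)P(b) \le P(K_A)P(K_B)} P(a)P(b)}
#'             {\sum_{a+b=K} P(a)P(b)}}
#' where each condition sum is modeled as negative binomial with mean the
#' pooled normalized mean scaled by the condition's summed size factors and
#' variance from the smoothed mean-variance model (Poisson limit when the
#' fitted variance does not exceed the mean).
#'
#' @param counts_a,counts_b raw per-replicate counts in each condition.
#' @param factors_a,factors_b per-replicate normalization (size) factors;
#'   default 1 for every replicate.
#' @param model variance model as accepted by [predict_variance()].
#' @return p-value in \code{[0, 1]}.
#' @export
#' @examples
#' nb_test(c(10, 12), c(30, 28))   # suggestive difference
#' nb_test(c(20, 20), c(20, 20))   # identical observations: p = 1
nb_test <- function(counts_a, counts_b,
                    factors_a = rep(1, length(counts_a)),
                    factors_b = rep(1, length(counts_b)),
                    model = NULL) {
  stopifnot(length(counts_a) >= 1, length(counts_b) >= 1,
            length(factors_a) == length(counts_a),
            length(factors_b) == length(counts_b))
  ka <- sum(counts_a); kb <- sum(counts_b)
  if (ka + kb == 0) return(1)
  q0 <- mean(c(counts_a / factors_a, counts_b / factors_b))
  mu_a <- q0 * sum(factors_a); mu_b <- q0 * sum(factors_b)
  v0 <- predict_variance(model, q0)
  var_a <- sum(factors_a^2) * v0; var_b <- sum(factors_b^2) * v0
  K <- ka + kb
  a <- 0:K
  joint <- nb_pmf(a, mu_a, var_a) * nb_pmf(K - a, mu_b, var_b)
  tot <- sum(joint)
  if (tot <= 0) return(1)
  obs <- joint[ka + 1]
  min(sum(joint[joint <= obs * (1 + 1e-7)]) / tot, 1)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment mapped back to the input order:
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} \, n / j}, capped at 1.
#'
#' @param p_values numeric vector of p-values in \code{[0, 1]}.
#' @return q-values in input order.
#' @export
bh_correct <- function(p_values) {
  if (length(p_values) == 0L) return(numeric())
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop_dn("p-values must lie in [0, 1]",
            class = "denovotx_validation_error")
  p.adjust(p_values, method = "BH")
}

#' Two-condition differential expression analysis
#'
#' Convenience pipeline: upper-quartile normalization, pooled variance
#' smoothing, per-transcript negative-binomial exact tests, and
#' Benjamini-Hochberg correction.
#'
#' @param matrix a [count_matrix()].
#' @param conditions per-sample condition labels (exactly two distinct).
#' @return data frame with columns \code{transcript_id}, \code{meanA},
#'   \code{meanB} (normalized condition means), \code{pValue},
#'   \code{qValue}.
#' @export
diff_expression <- function(matrix, conditions) {
  cm <- as_counts(matrix)
  conditions <- as.character(conditions)
  stopifnot(length(conditions) == ncol(cm$counts))
  lev <- unique(conditions)
  if (length(lev) != 2)
    stop_dn("exactly two conditions are required, found %d", length(lev),
            class = "denovotx_validation_error")
  fac <- upper_quartile_factors(cm)
  model <- fit_variance(cm, fac, condition_labels = conditions)
  ia <- which(conditions == lev[1]); ib <- which(conditions == lev[2])
  f <- fac$per_sample_factor
  norm <- sweep(cm$counts, 2, f, "/")
  p <- vapply(seq_len(nrow(cm$counts)), function(i) {
    nb_test(cm$counts[i, ia], cm$counts[i, ib], f[ia], f[ib], model)
  }, numeric(1))
  data.frame(transcript_id = cm$transcript_ids,
             meanA = rowMeans(norm[, ia, drop = FALSE]),
             meanB = rowMeans(norm[, ib, drop = FALSE]),
             pValue = p, qValue = bh_correct(p),
             stringsAsFactors = FALSE)
}
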