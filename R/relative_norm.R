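#' Scaled read proportions of repeat types across chromatin marks
#'
#' For datasets without an input library, enrichment is normalized against
#' the other marks: the starting point is the percentage of each mark's
#' reads assigned to each repeat type, `100 * s / S`.
#'
#' @param counts Integer matrix of assigned read counts, repeat types in
#'   rows, marks in columns (rownames/colnames required).
#' @param sizes Named numeric vector of effective dataset sizes `S`, one per
#'   mark (names matching the columns of `counts`).
#' @return A `MarkProportionTable`: list with matrices `s`, vector `S` and
#'   matrix `ratio` (percentages on the 0-100 scale).
#' @export
build_proportions <- function(counts, sizes) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  sizes <- sizes[colnames(counts)]
  if (anyNA(sizes)) stop("sizes must be named for every mark in counts")
  if (any(sizes <= 0)) stop("dataset size S must be positive for every mark")
  if (any(counts < 0) || any(t(counts) > sizes)) {
    stop("counts must satisfy 0 <= s <= S")
  }
  ratio <- sweep(counts, 2, sizes, "/") * 100
  structure(list(s = counts, S = sizes, ratio = ratio),
            class = "MarkProportionTable")
}

#' @export
print.MarkProportionTable <- function(x, ...) {
  cat("MarkProportionTable:", nrow(x$s), "repeat type(s) x", ncol(x$s),
      "mark(s)\n")
  invisible(x)
}

#' Resample a read percentage from its Beta posterior
#'
#' To propagate the uncertainty of small read counts, each percentage ratio
#' is resampled from the Beta posterior of the underlying proportion under
#' the Jeffreys prior, `Beta(s + 1/2, S - s + 1/2)`, scaled to the 0-100
#' range. The half-count prior matches the regularization used by
#' [enrichment_mle()].
#'
#' @param s Assigned read count.
#' @param S Dataset size (`0 <= s <= S`).
#' @param n Number of draws (default 100).
#' @return `n` sampled percentages.
#' @export
beta_resample <- function(s, S, n = 100L) {
  stopifnot(s >= 0, s <= S)
  100 * stats::rbeta(n, s + 0.5, S - s + 0.5)
}

#' Fit the trimmed Gaussian background for one repeat type
#'
#' Marks are ranked by their point percentage ratio; the `n_omit` highest
#' are excluded (they are the candidates for true enrichment and would
#' otherwise inflate the background), and the Gaussian mean and standard
#' deviation are fitted on all resampled percentages of the remaining marks
#' pooled together.
#'
#' @param point_ratios Named numeric vector: each mark's point percentage.
#' @param draws Numeric matrix of resampled percentages, draws in rows, one
#'   column per mark (colnames matching `point_ratios`).
#' @param n_omit Number of top-ranked marks excluded (default 5).
#' @return A list with `mu`, `sigma` (floored at a small epsilon when the
#'   pool is degenerate) and `trimmed_marks`.
#' @export
fit_background <- function(point_ratios, draws, n_omit = 5L) {
  marks <- names(point_ratios)
  if (length(marks) <= n_omit + 1L) {
    stop("need more than n_omit + 1 marks to fit a background")
  }
  stopifnot(all(marks %in% colnames(draws)))
  trimmed <- marks[order(point_ratios, decreasing = TRUE)][seq_len(n_omit)]
  kept <- setdiff(marks, trimmed)
  pool <- as.numeric(draws[, kept])
  mu <- mean(pool)
  sigma <- stats::sd(pool)
  sigma <- max(sigma, 1e-12 * max(mu, 1))
  list(mu = mu, sigma = sigma, trimmed_marks = trimmed)
}

#' Input-free relative enrichment Z-scores across marks
#'
#' For each repeat type, fits the trimmed Gaussian background over the marks
#' and scores every mark (including the trimmed ones, which are precisely
#' the enrichment candidates) as `Z = (ratio - mu) / sigma`. The method
#' assumes most marks are not enriched at a given repeat; it can call
#' significant enrichment but, by construction, cannot establish significant
#' depletion, so negative Z-scores are reported but flagged non-callable.
#'
#' @param table A `MarkProportionTable` from [build_proportions()].
#' @param n_omit Marks trimmed per repeat type (default 5).
#' @param n_resample Beta draws per mark (default 100).
#' @param seed Seed for the Beta resampling (required, for reproducibility).
#' @return A list with `z` (repeat x mark Z-score matrix), `callable`
#'   (logical matrix, `FALSE` where Z < 0), and `background` (a
#'   `data.frame(type, mu, sigma, trimmed_marks)`).
#' @export
relative_zscores <- function(table, n_omit = 5L, n_resample = 100L, seed) {
  stopifnot(inherits(table, "MarkProportionTable"))
  if (missing(seed)) stop("a seed is required for the Beta resampling")
  set.seed(seed)
  types <- rownames(table$s)
  marks <- colnames(table$s)
  z <- matrix(NA_real_, nrow = length(types), ncol = length(marks),
              dimnames = list(types, marks))
  bg <- vector("list", length(types))
  for (i in seq_along(types)) {
    draws <- vapply(marks, function(m) {
      beta_resample(table$s[i, m], table$S[[m]], n = n_resample)
    }, numeric(n_resample))
    fit <- fit_background(stats::setNames(table$ratio[i, ], marks), draws,
                          n_omit = n_omit)
    z[i, ] <- (table$ratio[i, ] - fit$mu) / fit$sigma
    bg[[i]] <- data.frame(type = types[i], mu = fit$mu, sigma = fit$sigma,
                          trimmed_marks = paste(fit$trimmed_marks,
                                                collapse = ","),
                          stringsAsFactors = FALSE)
  }
  list(z = z, callable = z >= 0, background = do.call(rbind, bg))
}
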