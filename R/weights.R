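#' Normalized per-neuron pooling weights across target lags
#'
#' For every admissible target lag (peri-saccadic `R^2` above
#' `r2_threshold`), takes the mean of each neuron's weights over
#' cross-validation sets, defines the neuron's pooling weight as the
#' average of the absolute mean weights to the X and Y channels,
#' `(|beta_X| + |beta_Y|) / 2`, and normalizes so the pooling weights sum
#' to one across the population. A pooling weight of 0.05 means the neuron
#' contributes 5% of the total input to the read-out units.
#'
#' @param sweep a `lag_sweep_result` (its per-set weights are used).
#' @param r2_threshold admission threshold on peri-saccadic `R^2`.
#' @return an object of class `weight_summary` core: numeric matrix
#'   `neuron x admissible lag` of pooling weights (columns sum to 1), with
#'   attribute `lags` (the admitted lags).
#' @export
pooling_weights <- function(sweep, r2_threshold = 0.75) {
  admit <- sweep$table$r2_peri > r2_threshold
  if (!any(admit)) {
    stop("no target lag passes the peri-saccadic R^2 threshold",
         call. = FALSE)
  }
  cols <- lapply(which(admit), function(i) {
    w <- sweep$decoded[[i]]$weights
    agg <- (abs(rowMeans(w$beta_X)) + abs(rowMeans(w$beta_Y))) / 2
    agg / sum(agg)
  })
  pw <- do.call(cbind, cols)
  colnames(pw) <- as.character(sweep$lags[admit])
  attr(pw, "lags") <- sweep$lags[admit]
  pw
}

#' Histogram of pooling weights, averaged across lags
#'
#' Bins each admissible lag's pooling weights on a common fixed-width grid
#' (20 bins on `[0, max weight]` by default) and reports the mean and SD of
#' the bin counts across lags. A narrow, bell-like histogram with small SD
#' indicates a distributed code that is stable across target lags.
#'
#' @param pw pooling-weight matrix from [pooling_weights()].
#' @param bins number of bins.
#' @return list with `breaks`, `mids`, `mean` and `sd` bin counts.
#' @export
weight_histogram <- function(pw, bins = 20) {
  breaks <- seq(0, max(pw), length.out = bins + 1)
  counts <- apply(pw, 2, function(col) {
    graphics::hist(col, breaks = breaks, plot = FALSE)$counts
  })
  counts <- matrix(counts, nrow = bins)
  list(breaks = breaks,
       mids = (breaks[-1] + breaks[-(bins + 1)]) / 2,
       mean = rowMeans(counts),
       sd = apply(counts, 1, stats::sd))
}

#' Modulation of each neuron's contribution across target lags
#'
#' `100 * (max - min) / mean` of the neuron's pooling weight over
#' admissible lags. Neurons with zero mean weight are flagged and excluded
#' from the population summary.
#'
#' @param pw pooling-weight matrix (needs >= 2 lags).
#' @return list with `modulation_pct` per neuron (NA for excluded),
#'   `mean` and `se` over included neurons, and `n_excluded`.
#' @export
weight_modulation <- function(pw) {
  if (ncol(pw) < 2) stop("need at least 2 admissible lags", call. = FALSE)
  m <- apply(pw, 1, mean)
  mod <- 100 * (apply(pw, 1, max) - apply(pw, 1, min)) / m
  mod[m == 0] <- NA_real_
  ok <- !is.na(mod)
  list(modulation_pct = mod,
       mean = mean(mod[ok]),
       se = stats::sd(mod[ok]) / sqrt(sum(ok)),
       n_excluded = sum(!ok))
}

#' Consistency of the weighting template across target lags
#'
#' Pearson correlation between the neuron-contribution vectors of every
#' pair of admissible lags; high mean correlation means the different
#' time-lagged read-outs reuse essentially the same weighting template.
#' Zero-variance vectors make a pair undefined; such pairs are skipped and
#' counted.
#'
#' @param pw pooling-weight matrix (needs >= 2 lags and >= 3 neurons).
#' @return list with the correlation `matrix`, `mean` and `se` over
#'   unordered pairs, and `n_skipped` pairs.
#' @export
weight_consistency <- function(pw) {
  if (ncol(pw) < 2) stop("need at least 2 admissible lags", call. = FALSE)
  if (nrow(pw) < 3) stop("need at least 3 neurons", call. = FALSE)
  sds <- apply(pw, 2, stats::sd)
  cm <- matrix(NA_real_, ncol(pw), ncol(pw),
               dimnames = list(colnames(pw), colnames(pw)))
  diag(cm) <- 1
  for (i in seq_len(ncol(pw) - 1)) {
    for (j in seq(i + 1, ncol(pw))) {
      if (sds[i] > 0 && sds[j] > 0) {
        cm[i, j] <- cm[j, i] <- stats::cor(pw[, i], pw[, j])
      }
    }
  }
  up <- cm[upper.tri(cm)]
  ok <- !is.na(up)
  list(matrix = cm,
       mean = mean(up[ok]),
       se = stats::sd(up[ok]) / sqrt(sum(ok)),
       n_skipped = sum(!ok))
}
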