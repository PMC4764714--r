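#' Direction-specific differential time courses
#'
#' Subtracts the rightward-saccade time course from the downward-saccade
#' time course for every neuron, isolating the saccade-direction-specific
#' component of the population dynamics.
#'
#' @param rm a `rate_matrices` with `rightward` and `downward` entries.
#' @return numeric `time x neuron` matrix `D = R_dwd - R_rwd`.
#' @export
differential_timecourses <- function(rm) {
  stopifnot(identical(dim(rm$R$downward), dim(rm$R$rightward)))
  rm$R$downward - rm$R$rightward
}

#' PCA of differential population time courses
#'
#' Each neuron's (column) mean over time is removed, then the time-by-time
#' covariance across neurons is eigendecomposed. The leading eigenvectors
#' are stereotyped peri-saccadic time courses; the eigenvalue fractions say
#' how much of the direction-specific variance each one captures. Component
#' signs are fixed so the largest-magnitude element of each is positive.
#'
#' @param D numeric `time x neuron` matrix (e.g. from
#'   [differential_timecourses()]).
#' @param k number of components to retain (<= min(dim(D))).
#' @param standardize if `TRUE`, z-score each neuron column (after
#'   centering) before the decomposition. Off by default: raw spikes/s keep
#'   strongly modulated neurons influential.
#'
#' @return an object of class `pc_result`: list with `components`
#'   (`time x k`, orthonormal), `scores` (`neuron x k` projections),
#'   `variance_fraction` (all components, non-increasing, sums to 1),
#'   `k`, and `center` (the removed column means).
#' @export
pca_timecourses <- function(D, k = 3, standardize = FALSE) {
  stopifnot(is.matrix(D))
  n_t <- nrow(D)
  n_n <- ncol(D)
  if (k > min(n_t, n_n)) {
    stop("k exceeds the rank bound min(time points, neurons)", call. = FALSE)
  }
  center <- colMeans(D)
  Dc <- sweep(D, 2, center)
  if (standardize) {
    s <- apply(Dc, 2, stats::sd)
    s[s == 0] <- 1
    Dc <- sweep(Dc, 2, s, "/")
  }
  C <- tcrossprod(Dc) / max(n_n - 1, 1)
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  comps <- e$vectors
  # sign convention: largest-|.| element positive
  for (j in seq_len(ncol(comps))) {
    m <- which.max(abs(comps[, j]))
    if (comps[m, j] < 0) comps[, j] <- -comps[, j]
  }
  structure(
    list(components = comps[, seq_len(k), drop = FALSE],
         scores = t(Dc) %*% comps[, seq_len(k), drop = FALSE],
         variance_fraction = vals / sum(vals),
         k = k, center = center),
    class = "pc_result"
  )
}

#' Neuron-resampling bootstrap of the time-course PCA
#'
#' Resamples neuron columns with replacement `n_boot` times, repeats the
#' PCA on each replicate, aligns each replicate's components to the
#' full-sample components by greedy matching on absolute correlation (with
#' sign flip), and reports the pointwise standard deviation across
#' replicates as a standard error band for each component.
#'
#' @param D numeric `time x neuron` matrix with at least 2 neurons.
#' @param k components to retain.
#' @param n_boot number of bootstrap replicates.
#' @param seed integer seed.
#' @inheritParams pca_timecourses
#'
#' @return the full-sample `pc_result` with extra fields `boot_se`
#'   (`time x k`) and `n_boot`.
#' @export
bootstrap_pca <- function(D, k = 3, n_boot = 1000, seed,
                          standardize = FALSE) {
  stopifnot(ncol(D) >= 2)
  full <- pca_timecourses(D, k = k, standardize = standardize)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  reps <- array(NA_real_, dim = c(nrow(D), k, n_boot))
  for (b in seq_len(n_boot)) {
    cols <- sample(ncol(D), replace = TRUE)
    pb <- pca_timecourses(D[, cols, drop = FALSE], k = k,
                          standardize = standardize)
    reps[, , b] <- align_components(pb$components, full$components)
  }
  full$boot_se <- apply(reps, c(1, 2), stats::sd)
  full$n_boot <- n_boot
  full
}

# Greedily match candidate components to reference components by absolute
# correlation and flip signs so each matched pair correlates positively.
align_components <- function(cand, ref) {
  k <- ncol(ref)
  out <- matrix(NA_real_, nrow(ref), k)
  avail <- seq_len(ncol(cand))
  for (j in seq_len(k)) {
    cors <- vapply(avail, function(a) {
      suppressWarnings(stats::cor(cand[, a], ref[, j]))
    }, numeric(1))
    cors[is.na(cors)] <- 0
    best <- which.max(abs(cors))
    v <- cand[, avail[best]]
    if (cors[best] < 0) v <- -v
    out[, j] <- v
    avail <- avail[-best]
    if (length(avail) == 0) break
  }
  out
}
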