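#' @title SMOTE class balancing
#' @name balance
NULL

#' Synthetic Minority Oversampling Technique
#'
#' Upsamples the minority class to exactly the majority count. Each synthetic
#' row is `x + u * (x_nn - x)` with `u ~ Uniform(0, 1)`, `x` a minority row and
#' `x_nn` one of its `k` nearest minority neighbours (Euclidean distance);
#' original rows are preserved verbatim. `k` is reduced automatically to
#' `minority size - 1` when the minority class is small.
#'
#' @param x numeric feature matrix (rows = samples).
#' @param y binary factor of labels aligned with `x` rows.
#' @param k number of nearest minority neighbours (default 5).
#' @param seed integer seed for the interpolation draws.
#' @return list with `x` (augmented matrix), `y` (augmented labels) and
#'   `synthetic` (logical flag per output row).
#' @export
smote <- function(x, y, k = 5, seed = 1L) {
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) != 2 || any(table(y) == 0))
    stop("SMOTE needs two non-empty classes", call. = FALSE)
  counts <- table(y)
  minority <- names(counts)[which.min(counts)]
  n_min <- min(counts)
  n_need <- max(counts) - n_min
  if (n_need == 0)
    return(list(x = x, y = y, synthetic = rep(FALSE, nrow(x))))
  if (n_min < 2)
    stop("minority class must have at least 2 samples", call. = FALSE)
  k <- min(k, n_min - 1)
  xm <- x[y == minority, , drop = FALSE]
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  nn <- t(matrix(apply(d, 1, function(row) order(row)[seq_len(k)]), nrow = k))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  base_idx <- rep(seq_len(n_min), length.out = n_need)
  nbr_idx <- vapply(base_idx, function(i) nn[i, sample.int(k, 1)], 0L)
  u <- stats::runif(n_need)
  synth <- xm[base_idx, , drop = FALSE] +
    u * (xm[nbr_idx, , drop = FALSE] - xm[base_idx, , drop = FALSE])
  list(x = rbind(x, synth),
       y = factor(c(as.character(y), rep(minority, n_need)), levels = levels(y)),
       synthetic = c(rep(FALSE, nrow(x)), rep(TRUE, n_need)))
}
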