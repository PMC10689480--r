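as_chain_matrix <- function(chains) {
  if (is.list(chains)) {
    len <- vapply(chains, length, integer(1))
    if (length(unique(len)) != 1)
      stop("chains must have equal lengths", call. = FALSE)
    chains <- do.call(cbind, chains)
  }
  if (is.vector(chains)) chains <- matrix(chains, ncol = 1)
  chains
}

#' Potential scale reduction factor (split-chain R-hat)
#'
#' Classic Gelman--Rubin statistic computed on split chains: each chain is
#' halved so within-chain drift also inflates the between-chain variance.
#' Values near 1 (<= 1.01 by the study's convergence rule) indicate that
#' the chains have mixed.
#'
#' @param chains matrix (iterations x chains) or list of equal-length
#'   numeric vectors; at least 2 chains.
#' @return R-hat (>= ~1 up to sampling noise; exactly 1 for constant
#'   chains).
#' @export
rhat <- function(chains) {
  m <- as_chain_matrix(chains)
  if (ncol(m) < 2) stop("R-hat needs at least 2 chains", call. = FALSE)
  n <- nrow(m)
  half <- n %/% 2L
  split <- cbind(m[seq_len(half), , drop = FALSE],
                 m[(n - half + 1):n, , drop = FALSE])
  W <- mean(apply(split, 2, var))
  if (W == 0) return(1)
  B_over_n <- var(colMeans(split))
  var_plus <- (half - 1) / half * W + B_over_n
  sqrt(var_plus / W)
}

# per-chain autocovariance (biased, divides by n) via FFT
autocov_fft <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  M <- nextn(2L * n)
  f <- fft(c(x, rep(0, M - n)))
  a <- Re(fft(Mod(f)^2, inverse = TRUE)) / M
  a[seq_len(n)] / n
}

#' Effective sample size
#'
#' Autocorrelation-based ESS for one parameter across one or more chains,
#' using the multi-chain autocorrelation estimate (within-chain
#' autocovariances combined with the between-chain variance) truncated by
#' Geyer's initial positive sequence rule. A constant chain is degenerate:
#' the total draw count is returned with a warning.
#'
#' @param chains matrix (iterations x chains) or list of equal-length
#'   numeric vectors.
#' @return estimated effective sample size.
#' @export
effective_sample_size <- function(chains) {
  m <- as_chain_matrix(chains)
  n <- nrow(m); k <- ncol(m)
  if (n < 4) return(NA_real_)
  chain_var <- apply(m, 2, var)
  W <- mean(chain_var)
  if (W == 0) {
    warning("constant chain: ESS reported as the total number of draws",
            call. = FALSE)
    return(n * k)
  }
  var_plus <- (n - 1) / n * W + (if (k > 1) var(colMeans(m)) else 0)
  acov <- vapply(seq_len(k), function(j) autocov_fft(m[, j]),
                 numeric(n))
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov) / var_plus
  # Geyer initial positive sequence over lag pairs (0,1), (2,3), ...
  tau <- 0
  i <- 1L
  while (i + 1L <= length(rho)) {
    p <- rho[i] + rho[i + 1L]
    if (p <= 0) break
    tau <- tau + p
    i <- i + 2L
  }
  iact <- max(2 * tau - 1, 1e-8)
  n * k / iact
}

effective_sample_size_quiet <- function(chains) {
  suppressWarnings(effective_sample_size(chains))
}
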