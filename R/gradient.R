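# All permutations of 1..n as a matrix (n! rows). Used for exact
# permutation tests at small bin counts.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 0L
  for (pos in seq_len(n)) {
    blk <- matrix(0L, nrow(sub), n)
    blk[, pos] <- n
    blk[, -pos] <- sub
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  out
}

# Spearman rho of x against bin order for each row-permutation of x.
perm_spearman <- function(x, perms) {
  rx <- rank(x)
  n <- length(x)
  ri <- seq_len(n)
  cri <- ri - mean(ri)
  denom_i <- sqrt(sum(cri^2))
  rmat <- matrix(rx[perms], nrow = nrow(perms))
  rmat <- rmat - rowMeans(rmat)
  denom_x <- sqrt(rowSums(rmat^2))
  num <- as.numeric(rmat %*% cri)
  rho <- num / (denom_x * denom_i)
  rho[denom_x == 0] <- 0
  rho
}

#' Call a rostrocaudal gradient for one expression profile
#'
#' Computes the Spearman rank correlation of intensity against bin index
#' (bin 1 = rostral pole) and a two-sided permutation p-value over bin
#' shuffles. When the number of possible orderings (`n_bins!`) does not
#' exceed `n_perm`, the permutation distribution is enumerated exactly;
#' otherwise `n_perm` random shuffles are drawn under `seed`. A profile is
#' called `high_caudal` for a significant positive correlation,
#' `high_rostral` for a significant negative one, and `none` otherwise
#' (including constant profiles, whose statistic is 0).
#'
#' @param intensities Non-negative intensities over ordered rostrocaudal
#'   bins (>= 3 bins).
#' @param rho_threshold Minimum absolute Spearman rho for a call.
#' @param alpha Significance level for the permutation p-value.
#' @param n_perm Number of permutations (>= 100); also the exact-enumeration
#'   cutoff.
#' @param seed RNG seed for the Monte Carlo branch.
#' @return List with `direction`, `statistic` (Spearman rho), `p_value`,
#'   and `exact` (TRUE when the permutation null was enumerated).
#' @examples
#' classify_gradient(c(1, 2, 3, 4, 5))   # high_caudal, rho = 1
#' classify_gradient(c(2, 2, 2, 2, 2))   # none
#' @export
classify_gradient <- function(intensities, rho_threshold = 0.8, alpha = 0.05,
                              n_perm = 10000L, seed = 1L) {
  n <- length(intensities)
  if (n < 3L) stop_ef("gradient profiles need >= 3 bins")
  if (n_perm < 100L) stop_ef("n_perm must be >= 100")
  if (any(intensities < 0)) stop_ef("intensities must be non-negative")
  idx <- seq_len(n)
  if (sd(intensities) == 0) {
    return(list(direction = "none", statistic = 0, p_value = 1, exact = TRUE))
  }
  rho <- cor(rank(intensities), idx)
  nfact <- factorial(n)
  if (nfact <= n_perm) {
    perms <- all_permutations(n)
    rho_null <- perm_spearman(intensities, perms)
    p <- mean(abs(rho_null) >= abs(rho) - 1e-12)
    exact <- TRUE
  } else {
    rho_null <- with_seed(sub_seed(seed, "permutation"), {
      perms <- t(vapply(seq_len(n_perm), function(i) sample.int(n), integer(n)))
      perm_spearman(intensities, perms)
    })
    p <- (1 + sum(abs(rho_null) >= abs(rho) - 1e-12)) / (n_perm + 1)
    exact <- FALSE
  }
  direction <- "none"
  if (!is.na(rho) && abs(rho) >= rho_threshold && p < alpha) {
    direction <- if (rho > 0) "high_caudal" else "high_rostral"
  }
  list(direction = direction, statistic = unname(rho), p_value = p, exact = exact)
}

#' Call gradients for a table of regional profiles
#'
#' @param profiles Data frame with `gene_id`, `zone_context`, and ordered
#'   `bin_*` columns (bin 1 = rostral).
#' @param rho_threshold,alpha,n_perm,seed See [classify_gradient()].
#' @return Data frame with one row per (gene, zone context): `gene_id`,
#'   `zone_context`, `direction`, `statistic`, `p_value`.
#' @export
classify_gradients <- function(profiles, rho_threshold = 0.8, alpha = 0.05,
                               n_perm = 10000L, seed = 1L) {
  bins <- grep("^bin_", names(profiles), value = TRUE)
  if (length(bins) < 3L) stop_ef("profiles need >= 3 bin_* columns")
  bins <- bins[order(as.integer(sub("bin_", "", bins)))]
  zc <- if ("zone_context" %in% names(profiles)) profiles$zone_context else
    rep(NA_character_, nrow(profiles))
  rows <- lapply(seq_len(nrow(profiles)), function(i) {
    call <- classify_gradient(as.numeric(profiles[i, bins]),
                              rho_threshold = rho_threshold, alpha = alpha,
                              n_perm = n_perm, seed = seed)
    data.frame(
      gene_id = profiles$gene_id[i],
      zone_context = zc[i],
      direction = call$direction,
      statistic = call$statistic,
      p_value = call$p_value,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
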