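#' Heterogeneous hidden Markov model segmentation of CNR profiles
#'
#' Segments a centered copy-number-ratio profile into runs of constant
#' copy-number state with a Gaussian-emission HMM whose transition
#' probabilities depend on the genomic distance between adjacent
#' windows: between windows whose midpoints are d bases apart the chain
#' redraws its state uniformly with probability
#' `rho(d) = 1 - exp(-d / decay_length)`, so the probability of leaving
#' the current state is `p_change(d) = rho(d) * (K - 1) / K` — near zero
#' for dense adjacent windows and approaching the uniform limit across
#' large gaps. State means and the common emission variance are fitted
#' by EM per chromosome; the number of states K is chosen by BIC over
#' `1..max_states`; the Viterbi path is collapsed into maximal
#' constant-state runs.
#'
#' Masked windows (zero pooled-normal count or low-coverage flag) are
#' excluded from fitting and from the reported segments.
#'
#' @param profile Centered `cnr_profile` from [center_cnr()].
#' @param max_states Largest number of copy-number states considered.
#' @param decay_length Distance scale (bases) of the transition kernel.
#' @param seed Integer seed for EM initialization jitter.
#' @param neutral_band Half-width of the CNR band labelled `neutral`;
#'   segments with mean CNR above `+neutral_band` are `gain`, below
#'   `-neutral_band` are `loss`.
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @return An object of class `cnv_segmentation`; `tidy()` gives the
#'   segment table (`chrom`, `start`, `end`, `n_windows`, `mean_cnr`,
#'   `state`), `glance()` the per-chromosome model summaries.
#' @export
segment_hmm <- function(profile, max_states = 5, decay_length = 1e6,
                        seed = 1L, neutral_band = 0.2,
                        max_iter = 100, tol = 1e-6) {
  assert_columns(profile, c("chrom", "start", "end", "cnr", "masked"),
                 "profile")
  if (!isTRUE(attr(profile, "centered"))) {
    warn("profile is not median-centered; segment states assume centering")
  }
  usable <- filter(as_tibble(profile), !.data$masked) |>
    arrange(.data$chrom, .data$start)
  if (!nrow(usable)) abort("no unmasked windows to segment")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, "hmm"))

  seg_list <- list(); mod_list <- list()
  for (ch in unique(usable$chrom)) {
    w <- usable[usable$chrom == ch, ]
    x <- w$cnr
    mid <- (w$start + w$end) / 2
    d <- diff(mid)
    fit <- fit_het_hmm(x, d, max_states, decay_length, max_iter, tol)
    runs <- rle(fit$path)
    stop_idx <- cumsum(runs$lengths)
    start_idx <- stop_idx - runs$lengths + 1L
    segs <- tibble(
      chrom = ch,
      start = w$start[start_idx],
      end = w$end[stop_idx],
      n_windows = runs$lengths,
      mean_cnr = vapply(seq_along(start_idx), function(i) {
        mean(x[start_idx[i]:stop_idx[i]])
      }, numeric(1))
    )
    seg_list[[ch]] <- segs
    mod_list[[ch]] <- tibble(chrom = ch, n_states = fit$K,
                             loglik = fit$loglik, bic = fit$bic,
                             converged = fit$converged,
                             sigma = fit$sigma, n_windows = length(x))
  }
  segments <- bind_rows(seg_list) |>
    mutate(state = dplyr::case_when(
      .data$mean_cnr > neutral_band ~ "gain",
      .data$mean_cnr < -neutral_band ~ "loss",
      TRUE ~ "neutral"
    ))
  structure(list(segments = segments, models = bind_rows(mod_list),
                 decay_length = decay_length, neutral_band = neutral_band,
                 profile = usable),
            class = "cnv_segmentation")
}

#' @export
print.cnv_segmentation <- function(x, ...) {
  cat(sprintf("CNV segmentation: %d segments over %d chromosome(s)\n",
              nrow(x$segments), nrow(x$models)))
  print(x$segments, n = 10)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cnv_segmentation <- function(x, ...) x$segments

#' @exportS3Method generics::glance
glance.cnv_segmentation <- function(x, ...) x$models

#' Probability of a state change between adjacent windows
#'
#' The heterogeneous transition kernel used by [segment_hmm()]: with
#' probability `rho(d) = 1 - exp(-d / decay_length)` the chain redraws
#' its state uniformly over the K states, so the probability of landing
#' in a different state is `rho(d) (K - 1) / K`. Monotone increasing in
#' the inter-window distance d.
#'
#' @param d Genomic distance between adjacent window midpoints (bases).
#' @param decay_length Kernel distance scale (bases).
#' @param n_states Number of HMM states K.
#' @return Change probability, vectorized over `d`.
#' @export
transition_change_prob <- function(d, decay_length = 1e6, n_states = 2) {
  (1 - exp(-d / decay_length)) * (n_states - 1) / n_states
}

# --- internal HMM machinery -------------------------------------------------

# Fit K-state models for K = 1..max_states and pick by BIC.
# Parameters counted: K state means + 1 common sd.
fit_het_hmm <- function(x, d, max_states, decay_length, max_iter, tol) {
  n <- length(x)
  kmax <- max(1L, min(max_states, n))
  fits <- vector("list", kmax)
  for (K in seq_len(kmax)) {
    fits[[K]] <- em_het_hmm(x, d, K, decay_length, max_iter, tol)
    fits[[K]]$bic <- -2 * fits[[K]]$loglik + (K + 1) * log(n)
  }
  best <- which.min(vapply(fits, `[[`, numeric(1), "bic"))
  fit <- fits[[best]]
  if (!fit$converged && best > 1) {
    # fall back to the largest smaller state count that converged
    for (K in rev(seq_len(best - 1))) {
      if (fits[[K]]$converged) {
        warn(sprintf("EM did not converge with %d states; falling back to %d",
                     best, K))
        fit <- fits[[K]]
        break
      }
    }
  }
  fit$path <- viterbi_het(x, d, fit$mu, fit$sigma, decay_length)
  fit
}

# Row i of the transition matrix at distance d:
#   (1 - rho) * I + rho / K   (uniform redraw with prob rho)
trans_mat <- function(d, K, decay_length) {
  rho <- 1 - exp(-d / decay_length)
  (1 - rho) * diag(K) + rho / K
}

em_het_hmm <- function(x, d, K, decay_length, max_iter, tol) {
  n <- length(x)
  if (K == 1) {
    mu <- mean(x)
    sigma <- max(sd_or_floor(x, mu), 1e-3)
    ll <- sum(dnorm(x, mu, sigma, log = TRUE))
    return(list(K = 1L, mu = mu, sigma = sigma, loglik = ll,
                converged = TRUE))
  }
  # quantile-spread initialization with small seeded jitter
  mu <- as.numeric(quantile(x, probs = (seq_len(K)) / (K + 1))) +
    stats::rnorm(K, 0, 0.01)
  sigma <- max(stats::sd(x) / K, 1e-3)
  A <- lapply(d, trans_mat, K = K, decay_length = decay_length)
  ll_old <- -Inf; converged <- FALSE
  for (iter in seq_len(max_iter)) {
    B <- vapply(seq_len(K), function(k) dnorm(x, mu[k], sigma), numeric(n))
    B <- pmax(B, 1e-300)
    # scaled forward
    alpha <- matrix(0, n, K); cvec <- numeric(n)
    a <- rep(1 / K, K) * B[1, ]
    cvec[1] <- sum(a); alpha[1, ] <- a / cvec[1]
    for (t in 2:n) {
      a <- (alpha[t - 1, ] %*% A[[t - 1]]) * B[t, ]
      cvec[t] <- sum(a); alpha[t, ] <- a / cvec[t]
    }
    # scaled backward
    beta <- matrix(0, n, K); beta[n, ] <- 1
    for (t in (n - 1):1) {
      b <- A[[t]] %*% (B[t + 1, ] * beta[t + 1, ])
      beta[t, ] <- as.numeric(b) / cvec[t + 1]
    }
    gamma <- alpha * beta
    gamma <- gamma / rowSums(gamma)
    ll <- sum(log(cvec))
    # M-step: means and common variance (transitions are structural)
    wsum <- colSums(gamma)
    mu_new <- colSums(gamma * x) / pmax(wsum, 1e-12)
    resid2 <- vapply(seq_len(K), function(k) (x - mu_new[k])^2, numeric(n))
    sigma_new <- sqrt(sum(gamma * resid2) / n)
    mu <- mu_new; sigma <- max(sigma_new, 1e-3)
    if (is.finite(ll) && abs(ll - ll_old) < tol * max(1, abs(ll))) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  list(K = as.integer(K), mu = mu, sigma = sigma, loglik = ll_old,
       converged = converged)
}

viterbi_het <- function(x, d, mu, sigma, decay_length) {
  K <- length(mu); n <- length(x)
  if (K == 1) return(rep(1L, n))
  logB <- vapply(seq_len(K), function(k) dnorm(x, mu[k], sigma, log = TRUE),
                 numeric(n))
  delta <- matrix(-Inf, n, K); psi <- matrix(0L, n, K)
  delta[1, ] <- log(1 / K) + logB[1, ]
  for (t in 2:n) {
    logA <- log(trans_mat(d[t - 1], K, decay_length))
    for (k in seq_len(K)) {
      cand <- delta[t - 1, ] + logA[, k]
      psi[t, k] <- which.max(cand)
      delta[t, k] <- cand[psi[t, k]] + logB[t, k]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path
}

sd_or_floor <- function(x, mu) {
  if (length(x) < 2) return(1e-3)
  sqrt(mean((x - mu)^2))
}
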