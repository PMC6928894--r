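## Reconstruction of a quasi-continuous reference BG profile on a 1-min grid
## from sparse noisy reference samples, by Tikhonov regularisation with a
## second-difference roughness penalty and likelihood-tuned smoothing.

default_gamma_grid <- function() 10^seq(-4, 8, length.out = 61L)

# Second-difference operator on an m-point uniform grid, sparse (m-2) x m.
second_diff_matrix <- function(m) {
  if (m < 3L) stopf("grid too short for a second-difference penalty")
  i <- rep(seq_len(m - 2L), each = 3L)
  j <- as.vector(vapply(seq_len(m - 2L), function(k) k + 0:2, integer(3L)))
  Matrix::sparseMatrix(i = i, j = j,
                       x = rep(c(1, -2, 1), m - 2L), dims = c(m - 2L, m))
}

# One-session Tikhonov smoother. y observed at grid indices `obs` of an
# m-point 1-min grid; w = 1/sd per observation. Returns the reconstruction
# and the GML score used to tune gamma.
smooth_session <- function(t_obs, y, cv, gamma = NULL,
                           gamma_grid = default_gamma_grid()) {
  t0 <- round(t_obs[1L]); t1 <- round(t_obs[length(t_obs)])
  grid <- seq(t0, t1, by = 1)
  m <- length(grid)
  # snap reference times to the nearest grid point: keeps the normal
  # equations pentadiagonal (selection matrix G has one 1 per row)
  obs <- pmin(pmax(round(t_obs) - t0 + 1L, 1L), m)
  w <- 1 / (cv * y)                      # heteroscedastic: sd_i = cv * y_i
  F2 <- second_diff_matrix(m)
  P <- Matrix::crossprod(F2)
  # G' W^2 G is diagonal with w^2 summed over duplicated grid points
  d <- rep.int(0, m)
  wy <- rep.int(0, m)
  for (k in seq_along(obs)) {
    d[obs[k]] <- d[obs[k]] + w[k]^2
    wy[obs[k]] <- wy[obs[k]] + w[k]^2 * y[k]
  }
  D <- Matrix::Diagonal(m, d)
  n_obs <- length(y)
  fit_one <- function(g) {
    M <- D + g * P
    u <- as.numeric(Matrix::solve(M, wy))
    u
  }
  gml_score <- function(g) {
    # Wahba's generalized maximum likelihood: minimise
    #   z'(I-A)z / det+(I-A)^(1/(n-2))
    # where z are whitened observations and A the influence matrix; the two
    # zero eigenvalues of I-A (unpenalised linear null space) are excluded.
    M <- D + g * P
    # columns of G' scaled by w: solve for the n_obs observation columns
    B <- Matrix::sparseMatrix(i = obs, j = seq_len(n_obs), x = w,
                              dims = c(m, n_obs))
    S <- Matrix::solve(M, B)
    A <- as.matrix(Matrix::crossprod(B, S))   # n_obs x n_obs influence
    z <- w * y
    q <- as.numeric(crossprod(z, (diag(n_obs) - A) %*% z))
    ev <- sort(eigen(diag(n_obs) - A, symmetric = TRUE,
                     only.values = TRUE)$values)
    pos <- ev[-(1:2)]                      # drop the two (numerically) zero ones
    pos <- pmax(pos, .Machine$double.eps)
    log(max(q, .Machine$double.xmin)) - mean(log(pos))
  }
  if (is.null(gamma)) {
    scores <- vapply(gamma_grid, gml_score, numeric(1L))
    gamma <- gamma_grid[which.min(scores)]
  }
  u <- fit_one(gamma)
  list(grid_times = grid, values = u, gamma = gamma)
}

#' Mask unreliable intervals between distant reference samples
#'
#' Returns the open intervals between consecutive reference samples whose
#' spacing exceeds `max_gap` minutes. Reconstructed values inside these
#' intervals are unreliable, so CGM samples falling in them are excluded
#' from matching.
#'
#' @param samples A [reference_samples()].
#' @param max_gap Maximum trusted spacing in minutes (default 20).
#' @return A two-column matrix of (start, end) minutes; zero rows when no
#'   gap exceeds the threshold.
#' @export
mask_gaps <- function(samples, max_gap = 20) {
  t <- samples$times
  if (length(t) < 2L) return(matrix(numeric(), ncol = 2L,
                                    dimnames = list(NULL, c("start", "end"))))
  gaps <- which(diff(t) > max_gap)
  cbind(start = t[gaps], end = t[gaps + 1L])
}

#' Reconstruct a smooth BG profile from sparse reference samples
#'
#' Per clinical session, solves the Tikhonov problem
#' `min_u (y - Gu)' Sigma^-1 (y - Gu) + gamma u' F2' F2 u`
#' on a 1-min grid, where G samples the grid at the reference times, Sigma
#' is diagonal with variances (cv * y_i)^2 and F2 is the second-difference
#' operator. Under the Bayesian reading (second differences of u are white
#' noise of unknown variance) the smoothing parameter gamma is chosen by
#' maximising the marginal likelihood of the data, searched on a log-spaced
#' grid; pass `gamma` to fix it instead. No extrapolation is performed
#' beyond the first/last sample of a session.
#'
#' @param samples A [reference_samples()].
#' @param session_bounds Optional two-column matrix of (start, end) minutes
#'   defining sessions; by default samples separated by more than
#'   `session_break` minutes start a new session.
#' @param gamma Fixed smoothing parameter (default `NULL`: likelihood-tuned).
#' @param gamma_grid Log-spaced candidate grid for the likelihood search.
#' @param max_gap Gap threshold passed to [mask_gaps()].
#' @param session_break Spacing (minutes) that separates two sessions when
#'   `session_bounds` is not given (default 180).
#' @return An object of class `smooth_profile`: list with `grid_times`
#'   (1-min grid, concatenated over sessions), `values`, `session_id`,
#'   `excluded_intervals` (from [mask_gaps()]) and per-session `gamma`.
#' @export
smooth_reference <- function(samples, session_bounds = NULL, gamma = NULL,
                             gamma_grid = default_gamma_grid(),
                             max_gap = 20, session_break = 180) {
  t <- samples$times; y <- samples$values
  if (is.null(session_bounds)) {
    sess <- run_ids(c(TRUE, diff(t) > session_break))
  } else {
    sess <- rep.int(NA_integer_, length(t))
    for (s in seq_len(nrow(session_bounds)))
      sess[t >= session_bounds[s, 1L] & t <= session_bounds[s, 2L]] <- s
    if (anyNA(sess)) {
      warnf("%d reference samples outside all session bounds dropped",
            sum(is.na(sess)))
      keep <- !is.na(sess); t <- t[keep]; y <- y[keep]; sess <- sess[keep]
    }
  }
  grid_times <- numeric(); values <- numeric(); session_id <- integer()
  gammas <- numeric()
  for (s in unique(sess)) {
    idx <- which(sess == s)
    if (length(idx) < 4L) {
      warnf("session %s skipped: fewer than 4 reference samples", s)
      next
    }
    fit <- smooth_session(t[idx], y[idx], samples$cv, gamma = gamma,
                          gamma_grid = gamma_grid)
    grid_times <- c(grid_times, fit$grid_times)
    values <- c(values, fit$values)
    session_id <- c(session_id, rep.int(as.integer(s), length(fit$grid_times)))
    gammas <- c(gammas, fit$gamma)
  }
  structure(list(grid_times = grid_times, values = values,
                 session_id = session_id,
                 excluded_intervals = mask_gaps(samples, max_gap),
                 gamma = gammas),
            class = "smooth_profile")
}

#' @export
print.smooth_profile <- function(x, ...) {
  cat(sprintf("<smooth_profile> %d grid points, %d session(s), %d excluded interval(s)\n",
              length(x$grid_times), length(unique(x$session_id)),
              nrow(x$excluded_intervals)))
  invisible(x)
}

#' Pair CGM samples with the reconstructed reference profile
#'
#' For each CGM sample, finds the nearest reference grid point; the pair is
#' kept when the temporal distance is at most `max_dist_s` seconds and the
#' grid point does not fall inside an excluded gap interval. Ties between
#' two equidistant grid points resolve to the earlier one. Retained pairs
#' are partitioned into segments: maximal runs of consecutive CGM samples
#' (consecutive in the original trace, spaced by its sampling period) that
#' all matched. Each segment also carries the full 1-min reference series
#' spanning it, as needed by the identification stage.
#'
#' @param profile A [smooth_reference()] result (or any list with
#'   `grid_times`, `values`, optional `excluded_intervals`).
#' @param cgm A CGM `glucose_trace`.
#' @param max_dist_s Maximum CGM-to-grid distance in seconds (default 30).
#' @return An object of class `matched_pairs`: data-frame-like list with
#'   `times`, `reference`, `cgm`, `segment_ids`, plus `ref_segments`, a list
#'   of per-segment 1-min reference series (`times`, `values`).
#' @export
match_cgm <- function(profile, cgm, max_dist_s = 30) {
  gt <- profile$grid_times
  gv <- profile$values
  excl <- profile$excluded_intervals
  n <- nrow(cgm)
  idx <- rep.int(NA_integer_, n)
  if (n > 0L && length(gt) > 0L) {
    pos <- findInterval(cgm$time_min, gt)
    for (k in seq_len(n)) {
      cand <- unique(pmin(pmax(c(pos[k], pos[k] + 1L), 1L), length(gt)))
      dist <- abs(gt[cand] - cgm$time_min[k])
      best <- cand[which.min(dist)]       # which.min takes the first: earlier point on ties
      if (min(dist) * 60 <= max_dist_s) idx[k] <- best
    }
  }
  if (!is.null(excl) && nrow(excl) > 0L) {
    for (g in seq_len(nrow(excl))) {
      bad <- !is.na(idx) & gt[idx] > excl[g, 1L] & gt[idx] < excl[g, 2L]
      idx[bad] <- NA_integer_
    }
  }
  keep <- which(!is.na(idx))
  period <- attr(cgm, "period")
  if (is.na(period)) period <- if (length(keep) > 1L)
    min(diff(cgm$time_min[keep])) else 5
  consecutive <- c(TRUE, diff(keep) == 1L &
                     abs(diff(cgm$time_min[keep]) - period) < 1e-9)
  seg <- if (length(keep)) run_ids(c(TRUE, !consecutive[-1L])) else integer()
  pairs <- list(times = cgm$time_min[keep],
                reference = gv[idx[keep]],
                cgm = cgm$glucose_mg_dl[keep],
                segment_ids = if (length(keep)) seg else integer())
  # per-segment 1-min reference slices for the kinetic convolution
  seg_fac <- factor(pairs$segment_ids,
                    levels = sort(unique(pairs$segment_ids)))
  # contiguous 1-min runs of the reference grid: each pair segment carries
  # the full run back to its start, so the kinetic convolution warms up on
  # all available reference history before the first matched sample
  grid_run <- if (length(gt)) run_ids(c(TRUE, diff(gt) > 1 + 1e-9)) else integer()
  ref_segments <- lapply(split(seq_along(keep), seg_fac), function(ii) {
    lo <- min(pairs$times[ii]); hi <- max(pairs$times[ii])
    sel <- which(gt >= lo - 1e-9 & gt <= hi + 1e-9)
    run_start <- min(which(grid_run == grid_run[sel[1L]]))
    sel <- run_start:max(sel)
    list(times = gt[sel], values = gv[sel])
  })
  structure(c(pairs, list(ref_segments = ref_segments)),
            class = "matched_pairs")
}

#' @export
print.matched_pairs <- function(x, ...) {
  cat(sprintf("<matched_pairs> %d pairs in %d segment(s)\n",
              length(x$times),
              if (length(x$segment_ids)) max(x$segment_ids) else 0L))
  invisible(x)
}
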