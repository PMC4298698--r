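#' Convert phase hours on a 24-hr circle to radians
#' @param h hours.
#' @export
hours_to_angle <- function(h) (2 * pi * h / 24) %% (2 * pi)

#' Convert radians to phase hours on a 24-hr circle
#' @param a radians.
#' @export
angle_to_hours <- function(a) (24 * a / (2 * pi)) %% 24

#' Circular summary: mean angle, resultant length, circular variance
#'
#' With \eqn{C = \sum \cos\theta / n}, \eqn{S = \sum \sin\theta / n}, the
#' mean resultant length is \eqn{R = \sqrt{C^2 + S^2}}, the mean angle
#' \eqn{\mu = \mathrm{atan2}(S, C)} and the circular variance
#' \eqn{V = 1 - R}. V is 0 for perfectly clustered phases and 1 for uniform
#' dispersion; the mean angle is undefined (flagged \code{NA}) when R = 0.
#'
#' @param angles phase angles in radians.
#' @return A \code{circ_summary} list: \code{n}, \code{mean_angle} (radians
#'   in [0, 2 pi)), \code{R}, \code{V}.
#' @export
circ_summary <- function(angles) {
  if (length(angles) == 0) stop("empty circular sample")
  C <- mean(cos(angles))
  S <- mean(sin(angles))
  R <- sqrt(C^2 + S^2)
  mu <- if (R < 1e-12) NA_real_ else atan2(S, C) %% (2 * pi)
  structure(list(n = length(angles), mean_angle = mu, R = R, V = 1 - R),
            class = "circ_summary")
}

#' @export
print.circ_summary <- function(x, ...) {
  cat(sprintf("<circ_summary> n = %d, mu = %s, R = %.4f, V = %.4f\n", x$n,
              if (is.na(x$mean_angle)) "undefined"
              else sprintf("%.1f deg (%.2f hr)", x$mean_angle * 180 / pi,
                           angle_to_hours(x$mean_angle)),
              x$R, x$V))
  invisible(x)
}

#' Per-animal circular variance across tissues
#'
#' For each animal, the circular variance of its peak phases across the
#' listed tissues on a 24-hr circle. Invariant to a common phase offset, so
#' converting phases between reference frames (e.g. ZT to CT) leaves it
#' unchanged. Animals with fewer than two of the listed tissues are skipped
#' (logged in attribute \code{skipped}).
#'
#' @param phase_map data frame with \code{animal_id}, \code{tissue},
#'   \code{angle} (radians).
#' @param tissues tissues entering the variance (default the six peripheral
#'   tissues: pituitary, liver, kidney, heart, lung, spleen).
#' @return Data frame \code{animal_id}, \code{n_tissues}, \code{V}.
#' @export
per_animal_variance <- function(phase_map,
                                tissues = c("pituitary", "liver", "kidney",
                                            "heart", "lung", "spleen")) {
  pm <- phase_map[phase_map$tissue %in% tissues, , drop = FALSE]
  skipped <- character(0)
  rows <- lapply(split(pm, factor(pm$animal_id)), function(g) {
    if (nrow(g) < 2) { return(NULL) }
    data.frame(animal_id = g$animal_id[1], n_tissues = nrow(g),
               V = circ_summary(g$angle)$V)
  })
  counts <- table(factor(pm$animal_id))
  skipped <- names(counts)[counts < 2]
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Mann-Whitney U test (two-sided)
#'
#' Exact p by enumeration of all group assignments when the combined sample
#' size is at most 12 and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction.
#'
#' @param a,b numeric samples.
#' @return List with \code{U} (for group \code{a}), \code{p} and
#'   \code{method} (\code{"exact"} or \code{"normal"}).
#' @export
mann_whitney <- function(a, b) {
  na <- length(a); nb <- length(b)
  stopifnot(na >= 1, nb >= 1)
  N <- na + nb
  u_stat <- function(xa, xb)
    sum(outer(xa, xb, ">")) + 0.5 * sum(outer(xa, xb, "=="))
  U <- u_stat(a, b)
  ties <- any(duplicated(c(a, b)))
  if (N <= 12 && !ties) {
    pool <- c(a, b)
    combs <- utils::combn(N, na)
    dev <- abs(U - na * nb / 2)
    stats <- apply(combs, 2, function(idx)
      u_stat(pool[idx], pool[-idx]))
    p <- mean(abs(stats - na * nb / 2) >= dev - 1e-12)
    list(U = U, p = p, method = "exact")
  } else {
    mu <- na * nb / 2
    t_tab <- table(c(a, b))
    tie_term <- sum(t_tab^3 - t_tab) / (N * (N - 1))
    sig2 <- na * nb / 12 * (N + 1 - tie_term)
    if (sig2 <= 0) return(list(U = U, p = 1, method = "normal"))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
    list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
  }
}

#' Watson-Williams F test for equal mean directions
#'
#' Two-sample test of a common mean angle under the von Mises assumption:
#' \deqn{F = g (N - 2) (R_1 + R_2 - R) / (N - R_1 - R_2)} with group
#' resultant lengths \eqn{R_i} and combined resultant \eqn{R} (all
#' unnormalized), correction \eqn{g = 1 + 3 / (8 \hat\kappa)} where
#' \eqn{\hat\kappa} is estimated from the mean within-group resultant
#' \eqn{(R_1 + R_2)/N}; p from the F distribution with (1, N - 2) df. The
#' test assumes reasonably concentrated samples; a warning attribute is set
#' when the mean resultant falls below 0.45.
#'
#' @param a,b phase angles (radians).
#' @return List with \code{F}, \code{p}, \code{kappa},
#'   \code{low_concentration} (logical warning flag).
#' @export
watson_williams <- function(a, b) {
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  stopifnot(n1 >= 2, n2 >= 2)
  res_len <- function(x) sqrt(sum(cos(x))^2 + sum(sin(x))^2)
  R1 <- res_len(a); R2 <- res_len(b); R <- res_len(c(a, b))
  rbar <- (R1 + R2) / N
  kappa <- est_kappa(rbar)
  g <- 1 + 3 / (8 * kappa)
  Fstat <- g * (N - 2) * (R1 + R2 - R) / (N - R1 - R2)
  Fstat <- max(Fstat, 0)
  p <- stats::pf(Fstat, 1, N - 2, lower.tail = FALSE)
  low <- rbar < 0.45
  if (low)
    warning("mean resultant length ", signif(rbar, 3),
            " < 0.45: Watson-Williams assumptions doubtful")
  list(F = Fstat, p = p, kappa = kappa, low_concentration = low)
}

## ML-style estimate of the von Mises concentration from a mean resultant
est_kappa <- function(rbar) {
  if (rbar < 0.53) 2 * rbar + rbar^3 + 5 * rbar^5 / 6
  else if (rbar < 0.85) -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
  else 1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
}

#' Bootstrap test for a difference in circular variance
#'
#' Each iteration resamples both groups with replacement (within group) and
#' computes the difference of circular variances V*_A - V*_B; the percentile
#' confidence interval of the resampled differences determines significance
#' (significant iff the interval excludes zero). Deterministic under a
#' fixed seed.
#'
#' @param a,b phase angles (radians), each of length >= 3.
#' @param n_iter bootstrap iterations (default 20000).
#' @param conf_level confidence level of the percentile interval.
#' @param seed optional integer seed; the caller's RNG state is preserved.
#' @return List with \code{observed} (V_A - V_B), \code{ci} (length-2),
#'   \code{significant}, \code{n_iter}, \code{seed}.
#' @export
bootstrap_var_diff <- function(a, b, n_iter = 20000, conf_level = 0.95,
                               seed = NULL) {
  na <- length(a); nb <- length(b)
  stopifnot(na >= 3, nb >= 3)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  vA <- circ_summary(a)$V
  vB <- circ_summary(b)$V
  boot_v <- function(x, n) {
    idx <- matrix(sample.int(n, n * n_iter, replace = TRUE), nrow = n_iter)
    C <- rowMeans(matrix(cos(x)[idx], nrow = n_iter))
    S <- rowMeans(matrix(sin(x)[idx], nrow = n_iter))
    1 - sqrt(C^2 + S^2)
  }
  diffs <- boot_v(a, na) - boot_v(b, nb)
  alpha <- 1 - conf_level
  ci <- unname(stats::quantile(diffs, c(alpha / 2, 1 - alpha / 2)))
  list(observed = vA - vB, ci = ci,
       significant = ci[1] > 0 || ci[2] < 0, n_iter = n_iter, seed = seed)
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler; with \code{kappa = 0} draws are uniform
#' on the circle.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0).
#' @return Angles in [0, 2 pi).
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa == 0) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  bb <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + bb^2) / (2 * bb)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out %% (2 * pi)
}
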