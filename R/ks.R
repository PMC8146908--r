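#' Two-sample Kolmogorov–Smirnov test
#'
#' The statistic D is the maximum vertical distance between the two
#' empirical cumulative distribution functions, evaluated over the pooled
#' sample points. The two-sided p-value comes from the asymptotic
#' Kolmogorov distribution at `sqrt(ne) * D` with effective sample size
#' `ne = n1 * n2 / (n1 + n2)`; the alternating series is truncated once a
#' term falls below 1e-10 in magnitude. The null hypothesis (both samples
#' drawn from the same distribution) is rejected at alpha = 0.05.
#'
#' @param x,y Non-empty numeric samples.
#' @return A `sv_ks` with `d`, `p_value`, `n1`, `n2`, `reject_at_0_05`.
#' @examples
#' ks_two_sample(c(1, 3), c(2, 4))   # D = 0.5
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0 || length(y) == 0)
    abort("ks_two_sample needs two non-empty samples",
          class = "sv_domain_error")
  if (anyNA(x) || anyNA(y))
    abort("ks_two_sample does not accept missing values",
          class = "sv_domain_error")
  n1 <- length(x); n2 <- length(y)
  sx <- sort(x); sy <- sort(y)
  z <- sort(unique(c(sx, sy)))
  fx <- findInterval(z, sx) / n1
  fy <- findInterval(z, sy) / n2
  d <- max(abs(fx - fy))
  ne <- n1 * n2 / (n1 + n2)
  p <- kolmogorov_sf(sqrt(ne) * d)
  structure(list(d = d, p_value = p, n1 = n1, n2 = n2,
                 reject_at_0_05 = p < 0.05),
            class = "sv_ks")
}

# Asymptotic two-sided Kolmogorov survival function
# Q(lambda) = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 lambda^2),
# truncated at term magnitude 1e-10.
kolmogorov_sf <- function(lambda) {
  if (lambda <= 0) return(1)
  s <- 0
  for (k in 1:200) {
    term <- (-1)^(k - 1) * exp(-2 * k^2 * lambda^2)
    s <- s + term
    if (abs(term) < 1e-10) break
  }
  min(max(2 * s, 0), 1)
}

#' @export
print.sv_ks <- function(x, ...) {
  cat(sprintf("Two-sample KS test: D = %.4f, p = %.4g (n1 = %d, n2 = %d)\n",
              x$d, x$p_value, x$n1, x$n2))
  cat(if (x$reject_at_0_05)
    "H0 (same distribution) rejected at alpha = 0.05\n"
    else "H0 (same distribution) not rejected at alpha = 0.05\n")
  invisible(x)
}

#' @export
tidy.sv_ks <- function(x, ...) {
  tibble::tibble(statistic = x$d, p.value = x$p_value,
                 n1 = x$n1, n2 = x$n2, reject_at_0_05 = x$reject_at_0_05)
}

#' @export
glance.sv_ks <- function(x, ...) tidy(x)
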