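#' Calibrate environmental and residual variances
#'
#' Variance components are anchored to the genetic variance of a reference
#' (base) population and then frozen for the whole simulation. The
#' environmental variance is `env_ratio` times the reference genetic
#' variance. The residual variance is scaled so that the entry-mean
#' heritability — the heritability of the phenotype averaged over `n_env`
#' environments, which is the value selection actually consumes — equals
#' `h2`: `sigma_R2 = n_env * sigma_g2 * (1 - h2) / h2`, giving
#' `sigma_g2 / (sigma_g2 + sigma_R2 / n_env) = h2`.
#'
#' @param base_pop the reference `gs_pop` (typically the founder panels).
#' @param q a `gs_qtl`.
#' @param h2 target entry-mean heritability in (0, 1).
#' @param env_ratio ratio of environmental to genetic variance.
#' @param n_env number of environments per phenotyping event.
#' @return An object of class `gs_varsettings` with fields `sigma_g2_ref`,
#'   `sigma_E2`, `sigma_R2`, `h2`, `n_env`.
#' @export
calibrate_variances <- function(base_pop, q, h2 = 0.5, env_ratio = 8,
                                n_env = 3) {
  stopifnot(h2 > 0, h2 < 1, n_env >= 1, env_ratio >= 0)
  sg2 <- var(genetic_values(base_pop, q)$gv_raw)
  if (!is.finite(sg2) || sg2 <= 0)
    stop("base population is monomorphic at the QTL (zero genetic variance)",
         call. = FALSE)
  structure(list(sigma_g2_ref = sg2, sigma_E2 = env_ratio * sg2,
                 sigma_R2 = n_env * sg2 * (1 - h2) / h2,
                 h2 = h2, n_env = as.integer(n_env)),
            class = "gs_varsettings")
}

#' @export
print.gs_varsettings <- function(x, ...) {
  cat(sprintf(
    "<gs_varsettings> sigma_g2_ref = %.4g, sigma_E2 = %.4g, sigma_R2 = %.4g (h2 = %.2f, %d env)\n",
    x$sigma_g2_ref, x$sigma_E2, x$sigma_R2, x$h2, x$n_env))
  invisible(x)
}

#' Simulate multi-environment phenotypes
#'
#' One phenotyping event: for each environment j a single effect
#' `e_j ~ N(0, sigma_E2)` is drawn and shared by every individual, and each
#' individual gets an independent residual `eps_ij ~ N(0, sigma_R2)` per
#' environment. The recorded phenotype is the mean over environments of
#' `y_ij = g_i + e_j + eps_ij`, with `g_i` the raw genetic value.
#'
#' @param pop a `gs_pop`.
#' @param q a `gs_qtl`.
#' @param vs a `gs_varsettings`.
#' @param cycle breeding cycle recorded on the phenotype records.
#' @return A tibble with columns `id`, `cycle`, `value`.
#' @export
simulate_phenotypes <- function(pop, q, vs, cycle = 0L) {
  n <- n_ind(pop)
  g <- genetic_values(pop, q)$gv_raw
  e <- rnorm(vs$n_env, 0, sqrt(vs$sigma_E2))
  eps <- matrix(rnorm(n * vs$n_env, 0, sqrt(vs$sigma_R2)), nrow = n)
  y <- g + mean(e) + rowMeans(eps)
  tibble::tibble(id = pop$id, cycle = as.integer(cycle), value = y)
}
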