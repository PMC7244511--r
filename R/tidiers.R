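# broom-style accessors for the fitted kinetic objects

#' @exportS3Method generics::tidy
tidy.frap_fit <- function(x, ...) {
  tibble::tibble(
    term = c("f_inf", "a_fast", "a_slow", "k_fast", "k_slow", "t_half",
             "mobile_fraction"),
    estimate = c(x$f_inf, x$a_fast, x$a_slow, x$k_fast, x$k_slow, x$t_half,
                 x$mobile_fraction)
  )
}

#' @exportS3Method generics::glance
glance.frap_fit <- function(x, ...) {
  tibble::tibble(sse = x$sse, n = nrow(x$trace), mode = x$mode,
                 clipped = x$clipped)
}

#' @exportS3Method generics::tidy
tidy.fcs_fit <- function(x, ...) {
  tibble::tibble(
    term = c("n_particles", "tau_d", "structure_s", "diffusion_coef"),
    estimate = c(x$n_particles, x$tau_d, x$structure_s, x$diffusion_coef)
  )
}

#' @exportS3Method generics::glance
glance.fcs_fit <- function(x, ...) {
  tibble::tibble(sse = x$sse, n = nrow(x$curve))
}

#' @exportS3Method generics::tidy
tidy.binding_fit <- function(x, ...) {
  tibble::tibble(
    term = c("kd", "b0"),
    estimate = c(x$kd, x$b0),
    std.error = c(x$kd_se, NA_real_)
  )
}

#' @exportS3Method generics::glance
glance.binding_fit <- function(x, ...) {
  tibble::tibble(sse = x$sse, n = nrow(x$titration))
}

#' @exportS3Method generics::tidy
tidy.hier_clust <- function(x, ...) x$assignment

#' @exportS3Method generics::glance
glance.hier_clust <- function(x, ...) {
  tibble::tibble(k = x$k, n = nrow(x$assignment))
}

#' @exportS3Method generics::tidy
tidy.proximity_enrich <- function(x, ...) x$proteins

#' @exportS3Method generics::glance
glance.proximity_enrich <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$proteins), n_dropped = length(x$dropped),
    enriched_cluster = x$enriched_cluster,
    n_enriched = sum(x$proteins$enriched)
  )
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(
    "FRAP fit (%s): t1/2 = %.3g s, mobile fraction = %.3g%s, sse = %.3g\n",
    x$mode, x$t_half, x$mobile_fraction,
    if (x$clipped) " (clipped)" else "", x$sse))
  invisible(x)
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat(sprintf("FCS fit: N = %.4g, tauD = %.4g s, S = %.3g, sse = %.3g\n",
              x$n_particles, x$tau_d, x$structure_s, x$sse))
  invisible(x)
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("Competition fit: Kd = %.4g (SE %.3g), b0 = %.3g, sse = %.3g\n",
              x$kd, x$kd_se, x$b0, x$sse))
  invisible(x)
}
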