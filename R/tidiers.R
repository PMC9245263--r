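#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy and glance methods for pipeline results
#'
#' `tidy()` returns the per-unit table of a result object;
#' `glance()` a one-row summary.
#'
#' @param x a `recomb_support`, `homology_summary` or `editing_summary`
#'   object.
#' @param ... unused.
#' @return a tibble.
#' @name organellr-tidiers
NULL

#' @rdname organellr-tidiers
#' @method tidy recomb_support
#' @export
tidy.recomb_support <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @rdname organellr-tidiers
#' @method glance recomb_support
#' @export
glance.recomb_support <- function(x, ...) {
  tibble(n_repeats = nrow(x),
         n_active = sum(x$active),
         n_reads = sum(x$n_major + x$n_alternative + x$n_ambiguous))
}

#' @rdname organellr-tidiers
#' @method tidy homology_summary
#' @export
tidy.homology_summary <- function(x, ...) as_tibble(unclass(x))

#' @rdname organellr-tidiers
#' @method glance homology_summary
#' @export
glance.homology_summary <- function(x, ...) {
  tibble(n_hits = x$n_hits, cp_fraction = x$cp_fraction,
         mt_fraction = x$mt_fraction)
}

#' @rdname organellr-tidiers
#' @method tidy editing_summary
#' @export
tidy.editing_summary <- function(x, ...) x$per_type

#' @rdname organellr-tidiers
#' @method glance editing_summary
#' @export
glance.editing_summary <- function(x, ...) {
  tibble(n_sites = x$n_sites, pct_above_0.9 = x$`pct_above_0.9`,
         n_c_to_u = x$per_type$n[x$per_type$edit_type == "C to U"])
}
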