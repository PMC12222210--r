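#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a feature-enrichment result
#'
#' @param x An `nmisv_enrichment` object.
#' @param ... Unused.
#' @return A plain tibble, one row per feature class.
#' @method tidy nmisv_enrichment
#' @export
tidy.nmisv_enrichment <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "nmisv_enrichment")
  out
}

#' @rdname tidy.nmisv_enrichment
#' @return `glance()` returns a one-row tibble summarising the analysis
#'   (set size, ensemble size, classes tested / significant, correction).
#' @method glance nmisv_enrichment
#' @export
glance.nmisv_enrichment <- function(x, ...) {
  tibble(
    set_size = attr(x, "set_size"), n_sets = attr(x, "n_sets"),
    n_classes = nrow(x),
    n_significant = sum(!is.na(x$p_adj) & x$p_adj < 0.05),
    n_low_count = sum(x$low_count_flag),
    correction = attr(x, "correction")
  )
}

#' Tidy a target-gene DEG enrichment result
#'
#' @param x An `nmisv_deg` object from [target_deg_test()].
#' @param ... Unused.
#' @return Two-row tibble (target vs background genes) with expressed / DE
#'   counts and rates.
#' @method tidy nmisv_deg
#' @export
tidy.nmisv_deg <- function(x, ...) {
  tibble(
    group = c("target", "background"),
    n_expressed = c(x$T_genes, x$G - x$T_genes),
    n_de = c(x$t_obs, x$D - x$t_obs),
    de_rate = c(x$target_rate,
                (x$D - x$t_obs) / (x$G - x$T_genes))
  )
}

#' @rdname tidy.nmisv_deg
#' @method glance nmisv_deg
#' @export
glance.nmisv_deg <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "nmisv_deg")
  out
}

#' Tidy a candidate set
#'
#' @param x An `nmisv_candidates` object from [select_candidates()].
#' @param ... Unused.
#' @return The per-step filter provenance (counts in and out per step).
#' @method tidy nmisv_candidates
#' @export
tidy.nmisv_candidates <- function(x, ...) {
  attr(x, "steps")
}

#' @rdname tidy.nmisv_candidates
#' @method glance nmisv_candidates
#' @export
glance.nmisv_candidates <- function(x, ...) {
  th <- attr(x, "thresholds")
  tibble(n_candidates = nrow(x), f_disc_min = th[["f_disc_min"]],
         f_both_min = th[["f_both_min"]],
         n_blacklist = attr(x, "n_blacklist"))
}
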