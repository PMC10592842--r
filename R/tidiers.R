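#' Tidy an evaluation report
#'
#' @param x an `ft_eval`.
#' @param ... unused.
#' @return One row per section (`n_true`, `n_tp`, `n_fp`).
#' @method tidy ft_eval
#' @export
tidy.ft_eval <- function(x, ...) x$per_section

#' @rdname tidy.ft_eval
#' @method glance ft_eval
#' @export
glance.ft_eval <- function(x, ...) {
  tibble(tpr = x$tpr, fp_avg = x$fp_avg, delta_fd = x$delta_fd,
         delta_fd_abs = x$delta_fd_abs, n_true = x$n_true,
         n_tp = x$n_tp, n_fp = x$n_fp, n_sections = x$n_sections)
}

#' Tidy a pathway fiber-density report
#'
#' @param x an `ft_pathway_report`.
#' @param ... unused.
#' @return Per-pathway tibble (`pathway`, `n`, `mean_fd`, `se_fd`).
#' @method tidy ft_pathway_report
#' @export
tidy.ft_pathway_report <- function(x, ...) x$summary

#' @rdname tidy.ft_pathway_report
#' @method glance ft_pathway_report
#' @export
glance.ft_pathway_report <- function(x, ...) {
  tibble(f_statistic = x$f_statistic, p_value = x$p_value,
         df_between = x$df[1], df_within = x$df[2])
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
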