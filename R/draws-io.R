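#' Persist posterior draws as a delimited long table
#'
#' Columns: `chain`, `draw` (index within chain), `parameter`, `value`.
#'
#' @param fit a `posterior_draws` object.
#' @param path output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  stopifnot(inherits(fit, "posterior_draws"))
  pars <- colnames(fit$draws)
  draw_in_chain <- stats::ave(seq_along(fit$chain), fit$chain,
                              FUN = seq_along)
  long <- data.frame(
    chain = rep(fit$chain, times = length(pars)),
    draw = rep(draw_in_chain, times = length(pars)),
    parameter = rep(pars, each = nrow(fit$draws)),
    value = as.vector(fit$draws)
  )
  utils::write.table(long, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Persist a posterior summary table
#'
#' Columns: `parameter`, `mean`, `sd`, `q2.5`, `q97.5`, `rhat`.
#'
#' @param fit a `posterior_draws` object.
#' @param path output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_summary <- function(fit, path) {
  utils::write.table(summary(fit), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
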