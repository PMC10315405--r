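#' Plot modal consumption patterns
#'
#' Image of modal consumption levels (patterns x items), one colour per level:
#' none, low, medium, high — the standard display for derived dietary
#' profiles.
#'
#' @param summary An `rpc_pattern_summary` with `modal` filled in (see
#'   [summarize_rpc()]).
#' @param scope `"global"` or a subgroup index for a local pattern set.
#' @param ... Passed to [graphics::image()].
#' @export
plot_modal_patterns <- function(summary, scope = "global", ...) {
  modal <- summary$modal
  set <- if (identical(scope, "global")) modal$global
         else modal$local[[scope]]
  lev <- set$levels
  cols <- c("#1f3c88", "#76b5e6", "#58a55c", "#f2c14e")[seq_len(summary$d)]
  graphics::image(seq_len(ncol(lev)), seq_len(nrow(lev)), t(lev),
                  col = cols, zlim = c(1, summary$d), axes = FALSE,
                  xlab = "", ylab = "pattern",
                  main = paste("modal consumption levels:", scope), ...)
  graphics::axis(1, at = seq_len(ncol(lev)), labels = colnames(lev),
                 las = 2, cex.axis = 0.6)
  graphics::axis(2, at = seq_len(nrow(lev)))
  invisible(summary)
}

#' Plot the global-allocation probability heatmap
#'
#' Items on the y-axis, subgroups on the x-axis; darker cells mark items more
#' likely to follow a global (population-shared) pattern, lighter cells items
#' that localize to the subgroup.
#'
#' @param allocation An `rpc_allocation` from [allocation_heatmap()].
#' @param which `"G"` (indicator-based) or `"nu"` (allocation-probability
#'   based) estimate.
#' @param ... Passed to [graphics::image()].
#' @export
plot_allocation_heatmap <- function(allocation, which = "G", ...) {
  m <- allocation[[which]]
  pal <- grDevices::colorRampPalette(c("#f7fbff", "#08306b"))(100)
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m), col = pal,
                  zlim = c(0, 1), axes = FALSE, xlab = "subgroup", ylab = "",
                  main = "P(item follows a global pattern)", ...)
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m),
                 cex.axis = 0.8)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rownames(m), las = 2,
                 cex.axis = 0.6)
  invisible(allocation)
}
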