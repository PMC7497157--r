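#' Density plot of discriminant scores with cutoffs and PMarks
#'
#' Per-sex densities of the discriminant scores of a reference sample, with
#' the classical cutoff (score 0, solid) and any PMark levels (dotted /
#' dashed / dot-dash by level) as vertical lines. Requires ggplot2.
#'
#' @param model an `lda_sex_model`.
#' @param sample the [reference_sample()] to score.
#' @param pmarks optional `pmark_set` or `pmark_levels`.
#' @return A ggplot object.
#' @export
plot_scores <- function(model, sample, pmarks = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_scores() requires the ggplot2 package")
  }
  stopifnot(inherits(model, "lda_sex_model"),
            inherits(sample, "reference_sample"))
  df <- data.frame(
    score = discriminant_score(model, measurement_matrix(sample, model$variables)),
    sex = sample$data$sex)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$score, fill = .data$sex)) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::geom_vline(xintercept = 0, linetype = "solid") +
    ggplot2::labs(x = "discriminant score", y = "density", fill = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(pmarks)) {
    if (inherits(pmarks, "pmark_set")) pmarks <- list(pmarks)
    lt <- c("dotted", "dashed", "dotdash", "longdash")
    for (i in seq_along(pmarks)) {
      pm <- pmarks[[i]]
      gg <- gg + ggplot2::geom_vline(
        xintercept = c(pm$pmark_F, pm$pmark_M),
        linetype = lt[((i - 1L) %% length(lt)) + 1L])
    }
  }
  gg
}
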