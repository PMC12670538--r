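#' Omnibus ANOVA with rank-based post-hoc comparisons
#'
#' The reporting scheme used throughout the pipeline: an omnibus one- or
#' two-way ANOVA first; only when it is significant (`p < alpha`) are
#' pairwise post-hoc tests run - Wilcoxon signed rank for paired designs
#' (session means within subjects), Wilcoxon rank sum otherwise. All
#' tests are two-tailed. No further multiple-testing correction is
#' applied beyond this ANOVA-gated scheme.
#'
#' @param data Data frame with columns `value`, `group`, optionally
#'   `subject` (required for `design = "paired"`) and `factor2` (required
#'   for `design = "two_way"`).
#' @param design `"one_way"`, `"two_way"`, or `"paired"`.
#' @param alpha Gate for running post-hocs (default 0.05).
#' @return Data frame of test reports: `test`, `term`, `statistic`, `p`,
#'   `n_a`, `n_b`, `direction` (sign of the a-minus-b effect for
#'   post-hocs). Unbalanced two-way designs are fitted with type-II sums
#'   of squares, noted in the `test` field.
#' @export
stage_comparison <- function(data, design = c("one_way", "two_way", "paired"),
                             alpha = 0.05) {
  design <- match.arg(design)
  stopifnot(all(c("value", "group") %in% names(data)))
  data$group <- factor(data$group)
  if (nlevels(data$group) < 2) stop("need >= 2 groups")
  if (any(table(data$group) < 2)) stop("need >= 2 observations per group")
  reports <- list()
  add <- function(...) reports[[length(reports) + 1L]] <<- data.frame(...)

  if (design == "two_way") {
    stopifnot("factor2" %in% names(data))
    data$factor2 <- factor(data$factor2)
    balanced <- length(unique(table(data$group, data$factor2))) == 1
    fit <- lm(value ~ group * factor2, data = data)
    an <- car::Anova(fit, type = 2)
    for (term in setdiff(rownames(an), "Residuals"))
      add(test = paste0("two-way ANOVA (type II",
                        if (!balanced) ", unbalanced" else "", ")"),
          term = term, statistic = an[term, "F value"],
          p = an[term, "Pr(>F)"], n_a = nrow(data), n_b = NA,
          direction = NA)
    omnibus_p <- an["group", "Pr(>F)"]
  } else {
    an <- summary(aov(value ~ group, data = data))[[1]]
    add(test = "one-way ANOVA", term = "group",
        statistic = an["group", "F value"], p = an["group", "Pr(>F)"],
        n_a = nrow(data), n_b = NA, direction = NA)
    omnibus_p <- an["group", "Pr(>F)"]
  }

  if (is.finite(omnibus_p) && omnibus_p < alpha) {
    lv <- levels(data$group)
    cmb <- utils::combn(lv, 2)
    for (j in seq_len(ncol(cmb))) {
      ga <- cmb[1, j]; gb <- cmb[2, j]
      if (design == "paired") {
        stopifnot("subject" %in% names(data))
        wide <- merge(data[data$group == ga, c("subject", "value")],
                      data[data$group == gb, c("subject", "value")],
                      by = "subject")
        wt <- suppressWarnings(
          wilcox.test(wide$value.x, wide$value.y, paired = TRUE))
        test <- "Wilcoxon signed rank (paired)"
        na <- nb <- nrow(wide)
        dirn <- sign(median(wide$value.x - wide$value.y))
      } else {
        a <- data$value[data$group == ga]; b <- data$value[data$group == gb]
        wt <- suppressWarnings(wilcox.test(a, b))
        test <- "Wilcoxon rank sum"
        na <- length(a); nb <- length(b)
        dirn <- sign(median(a) - median(b))
      }
      add(test = test, term = paste(ga, "vs", gb),
          statistic = unname(wt$statistic), p = wt$p.value,
          n_a = na, n_b = nb, direction = dirn)
    }
  }
  do.call(rbind, reports)
}
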