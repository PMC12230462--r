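# Relative expression (2^-ddCt), normalization to control, and the
# group-comparison layer: unpaired t-test for two groups, one/two-way ANOVA
# with Tukey's HSD, Kruskal-Wallis with Dunn's post hoc for non-normal data.

#' Relative expression by the 2^-ddCt (Livak) method
#'
#' Per sample and target gene: dCt = Ct_target - Ct_housekeeping;
#' ddCt = dCt - mean(dCt of the control group); fold = 2^-ddCt.  Centering
#' on the arithmetic mean of the control dCt makes the control group's
#' geometric-mean fold exactly 1.
#'
#' @param table data.frame with columns `sample`, `group`, `gene`, `ct`
#' @param housekeeping housekeeping gene name (e.g. "Gapdh")
#' @param control control group label
#' @return data.frame, one row per sample x target gene: `sample`, `group`,
#'   `gene`, `dct`, `ddct`, `fold`
#' @export
ddct <- function(table, housekeeping = "Gapdh", control = "CTRL") {
  stopifnot(all(c("sample", "group", "gene", "ct") %in% names(table)))
  if (!control %in% table$group) stop("control group '", control, "' not in table")
  hk <- table[table$gene == housekeeping, ]
  if (anyNA(hk$ct) || any(!is.finite(hk$ct))) stop("non-finite housekeeping Ct")
  hk_ct <- stats::setNames(hk$ct, hk$sample)
  tg <- table[table$gene != housekeeping, , drop = FALSE]
  missing_hk <- setdiff(unique(tg$sample), names(hk_ct))
  if (length(missing_hk) > 0) {
    stop("samples without housekeeping Ct: ", paste(missing_hk, collapse = ", "))
  }
  tg$dct <- tg$ct - hk_ct[tg$sample]
  out <- do.call(rbind, lapply(split(tg, tg$gene), function(d) {
    ref <- mean(d$dct[d$group == control])
    d$ddct <- d$dct - ref
    d$fold <- 2^(-d$ddct)
    d
  }))
  rownames(out) <- NULL
  out[, c("sample", "group", "gene", "dct", "ddct", "fold")]
}

#' Normalize values to the control-group mean, in percent
#'
#' @param table data.frame with columns `group`, `value` (other columns kept)
#' @param control control group label
#' @return the table with `value` replaced by 100 * value / mean(control);
#'   the control group's mean maps to 100 exactly
#' @export
normalize_to_control <- function(table, control = "CTRL") {
  stopifnot(all(c("group", "value") %in% names(table)))
  ctl <- table$value[table$group == control]
  if (length(ctl) == 0) stop("control group '", control, "' not in table")
  m <- mean(ctl)
  if (m == 0) stop("control mean is zero: normalization undefined")
  table$value <- 100 * table$value / m
  table
}

#' Group comparison with the protocol's statistics
#'
#' Two groups: unpaired Student's t-test.  More groups: one-way ANOVA with
#' Tukey's HSD; with a second factor, two-way ANOVA with Tukey contrasts on
#' the group factor within each level of the second factor.  `auto` runs a
#' Shapiro-Wilk normality screen per group (alpha 0.05) and falls back to
#' Kruskal-Wallis with Dunn's post hoc when any group fails.
#'
#' @param table data.frame with columns `group`, `value`, optionally
#'   `factor2` (e.g. pacing frequency) for the two-way design
#' @param design `"auto"`, `"one-way"`, `"two-way"`, `"nonparametric"`, or
#'   `"t-test"`
#' @param alpha significance level carried in the result (0.05)
#' @param dunn_adjust p adjustment for Dunn's test: `"holm"` (default) or
#'   `"bonferroni"`
#' @return list of class `group_test`: `method`, `statistic`, `p_value`
#'   (omnibus), `pairwise` (data.frame pair / p_adjusted), `alpha`,
#'   `degenerate` flag
#' @export
compare_groups <- function(table, design = c("auto", "one-way", "two-way",
                                             "nonparametric", "t-test"),
                           alpha = 0.05, dunn_adjust = c("holm", "bonferroni")) {
  design <- match.arg(design)
  dunn_adjust <- match.arg(dunn_adjust)
  stopifnot(all(c("group", "value") %in% names(table)))
  table$group <- factor(table$group)
  groups <- levels(table$group)
  if (length(groups) < 2) stop("need at least 2 groups")
  sizes <- table(table$group)
  if (any(sizes < 2)) {
    stop("groups with fewer than 2 observations: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  degenerate <- all(tapply(table$value, table$group, stats::var) == 0)
  if (design == "auto") {
    normal <- vapply(split(table$value, table$group), function(v) {
      if (length(unique(v)) < 3) return(TRUE)
      stats::shapiro.test(v)$p.value >= 0.05
    }, logical(1))
    design <- if (!all(normal)) "nonparametric"
      else if ("factor2" %in% names(table)) "two-way"
      else if (length(groups) == 2) "t-test" else "one-way"
  }
  out <- switch(design,
    "t-test" = {
      if (length(groups) != 2) stop("t-test needs exactly 2 groups")
      v1 <- table$value[table$group == groups[1]]
      v2 <- table$value[table$group == groups[2]]
      if (degenerate && identical(sort(v1), sort(v2))) {
        list(method = "t-test", statistic = 0, p_value = 1, pairwise = NULL)
      } else {
        tt <- stats::t.test(v1, v2, var.equal = TRUE)
        list(method = "t-test", statistic = unname(tt$statistic),
             p_value = tt$p.value, pairwise = NULL)
      }
    },
    "one-way" = {
      fit <- stats::aov(value ~ group, data = table)
      an <- summary(fit)[[1]]
      tk <- stats::TukeyHSD(fit)$group
      list(method = "one-way ANOVA + Tukey HSD",
           statistic = an[["F value"]][1], p_value = an[["Pr(>F)"]][1],
           pairwise = data.frame(pair = rownames(tk),
                                 p_adjusted = tk[, "p adj"],
                                 row.names = NULL))
    },
    "two-way" = {
      if (!"factor2" %in% names(table)) stop("two-way design needs a factor2 column")
      table$factor2 <- factor(table$factor2)
      fit <- stats::aov(value ~ group * factor2, data = table)
      an <- summary(fit)[[1]]
      pw <- do.call(rbind, lapply(levels(table$factor2), function(l) {
        sub <- table[table$factor2 == l, ]
        tk <- stats::TukeyHSD(stats::aov(value ~ group, data = sub))$group
        data.frame(pair = paste0(rownames(tk), " | factor2=", l),
                   p_adjusted = tk[, "p adj"], row.names = NULL)
      }))
      i <- grep("^group *$", trimws(rownames(an)))
      if (length(i) == 0) i <- 1
      list(method = "two-way ANOVA + Tukey HSD within levels",
           statistic = an[["F value"]][i], p_value = an[["Pr(>F)"]][i],
           pairwise = pw)
    },
    "nonparametric" = {
      kw <- stats::kruskal.test(value ~ group, data = table)
      list(method = "Kruskal-Wallis + Dunn",
           statistic = unname(kw$statistic), p_value = kw$p.value,
           pairwise = dunn_test(table$value, table$group, adjust = dunn_adjust))
    })
  structure(c(out, list(alpha = alpha, degenerate = degenerate,
                        design = design)), class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, omnibus p = %.4g (alpha %.2f)\n",
              x$method, x$statistic, x$p_value, x$alpha))
  if (!is.null(x$pairwise)) {
    cat("pairwise (adjusted):\n")
    print(x$pairwise, digits = 4)
  }
  invisible(x)
}

#' Dunn's rank-based post hoc test
#'
#' Pairwise z statistics on mean ranks with the tie-corrected Kruskal-Wallis
#' variance,
#' z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T)(1/n_i + 1/n_j)),
#' T = sum(t^3 - t) / (12 (N - 1)) over tie groups; two-sided p values with
#' Holm (default) or Bonferroni adjustment.
#'
#' @param value numeric vector
#' @param group factor of the same length
#' @param adjust `"holm"` or `"bonferroni"`
#' @return data.frame: `pair`, `z`, `p_unadjusted`, `p_adjusted`
#' @export
dunn_test <- function(value, group, adjust = c("holm", "bonferroni")) {
  adjust <- match.arg(adjust)
  group <- factor(group)
  n <- length(value)
  r <- rank(value)
  ties <- table(value)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  s2 <- n * (n + 1) / 12 - tie_corr
  rb <- tapply(r, group, mean)
  ns <- tapply(r, group, length)
  gl <- levels(group)
  pairs <- utils::combn(gl, 2)
  z <- apply(pairs, 2, function(p) {
    (rb[[p[1]]] - rb[[p[2]]]) / sqrt(s2 * (1 / ns[[p[1]]] + 1 / ns[[p[2]]]))
  })
  p_un <- 2 * stats::pnorm(-abs(z))
  data.frame(pair = apply(pairs, 2, paste, collapse = "-"), z = z,
             p_unadjusted = p_un,
             p_adjusted = stats::p.adjust(p_un, method = adjust))
}

#' Write / read a tidy group table as CSV
#' @param table data.frame (unit id, group, value, optional factor2)
#' @param path CSV path
#' @export
write_group_csv <- function(table, path) {
  num <- vapply(table, is.numeric, logical(1))
  out <- table
  out[num] <- lapply(table[num], .fmt_num)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_group_csv
#' @export
read_group_csv <- function(path) {
  utils::read.csv(path)
}
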