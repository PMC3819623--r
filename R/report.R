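# Group-level summaries and statistics: mean +/- SEM per group, one-way or
# two-way repeated-measures ANOVA with Bonferroni-adjusted pairwise
# post-hoc comparisons, and the significance-star convention used in the
# figures (p < 0.05 / 0.01 / 0.001).

#' Summarize a measurement table by group
#'
#' @param table data.frame with at least columns \code{group} and
#'   \code{value}; an optional \code{timepoint} column subdivides groups
#' @return data.frame per group (x timepoint): n, mean, sd, sem. SEM is
#'   sd/sqrt(n) with the sample (n-1) sd and is NA for single values;
#'   empty groups are dropped with a warning.
#' @examples
#' summarizeGroups(data.frame(group = "a", value = c(1, 2, 3)))
#' @export
summarizeGroups <- function(table) {
  stopifnot(all(c("group", "value") %in% names(table)))
  keys <- if ("timepoint" %in% names(table))
    interaction(table$group, table$timepoint, drop = FALSE)
  else factor(table$group)
  drop <- is.na(table$value)
  if (any(drop)) {
    warning(sum(drop), " missing values excluded from summary")
    table <- table[!drop, , drop = FALSE]
    keys <- droplevels(keys[!drop])
  }
  out <- do.call(rbind, lapply(split(table, keys), function(g) {
    n <- nrow(g)
    data.frame(group = g$group[1],
               timepoint = if ("timepoint" %in% names(g)) g$timepoint[1]
                 else NA,
               n = n, mean = mean(g$value),
               sd = if (n > 1) sd(g$value) else NA_real_,
               sem = if (n > 1) sd(g$value) / sqrt(n) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Compare groups by ANOVA with Bonferroni post-hoc tests
#'
#' One-way ANOVA across groups, or two-way repeated-measures ANOVA
#' (within-subject factor \code{timepoint}, subject id \code{embryo_id}).
#' Pairwise post-hoc comparisons are two-sample t tests whose p-values are
#' Bonferroni-adjusted: raw p x number of comparisons in the family,
#' capped at 1. For the repeated-measures design the pairwise family is
#' all group pairs within each timepoint.
#'
#' @param table data.frame with columns \code{group}, \code{value}, plus
#'   \code{timepoint} and \code{embryo_id} for the repeated design
#' @param design \code{"one_way"} or \code{"two_way_repeated"}
#' @return list with \code{anova} (data.frame of F tests) and
#'   \code{pairwise} (data.frame: comparison, raw p, Bonferroni p, stars)
#' @export
compareGroups <- function(table, design = c("one_way", "two_way_repeated")) {
  design <- match.arg(design)
  stopifnot(all(c("group", "value") %in% names(table)))
  table$group <- factor(table$group)
  if (nlevels(table$group) < 2)
    stop("need >= 2 groups to compare")
  if (any(tapply(table$value, table$group, length) < 2))
    stop("need >= 2 values per group")

  if (design == "one_way") {
    fit <- aov(value ~ group, data = table)
    an <- as.data.frame(summary(fit)[[1]])
    an <- data.frame(term = trimws(rownames(an)), an, check.names = FALSE,
                     row.names = NULL)
    pw <- pairwiseBonferroni(table)
  } else {
    if (!all(c("timepoint", "embryo_id") %in% names(table)))
      stop("two_way_repeated design needs timepoint and embryo_id columns")
    table$timepoint <- factor(table$timepoint)
    table$embryo_id <- factor(table$embryo_id)
    cells <- table(table$group, table$timepoint)
    if (any(cells == 0))
      stop("unbalanced repeated-measures design: empty group x timepoint cell")
    fit <- aov(value ~ group * timepoint + Error(embryo_id / timepoint),
               data = table)
    an <- do.call(rbind, lapply(summary(fit), function(s) {
      d <- as.data.frame(s[[1]])
      data.frame(term = trimws(rownames(d)), d, check.names = FALSE,
                 row.names = NULL)
    }))
    rownames(an) <- NULL
    pw <- do.call(rbind, lapply(levels(table$timepoint), function(tp) {
      sub <- table[table$timepoint == tp, , drop = FALSE]
      res <- pairwiseBonferroni(sub)
      res$timepoint <- tp
      res
    }))
  }
  list(anova = an, pairwise = pw)
}

# All pairwise Welch t tests within `table`, Bonferroni-adjusted over the
# family of all pairs present.
pairwiseBonferroni <- function(table) {
  gl <- levels(droplevels(factor(table$group)))
  pairs <- combn(gl, 2, simplify = FALSE)
  k <- length(pairs)
  out <- do.call(rbind, lapply(pairs, function(pr) {
    a <- table$value[table$group == pr[1]]
    b <- table$value[table$group == pr[2]]
    p <- if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b)) 1
      else t.test(a, b)$p.value
    data.frame(comparison = paste(pr, collapse = " vs "),
               p_raw = p, p_bonferroni = min(1, p * k))
  }))
  out$stars <- significanceStars(out$p_bonferroni)
  out
}

#' Significance stars at the usual convention
#'
#' @param p numeric p-values
#' @return character: "***" p<0.001, "**" p<0.01, "*" p<0.05, "" otherwise
#' @export
significanceStars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}
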