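# --- Screening statistics -----------------------------------------------------

#' Stimulus-preference bias of a bout-locked metric
#'
#' For each unit (region or pair) and task: bias = value(preferred stimulus) -
#' value(less-preferred stimulus). Sign convention: positive means biased
#' toward the task's preferred stimulus (SP: social; EsP: isolated;
#' SxP: female).
#'
#' @param table long table with columns `task`, `stimulus`, `value`, and a
#'   unit column (`pair` or `region`), e.g. from [dataset_coherence_table()]
#'   in bout mode, averaged over sessions.
#' @param unit_col name of the unit column.
#' @return data frame `unit, task, bias`.
#' @export
bias_table <- function(table, unit_col = "pair") {
  ag <- aggregate(table$value,
                  by = list(unit = table[[unit_col]], task = table$task,
                            stimulus = table$stimulus),
                  FUN = mean, na.rm = TRUE)
  names(ag)[4] <- "value"
  out <- do.call(rbind, lapply(split(ag, list(ag$unit, ag$task), drop = TRUE),
    function(d) {
      pref <- task_preferred_stimulus(d$task[1])
      vp <- d$value[d$stimulus == pref]
      vo <- d$value[d$stimulus != pref]
      if (!length(vp) || !length(vo)) return(NULL)
      data.frame(unit = d$unit[1], task = d$task[1], bias = vp - mean(vo),
                 stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out
}

#' Select units crossing the mean +/- 1.5 SD bias threshold
#'
#' A unit is selected iff its bias strictly exceeds `mean + k_sd * SD` or falls
#' strictly below `mean - k_sd * SD` of the bias distribution over all units
#' (for one task/band/metric). Ties exactly at the boundary are not selected
#' ("crossed" read strictly).
#'
#' @param biases numeric vector of unit biases (named by unit).
#' @param k_sd threshold multiplier (default 1.5).
#' @return list with `selected` (names or indices), `direction` (+1/-1 per
#'   selected unit), `mean`, `sd`, `lower`, `upper`.
#' @export
threshold_bias <- function(biases, k_sd = 1.5) {
  stopifnot(length(biases) >= 3)
  m <- mean(biases); s <- sd(biases)
  if (!is.finite(s) || s == 0) {
    warning("zero SD of biases; nothing selected")
    return(list(selected = character(0), direction = integer(0),
                mean = m, sd = s, lower = m, upper = m))
  }
  lo <- m - k_sd * s; hi <- m + k_sd * s
  up <- biases > hi; dn <- biases < lo
  ids <- names(biases) %||% as.character(seq_along(biases))
  sel <- ids[up | dn]
  list(selected = sel,
       direction = setNames(ifelse(up[up | dn], 1L, -1L), sel),
       mean = m, sd = s, lower = lo, upper = hi)
}

#' Region over-representation among selected pairs
#'
#' For each region: `k` = number of selected pairs containing it, `m` = number
#' of selected pairs, `p0` = fraction of universe pairs containing it; exact
#' one-sided binomial tail `P(X >= k)`, `X ~ Binomial(m, p0)`.
#'
#' @param selected_pairs,universe_pairs character vectors of pair keys
#'   (`"A|B"`).
#' @return data frame `region, k, m, p0, p`, sorted by p.
#' @export
region_overrepresentation <- function(selected_pairs, universe_pairs) {
  stopifnot(length(universe_pairs) > 0)
  um <- pair_split(universe_pairs)
  regions <- sort(unique(as.vector(um)))
  sm <- if (length(selected_pairs)) pair_split(selected_pairs) else
    matrix(character(0), ncol = 2)
  m <- length(selected_pairs)
  out <- do.call(rbind, lapply(regions, function(r) {
    k <- sum(sm[, 1] == r | sm[, 2] == r)
    p0 <- mean(um[, 1] == r | um[, 2] == r)
    p <- if (k == 0) 1 else pbinom(k - 1, m, p0, lower.tail = FALSE)
    data.frame(region = r, k = k, m = m, p0 = p0, p = min(1, p),
               stringsAsFactors = FALSE)
  }))
  out[order(out$p), ]
}

#' Octant classification of per-task bias signs
#'
#' Each region's bias sign across the three tasks (SP, EsP, SxP) places it in
#' one of 8 sign combinations; the function reports per-octant counts and the
#' exact binomial tail probability of the observed maximum-octant count under
#' uniform 1/8 assignment. Zero biases are tie-broken to the positive class
#' with a warning.
#'
#' @param biases data frame `unit, task, bias` covering all three tasks per
#'   unit (see [bias_table()]).
#' @return list with `octants` (data frame `unit, SP, EsP, SxP, octant`),
#'   `counts` (table over the 8 octants), `max_count`, and `p_arrangement`
#'   (`P(X >= max_count)`, `X ~ Binomial(n_units, 1/8)`).
#' @export
octant_classification <- function(biases) {
  wide <- do.call(rbind, lapply(split(biases, biases$unit), function(d) {
    if (!all(task_vocabulary() %in% d$task)) return(NULL)
    v <- setNames(d$bias[match(task_vocabulary(), d$task)], task_vocabulary())
    if (any(v == 0)) warning("zero bias tie-broken to the positive class for ",
                             d$unit[1])
    sg <- ifelse(v >= 0, "+", "-")
    data.frame(unit = d$unit[1], SP = sg[["SP"]], EsP = sg[["EsP"]],
               SxP = sg[["SxP"]],
               octant = paste0(sg, collapse = ""), stringsAsFactors = FALSE)
  }))
  rownames(wide) <- NULL
  all_oct <- apply(expand.grid(c("+", "-"), c("+", "-"), c("+", "-")), 1,
                   paste0, collapse = "")
  counts <- table(factor(wide$octant, levels = sort(all_oct)))
  kmax <- max(counts)
  n <- nrow(wide)
  list(octants = wide, counts = counts, max_count = kmax,
       p_arrangement = pbinom(kmax - 1, n, 1 / 8, lower.tail = FALSE))
}

#' Correlation with two-sided test
#'
#' Pearson's or Spearman's correlation, pairwise removal of missing values.
#'
#' @param x,y equal-length numeric vectors.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `r`, `p`, `n`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance input")
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up BH procedure: returns the rejected set at level `q` and monotone
#' adjusted p-values.
#'
#' @param pvals p-values in [0, 1].
#' @param q FDR level.
#' @return list with `rejected` (logical), `p_adj`.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  p_adj <- p.adjust(pvals, method = "BH")
  list(rejected = !is.na(p_adj) & p_adj <= q, p_adj = p_adj)
}

#' Normality-dispatched group comparison
#'
#' Screens each sample (the paired differences, for a paired design) with
#' Shapiro-Wilk and dispatches: paired t / Wilcoxon signed-rank, two-sample t /
#' Mann-Whitney, or one-way ANOVA / Kruskal-Wallis with Dunn's post-hoc
#' (BH-adjusted).
#'
#' @param samples list of numeric vectors (length 2 for the two-sample
#'   designs).
#' @param design `"paired_2"`, `"unpaired_2"` or `"k_groups"`.
#' @param alpha normality-screen level.
#' @return list with `test` (name), `statistic`, `p`, `normal`, and for
#'   `k_groups` a `posthoc` data frame (Dunn's z and adjusted p per pair).
#' @export
group_compare <- function(samples, design = c("paired_2", "unpaired_2",
                                              "k_groups"),
                          alpha = 0.05) {
  design <- match.arg(design)
  shapiro_ok <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 3 || sd(x) == 0) return(FALSE)
    shapiro.test(x)$p.value > alpha
  }
  if (design == "paired_2") {
    stopifnot(length(samples) == 2, length(samples[[1]]) == length(samples[[2]]))
    d <- samples[[1]] - samples[[2]]
    if (length(d) < 3) stop("too few pairs")
    if (all(d == 0))
      return(list(test = "identical", statistic = 0, p = 1, normal = NA))
    if (shapiro_ok(d)) {
      tt <- t.test(samples[[1]], samples[[2]], paired = TRUE)
      list(test = "paired t", statistic = unname(tt$statistic), p = tt$p.value,
           normal = TRUE)
    } else {
      wt <- suppressWarnings(wilcox.test(samples[[1]], samples[[2]],
                                         paired = TRUE))
      list(test = "wilcoxon signed-rank", statistic = unname(wt$statistic),
           p = wt$p.value, normal = FALSE)
    }
  } else if (design == "unpaired_2") {
    stopifnot(length(samples) == 2)
    if (min(lengths(samples)) < 3) stop("too few observations per group")
    if (all(vapply(samples, shapiro_ok, logical(1)))) {
      tt <- t.test(samples[[1]], samples[[2]])
      list(test = "t", statistic = unname(tt$statistic), p = tt$p.value,
           normal = TRUE)
    } else {
      wt <- suppressWarnings(wilcox.test(samples[[1]], samples[[2]]))
      list(test = "mann-whitney", statistic = unname(wt$statistic),
           p = wt$p.value, normal = FALSE)
    }
  } else {
    stopifnot(length(samples) >= 3)
    if (min(lengths(samples)) < 3) stop("too few observations per group")
    g <- factor(rep(seq_along(samples), lengths(samples)))
    x <- unlist(samples)
    if (all(vapply(samples, shapiro_ok, logical(1)))) {
      fit <- aov(x ~ g)
      s <- summary(fit)[[1]]
      list(test = "anova", statistic = s$`F value`[1], p = s$`Pr(>F)`[1],
           normal = TRUE, posthoc = NULL)
    } else {
      kw <- kruskal.test(x, g)
      list(test = "kruskal-wallis", statistic = unname(kw$statistic),
           p = kw$p.value, normal = FALSE, posthoc = dunn_posthoc(x, g))
    }
  }
}

# Dunn's post-hoc z tests on rank sums with tie correction, BH-adjusted.
dunn_posthoc <- function(x, g) {
  n <- length(x)
  r <- rank(x)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  levs <- levels(g)
  rbar <- tapply(r, g, mean)
  ni <- tapply(r, g, length)
  out <- list()
  for (i in seq_along(levs)) for (j in seq_along(levs)) {
    if (j <= i) next
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ni[i] + 1 / ni[j]))
    z <- (rbar[i] - rbar[j]) / se
    out[[length(out) + 1]] <- data.frame(
      group1 = levs[i], group2 = levs[j], z = unname(z),
      p = 2 * pnorm(-abs(unname(z))), stringsAsFactors = FALSE)
  }
  ph <- do.call(rbind, out)
  ph$p_adj <- p.adjust(ph$p, method = "BH")
  ph
}
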