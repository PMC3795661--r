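#' Attribute taxa to temporal scales by Spearman rank correlation
#'
#' Relates every taxon's raw (untransformed) biovolume series to the lc
#' scores of each significant canonical axis by a two-sided Spearman rank
#' test. A taxon is assigned to the axis with the largest absolute rho among
#' the axes where the test is significant at `alpha_species`; ties go to the
#' lower-numbered (slower) axis. Taxa significant on no axis — and taxa with
#' constant series, for which rank correlation is undefined — are counted as
#' stochastic. Assignment is unique, so the per-axis counts and the
#' stochastic count always partition the taxon total.
#'
#' @param cts the [community_ts()] the model was fitted to.
#' @param model a fitted [scale_rda()] with at least one significant axis
#'   (with none, use [empty_attribution()] semantics: everything
#'   stochastic).
#' @param alpha_species per-test significance level.
#' @param p_adjust_method optional [stats::p.adjust()] method applied per
#'   taxon across axes (`"none"` by default: plain screening).
#' @return Object of class `scale_attribution`: `assignment` (per-taxon
#'   axis label or `"Stochastic"`), `rho` and `p_value` matrices
#'   (taxa x axes), `per_axis_species` (list of taxon sets), `counts`,
#'   `percentages` (integer percents of the total, rounded half away from
#'   zero), `total`.
#' @export
attribute_species <- function(cts, model, alpha_species = 0.05,
                              p_adjust_method = "none") {
  sig <- which(model$axes$significant)
  taxa <- cts$taxa
  if (!length(sig)) return(empty_attribution(taxa))
  lc <- model$lc_scores[, sig, drop = FALSE]
  Y <- cts$biovolume

  rho <- p <- matrix(NA_real_, length(taxa), length(sig),
                     dimnames = list(taxa, colnames(lc)))
  for (j in seq_along(taxa)) {
    yj <- Y[, j]
    if (length(unique(yj)) < 2L) next       # constant: rho undefined
    for (k in seq_along(sig)) {
      ct <- suppressWarnings(
        cor.test(yj, lc[, k], method = "spearman", exact = FALSE))
      rho[j, k] <- unname(ct$estimate)
      p[j, k] <- ct$p.value
    }
  }
  p_eff <- p
  if (p_adjust_method != "none")
    p_eff <- t(apply(p, 1, stats::p.adjust, method = p_adjust_method))

  assignment <- rep("Stochastic", length(taxa))
  names(assignment) <- taxa
  for (j in seq_along(taxa)) {
    ok <- which(!is.na(p_eff[j, ]) & p_eff[j, ] <= alpha_species)
    if (length(ok)) {
      best <- ok[which.max(abs(rho[j, ok]))]   # which.max: first (slower) wins ties
      assignment[j] <- colnames(lc)[best]
    }
  }
  build_attribution(assignment, colnames(lc), rho = rho, p_value = p)
}

#' All-stochastic attribution for an empty model
#'
#' @param taxa taxon labels.
#' @return A `scale_attribution` assigning every taxon to the stochastic
#'   set (the case of a community window with no significant temporal
#'   structure).
#' @export
empty_attribution <- function(taxa) {
  assignment <- rep("Stochastic", length(taxa))
  names(assignment) <- taxa
  build_attribution(assignment, character(0), rho = NULL, p_value = NULL)
}

build_attribution <- function(assignment, axis_names, rho, p_value) {
  levels <- c(axis_names, "Stochastic")
  counts <- vapply(levels, function(l) sum(assignment == l), integer(1))
  total <- length(assignment)
  structure(list(assignment = assignment,
                 per_axis_species = lapply(levels[seq_along(axis_names)],
                                           function(l) names(assignment)[assignment == l]),
                 rho = rho, p_value = p_value,
                 counts = counts,
                 percentages = scale_percentages(counts, total),
                 total = total),
            class = "scale_attribution")
}

# integer percentages, rounded half away from zero
scale_percentages <- function(counts, total) {
  if (total == 0) return(counts * NA_integer_)
  x <- 100 * counts / total
  stats::setNames(as.integer(sign(x) * floor(abs(x) + 0.5)), names(counts))
}

#' Build an attribution from per-axis counts
#'
#' Reconstructs a `scale_attribution` from published per-axis species
#' counts and a taxon total (anonymous taxon labels), deriving the
#' stochastic count as the remainder. Useful for re-deriving stochastic
#' fractions and percentages from reported count tables.
#'
#' @param per_axis integer vector of species counts on axes 1..k.
#' @param total total number of taxa used for modelling.
#' @return A `scale_attribution`.
#' @examples
#' a <- attribution_from_counts(c(15, 6, 2, 8, 4), total = 50)
#' count_stochastic(a)                    # 15
#' a$percentages[["Stochastic"]]          # 30
#' @export
attribution_from_counts <- function(per_axis, total) {
  per_axis <- as.integer(per_axis)
  n_st <- total - sum(per_axis)
  if (n_st < 0) stop("per-axis counts exceed the total")
  axes <- paste0("RDA", seq_along(per_axis))
  assignment <- c(if (length(per_axis)) rep(axes, per_axis),
                  rep("Stochastic", n_st))
  names(assignment) <- paste0("taxon", seq_len(total))
  build_attribution(assignment, axes, rho = NULL, p_value = NULL)
}

#' Stochastic species count
#'
#' The number of taxa attributed to no significant canonical axis: the
#' total minus the sum of the per-axis counts.
#'
#' @param attribution a `scale_attribution`.
#' @return Integer count.
#' @export
count_stochastic <- function(attribution) {
  k <- length(attribution$counts)
  attribution$total - sum(attribution$counts[-k])
}

#' @export
print.scale_attribution <- function(x, ...) {
  df <- data.frame(count = x$counts,
                   percent = x$percentages)
  cat(sprintf("Species attribution (%d taxa):\n", x$total))
  print(df)
  invisible(x)
}

#' Resilience summary across site-state models
#'
#' Collates the resilience attributes of a set of fitted models: the
#' cross-scale structure (number of significant canonical axes), the
#' within-scale richness (taxa per axis), the stochastic fraction and the
#' model's adjusted R-squared; optionally a paired comparison between two
#' states (deltas computed as `second - first` per site).
#'
#' @param fits list of fitted [scale_rda()] objects.
#' @param compare_states optional character vector of two state labels to
#'   contrast (e.g. `c("wet", "dry")`).
#' @return Object of class `resilience_summary`: `table` (one row per
#'   site-state) and, when requested, `contrast` (per-site deltas of
#'   n_scales, stochastic percent and adjusted R-squared).
#' @export
resilience_summary <- function(fits, compare_states = NULL) {
  rows <- lapply(fits, function(f) {
    ws <- f$attribution$counts
    ws <- ws[-length(ws)]                    # drop stochastic row
    data.frame(site = f$community$site_id, state = f$community$state_id,
               n_scales = f$n_scales,
               within_scale = paste(ws[seq_len(f$n_scales)], collapse = ","),
               stochastic_n = f$attribution$counts[["Stochastic"]],
               stochastic_pct = f$attribution$percentages[["Stochastic"]],
               total_taxa = f$attribution$total,
               adj_r2 = f$adj_r2)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  out <- list(table = tab, contrast = NULL)
  if (!is.null(compare_states)) {
    stopifnot(length(compare_states) == 2)
    a <- tab[tab$state == compare_states[1], ]
    b <- tab[tab$state == compare_states[2], ]
    common <- intersect(a$site, b$site)
    a <- a[match(common, a$site), ]; b <- b[match(common, b$site), ]
    out$contrast <- data.frame(
      site = common,
      d_n_scales = b$n_scales - a$n_scales,
      d_stochastic_pct = b$stochastic_pct - a$stochastic_pct,
      d_adj_r2 = b$adj_r2 - a$adj_r2)
  }
  class(out) <- "resilience_summary"
  out
}

#' @export
print.resilience_summary <- function(x, digits = 3, ...) {
  cat("Resilience attributes per site and state:\n")
  print(x$table, row.names = FALSE, digits = digits)
  if (!is.null(x$contrast)) {
    cat("\nState contrast (second minus first):\n")
    print(x$contrast, row.names = FALSE, digits = digits)
  }
  invisible(x)
}

#' Cross-tabulate attributions in the style of a per-axis count table
#'
#' Builds the table of per-axis and stochastic counts across site-state
#' models, each cell formatted `count(percent)`, with a final `Total` row —
#' the standard presentation of within-scale species distributions.
#'
#' @param fits list of fitted [scale_rda()] objects.
#' @return Character matrix, rows = RDA 1..k / Stochastic / Total, columns =
#'   site-state.
#' @export
attribution_table <- function(fits) {
  kmax <- max(vapply(fits, function(f) f$n_scales, integer(1)), 1L)
  rows <- c(paste("RDA", seq_len(kmax)), "Stochastic", "Total")
  cols <- vapply(fits, function(f)
    paste0(f$community$site_id, ".", f$community$state_id), character(1))
  m <- matrix("---", length(rows), length(cols), dimnames = list(rows, cols))
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    cnt <- f$attribution$counts
    pct <- f$attribution$percentages
    if (f$n_scales > 0)
      for (k in seq_len(f$n_scales))
        m[k, i] <- sprintf("%d(%d)", cnt[[k]], pct[[k]])
    m["Stochastic", i] <- sprintf("%d(%d)", cnt[["Stochastic"]],
                                  pct[["Stochastic"]])
    m["Total", i] <- as.character(f$attribution$total)
  }
  m
}
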