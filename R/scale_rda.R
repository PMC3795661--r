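#' Scale-specific time series model of community dynamics
#'
#' Fits the full temporal model for one community window (one site in one
#' state): the biovolume matrix is Hellinger-transformed, an AEM temporal
#' basis is built from the window's own time vector, a parsimonious
#' predictor set is chosen by permutation-based forward selection (gated on
#' a significant global model), a redundancy analysis is fitted on the
#' selection, the canonical axes are tested sequentially by permutation, and
#' every taxon's raw biovolume series is attributed to the significant axis
#' it tracks most closely (Spearman), or declared stochastic.
#'
#' The number of significant canonical axes is the community's cross-scale
#' structure (number of distinct temporal scales); the taxa attributed to
#' each axis measure within-scale richness; the remainder are the stochastic
#' species. Together these are the resilience attributes the model
#' quantifies.
#'
#' @param cts a [community_ts()] (or a bare biovolume matrix).
#' @param alpha significance level for the global test, forward selection
#'   and axis tests.
#' @param alpha_species significance level for the per-taxon Spearman
#'   screen.
#' @param n_perm permutations per test (>= 99).
#' @param seed integer seed; all permutation streams derive from it.
#' @param p_adjust_method optional multiplicity correction for the Spearman
#'   screen (a [stats::p.adjust()] method; `"none"` by default).
#' @return An object of class `scale_rda` with components `basis`
#'   ([aem()]), `selection` (forward-selection trace), `selected` (AEM
#'   names), `axes` (per-axis eigenvalue/F/p table), `n_scales`,
#'   `attribution` ([attribute_species()] result or `NULL` for an empty
#'   model), `r2`, `adj_r2`, `lc_scores`, `species_scores`, `coefficients`,
#'   and the call. Supports `print`, `summary`, `coef`, `fitted`,
#'   `residuals`, `predict` and `plot`.
#' @examples
#' sim <- simulate_community(seed = 42)
#' fit <- scale_rda(sim$community, n_perm = 199, seed = 1)
#' fit
#' summary(fit)
#' @export
scale_rda <- function(cts, alpha = 0.05, alpha_species = 0.05, n_perm = 999,
                      seed = NULL, p_adjust_method = "none") {
  if (!inherits(cts, "community_ts")) cts <- community_ts(as.matrix(cts))
  Y <- cts$biovolume
  n <- nrow(Y)
  Yt <- hellinger(Y)
  basis <- aem(n)
  X_all <- aem_predictors(basis)

  if (!is.null(seed)) set.seed(as.integer(seed))
  fs <- forward_select(Yt, X_all, alpha = alpha, n_perm = n_perm)

  out <- list(community = cts, basis = basis, selection = fs$order,
              selected = colnames(X_all)[fs$selected],
              global = fs$global, alpha = alpha,
              alpha_species = alpha_species, n_perm = n_perm, seed = seed,
              call = match.call())
  class(out) <- "scale_rda"

  if (!length(fs$selected)) {
    # no significant temporal structure: empty model, all taxa stochastic
    out$n_scales <- 0L
    out$r2 <- 0; out$adj_r2 <- 0
    out$axes <- NULL; out$core <- NULL
    out$attribution <- empty_attribution(cts$taxa)
    return(out)
  }

  X <- X_all[, fs$selected, drop = FALSE]
  core <- rda_core(Yt, X)
  out$core <- core
  out$r2 <- core$r2
  out$adj_r2 <- adjusted_r2(core$r2, n, ncol(X))
  out$coefficients <- core$coefficients
  out$lc_scores <- core$lc_scores
  out$species_scores <- core$species_scores

  out$axes <- test_axes(core, alpha = alpha, n_perm = n_perm)
  # per-axis explanatory power: eigenvalue share of the model adjusted R2
  out$axes$adj_r2 <- out$adj_r2 * core$eig / sum(core$eig)
  out$n_scales <- sum(out$axes$significant)

  out$attribution <- attribute_species(cts, out, alpha_species = alpha_species,
                                       p_adjust_method = p_adjust_method)
  out
}

#' @export
print.scale_rda <- function(x, ...) {
  cat("Scale-specific community time series model (RDA on AEM basis)\n")
  cts <- x$community
  cat(sprintf("  %s%s%d time steps, %d taxa\n",
              if (!is.na(cts$site_id)) paste0("site ", cts$site_id, ", ") else "",
              if (!is.na(cts$state_id)) paste0("state ", cts$state_id, ", ") else "",
              nrow(cts$biovolume), length(cts$taxa)))
  cat(sprintf("  global model: R2 = %.3f, adj R2 = %.3f, p = %.4g\n",
              x$global$r2, x$global$adj_r2, x$global$p_value))
  if (length(x$selected)) {
    cat(sprintf("  selected predictors: %s (adj R2 = %.3f)\n",
                paste(x$selected, collapse = ", "), x$adj_r2))
    cat(sprintf("  %d significant canonical ax%s (temporal scales)\n",
                x$n_scales, if (x$n_scales == 1) "is" else "es"))
  } else {
    cat("  no predictors selected: no detectable temporal structure\n")
  }
  cat(sprintf("  stochastic taxa: %d of %d (%d%%)\n",
              x$attribution$counts[["Stochastic"]], x$attribution$total,
              x$attribution$percentages[["Stochastic"]]))
  invisible(x)
}

#' @export
summary.scale_rda <- function(object, ...) {
  structure(list(fit = object), class = "summary.scale_rda")
}

#' @export
print.summary.scale_rda <- function(x, ...) {
  f <- x$fit
  print(f)
  if (!is.null(f$selection)) {
    cat("\nForward selection trace:\n")
    print(f$selection, row.names = FALSE, digits = 4)
  }
  if (!is.null(f$axes)) {
    cat("\nCanonical axes (sequential permutation tests):\n")
    print(f$axes, row.names = FALSE, digits = 4)
  }
  if (!is.null(f$attribution)) {
    cat("\nSpecies attribution:\n")
    print(f$attribution)
  }
  invisible(x)
}

#' @export
coef.scale_rda <- function(object, ...) object$coefficients

#' @export
fitted.scale_rda <- function(object, ...) {
  if (is.null(object$core)) return(NULL)
  f <- object$core$fitted
  dimnames(f) <- dimnames(object$community$biovolume)
  f
}

#' @export
residuals.scale_rda <- function(object, ...) {
  if (is.null(object$core)) return(NULL)
  r <- object$core$Yc - object$core$fitted
  dimnames(r) <- dimnames(object$community$biovolume)
  r
}

#' Predict modelled (centred Hellinger-scale) community trajectories
#'
#' @param object a fitted [scale_rda()].
#' @param newdata optional matrix of predictor values with one column per
#'   selected AEM variable (centred like the training predictors); default
#'   re-predicts the training window.
#' @param ... unused.
#' @return Matrix of predicted centred Hellinger-transformed biovolumes.
#' @export
predict.scale_rda <- function(object, newdata = NULL, ...) {
  if (is.null(object$core)) stop("empty model: nothing to predict")
  if (is.null(newdata)) return(fitted(object))
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$selected))
    stop("newdata must have ", length(object$selected), " columns (",
         paste(object$selected, collapse = ", "), ")")
  X %*% object$core$coefficients
}

#' Plot modelled temporal patterns (lc scores)
#'
#' Draws the linear-combination site scores of the significant canonical
#' axes against time: one curve per detected temporal scale, slow to fast.
#'
#' @param x a fitted [scale_rda()].
#' @param which axes to draw; defaults to the significant ones.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.scale_rda <- function(x, which = NULL, ...) {
  if (is.null(x$lc_scores)) {
    warning("empty model: nothing to plot")
    return(invisible(x))
  }
  if (is.null(which)) which <- seq_len(max(x$n_scales, 1L))
  lc <- x$lc_scores[, which, drop = FALSE]
  lab <- sprintf("%s (adj R2 = %.3f)", colnames(lc), x$axes$adj_r2[which])
  matplot(x$community$times, lc, type = "l", lty = 1, lwd = 2,
          xlab = "time (months)", ylab = "lc score", ...)
  legend("topright", lab, col = seq_along(which), lty = 1, lwd = 2,
         bty = "n", cex = 0.8)
  invisible(x)
}

#' Extract site (lc) or species scores
#'
#' @param x a fitted [scale_rda()].
#' @param display `"lc"` (site scores: linear combinations of the selected
#'   AEM variables) or `"species"` (taxon loadings).
#' @param ... unused.
#' @return Score matrix.
#' @importFrom vegan scores
#' @method scores scale_rda
#' @export
scores.scale_rda <- function(x, display = c("lc", "species"), ...) {
  display <- match.arg(display)
  if (display == "lc") x$lc_scores else x$species_scores
}
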