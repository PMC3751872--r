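#' Unfold a correlation-matrix spectrum
#'
#' Maps sorted distinct eigenvalues onto a uniform density by fitting a
#' smoothing spline to the empirical cumulative count, so that
#' nearest-neighbour spacings can be compared across spectra.  Exact
#' degeneracies (e.g. the unit eigenvalues contributed by genes isolated
#' by pruning) carry no spacing information and are collapsed first.
#'
#' @param eigenvalues numeric vector of eigenvalues.
#' @param df degrees of freedom of the smoothing spline.
#' @return numeric vector of unfolded eigenvalue positions (ascending).
#' @export
unfoldEigenvalues <- function(eigenvalues, df = 10) {
    ev <- sort(round(eigenvalues, 8))
    x <- unique(ev)
    if (length(x) < 5) return(numeric(0))
    cumCount <- cumsum(as.numeric(table(factor(ev, levels = x))))
    fit <- stats::smooth.spline(x, cumCount,
                                df = min(df, length(x) - 1))
    stats::predict(fit, x)$y
}

#' Nearest-neighbour spacings of an unfolded spectrum
#'
#' @param unfolded ascending unfolded eigenvalue positions.
#' @return spacings normalised to unit mean (non-positive spacings from
#'   spline overshoot are dropped).
#' @export
nnsdSpacings <- function(unfolded) {
    s <- diff(unfolded)
    s <- s[s > 0]
    if (length(s) == 0) return(numeric(0))
    s / mean(s)
}

#' Chi-square goodness of fit of spacings to the Poisson (exponential) law
#'
#' Tests whether unit-mean nearest-neighbour spacings follow the
#' exponential distribution that characterises Poisson eigenvalue
#' statistics (uncorrelated spectra), as opposed to the Wigner-Dyson
#' (GOE) repulsion of a noise-dominated correlation matrix.  Binning uses
#' about `sqrt(n)` equal-probability bins under the exponential law,
#' capped so every expected count is at least 5; degrees of freedom are
#' bins - 2 (one for the total, one for the fitted mean).
#'
#' @param spacings unit-mean spacings ([nnsdSpacings()]).
#' @return list with `statistic`, `df`, `p.value`, `n`.
#' @export
nnsdPoissonTest <- function(spacings) {
    n <- length(spacings)
    if (n < 15)
        return(list(statistic = NA_real_, df = NA_integer_,
                    p.value = NA_real_, n = n))
    k <- max(3L, min(floor(sqrt(n)), floor(n / 5)))
    edges <- stats::qexp(seq(0, 1, length.out = k + 1))
    obs <- table(cut(spacings, breaks = edges, include.lowest = TRUE))
    expd <- n / k
    stat <- sum((as.numeric(obs) - expd)^2 / expd)
    df <- k - 2L
    list(statistic = stat, df = df,
         p.value = stats::pchisq(stat, df, lower.tail = FALSE), n = n)
}

#' Select a correlation threshold by random-matrix-theory criteria
#'
#' Walks an ascending grid of candidate thresholds; at each, off-diagonal
#' correlations below the candidate are zeroed, the eigenvalue spectrum
#' of the pruned matrix is unfolded, and the nearest-neighbour spacing
#' distribution (NNSD) is tested against the Poisson (exponential) form.
#' The selected threshold is the smallest candidate at which Poisson
#' statistics are not rejected (`p > alpha`) - the point where the
#' spectrum has shed the noise-driven GOE correlations.  If no candidate
#' is accepted (including when spectra are too degenerate to test), the
#' grid maximum is returned with a warning.
#'
#' @param cm symmetric gene-gene Pearson correlation matrix (unit
#'   diagonal), at least 10 x 10.
#' @param grid ascending candidate thresholds in (0, 1].
#' @param alpha significance level of the NNSD test.
#' @return list with `threshold`, and a per-candidate data.frame `trace`
#'   (`threshold`, `nSpacings`, `p.value`, `accepted`).
#' @export
rmtThreshold <- function(cm, grid = seq(0.50, 0.99, by = 0.01),
                         alpha = 0.05) {
    cm <- as.matrix(cm)
    if (nrow(cm) < 10)
        stop("correlation matrix must be at least 10 x 10 to unfold")
    if (is.unsorted(grid) || any(grid <= 0) || any(grid > 1))
        stop("grid must be ascending within (0, 1]")
    trace <- data.frame(threshold = grid, nSpacings = NA_integer_,
                        p.value = NA_real_, accepted = FALSE)
    for (i in seq_along(grid)) {
        pruned <- cm
        pruned[abs(pruned) < grid[i]] <- 0
        diag(pruned) <- 1
        ev <- eigen(pruned, symmetric = TRUE, only.values = TRUE)$values
        sp <- nnsdSpacings(unfoldEigenvalues(ev))
        test <- nnsdPoissonTest(sp)
        trace$nSpacings[i] <- test$n
        trace$p.value[i] <- test$p.value
        if (!is.na(test$p.value) && test$p.value > alpha) {
            trace$accepted[i] <- TRUE
            return(list(threshold = grid[i], trace = trace))
        }
    }
    warning("no candidate threshold reached Poisson spacing statistics; ",
            "returning the grid maximum")
    list(threshold = grid[length(grid)], trace = trace)
}
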